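#' @rdname MRIVolume-class
#' @param x an object with voxel data
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @rdname MRIVolume-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname LabelVolume-class
#' @param x a LabelVolume
#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))

#' @rdname GibbsFilterPair-class
#' @param x a GibbsFilterPair
#' @export
setGeneric("gxFilter", function(x) standardGeneric("gxFilter"))

#' @rdname GibbsFilterPair-class
#' @export
setGeneric("gyFilter", function(x) standardGeneric("gyFilter"))

#' @rdname BiasFieldResult-class
#' @param x a BiasFieldResult
#' @export
setGeneric("correctedVolume", function(x) standardGeneric("correctedVolume"))

#' @rdname BiasFieldResult-class
#' @export
setGeneric("biasField", function(x) standardGeneric("biasField"))

#' @rdname BiasFieldResult-class
#' @export
setGeneric("residualLogFields", function(x) standardGeneric("residualLogFields"))

#' @rdname BiasFieldResult-class
#' @export
setGeneric("iterationsRun", function(x) standardGeneric("iterationsRun"))

#' @rdname BiasFieldResult-class
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname NyulModel-class
#' @param x a NyulModel
#' @export
setGeneric("landmarks", function(x) standardGeneric("landmarks"))

#' @rdname NyulModel-class
#' @export
setGeneric("percentileSchedule", function(x) standardGeneric("percentileSchedule"))

#' @rdname NyulModel-class
#' @export
setGeneric("standardRange", function(x) standardGeneric("standardRange"))

#' @rdname PreprocSequence-class
#' @param x a PreprocSequence
#' @export
setGeneric("sequenceName", function(x) standardGeneric("sequenceName"))

#' @rdname PreprocSequence-class
#' @export
setGeneric("sequenceStages", function(x) standardGeneric("sequenceStages"))

#' @rdname RunRecord-class
#' @param x a RunRecord
#' @export
setGeneric("stageStats", function(x) standardGeneric("stageStats"))
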
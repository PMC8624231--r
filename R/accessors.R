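#' Construct an MRIVolume
#'
#' @param data 3D numeric array of intensities.
#' @param spacing mm per voxel per axis (recycled if scalar).
#' @return an [MRIVolume-class] object.
#' @examples
#' v <- mriVolume(array(rnorm(8), c(2, 2, 2)))
#' dim(v)
#' @export
mriVolume <- function(data, spacing = c(1, 1, 1)) {
  if (is.null(dim(data))) dim(data) <- c(length(data), 1L, 1L)
  storage.mode(data) <- "double"
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("MRIVolume", data = data, spacing = as.numeric(spacing))
}

#' Construct a LabelVolume
#'
#' @param labels 3D array of integer labels.
#' @param spacing mm per voxel per axis.
#' @return a [LabelVolume-class] object.
#' @export
labelVolume <- function(labels, spacing = c(1, 1, 1)) {
  if (is.null(dim(labels))) dim(labels) <- c(length(labels), 1L, 1L)
  storage.mode(labels) <- "integer"
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("LabelVolume", labels = labels, spacing = as.numeric(spacing))
}

#' @rdname MRIVolume-class
#' @export
setMethod("volData", "MRIVolume", function(x) x@data)

#' @rdname MRIVolume-class
#' @export
setMethod("voxelSpacing", "MRIVolume", function(x) x@spacing)

#' @rdname LabelVolume-class
#' @export
setMethod("voxelSpacing", "LabelVolume", function(x) x@spacing)

#' @rdname LabelVolume-class
#' @export
setMethod("labelData", "LabelVolume", function(x) x@labels)

#' @rdname MRIVolume-class
#' @export
setMethod("dim", "MRIVolume", function(x) dim(x@data))

#' @rdname LabelVolume-class
#' @export
setMethod("dim", "LabelVolume", function(x) dim(x@labels))

#' @rdname GibbsFilterPair-class
#' @export
setMethod("gxFilter", "GibbsFilterPair", function(x) x@gx)

#' @rdname GibbsFilterPair-class
#' @export
setMethod("gyFilter", "GibbsFilterPair", function(x) x@gy)

#' @rdname BiasFieldResult-class
#' @export
setMethod("correctedVolume", "BiasFieldResult", function(x) x@corrected)

#' @rdname BiasFieldResult-class
#' @export
setMethod("biasField", "BiasFieldResult", function(x) x@field)

#' @rdname BiasFieldResult-class
#' @export
setMethod("residualLogFields", "BiasFieldResult", function(x) x@residualLogFields)

#' @rdname BiasFieldResult-class
#' @export
setMethod("iterationsRun", "BiasFieldResult", function(x) x@iterations)

#' @rdname BiasFieldResult-class
#' @export
setMethod("isConverged", "BiasFieldResult", function(x) x@converged)

#' @rdname NyulModel-class
#' @export
setMethod("landmarks", "NyulModel", function(x) x@landmarks)

#' @rdname NyulModel-class
#' @export
setMethod("percentileSchedule", "NyulModel", function(x) x@schedule)

#' @rdname NyulModel-class
#' @export
setMethod("standardRange", "NyulModel", function(x) x@standardRange)

#' @rdname PreprocSequence-class
#' @export
setMethod("sequenceName", "PreprocSequence", function(x) x@name)

#' @rdname PreprocSequence-class
#' @export
setMethod("sequenceStages", "PreprocSequence", function(x) x@stages)

#' @rdname RunRecord-class
#' @export
setMethod("stageStats", "RunRecord", function(x) x@stats)

#' Parameter constructors
#'
#' Convenience constructors with the package defaults.
#'
#' @param numShifts,minWindow,maxWindow,slicePlane see [UnringParams-class].
#' @return the corresponding parameter object.
#' @export
unringParams <- function(numShifts = 20L, minWindow = 1L, maxWindow = 3L,
                         slicePlane = c(1L, 2L)) {
  new("UnringParams", numShifts = as.integer(numShifts),
      minWindow = as.integer(minWindow), maxWindow = as.integer(maxWindow),
      slicePlane = as.integer(slicePlane))
}

#' @rdname unringParams
#' @param maxIterations,convergenceThreshold,histogramBins,sharpenFWHM,wienerNoise,smoothingScale
#'   see [BiasParams-class].
#' @export
biasParams <- function(maxIterations = 50L, convergenceThreshold = 0.001,
                       histogramBins = 200L, sharpenFWHM = 0.15,
                       wienerNoise = 0.01, smoothingScale = NA_real_) {
  new("BiasParams", maxIterations = as.integer(maxIterations),
      convergenceThreshold = convergenceThreshold,
      histogramBins = as.integer(histogramBins), sharpenFWHM = sharpenFWHM,
      wienerNoise = wienerNoise, smoothingScale = as.numeric(smoothingScale))
}

#' @rdname unringParams
#' @param tiles,bins,clipLimit see [AHEParams-class].
#' @export
aheParams <- function(tiles = c(8L, 8L, 4L), bins = 256L,
                      clipLimit = NA_real_) {
  if (length(tiles) == 1L) tiles <- rep(tiles, 3L)
  new("AHEParams", tiles = as.integer(tiles), bins = as.integer(bins),
      clipLimit = as.numeric(clipLimit))
}

#' @rdname PreprocStage-class
#' @param kind stage kind ("gibbs", "bias", "zscore", "nyul", "ahe").
#' @param params matching parameter object, or NULL for defaults.
#' @export
preprocStage <- function(kind, params = NULL) {
  new("PreprocStage", kind = kind, params = params)
}

#' @rdname PreprocSequence-class
#' @param name label for the sequence.
#' @param stages list of [PreprocStage-class] objects.
#' @export
preprocSequence <- function(name, stages) {
  new("PreprocSequence", name = name, stages = stages)
}
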
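#' @import methods
#' @importFrom stats approx fft mvfft nextn quantile rnorm sd
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' MRIVolume: a single-channel 3D scalar image
#'
#' The universal currency of all pre-processing stages: a 3D array of
#' floating-point intensities together with the voxel spacing in millimetres.
#'
#' @slot data 3D numeric array of intensities (arbitrary units).
#' @slot spacing numeric(3), mm per voxel along each axis; strictly positive.
#'
#' @seealso [mriVolume()], [volData()], [voxelSpacing()]
#' @export
setClass("MRIVolume",
  representation(data = "array", spacing = "numeric"),
  prototype(data = array(0, c(1, 1, 1)), spacing = c(1, 1, 1))
)

setValidity("MRIVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "data must be finite everywhere")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three strictly positive numbers")
  if (length(msg)) msg else TRUE
})

#' LabelVolume: an integer-valued segmentation map
#'
#' Voxel labels follow the BraTS dialect: 0 = background, 1 = necrotic /
#' non-enhancing core, 2 = edema, 4 = enhancing tumor. The three nested
#' evaluation regions derive from these: whole = \{1, 2, 4\}, core = \{1, 4\},
#' enhancing = \{4\}.
#'
#' @slot labels 3D integer array.
#' @slot spacing numeric(3), mm per voxel.
#'
#' @seealso [labelVolume()], [regionMasks()], [regionDice()]
#' @export
setClass("LabelVolume",
  representation(labels = "array", spacing = "numeric"),
  prototype(labels = array(0L, c(1, 1, 1)), spacing = c(1, 1, 1))
)

setValidity("LabelVolume", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  if (!is.integer(object@labels))
    msg <- c(msg, "labels must be stored as integers")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three strictly positive numbers")
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: geometry of a synthetic brain-like phantom
#'
#' Describes a piecewise-constant scene of (rotated) ellipsoids plus an
#' optional nested tumor: three concentric ellipsoids encoding the whole /
#' core / enhancing subregions. Nesting is guaranteed by construction: the
#' core and enhancing ellipsoids are the whole-tumor ellipsoid scaled by
#' \code{coreFrac} and \code{enhFrac}.
#'
#' @slot shape integer(3) voxel dimensions.
#' @slot spacing numeric(3) mm per voxel.
#' @slot ellipsoids list of ellipsoid descriptors, each a list with elements
#'   \code{center} (voxel coords), \code{axes} (semi-axes, voxels),
#'   \code{angles} (Euler rotation angles, radians) and \code{level}
#'   (intensity).
#' @slot tumor either an empty list (no tumor) or a list with \code{center},
#'   \code{axes}, \code{angles}, \code{coreFrac}, \code{enhFrac} and
#'   \code{levels} (named intensities for whole/core/enhancing).
#' @slot jitter fractional random perturbation applied to centers, semi-axes
#'   and intensity levels so that different seeds give different phantoms.
#' @slot seed integer RNG seed; identical seeds give bitwise-identical output.
#'
#' @seealso [phantomSpec()], [makePhantom()]
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric", ellipsoids = "list",
                 tumor = "list", jitter = "numeric", seed = "integer")
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be three positive integers")
  for (e in object@ellipsoids) {
    if (!all(c("center", "axes", "level") %in% names(e)))
      msg <- c(msg, "each ellipsoid needs center, axes and level")
    else if (any(e$axes <= 0))
      msg <- c(msg, "all semi-axes must be > 0")
  }
  if (length(object@tumor)) {
    tm <- object@tumor
    if (any(tm$axes <= 0)) msg <- c(msg, "tumor semi-axes must be > 0")
    if (!(tm$enhFrac <= tm$coreFrac && tm$coreFrac <= 1))
      msg <- c(msg, "tumor fractions must satisfy enhFrac <= coreFrac <= 1")
  }
  if (object@jitter < 0) msg <- c(msg, "jitter must be >= 0")
  if (length(msg)) msg else TRUE
})

#' BiasFieldSpec: a smooth synthetic multiplicative bias field
#'
#' The log-field is standardized to zero mean over the volume with maximum
#' absolute value \code{log(amplitude)}, so the generated field lies within
#' \code{[1/amplitude, amplitude]} and carries unit geometric mean -- the
#' identifiable parameterization of the multiplicative model V = u f.
#'
#' @slot kind "gaussian-bump" or "polynomial" (low-order).
#' @slot amplitude multiplicative range bound a >= 1.
#' @slot scale smoothness scale in voxels (bump width / polynomial span).
#' @slot seed integer RNG seed.
#'
#' @seealso [biasFieldSpec()], [addBiasField()]
#' @export
setClass("BiasFieldSpec",
  representation(kind = "character", amplitude = "numeric", scale = "numeric",
                 seed = "integer")
)

setValidity("BiasFieldSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("gaussian-bump", "polynomial"))
    msg <- c(msg, "kind must be 'gaussian-bump' or 'polynomial'")
  if (object@amplitude < 1) msg <- c(msg, "amplitude must be >= 1")
  if (object@scale <= 0) msg <- c(msg, "scale must be > 0")
  if (length(msg)) msg else TRUE
})

#' GibbsFilterPair: directional k-space weighting filters
#'
#' The weights Gx and Gy on the centered frequency grid (kx, ky in [-pi, pi)):
#' Gx = (1 + cos ky) / ((1 + cos ky) + (1 + cos kx)) and Gy its counterpart,
#' with Gx = Gy = 1/2 at the double Nyquist point where both terms vanish.
#' Gy is stored as 1 - Gx so the normalization Gx + Gy = 1 is exact in
#' floating point.
#'
#' @slot gx,gy numeric matrices over the centered frequency grid, in [0, 1].
#'
#' @seealso [gibbsWeightFilters()], [unringSlice()]
#' @export
setClass("GibbsFilterPair",
  representation(gx = "matrix", gy = "matrix")
)

setValidity("GibbsFilterPair", function(object) {
  msg <- character()
  if (!identical(dim(object@gx), dim(object@gy)))
    msg <- c(msg, "gx and gy must have identical dimensions")
  if (any(object@gx < 0 | object@gx > 1) || any(object@gy < 0 | object@gy > 1))
    msg <- c(msg, "filter weights must lie in [0, 1]")
  if (any(object@gx + object@gy != 1))
    msg <- c(msg, "gx + gy must equal 1 at every frequency")
  if (length(msg)) msg else TRUE
})

#' UnringParams: tuning of the sub-voxel-shift Gibbs removal
#'
#' @slot numShifts number of sub-voxel shift candidates per side; the search
#'   covers 2 numShifts + 1 shifts s = t / (2 numShifts), t = -numShifts ...
#'   numShifts.
#' @slot minWindow,maxWindow neighborhood extent (voxels) of the oscillation
#'   measure on each side of a voxel.
#' @slot slicePlane integer(2): the axis pair over which 2D unringing runs
#'   (default axial, the first two storage axes).
#'
#' @seealso [unringParams()], [unringVolume()]
#' @export
setClass("UnringParams",
  representation(numShifts = "integer", minWindow = "integer",
                 maxWindow = "integer", slicePlane = "integer"),
  prototype(numShifts = 20L, minWindow = 1L, maxWindow = 3L,
            slicePlane = c(1L, 2L))
)

setValidity("UnringParams", function(object) {
  msg <- character()
  if (object@numShifts < 1L) msg <- c(msg, "numShifts must be >= 1")
  if (!(object@minWindow >= 1L && object@minWindow <= object@maxWindow))
    msg <- c(msg, "need 1 <= minWindow <= maxWindow")
  if (length(object@slicePlane) != 2L ||
      any(!object@slicePlane %in% 1:3) ||
      object@slicePlane[1] == object@slicePlane[2])
    msg <- c(msg, "slicePlane must be two distinct axes in 1:3")
  if (length(msg)) msg else TRUE
})

#' BiasParams: tuning of the iterative bias field correction
#'
#' @slot maxIterations iteration cap of the residual-field loop.
#' @slot convergenceThreshold coefficient of variation of the ratio between
#'   successive field estimates below which the loop stops.
#' @slot histogramBins bins of the log-intensity histogram.
#' @slot sharpenFWHM full width at half maximum of the assumed log-intensity
#'   blur, as a fraction of the masked log-intensity range.
#' @slot wienerNoise noise constant of the Wiener deconvolution.
#' @slot smoothingScale FWHM (mm) of the Gaussian field-smoothing operator;
#'   NA means one third of the smallest masked extent.
#'
#' @seealso [biasParams()], [correctBiasField()]
#' @export
setClass("BiasParams",
  representation(maxIterations = "integer", convergenceThreshold = "numeric",
                 histogramBins = "integer", sharpenFWHM = "numeric",
                 wienerNoise = "numeric", smoothingScale = "numeric"),
  prototype(maxIterations = 50L, convergenceThreshold = 0.001,
            histogramBins = 200L, sharpenFWHM = 0.15, wienerNoise = 0.01,
            smoothingScale = NA_real_)
)

setValidity("BiasParams", function(object) {
  msg <- character()
  if (object@maxIterations < 1L) msg <- c(msg, "maxIterations must be >= 1")
  if (!(object@convergenceThreshold > 0 && object@convergenceThreshold < 1))
    msg <- c(msg, "convergenceThreshold must be in (0, 1)")
  if (object@histogramBins < 2L) msg <- c(msg, "histogramBins must be >= 2")
  if (object@sharpenFWHM <= 0) msg <- c(msg, "sharpenFWHM must be > 0")
  if (object@wienerNoise <= 0) msg <- c(msg, "wienerNoise must be > 0")
  if (!is.na(object@smoothingScale) && object@smoothingScale <= 0)
    msg <- c(msg, "smoothingScale must be > 0 (or NA for automatic)")
  if (length(msg)) msg else TRUE
})

#' BiasFieldResult: output of the iterative bias correction
#'
#' Bookkeeping identities hold to floating point: the log field equals the
#' sum of the residual log fields, and on the mask the log corrected image
#' plus the log field equals the log input.
#'
#' @slot corrected the corrected volume (intensity units).
#' @slot field the multiplicative bias field estimate (unitless, positive).
#' @slot residualLogFields list of per-iteration residual log fields (arrays).
#' @slot iterations number of iterations run.
#' @slot converged whether the convergence criterion fired before the cap.
#' @slot mask logical array: voxels that entered the estimation.
#'
#' @seealso [correctBiasField()], [correctedVolume()], [biasField()]
#' @export
setClass("BiasFieldResult",
  representation(corrected = "MRIVolume", field = "MRIVolume",
                 residualLogFields = "list", iterations = "integer",
                 converged = "logical", mask = "array")
)

#' NyulModel: learned landmarks of the piecewise linear intensity mapping
#'
#' @slot schedule strictly increasing percentiles (default 1, 10, ..., 90, 99).
#' @slot landmarks mean landmark intensities on the standard scale,
#'   non-decreasing and within the standard range.
#' @slot standardRange the (s1, s2) span of the standard scale.
#'
#' @seealso [nyulTrain()], [nyulApply()]
#' @export
setClass("NyulModel",
  representation(schedule = "numeric", landmarks = "numeric",
                 standardRange = "numeric")
)

setValidity("NyulModel", function(object) {
  msg <- character()
  if (any(diff(object@schedule) <= 0))
    msg <- c(msg, "percentile schedule must be strictly increasing")
  if (length(object@landmarks) != length(object@schedule))
    msg <- c(msg, "one landmark per scheduled percentile required")
  if (any(diff(object@landmarks) < 0))
    msg <- c(msg, "landmarks must be non-decreasing")
  if (length(object@standardRange) != 2L ||
      diff(object@standardRange) <= 0)
    msg <- c(msg, "standardRange must be an increasing pair")
  tol <- 1e-8 * diff(object@standardRange)
  if (length(object@landmarks) &&
      (min(object@landmarks) < object@standardRange[1] - tol ||
       max(object@landmarks) > object@standardRange[2] + tol))
    msg <- c(msg, "landmarks must lie within the standard range")
  if (length(msg)) msg else TRUE
})

#' AHEParams: tuning of block-based 3D adaptive histogram equalization
#'
#' @slot tiles integer(3): per-axis tile counts partitioning the volume.
#' @slot bins histogram bins per tile.
#' @slot clipLimit optional contrast-limit fraction of the tile voxel count;
#'   NA means plain (unclipped) adaptive equalization.
#'
#' @seealso [aheParams()], [aheEqualize()]
#' @export
setClass("AHEParams",
  representation(tiles = "integer", bins = "integer", clipLimit = "numeric"),
  prototype(tiles = c(8L, 8L, 4L), bins = 256L, clipLimit = NA_real_)
)

setValidity("AHEParams", function(object) {
  msg <- character()
  if (length(object@tiles) != 3L || any(object@tiles < 1L))
    msg <- c(msg, "tiles must be three counts >= 1")
  if (object@bins < 2L) msg <- c(msg, "bins must be >= 2")
  if (!is.na(object@clipLimit) && object@clipLimit <= 0)
    msg <- c(msg, "clipLimit must be > 0 (or NA for no clipping)")
  if (length(msg)) msg else TRUE
})

#' PreprocStage: one stage of a pre-processing sequence
#'
#' @slot kind one of "gibbs", "bias", "zscore", "nyul", "ahe".
#' @slot params the matching parameter object (or NULL for stage defaults).
#'
#' @seealso [preprocStage()], [presetSequence()], [runSequence()]
#' @export
setClass("PreprocStage", representation(kind = "character", params = "ANY"))

setValidity("PreprocStage", function(object) {
  kinds <- c("gibbs", "bias", "zscore", "nyul", "ahe")
  if (!object@kind %in% kinds)
    return(sprintf("kind must be one of: %s", paste(kinds, collapse = ", ")))
  TRUE
})

#' PreprocSequence: an ordered pre-processing recipe
#'
#' Order is significant and preserved; the ten named presets are available
#' through [presetSequence()].
#'
#' @slot name preset identifier or free-form label.
#' @slot stages ordered list of [PreprocStage-class] objects.
#'
#' @seealso [presetSequence()], [runSequence()]
#' @export
setClass("PreprocSequence",
  representation(name = "character", stages = "list")
)

setValidity("PreprocSequence", function(object) {
  if (!all(vapply(object@stages, is, logical(1), class2 = "PreprocStage")))
    return("all stages must be PreprocStage objects")
  TRUE
})

#' RunRecord: provenance of one pipeline run
#'
#' Captures everything needed to re-run the pipeline identically: sequence
#' name, per-stage parameters, seed, package version, timestamps, and masked
#' mean/sd summary statistics before and after every stage.
#'
#' @slot sequenceName name of the executed sequence.
#' @slot stages list of stage descriptors (kind + parameters).
#' @slot stats data.frame with one row per stage: masked mean/sd before and
#'   after, and elapsed seconds.
#' @slot seed integer seed in force (NA if none).
#' @slot version package version string.
#' @slot startedAt,finishedAt POSIXct timestamps.
#'
#' @seealso [runSequence()]
#' @export
setClass("RunRecord",
  representation(sequenceName = "character", stages = "list",
                 stats = "data.frame", seed = "integer", version = "character",
                 startedAt = "POSIXct", finishedAt = "POSIXct")
)
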
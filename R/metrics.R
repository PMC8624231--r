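# Segmentation overlap metrics and phantom-suite image quality measures.

#' Dice overlap between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`. When both masks are empty the score is
#' defined as 1 (the masks agree on absence).
#'
#' @param pred,truth logical arrays of identical shape (numeric input is
#'   coerced with `!= 0`).
#' @return a fraction in `[0, 1]`.
#' @examples
#' diceScore(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
diceScore <- function(pred, truth) {
  if (is(pred, "LabelVolume")) pred <- labelData(pred) != 0
  if (is(truth, "LabelVolume")) truth <- labelData(truth) != 0
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop("mask shapes do not agree", call. = FALSE)
  pred <- pred != 0; truth <- truth != 0
  denom <- sum(pred) + sum(truth)
  if (denom == 0) return(1)
  2 * sum(pred & truth) / denom
}

#' Nested evaluation regions of a BraTS-style label map
#'
#' whole = labels \{1, 2, 4\}, core = \{1, 4\}, enhancing = \{4\}; by
#' construction enhancing is contained in core is contained in whole.
#'
#' @param labels a [LabelVolume-class] or integer array over \{0, 1, 2, 4\}.
#' @return list of logical arrays `whole`, `core`, `enhancing`.
#' @export
regionMasks <- function(labels) {
  if (is(labels, "LabelVolume")) labels <- labelData(labels)
  bad <- setdiff(unique(as.vector(labels)), c(0L, 1L, 2L, 4L))
  if (length(bad))
    stop("unknown label values: ", paste(sort(bad), collapse = ", "),
         call. = FALSE)
  list(whole = labels == 1L | labels == 2L | labels == 4L,
       core = labels == 1L | labels == 4L,
       enhancing = labels == 4L)
}

#' Per-region dice scores
#'
#' @param pred,truth [LabelVolume-class] objects (or integer arrays) in the
#'   same label dialect and of the same shape.
#' @return named numeric(3): dice for whole, core and enhancing regions.
#' @export
regionDice <- function(pred, truth) {
  pm <- regionMasks(pred)
  tm <- regionMasks(truth)
  if (!identical(dim(pm$whole), dim(tm$whole)))
    stop("label map shapes do not agree", call. = FALSE)
  c(whole = diceScore(pm$whole, tm$whole),
    core = diceScore(pm$core, tm$core),
    enhancing = diceScore(pm$enhancing, tm$enhancing))
}

#' Multiclass soft dice loss
#'
#' `L = -(2 / K) * sum_k [ sum_i l_ik m_ik / (sum_i l_ik + sum_i m_ik) ]`
#' where `l` holds per-voxel, per-class scores (softmax output) and `m` the
#' one-hot ground truth. A class with an all-zero denominator contributes 0.
#' The loss is bounded in `[-1, 0]`; perfect one-hot agreement gives exactly
#' -1 (each class term is 1/2), complete disagreement gives 0.
#'
#' @param softPred numeric matrix (voxels x classes), rows summing to 1
#'   within 1e-6, values in `[0, 1]`.
#' @param oneHotTruth 0/1 matrix of the same shape, rows summing to exactly 1.
#' @return scalar loss in `[-1, 0]`.
#' @export
multiclassDiceLoss <- function(softPred, oneHotTruth) {
  softPred <- as.matrix(softPred)
  oneHotTruth <- as.matrix(oneHotTruth)
  if (!identical(dim(softPred), dim(oneHotTruth)))
    stop("prediction and truth shapes do not agree", call. = FALSE)
  if (any(softPred < 0) || any(softPred > 1))
    stop("scores must lie in [0, 1]", call. = FALSE)
  if (any(abs(rowSums(softPred) - 1) > 1e-6))
    stop("per-voxel scores must sum to 1 across classes", call. = FALSE)
  if (!all(oneHotTruth %in% c(0, 1)) || any(rowSums(oneHotTruth) != 1))
    stop("truth must be one-hot encoded", call. = FALSE)
  K <- ncol(softPred)
  terms <- vapply(seq_len(K), function(k) {
    den <- sum(softPred[, k]) + sum(oneHotTruth[, k])
    if (den == 0) 0 else sum(softPred[, k] * oneHotTruth[, k]) / den
  }, numeric(1))
  -(2 / K) * sum(terms)
}

#' Image quality of a volume against a reference
#'
#' Masked root-mean-square error, peak signal-to-noise ratio
#' (`20 log10(peak / RMSE)` with peak the maximum absolute masked reference
#' intensity), and the ratio of masked means.
#'
#' @param vol,reference [MRIVolume-class] objects of identical shape.
#' @param mask logical array or NULL (all voxels).
#' @return named numeric: `rmse`, `psnr` (dB, `Inf` for identical inputs),
#'   `meanRatio`.
#' @export
imageQuality <- function(vol, reference, mask = NULL) {
  vol <- .asVolume(vol); reference <- .asVolume(reference, "reference")
  if (!identical(dim(vol), dim(reference)))
    stop("volume shapes do not agree", call. = FALSE)
  V <- volData(vol); R <- volData(reference)
  if (is.null(mask)) mask <- array(TRUE, dim(V))
  if (is(mask, "MRIVolume")) mask <- volData(mask) != 0
  rmse <- sqrt(mean((V[mask] - R[mask])^2))
  peak <- max(abs(R[mask]))
  psnr <- if (rmse == 0) Inf else 20 * log10(peak / rmse)
  mr <- mean(V[mask]) / mean(R[mask])
  c(rmse = rmse, psnr = psnr, meanRatio = mr)
}
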
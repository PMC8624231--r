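# Intensity normalization (z-score, Nyul landmark mapping) and block-based
# 3D adaptive histogram equalization.

#' Z-score intensity normalization
#'
#' Transforms masked voxels to zero mean and unit variance; voxels outside
#' the mask are set to 0, keeping the background the dominant class for
#' downstream segmentation. With no mask given, strictly positive voxels are
#' used (skull-stripped data have exact-zero backgrounds).
#'
#' @param vol an [MRIVolume-class].
#' @param mask logical array or [MRIVolume-class], or NULL.
#' @return the normalized [MRIVolume-class].
#' @export
zscoreNormalize <- function(vol, mask = NULL) {
  vol <- .asVolume(vol)
  V <- volData(vol)
  mask <- .resolveMask(V, mask)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  mu <- mean(V[mask])
  sg <- sd(V[mask])
  if (!is.finite(sg) || sg == 0)
    stop("masked intensities have zero variance; z-score is undefined",
         call. = FALSE)
  out <- array(0, dim(V))
  out[mask] <- (V[mask] - mu) / sg
  mriVolume(out, voxelSpacing(vol))
}

#' Learn a Nyul piecewise linear normalization model
#'
#' For each training volume the scheduled percentiles of the masked
#' intensities are computed; the volume's (p1, p99) span (the first and last
#' scheduled percentiles) is mapped affinely onto the standard range, and the
#' mapped landmarks are averaged across volumes. Because the span mapping is
#' affine, training volumes that differ only by an affine intensity transform
#' contribute identical landmarks.
#'
#' @param vols list of [MRIVolume-class] (a single volume is accepted).
#' @param masks optional list of masks matching `vols` (NULL entries default
#'   to strictly positive voxels).
#' @param schedule strictly increasing percentiles, default
#'   `c(1, 10, 20, ..., 90, 99)`.
#' @param standardRange the (s1, s2) span of the standard scale, default
#'   `c(1, 100)`.
#' @return a [NyulModel-class].
#' @export
nyulTrain <- function(vols, masks = NULL,
                      schedule = c(1, seq(10, 90, by = 10), 99),
                      standardRange = c(1, 100)) {
  if (is(vols, "MRIVolume")) vols <- list(vols)
  if (!length(vols)) stop("need at least one training volume", call. = FALSE)
  if (any(diff(schedule) <= 0))
    stop("percentile schedule must be strictly increasing", call. = FALSE)
  s1 <- standardRange[1]; s2 <- standardRange[2]
  lm <- vapply(seq_along(vols), function(i) {
    v <- .asVolume(vols[[i]])
    V <- volData(v)
    mask <- .resolveMask(V, if (is.null(masks)) NULL else masks[[i]])
    q <- quantile(V[mask], schedule / 100, names = FALSE, type = 7)
    if (q[length(q)] - q[1] <= 0)
      stop("degenerate masked intensity span in training volume ", i,
           call. = FALSE)
    s1 + (q - q[1]) * (s2 - s1) / (q[length(q)] - q[1])
  }, numeric(length(schedule)))
  new("NyulModel", schedule = schedule, landmarks = rowMeans(lm),
      standardRange = as.numeric(standardRange))
}

#' Apply a Nyul normalization model
#'
#' Computes the volume's own scheduled percentiles and maps intensities
#' piecewise-linearly, segment by segment, onto the model's standard
#' landmarks. Intensities beyond the outermost percentiles continue on the
#' terminal segments' slopes. The mapping is non-decreasing.
#'
#' @param vol an [MRIVolume-class].
#' @param model a [NyulModel-class] from [nyulTrain()].
#' @param mask logical array or NULL (strictly positive voxels). Percentiles
#'   are computed on the mask; the mapping is applied to masked voxels and
#'   unmasked voxels are set to 0.
#' @return the normalized [MRIVolume-class].
#' @export
nyulApply <- function(vol, model, mask = NULL) {
  vol <- .asVolume(vol)
  if (!is(model, "NyulModel")) stop("model must be a NyulModel", call. = FALSE)
  validObject(model)
  V <- volData(vol)
  mask <- .resolveMask(V, mask)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  q <- quantile(V[mask], model@schedule / 100, names = FALSE, type = 7)
  if (q[length(q)] - q[1] <= 0)
    stop("degenerate masked intensity span", call. = FALSE)
  out <- array(0, dim(V))
  out[mask] <- .piecewiseMap(V[mask], q, model@landmarks)
  mriVolume(out, voxelSpacing(vol))
}

# non-decreasing piecewise linear map q -> lm with terminal-slope
# extrapolation; duplicate abscissae (piecewise-constant data) are collapsed
.piecewiseMap <- function(x, q, lm) {
  keep <- !duplicated(q)
  q <- q[keep]; lm <- lm[keep]
  if (length(q) < 2L) return(rep(lm[1], length(x)))
  y <- approx(q, lm, xout = x, rule = 2, ties = "ordered")$y
  k <- length(q)
  sl1 <- (lm[2] - lm[1]) / (q[2] - q[1])
  sl2 <- (lm[k] - lm[k - 1]) / (q[k] - q[k - 1])
  lo <- x < q[1]; hi <- x > q[k]
  y[lo] <- lm[1] + (x[lo] - q[1]) * sl1
  y[hi] <- lm[k] + (x[hi] - q[k]) * sl2
  y
}

#' Persist a Nyul model as structured text
#'
#' @param model a [NyulModel-class].
#' @param path output file (JSON).
#' @return `path`, invisibly.
#' @export
writeNyulModel <- function(model, path) {
  validObject(model)
  jsonlite::write_json(
    list(schedule = model@schedule, landmarks = model@landmarks,
         standardRange = model@standardRange),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeNyulModel
#' @export
readNyulModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("NyulModel", schedule = as.numeric(x$schedule),
      landmarks = as.numeric(x$landmarks),
      standardRange = as.numeric(x$standardRange))
}

#' Block-based 3D adaptive histogram equalization
#'
#' Partitions the volume into `tiles` blocks, computes each block's histogram
#' over the global intensity range and its cumulative mapping onto that same
#' range, and transforms every voxel by trilinear interpolation among the
#' mappings of the eight surrounding block centers (boundary blocks
#' replicated). With `tiles = c(1, 1, 1)` this reduces exactly to global
#' histogram equalization. A block whose histogram occupies a single bin maps
#' by identity, so constant volumes pass through unchanged. An optional
#' contrast limit clips each block histogram at `clipLimit` times the block
#' voxel count and redistributes the excess uniformly.
#'
#' @param vol an [MRIVolume-class].
#' @param params an [AHEParams-class].
#' @return the equalized [MRIVolume-class], on the same intensity range as
#'   the input.
#' @export
aheEqualize <- function(vol, params = aheParams()) {
  vol <- .asVolume(vol)
  validObject(params)
  V <- volData(vol)
  d <- dim(V)
  tiles <- params@tiles
  if (any(tiles > d))
    stop("more tiles than voxels along an axis", call. = FALSE)
  B <- params@bins
  gmin <- min(V); gmax <- max(V)
  if (gmax <= gmin) return(vol)
  bw <- (gmax - gmin) / B
  bin <- pmin(pmax(floor((V - gmin) / bw) + 1L, 1L), B)
  tileOf <- lapply(1:3, function(a)
    pmin(floor((seq_len(d[a]) - 1L) / d[a] * tiles[a]) + 1L, tiles[a]))
  t1 <- tileOf[[1]][slice.index(V, 1)]
  t2 <- tileOf[[2]][slice.index(V, 2)]
  t3 <- tileOf[[3]][slice.index(V, 3)]
  tileLin <- t1 + tiles[1] * ((t2 - 1L) + tiles[2] * (t3 - 1L))
  nt <- prod(tiles)
  counts <- tabulate(bin + B * (tileLin - 1L), B * nt)
  dim(counts) <- c(B, nt)
  if (!is.na(params@clipLimit)) {
    tot <- colSums(counts)
    for (t in seq_len(nt)) {
      cap <- max(1, ceiling(params@clipLimit * tot[t]))
      excess <- sum(pmax(counts[, t] - cap, 0))
      counts[, t] <- pmin(counts[, t], cap) + excess / B
    }
  }
  tileN <- colSums(counts)
  # per-tile mapping evaluated at bin values: gmin + range * cdf(bin)
  Mmap <- gmin + (gmax - gmin) * (apply(counts, 2, cumsum) / rep(tileN, each = B))
  singleBin <- colSums(counts > 0) == 1L
  # per-axis interpolation coordinates among tile centers (replicated edges)
  axisInterp <- function(n, tcount) {
    edges <- floor((0:tcount) / tcount * n)
    centers <- (edges[-1] + edges[-length(edges)] + 1) / 2
    x <- seq_len(n)
    lo <- findInterval(x, centers)
    lo <- pmin(pmax(lo, 1L), tcount)
    hi <- pmin(lo + 1L, tcount)
    fr <- ifelse(hi == lo, 0, (x - centers[lo]) / (centers[hi] - centers[lo]))
    fr[x <= centers[1]] <- 0
    hi[x <= centers[1]] <- lo[x <= centers[1]]
    fr[x >= centers[tcount]] <- 0
    list(lo = lo, hi = hi, fr = pmin(pmax(fr, 0), 1))
  }
  ax <- lapply(1:3, function(a) axisInterp(d[a], tiles[a]))
  i1 <- slice.index(V, 1); i2 <- slice.index(V, 2); i3 <- slice.index(V, 3)
  out <- array(0, d)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    tx <- if (cx == 0) ax[[1]]$lo[i1] else ax[[1]]$hi[i1]
    wx <- if (cx == 0) 1 - ax[[1]]$fr[i1] else ax[[1]]$fr[i1]
    ty <- if (cy == 0) ax[[2]]$lo[i2] else ax[[2]]$hi[i2]
    wy <- if (cy == 0) 1 - ax[[2]]$fr[i2] else ax[[2]]$fr[i2]
    tz <- if (cz == 0) ax[[3]]$lo[i3] else ax[[3]]$hi[i3]
    wz <- if (cz == 0) 1 - ax[[3]]$fr[i3] else ax[[3]]$fr[i3]
    w <- wx * wy * wz
    if (all(w == 0)) next
    tl <- tx + tiles[1] * ((ty - 1L) + tiles[2] * (tz - 1L))
    cv <- Mmap[cbind(as.vector(bin), as.vector(tl))]
    sb <- singleBin[as.vector(tl)]
    cv[sb] <- V[sb]  # single-occupied-bin tiles map by identity
    out <- out + w * array(cv, d)
  }
  mriVolume(out, voxelSpacing(vol))
}
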
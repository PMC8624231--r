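# Internal numeric helpers shared across modules.

# DFT frequency index in native (DC-first) order: 0, 1, ..., -2, -1.
# For even n the single Nyquist sample is assigned to the negative side
# (-n/2), which keeps centered truncation windows symmetric with the extra
# sample on the negative-frequency side.
.freqIndex <- function(n) {
  m <- 0:(n - 1)
  hi <- m >= ceiling(n / 2)
  m[hi] <- m[hi] - n
  m
}

# logical keep-mask (native order) of the centered window retaining k samples
.keepMask <- function(n, keep) {
  m <- .freqIndex(n)
  m >= -floor(keep / 2) & m <= ceiling(keep / 2) - 1
}

.asVolume <- function(x, what = "vol") {
  if (!is(x, "MRIVolume"))
    stop(sprintf("'%s' must be an MRIVolume", what), call. = FALSE)
  x
}

# resolve a mask argument: NULL -> strictly positive voxels of `data`
.resolveMask <- function(data, mask, requirePositive = FALSE) {
  if (is.null(mask)) {
    mask <- data > 0
  } else {
    if (is(mask, "MRIVolume")) mask <- volData(mask) != 0
    if (!identical(dim(mask), dim(data)))
      stop("mask dimensions do not match the volume", call. = FALSE)
    mask <- as.logical(mask) & is.finite(data)
    dim(mask) <- dim(data)
    if (requirePositive) mask <- mask & data > 0
  }
  mask
}

# evaluate `expr` under a temporary RNG state seeded with `seed`;
# the caller's RNG state is restored afterwards
.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Gaussian low-pass of an nD array by FFT on a zero-padded grid.
# sigma is in voxels per axis. Returns the smoothed array; the padded kernel
# FFT can be precomputed with .gaussKernelFFT and reused across calls.
.gaussPadDims <- function(d, sigma) {
  vapply(seq_along(d), function(i)
    stats::nextn(d[i] + ceiling(4 * sigma[i]), c(2, 3, 5)), numeric(1))
}

.gaussKernelFFT <- function(padto, sigma) {
  ks <- lapply(seq_along(padto), function(i) {
    v <- exp(-.freqIndex(padto[i])^2 / (2 * sigma[i]^2))
    v / sum(v)
  })
  K <- ks[[1]]
  for (i in seq_along(ks)[-1]) K <- outer(K, ks[[i]])
  dim(K) <- padto
  fft(K)
}

.gaussSmooth <- function(arr, kernelFFT, padto) {
  d <- dim(arr)
  A <- array(0, padto)
  A[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
  sm <- Re(fft(fft(A) * kernelFFT, inverse = TRUE)) / prod(padto)
  sm[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
}

.rmse <- function(a, b, mask = TRUE) sqrt(mean((a[mask] - b[mask])^2))
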
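# Independent brute-force oracles and shared fixtures. Every oracle is
# written as plain loops / direct DFT sums so it shares no code path with
# the package implementation it checks.

# ---- direct DFT helpers (O(n^2), matrix form) -------------------------------

oracleDFT <- function(x) {
  n <- length(x)
  W <- exp(-2i * pi * outer(0:(n - 1), 0:(n - 1)) / n)
  as.vector(W %*% x)
}

oracleIDFT <- function(X) {
  n <- length(X)
  W <- exp(2i * pi * outer(0:(n - 1), 0:(n - 1)) / n)
  as.vector(W %*% X) / n
}

oracleFreqIndex <- function(n) {
  m <- 0:(n - 1)
  ifelse(m >= ceiling(n / 2), m - n, m)
}

# zero-fill central truncation of a 1D signal via direct DFT sums
oracleTruncate1D <- function(x, keep) {
  n <- length(x)
  X <- oracleDFT(x)
  m <- oracleFreqIndex(n)
  X[!(m >= -floor(keep / 2) & m <= ceiling(keep / 2) - 1)] <- 0
  Re(oracleIDFT(X))
}

# acquisition-style truncation: keep the n centered coefficients of a longer
# signal and reconstruct on the n-point grid
oracleCrop1D <- function(x, n) {
  N <- length(x)
  X <- oracleDFT(x)
  mN <- oracleFreqIndex(N)
  mn <- oracleFreqIndex(n)
  Re(oracleIDFT(X[match(mn, mN)])) * (n / N)
}

# ---- exhaustive sub-voxel shift-search oracle -------------------------------

# independent re-implementation of the 1D unringing: direct DFT shifts,
# explicit per-voxel loops over every candidate, same tie-break order
# (0, -1, +1, -2, +2, ...). Returns the line and the selected shift integers.
oracleUnring1D <- function(x, numShifts = 20L, minW = 1L, maxW = 3L) {
  n <- length(x)
  m <- oracleFreqIndex(n)
  X <- oracleDFT(x)
  ts <- c(0L, as.vector(rbind(-(1:numShifts), 1:numShifts)))
  shifted <- matrix(0, n, length(ts))
  for (j in seq_along(ts)) {
    s <- ts[j] / (2 * numShifts)
    if (ts[j] == 0L) shifted[, j] <- x
    else {
      ph <- exp(2i * pi * m * s / n)
      if (n %% 2 == 0) ph[m == -n / 2] <- cos(pi * s)
      shifted[, j] <- Re(oracleIDFT(X * ph))
    }
  }
  wrap <- function(i) ((i - 1) %% n) + 1
  out <- numeric(n)
  pick <- integer(n)
  for (i in seq_len(n)) {
    best <- Inf; bj <- 1L
    for (j in seq_along(ts)) {
      left <- 0; right <- 0
      for (w in minW:maxW) {
        left <- left + abs(shifted[wrap(i - w + 1), j] -
                           shifted[wrap(i - w), j])
        right <- right + abs(shifted[wrap(i + w), j] -
                             shifted[wrap(i + w - 1), j])
      }
      meas <- min(left, right)
      if (meas < best) { best <- meas; bj <- j }
    }
    t <- ts[bj]; s <- t / (2 * numShifts)
    pick[i] <- t
    if (t == 0L) out[i] <- x[i]
    else if (s > 0)
      out[i] <- (1 - s) * shifted[i, bj] + s * shifted[wrap(i - 1), bj]
    else
      out[i] <- (1 + s) * shifted[i, bj] + (-s) * shifted[wrap(i + 1), bj]
  }
  list(line = out, shifts = pick)
}

# package-side shift selection, for comparing the discrete search outcome
packageUnringShifts <- function(x, numShifts = 20L, minW = 1L, maxW = 3L) {
  n <- length(x)
  u <- unringLine(x, unringParams(numShifts, minW, maxW))
  u
}

# ---- global histogram equalization oracle -----------------------------------

# explicit per-voxel implementation of the single-tile mapping:
# out = gmin + (gmax - gmin) * cdf(bin(v)); single-occupied-bin -> identity
oracleGlobalHE <- function(v, bins) {
  gmin <- min(v); gmax <- max(v)
  if (gmax <= gmin) return(v)
  bw <- (gmax - gmin) / bins
  b <- pmin(pmax(floor((v - gmin) / bw) + 1L, 1L), bins)
  h <- numeric(bins)
  for (i in seq_along(v)) h[b[i]] <- h[b[i]] + 1
  if (sum(h > 0) == 1L) return(v)
  cdf <- cumsum(h) / sum(h)
  out <- v
  for (i in seq_along(v)) out[i] <- gmin + (gmax - gmin) * cdf[b[i]]
  out
}

# ---- dice / image-quality oracles -------------------------------------------

oracleDice <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    if (a[i]) na <- na + 1
    if (b[i]) nb <- nb + 1
    if (a[i] && b[i]) inter <- inter + 1
  }
  if (na + nb == 0) 1 else 2 * inter / (na + nb)
}

oracleRMSE <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  sqrt(s / length(a))
}

# ---- deconvolution oracle for the histogram E-step --------------------------

# E[u|v] computed by explicit DFT-matrix Wiener deconvolution and quadrature,
# sharing no fft() calls with the implementation
oracleSharpenMap <- function(sample, bins = 200L, fwhm = 0.15, wn = 0.01) {
  rng <- range(sample); span <- diff(rng)
  bw <- span / bins
  ctr <- rng[1] + (seq_len(bins) - 0.5) * bw
  b <- pmin(pmax(floor((sample - rng[1]) / bw) + 1L, 1L), bins)
  h <- tabulate(b, bins)
  sigBins <- (fwhm * span) / (2 * sqrt(2 * log(2))) / bw
  marg <- ceiling(4 * sigBins)
  P <- stats::nextn(bins + 2L * marg, c(2, 3, 5))
  Q <- (P - bins) %/% 2
  pos <- oracleFreqIndex(P)
  g <- exp(-pos^2 / (2 * sigBins^2)); g <- g / sum(g)
  G <- oracleDFT(g)
  hp <- numeric(P); hp[Q + seq_len(bins)] <- h
  fu <- Re(oracleIDFT(oracleDFT(hp) * Conj(G) / (Mod(G)^2 + wn)))
  fu[fu < 0] <- 0
  keep <- seq_len(P) >= Q + 1 - marg & seq_len(P) <= Q + bins + marg
  fu[!keep] <- 0
  ramp <- rng[1] + (seq_len(P) - Q - 0.5) * bw
  num <- Re(oracleIDFT(oracleDFT(fu * ramp) * G))
  den <- Re(oracleIDFT(oracleDFT(fu) * G))
  sel <- Q + seq_len(bins)
  Ev <- ctr
  ok <- den[sel] > max(den) * 1e-8
  Ev[ok] <- (num[sel] / den[sel])[ok]
  Ev <- pmin(pmax(Ev, rng[1]), rng[2])
  slo <- (Ev[2] - Ev[1]) / bw
  shi <- (Ev[bins] - Ev[bins - 1]) / bw
  xs <- c(rng[1], ctr, rng[2])
  ys <- pmin(pmax(c(Ev[1] - slo * bw / 2, Ev, Ev[bins] + shi * bw / 2),
                  rng[1]), rng[2])
  stats::approx(xs, ys, xout = sample, rule = 2, ties = "ordered")$y
}

# ---- shared fixtures --------------------------------------------------------

# three-tissue brain-like phantom spec (CSF / GM / WM), log-intensity class
# separations well above the default histogram-sharpening blur
threeClassSpec <- function(shape = c(48L, 48L, 40L), seed = 1L) {
  sh <- as.integer(shape); ctr <- (sh + 1) / 2
  phantomSpec(shape = sh, seed = seed,
    ellipsoids = list(
      list(center = ctr, axes = 0.40 * sh, angles = c(0, 0, 0), level = 40),
      list(center = ctr + c(0.02, -0.02, 0) * sh, axes = 0.33 * sh,
           angles = c(0.1, 0, 0.2), level = 80),
      list(center = ctr + c(-0.03, 0.03, 0.02) * sh, axes = 0.20 * sh,
           angles = c(0, 0.2, 0), level = 130)),
    tumor = list())
}

# voxels within `width` voxels of a value change in the piecewise-constant
# reference (the band-limited representation error zone)
interfaceShell <- function(ref, width = 2L) {
  d <- dim(ref)
  shell <- array(FALSE, d)
  for (ax in 1:3) for (off in c(-(width:1), 1:width)) {
    idx <- pmin(pmax(seq_len(d[ax]) + off, 1L), d[ax])
    shifted <- switch(ax, ref[idx, , , drop = FALSE],
                      ref[, idx, , drop = FALSE], ref[, , idx, drop = FALSE])
    shell <- shell | (shifted != ref)
  }
  shell
}

# ringing-quantification mask: brain support minus the interface shell
ringingMask <- function(cleanArr, width = 2L) {
  (cleanArr > 0) & !interfaceShell(cleanArr, width)
}

maskedRMSE <- function(volA, volB, mask) {
  a <- if (is(volA, "MRIVolume")) volData(volA) else volA
  b <- if (is(volB, "MRIVolume")) volData(volB) else volB
  sqrt(mean((a[mask] - b[mask])^2))
}

# corrupt a clean ringed phantom pair with a bias field and re-mask to the
# brain support (skull-strip after acquisition)
doublyCorrupted <- function(spec, keep = 0.25, amplitude = 1.25,
                            fieldScale = 25, fieldSeed = 3L) {
  rp <- makeRingedPhantom(spec, keep)
  cl <- volData(rp$clean)
  brain <- cl > 0
  bf <- addBiasField(rp$ringed, biasFieldSpec(amplitude = amplitude,
                                              scale = fieldScale,
                                              seed = fieldSeed))
  arr <- volData(bf$volume)
  arr[!brain] <- 0
  list(corrupt = mriVolume(arr, voxelSpacing(rp$clean)), clean = rp$clean,
       brain = brain, field = bf$field, ringed = rp$ringed)
}
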
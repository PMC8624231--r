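# Synthetic brain-like phantoms with controllable Gibbs ringing, bias field
# and noise, so every downstream stage is testable fully offline.

#' Describe a synthetic phantom
#'
#' The default geometry mirrors the skull-stripped, 1 mm isotropic
#' 240 x 240 x 155 layout of the BraTS datasets: a large "brain" ellipsoid
#' with two internal tissue structures plus a nested three-region tumor
#' (whole / core / enhancing, labels 2 / 1 / 4). A small seeded jitter
#' perturbs centers, semi-axes and intensities so different seeds give
#' different (but statistically equivalent) phantoms.
#'
#' @param shape voxel dimensions (default `c(240, 240, 155)`).
#' @param spacing mm per voxel (default 1 mm isotropic).
#' @param ellipsoids list of ellipsoid descriptors; see [PhantomSpec-class].
#' @param tumor nested tumor descriptor or `list()` for none.
#' @param jitter fractional seeded perturbation (default 0.02).
#' @param seed integer RNG seed.
#' @return a [PhantomSpec-class] object.
#' @examples
#' spec <- phantomSpec(shape = c(48, 48, 32), seed = 7L)
#' ph <- makePhantom(spec)
#' dim(ph$volume)
#' @export
phantomSpec <- function(shape = c(240L, 240L, 155L), spacing = c(1, 1, 1),
                        ellipsoids = NULL, tumor = NULL, jitter = 0.02,
                        seed = 1L) {
  shape <- as.integer(shape)
  if (is.null(ellipsoids)) {
    ctr <- (shape + 1) / 2
    # piecewise-constant tissue contrast with log-intensity class separations
    # well above the default histogram-sharpening blur: an outer gray-matter
    # shell, a white-matter core and a dark CSF cavity
    ellipsoids <- list(
      list(center = ctr, axes = 0.36 * shape, angles = c(0, 0, 0), level = 80),
      list(center = ctr + c(-0.04, 0.02, 0) * shape, axes = 0.22 * shape,
           angles = c(0.2, 0, 0.3), level = 130),
      list(center = ctr + c(0.02, -0.05, 0.03) * shape, axes = 0.06 * shape,
           angles = c(0, 0, 0), level = 40)
    )
  }
  if (is.null(tumor)) {
    # bright lesion with nested subregions (edema / core / enhancing)
    tumor <- list(center = (0.62 + c(0, 0.02, 0.05)) * shape,
                  axes = 0.11 * shape, angles = c(0.4, 0.1, 0),
                  coreFrac = 0.6, enhFrac = 0.35,
                  levels = c(whole = 180, core = 230, enhancing = 290))
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("PhantomSpec", shape = shape, spacing = as.numeric(spacing),
      ellipsoids = ellipsoids, tumor = tumor, jitter = jitter,
      seed = as.integer(seed))
}

#' Describe a synthetic bias field
#'
#' @param kind "gaussian-bump" (default) or "polynomial".
#' @param amplitude multiplicative range bound `a >= 1`; the field lies in
#'   `[1/a, a]` and has zero-mean log over the volume.
#' @param scale smoothness scale in voxels (default 1/3 of typical brain
#'   extent at BraTS geometry).
#' @param seed integer RNG seed.
#' @return a [BiasFieldSpec-class] object.
#' @export
biasFieldSpec <- function(kind = "gaussian-bump", amplitude = 1.25,
                          scale = 60, seed = 1L) {
  new("BiasFieldSpec", kind = kind, amplitude = amplitude, scale = scale,
      seed = as.integer(seed))
}

# apply the seeded jitter of a PhantomSpec once, returning concrete geometry
.materializeSpec <- function(spec) {
  .withSeed(spec@seed, {
    j <- spec@jitter
    ells <- lapply(spec@ellipsoids, function(e) {
      if (is.null(e$angles)) e$angles <- c(0, 0, 0)
      e$center <- e$center + rnorm(3) * j * e$axes
      e$axes <- pmax(e$axes * (1 + j * rnorm(3)), 1e-6)
      e$level <- e$level * (1 + j * rnorm(1))
      e
    })
    tm <- spec@tumor
    if (length(tm)) {
      if (is.null(tm$angles)) tm$angles <- c(0, 0, 0)
      tm$center <- tm$center + rnorm(3) * j * tm$axes
      tm$axes <- pmax(tm$axes * (1 + j * rnorm(3)), 1e-6)
      tm$levels <- tm$levels * (1 + j * rnorm(3))
    }
    list(ellipsoids = ells, tumor = tm)
  })
}

.rotationMatrix <- function(angles) {
  ca <- cos(angles); sa <- sin(angles)
  rx <- rbind(c(1, 0, 0), c(0, ca[1], -sa[1]), c(0, sa[1], ca[1]))
  ry <- rbind(c(ca[2], 0, sa[2]), c(0, 1, 0), c(-sa[2], 0, ca[2]))
  rz <- rbind(c(ca[3], -sa[3], 0), c(sa[3], ca[3], 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

# slice mask of a rotated ellipsoid at through-plane coordinate z
.ellipsoidSliceMask <- function(X, Y, z, center, axes, angles) {
  R <- .rotationMatrix(angles)
  dx <- X - center[1]; dy <- Y - center[2]; dz <- z - center[3]
  q1 <- R[1, 1] * dx + R[2, 1] * dy + R[3, 1] * dz
  q2 <- R[1, 2] * dx + R[2, 2] * dy + R[3, 2] * dz
  q3 <- R[1, 3] * dx + R[2, 3] * dy + R[3, 3] * dz
  (q1 / axes[1])^2 + (q2 / axes[2])^2 + (q3 / axes[3])^2 <= 1
}

# render a materialized scene on the grid given by coordinate vectors;
# returns intensity volume and BraTS-style label volume
.renderScene <- function(xs, ys, zs, scene) {
  n1 <- length(xs); n2 <- length(ys); n3 <- length(zs)
  vol <- array(0, c(n1, n2, n3))
  lab <- array(0L, c(n1, n2, n3))
  X <- matrix(xs, n1, n2)
  Y <- matrix(ys, n1, n2, byrow = TRUE)
  tm <- scene$tumor
  for (k in seq_len(n3)) {
    z <- zs[k]
    sl <- matrix(0, n1, n2)
    for (e in scene$ellipsoids) {
      m <- .ellipsoidSliceMask(X, Y, z, e$center, e$axes, e$angles)
      sl[m] <- e$level
    }
    if (length(tm)) {
      lsl <- matrix(0L, n1, n2)
      mw <- .ellipsoidSliceMask(X, Y, z, tm$center, tm$axes, tm$angles)
      sl[mw] <- tm$levels[["whole"]]; lsl[mw] <- 2L
      mc <- .ellipsoidSliceMask(X, Y, z, tm$center, tm$axes * tm$coreFrac,
                                tm$angles)
      sl[mc] <- tm$levels[["core"]]; lsl[mc] <- 1L
      me <- .ellipsoidSliceMask(X, Y, z, tm$center, tm$axes * tm$enhFrac,
                                tm$angles)
      sl[me] <- tm$levels[["enhancing"]]; lsl[me] <- 4L
      lab[, , k] <- lsl
    }
    vol[, , k] <- sl
  }
  list(vol = vol, lab = lab)
}

#' Generate a piecewise-constant phantom with nested tumor labels
#'
#' @param spec a [PhantomSpec-class]; defaults to [phantomSpec()].
#' @return a list with elements `volume` ([MRIVolume-class]) and `labels`
#'   ([LabelVolume-class]). The label regions are nested by construction:
#'   enhancing (4) inside core (1, 4) inside whole (1, 2, 4).
#' @examples
#' ph <- makePhantom(phantomSpec(shape = c(40, 40, 24), seed = 3L))
#' table(labelData(ph$labels))
#' @export
makePhantom <- function(spec = phantomSpec()) {
  validObject(spec)
  scene <- .materializeSpec(spec)
  r <- .renderScene(seq_len(spec@shape[1]), seq_len(spec@shape[2]),
                    seq_len(spec@shape[3]), scene)
  list(volume = mriVolume(r$vol, spec@spacing),
       labels = labelVolume(r$lab, spec@spacing))
}

#' Inject Gibbs ringing by zero-filled central k-space truncation
#'
#' Forward FFT, zero every coefficient outside the centered window retaining
#' the given fraction per axis, inverse FFT, real part. The grid (and hence
#' the output shape) is unchanged, so the surviving oscillation has period
#' `2 / keepFraction` voxels -- larger than the 2-voxel Nyquist period of
#' acquisition-truncated data whenever `keepFraction < 1`. Use
#' [makeRingedPhantom()] to emulate acquisition truncation, the regime the
#' sub-voxel-shift removal is designed for.
#'
#' @param vol an [MRIVolume-class].
#' @param keepFraction fraction of k-space retained per axis, in (0, 1];
#'   scalar (recycled) or length 3.
#' @return the ringed [MRIVolume-class]; the spatial mean (DC coefficient)
#'   is preserved.
#' @export
addGibbsRinging <- function(vol, keepFraction) {
  vol <- .asVolume(vol)
  if (length(keepFraction) == 1L) keepFraction <- rep(keepFraction, 3L)
  if (length(keepFraction) != 3L || any(keepFraction <= 0) ||
      any(keepFraction > 1))
    stop("keepFraction must be per-axis fractions in (0, 1]", call. = FALSE)
  d <- dim(vol)
  keep <- pmax(1, round(keepFraction * d))
  if (all(keep == d)) return(vol)
  W <- outer(outer(.keepMask(d[1], keep[1]), .keepMask(d[2], keep[2])),
             .keepMask(d[3], keep[3]))
  dim(W) <- d
  out <- Re(fft(fft(volData(vol)) * W, inverse = TRUE)) / prod(d)
  mriVolume(out, voxelSpacing(vol))
}

#' Generate a phantom with acquisition-style Gibbs ringing
#'
#' Renders the phantom scene on an in-plane supersampled grid and crops its
#' k-space to the target shape, emulating an MR acquisition that samples a
#' truncated k-space and reconstructs on the matching grid. The resulting
#' ringing oscillates at the Nyquist period (2 voxels) of the output grid,
#' the regime that [unringVolume()] is designed to correct. The clean
#' reference is the same (identically jittered) scene rendered directly at
#' the output resolution.
#'
#' @param spec a [PhantomSpec-class].
#' @param keepFraction fraction of in-plane k-space acquired, in (0, 1);
#'   scalar or length 2 (one per in-plane axis). The supersampling factor is
#'   `round(1 / keepFraction)` per axis.
#' @return list with `ringed`, `clean` (both [MRIVolume-class]) and `labels`
#'   ([LabelVolume-class]).
#' @export
makeRingedPhantom <- function(spec = phantomSpec(), keepFraction = 0.25) {
  validObject(spec)
  if (length(keepFraction) == 1L) keepFraction <- rep(keepFraction, 2L)
  if (any(keepFraction <= 0) || any(keepFraction >= 1))
    stop("keepFraction must be in (0, 1)", call. = FALSE)
  ss <- pmax(2L, as.integer(round(1 / keepFraction)))
  scene <- .materializeSpec(spec)
  d <- spec@shape
  clean <- .renderScene(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), scene)
  # fine in-plane grid aligned so that k-space cropping lands samples on the
  # native voxel centers 1, 2, ..., n
  xf <- 1 + (seq_len(d[1] * ss[1]) - 1) / ss[1]
  yf <- 1 + (seq_len(d[2] * ss[2]) - 1) / ss[2]
  fine <- .renderScene(xf, yf, seq_len(d[3]), scene)$vol
  N1 <- d[1] * ss[1]; N2 <- d[2] * ss[2]
  ix <- match(.freqIndex(d[1]), .freqIndex(N1))
  iy <- match(.freqIndex(d[2]), .freqIndex(N2))
  ringed <- array(0, d)
  for (k in seq_len(d[3])) {
    FT <- fft(fine[, , k])
    ringed[, , k] <- Re(fft(FT[ix, iy], inverse = TRUE)) / (N1 * N2)
  }
  list(ringed = mriVolume(ringed, spec@spacing),
       clean = mriVolume(clean$vol, spec@spacing),
       labels = labelVolume(clean$lab, spec@spacing))
}

#' Multiply a volume by a smooth synthetic bias field
#'
#' The log-field is a seeded smooth function (Gaussian bump or low-order
#' polynomial) standardized to zero mean over the volume with maximum
#' absolute value `log(amplitude)`, so the field lies in
#' `[1/amplitude, amplitude]` and has unit geometric mean.
#'
#' @param vol an [MRIVolume-class].
#' @param fspec a [BiasFieldSpec-class].
#' @return list with `volume` (the corrupted volume, `vol * field`) and
#'   `field` (the field itself, an [MRIVolume-class]).
#' @export
addBiasField <- function(vol, fspec = biasFieldSpec()) {
  vol <- .asVolume(vol)
  validObject(fspec)
  d <- dim(vol)
  h <- .withSeed(fspec@seed, {
    if (fspec@kind == "gaussian-bump") {
      ctr <- d * runif(3, 0.25, 0.75)
      x <- (seq_len(d[1]) - ctr[1]) / fspec@scale
      y <- (seq_len(d[2]) - ctr[2]) / fspec@scale
      z <- (seq_len(d[3]) - ctr[3]) / fspec@scale
      g <- exp(-outer(outer(x^2, y^2, "+"), z^2, "+") / 2)
    } else {
      cf <- runif(9, -1, 1)
      x <- (seq_len(d[1]) - (d[1] + 1) / 2) / fspec@scale
      y <- (seq_len(d[2]) - (d[2] + 1) / 2) / fspec@scale
      z <- (seq_len(d[3]) - (d[3] + 1) / 2) / fspec@scale
      X <- array(x, d)
      Y <- array(rep(y, each = d[1]), d)
      Z <- array(rep(z, each = d[1] * d[2]), d)
      g <- cf[1] * X + cf[2] * Y + cf[3] * Z + cf[4] * X * Y +
        cf[5] * X * Z + cf[6] * Y * Z + cf[7] * X^2 + cf[8] * Y^2 +
        cf[9] * Z^2
    }
    dim(g) <- d
    g
  })
  h <- h - mean(h)
  mx <- max(abs(h))
  if (mx > 0) h <- h / mx
  field <- fspec@amplitude^h
  list(volume = mriVolume(volData(vol) * field, voxelSpacing(vol)),
       field = mriVolume(field, voxelSpacing(vol)))
}

#' Add measurement noise
#'
#' Gaussian: `out = in + N(0, sigma^2)` i.i.d. (the additive noise of the
#' image-formation model). Rician: magnitude of the input plus complex
#' Gaussian noise, the actual distribution of MR magnitude images; in
#' zero-signal background its mean is `sigma * sqrt(pi / 2)`.
#'
#' @param vol an [MRIVolume-class].
#' @param sigma noise level in intensity units, `>= 0`.
#' @param model "gaussian" (default) or "rician".
#' @param seed optional integer seed for reproducibility.
#' @return the noisy [MRIVolume-class].
#' @export
addNoise <- function(vol, sigma, model = c("gaussian", "rician"),
                     seed = NULL) {
  vol <- .asVolume(vol)
  model <- match.arg(model)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(vol)
  d <- dim(vol)
  out <- .withSeed(seed, {
    if (model == "gaussian") {
      volData(vol) + array(rnorm(prod(d), 0, sigma), d)
    } else {
      re <- volData(vol) + array(rnorm(prod(d), 0, sigma), d)
      im <- array(rnorm(prod(d), 0, sigma), d)
      sqrt(re^2 + im^2)
    }
  })
  mriVolume(out, voxelSpacing(vol))
}
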
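test_that("weight filters are normalized exactly and take their closed-form values", {
  for (sh in list(c(8L, 8L), c(9L, 9L), c(8L, 9L), c(17L, 5L), c(64L, 64L))) {
    fp <- gibbsWeightFilters(sh)
    gx <- gxFilter(fp); gy <- gyFilter(fp)
    expect_identical(dim(gx), sh)
    expect_true(all(gx + gy == 1))          # exact in double precision
    expect_true(all(gx >= 0 & gx <= 1))
    # DC point (centered grid): kx = ky = 0 -> both weights 1/2
    i0 <- floor(sh[1] / 2) + 1L; j0 <- floor(sh[2] / 2) + 1L
    expect_identical(gx[i0, j0], 0.5)
    expect_identical(gy[i0, j0], 0.5)
  }
  # (kx, ky) = (pi, 0): Gx = 2 / (2 + 0) = 1, Gy = 0 (even first dimension)
  fp <- gibbsWeightFilters(c(8L, 8L))
  expect_equal(gxFilter(fp)[1, 5], 1)
  expect_equal(gyFilter(fp)[1, 5], 0)
  # kx = ky = pi is the 0/0 point, defined as 1/2 by symmetry
  expect_identical(gxFilter(fp)[1, 1], 0.5)
  expect_error(gibbsWeightFilters(c(0L, 4L)), "dimensions")
})

test_that("unringLine preserves artifact-free signals", {
  expect_identical(unringLine(rep(2.5, 32)), rep(2.5, 32))
  r <- seq(0, 1, length.out = 64)
  # periodic resampling perturbs a non-periodic ramp only near the wrap
  expect_lt(max(abs(unringLine(r) - r)[4:60]), 0.01)
  expect_error(unringLine(c(1, 2), unringParams(maxWindow = 3)), "length")
})

test_that("unringLine equals the exhaustive shift-search oracle and removes off-edge ringing", {
  # acquisition-truncated step: 512-sample step reconstructed at 128
  step <- c(rep(0, 254), rep(1.5, 258))
  ringed <- oracleCrop1D(step, 128L)
  ideal <- as.numeric(seq(1, 512, by = 4) > 254.5) * 1.5
  orc <- oracleUnring1D(ringed)
  u <- unringLine(ringed)
  expect_lt(max(abs(u - orc$line)), 1e-10)
  # ringing (away from the +-2 voxel edge zone) is cut by >= 50%
  edge <- which(abs(diff(ideal)) > 0)
  off <- setdiff(seq_len(128), c(outer(edge, -2:3, "+"), 1:3, 126:128))
  expect_lt(oracleRMSE(u[off], ideal[off]),
            0.5 * oracleRMSE(ringed[off], ideal[off]))
})

test_that("unringLine matches the oracle on random lines", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(8:64, 1)
    x <- cumsum(rnorm(n))                 # smooth-ish random walk
    x <- x + 0.5 * sin(pi * seq_len(n))   # add a Nyquist oscillation
    orc <- oracleUnring1D(x)
    expect_lt(max(abs(unringLine(x) - orc$line)), 1e-10)
  }
})

test_that("unringSlice recombination is exact for equal directional inputs", {
  set.seed(1)
  A <- matrix(rnorm(32 * 24), 32, 24)
  fp <- gibbsWeightFilters(c(32L, 24L))
  # undo the centered ordering to apply on the raw FFT grid
  ord1 <- order(order(oracleFreqIndex(32)))
  ord2 <- order(order(oracleFreqIndex(24)))
  gx <- gxFilter(fp)[ord1, ord2]; gy <- gyFilter(fp)[ord1, ord2]
  FT <- fft(A)
  back <- Re(fft(FT * gx + FT * gy, inverse = TRUE)) / length(A)
  expect_lt(max(abs(back - A)), 1e-10 * max(abs(A)))
})

test_that("unringSlice passes smooth images through and improves ringed slices", {
  x <- seq(-1, 1, length.out = 48)
  smooth <- outer(1 + x + 0.5 * x^2, 1 - 0.3 * x, "*") * 10
  out <- unringSlice(smooth)
  expect_lt(sqrt(mean((out - smooth)^2)) / diff(range(smooth)), 0.01)

  rp <- makeRingedPhantom(threeClassSpec(c(48L, 48L, 8L)), 0.25)
  k <- 4L
  ringedSl <- volData(rp$ringed)[, , k]
  cleanSl <- volData(rp$clean)[, , k]
  unrung <- unringSlice(ringedSl)
  # ringing error (outside the band-limited interface zone) strictly drops
  qm <- ringingMask(volData(rp$clean))[, , k]
  expect_lt(sqrt(mean((unrung - cleanSl)[qm]^2)),
            sqrt(mean((ringedSl - cleanSl)[qm]^2)))
  expect_error(unringSlice(matrix(0, 3, 50)), "small")
})

test_that("unringVolume reduces to slice unringing and treats slices independently", {
  rp <- makeRingedPhantom(threeClassSpec(c(32L, 32L, 8L)), 0.25)
  oneSlice <- mriVolume(volData(rp$ringed)[, , 3, drop = FALSE])
  expect_equal(volData(unringVolume(oneSlice))[, , 1],
               unringSlice(volData(rp$ringed)[, , 3]), tolerance = 1e-12)
  # identical slices give identical outputs
  rep3 <- mriVolume(array(volData(rp$ringed)[, , 3], c(32, 32, 3)))
  u <- volData(unringVolume(rep3))
  expect_identical(u[, , 1], u[, , 2])
  expect_identical(u[, , 2], u[, , 3])
  # full ringed phantom improves volume-wide over the ringing mask
  un <- unringVolume(rp$ringed)
  qm <- ringingMask(volData(rp$clean))
  expect_lt(maskedRMSE(un, rp$clean, qm), maskedRMSE(rp$ringed, rp$clean, qm))
})

test_that("unringVolume honors the configured slice plane", {
  rp <- makeRingedPhantom(threeClassSpec(c(32L, 32L, 12L)), 0.4)
  a <- volData(unringVolume(rp$ringed))
  # process the same data with axes permuted and the matching slice plane
  perm <- mriVolume(aperm(volData(rp$ringed), c(3, 1, 2)))
  b <- volData(unringVolume(perm, unringParams(slicePlane = c(2L, 3L))))
  expect_equal(aperm(b, c(2, 3, 1)), a, tolerance = 1e-12)
})

test_that("unringing is contractive and mean-preserving on the phantom suite", {
  rp <- makeRingedPhantom(threeClassSpec(c(48L, 48L, 12L)), 0.25)
  pass1 <- unringVolume(rp$ringed)
  pass2 <- unringVolume(pass1)
  d1 <- sqrt(mean((volData(pass1) - volData(rp$ringed))^2))
  d2 <- sqrt(mean((volData(pass2) - volData(pass1))^2))
  expect_lt(d2, d1)
  m0 <- mean(volData(rp$ringed)); m1 <- mean(volData(pass1))
  expect_lt(abs(m1 - m0) / abs(m0), 0.005)
})
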
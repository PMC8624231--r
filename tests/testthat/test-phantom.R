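test_that("default phantom matches the BraTS geometry with nested labels", {
  ph <- makePhantom(phantomSpec(seed = 1L))
  expect_identical(dim(ph$volume), c(240L, 240L, 155L))
  expect_identical(voxelSpacing(ph$volume), c(1, 1, 1))
  lab <- labelData(ph$labels)
  expect_true(all(lab %in% c(0L, 1L, 2L, 4L)))
  rm <- regionMasks(ph$labels)
  expect_true(all(rm$enhancing[rm$enhancing] & rm$core[rm$enhancing]))
  expect_true(all(!rm$enhancing | rm$core))
  expect_true(all(!rm$core | rm$whole))
  expect_gt(sum(rm$enhancing), 0)
})

test_that("empty scene yields an all-zero volume and background labels", {
  spec <- phantomSpec(shape = c(16, 16, 8), ellipsoids = list(),
                      tumor = list(), seed = 5L)
  ph <- makePhantom(spec)
  expect_true(all(volData(ph$volume) == 0))
  expect_true(all(labelData(ph$labels) == 0L))
})

test_that("phantoms are bitwise deterministic under a seed and vary across seeds", {
  a <- makePhantom(phantomSpec(shape = c(32, 32, 20), seed = 7L))
  b <- makePhantom(phantomSpec(shape = c(32, 32, 20), seed = 7L))
  c <- makePhantom(phantomSpec(shape = c(32, 32, 20), seed = 8L))
  expect_identical(volData(a$volume), volData(b$volume))
  expect_identical(labelData(a$labels), labelData(b$labels))
  expect_false(identical(volData(a$volume), volData(c$volume)))
})

test_that("invalid phantom geometry is rejected", {
  expect_error(phantomSpec(shape = c(0, 16, 16)), "shape")
  expect_error(phantomSpec(shape = c(16, 16, 16),
    ellipsoids = list(list(center = c(8, 8, 8), axes = c(4, -1, 4),
                           level = 10)), tumor = list()), "semi-axes")
})

test_that("zero-fill truncation follows the centered-window contract", {
  ph <- makePhantom(phantomSpec(shape = c(24, 24, 16), seed = 2L))
  # keepFraction 1 is the identity
  same <- addGibbsRinging(ph$volume, 1)
  expect_lt(max(abs(volData(same) - volData(ph$volume))),
            1e-10 * max(abs(volData(ph$volume))))
  # a constant volume only has DC, which survives any truncation
  cv <- mriVolume(array(3.7, c(16, 16, 8)))
  out <- addGibbsRinging(cv, 0.3)
  expect_lt(max(abs(volData(out) - 3.7)), 1e-10)
  # spatial mean (DC) is preserved by any truncation
  ringed <- addGibbsRinging(ph$volume, c(0.25, 0.5, 1))
  expect_lt(abs(mean(volData(ringed)) - mean(volData(ph$volume))),
            1e-10 * abs(mean(volData(ph$volume))))
  expect_error(addGibbsRinging(ph$volume, 0), "keepFraction")
  expect_error(addGibbsRinging(ph$volume, 1.2), "keepFraction")
})

test_that("1D step truncation reproduces the brute-force DFT oracle and the Gibbs overshoot", {
  n <- 128L; h <- 2.5
  step <- c(rep(0, n / 2), rep(h, n / 2))
  vol <- mriVolume(array(step, c(n, 1, 1)))
  ringed <- volData(addGibbsRinging(vol, c(32 / n, 1, 1)))[, 1, 1]
  oracle <- oracleTruncate1D(step, 32L)
  expect_lt(max(abs(ringed - oracle)), 1e-9)
  # first overshoot of the truncated Fourier series is ~9% of the step height
  overshoot <- (max(ringed) - h) / h
  expect_gt(overshoot, 0.07)
  expect_lt(overshoot, 0.10)
})

test_that("synthetic bias fields honor their amplitude, smoothness and inverse", {
  ph <- makePhantom(threeClassSpec(c(32L, 32L, 24L)))
  # amplitude 1 gives the exact unit field
  bf1 <- addBiasField(ph$volume, biasFieldSpec(amplitude = 1, scale = 10))
  expect_true(all(volData(bf1$field) == 1))
  expect_identical(volData(bf1$volume), volData(ph$volume))
  # output / field recovers the input to floating point
  bf <- addBiasField(ph$volume,
                     biasFieldSpec(amplitude = 1.25, scale = 12, seed = 4L))
  rel <- abs(volData(bf$volume) / volData(bf$field) - volData(ph$volume))
  expect_lt(max(rel), 1e-10 * max(volData(ph$volume)))
  f <- volData(bf$field)
  expect_gte(min(f), 1 / 1.25)
  expect_lte(max(f), 1.25)
  # direct evaluation of the analytic bump: the construction draws the bump
  # center as runif(3, 0.25, 0.75) of the shape under the given seed
  d <- dim(f)
  set.seed(4L)
  ctr <- d * runif(3, 0.25, 0.75)
  gx <- exp(-outer(outer(((seq_len(d[1]) - ctr[1]) / 12)^2,
                         ((seq_len(d[2]) - ctr[2]) / 12)^2, "+"),
                   ((seq_len(d[3]) - ctr[3]) / 12)^2, "+") / 2)
  hh <- gx - mean(gx); hh <- hh / max(abs(hh))
  lf <- log(f)
  expect_lt(max(abs(lf - log(1.25) * hh)), 1e-12)
  # per-axis gradient of the log field is bounded by the smoothness scale:
  # |d/dx a^h| <= log(a) * sup|grad of the standardized bump| ~ log(a)/scale
  axdiff <- function(a) {
    n <- d[a]
    idx1 <- slice.index(lf, a) < n
    abs((switch(a, lf[-1, , ], lf[, -1, ], lf[, , -1])) - lf[idx1])
  }
  gmax <- max(vapply(1:3, function(a) max(axdiff(a)), numeric(1)))
  expect_lt(gmax, 2 * log(1.25) / 12)
})

test_that("polynomial bias fields are smooth, bounded and deterministic", {
  ph <- makePhantom(threeClassSpec(c(24L, 24L, 16L)))
  bf <- addBiasField(ph$volume, biasFieldSpec(kind = "polynomial",
                                              amplitude = 1.4, scale = 12,
                                              seed = 6L))
  f <- volData(bf$field)
  expect_gte(min(f), 1 / 1.4)
  expect_lte(max(f), 1.4)
  bf2 <- addBiasField(ph$volume, biasFieldSpec(kind = "polynomial",
                                               amplitude = 1.4, scale = 12,
                                               seed = 6L))
  expect_identical(f, volData(bf2$field))
  expect_error(biasFieldSpec(amplitude = 0.9), "amplitude")
})

test_that("noise models match their closed-form statistics", {
  ph <- makePhantom(phantomSpec(shape = c(100L, 100L, 100L), seed = 3L))
  expect_identical(volData(addNoise(ph$volume, 0)), volData(ph$volume))
  ns <- addNoise(ph$volume, 5, "gaussian", seed = 11L)
  emp <- sd(volData(ns) - volData(ph$volume))
  expect_lt(abs(emp - 5) / 5, 0.02)
  # rician background mean is sigma * sqrt(pi / 2)
  zero <- mriVolume(array(0, c(60, 60, 60)))
  rn <- addNoise(zero, 5, "rician", seed = 12L)
  expect_lt(abs(mean(volData(rn)) - 5 * sqrt(pi / 2)) / (5 * sqrt(pi / 2)),
            0.03)
  # determinism under a fixed seed
  expect_identical(volData(addNoise(ph$volume, 5, seed = 9L)),
                   volData(addNoise(ph$volume, 5, seed = 9L)))
  expect_error(addNoise(ph$volume, -1), "sigma")
})

test_that("acquisition-style ringed phantoms ring at the Nyquist period", {
  rp <- makeRingedPhantom(threeClassSpec(c(48L, 48L, 16L)), 0.25)
  expect_identical(dim(rp$ringed), c(48L, 48L, 16L))
  expect_identical(volData(rp$clean),
                   volData(makePhantom(threeClassSpec(c(48L, 48L, 16L)))$volume))
  dif <- volData(rp$ringed) - volData(rp$clean)
  expect_gt(sqrt(mean(dif^2)), 0)
  # oscillation is concentrated near the in-plane Nyquist frequency: energy
  # in the top in-plane frequency band dominates the background error
  bg <- volData(rp$ringed)[volData(rp$clean) == 0]
  expect_gt(sd(bg), 0.01)
})
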
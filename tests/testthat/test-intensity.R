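test_that("z-score normalization is definitional, idempotent and affine-invariant", {
  ph <- makePhantom(phantomSpec(shape = c(32, 32, 24), seed = 2L))
  noisy <- addNoise(ph$volume, 3, seed = 1L)
  arr <- volData(noisy); arr[volData(ph$volume) == 0] <- 0
  v <- mriVolume(arr)
  msk <- arr > 0
  z <- zscoreNormalize(v)
  expect_lt(abs(mean(volData(z)[msk])), 1e-6)
  expect_lt(abs(sd(volData(z)[msk]) - 1), 1e-6)
  expect_true(all(volData(z)[!msk] == 0))
  # idempotence (explicit mask: the first pass creates negative intensities)
  z2 <- zscoreNormalize(z, msk)
  expect_lt(max(abs(volData(z2)[msk] - volData(z)[msk])), 1e-6)
  # affine invariance: zscore(a v + b) == zscore(v)
  va <- mriVolume(3.7 * arr + 12)
  expect_lt(max(abs(volData(zscoreNormalize(va, msk))[msk] -
                    volData(z)[msk])), 1e-8)
  expect_error(zscoreNormalize(mriVolume(array(5, c(4, 4, 4)))), "variance")
})

test_that("Nyul training maps spans affinely and cancels affine differences", {
  ph <- makePhantom(phantomSpec(shape = c(32, 32, 24), seed = 3L))
  v <- addNoise(ph$volume, 4, seed = 2L)
  arr <- volData(v); arr[volData(ph$volume) == 0] <- 0
  v <- mriVolume(arr)
  msk <- arr > 0
  sched <- c(1, seq(10, 90, 10), 99)
  m1 <- nyulTrain(list(v), list(msk))
  q <- quantile(arr[msk], sched / 100, names = FALSE)
  expected <- 1 + (q - q[1]) * 99 / (q[11] - q[1])
  expect_lt(max(abs(landmarks(m1) - expected)), 1e-10)
  expect_true(all(diff(landmarks(m1)) >= 0))
  # {v, 2.5 v + 7} trains the same model as {v, v}
  vAff <- mriVolume(ifelse(msk, 2.5 * arr + 7, 0))
  m2 <- nyulTrain(list(v, vAff), list(msk, msk))
  expect_lt(max(abs(landmarks(m2) - landmarks(m1))), 1e-8)
  expect_error(nyulTrain(list()), "training")
  expect_error(nyulTrain(list(mriVolume(array(2, c(4, 4, 4))))), "span|degenerate")
})

test_that("Nyul application pins self-landmarks and normalizes affine pairs together", {
  ph <- makePhantom(phantomSpec(shape = c(32, 32, 24), seed = 4L))
  v <- addNoise(ph$volume, 4, seed = 5L)
  arr <- volData(v); arr[volData(ph$volume) == 0] <- 0
  v <- mriVolume(arr); msk <- arr > 0
  model <- nyulTrain(list(v), list(msk))
  out <- nyulApply(v, model, msk)
  q <- quantile(arr[msk], percentileSchedule(model) / 100, names = FALSE)
  mapped <- approx(q, landmarks(model), xout = q)$y
  expect_lt(max(abs(mapped - landmarks(model))), 1e-8)
  # affine-transformed volume maps to the same output
  vAff <- mriVolume(ifelse(msk, 1.8 * arr - 3, 0))
  outAff <- nyulApply(vAff, model, msk)
  expect_lt(max(abs(volData(outAff)[msk] - volData(out)[msk])),
            1e-6 * diff(standardRange(model)))
  # monotonicity
  x <- arr[msk]; y <- volData(out)[msk]
  ordx <- order(x)
  expect_true(all(diff(y[ordx]) >= -1e-12))
  # idempotence after the first application
  out2 <- nyulApply(out, model, msk)
  out3 <- nyulApply(out2, model, msk)
  expect_lt(max(abs(volData(out3)[msk] - volData(out2)[msk])), 1e-6)
})

test_that("Nyul models survive a text round trip", {
  ph <- makePhantom(phantomSpec(shape = c(24, 24, 16), seed = 6L))
  v <- addNoise(ph$volume, 2, seed = 7L)
  model <- nyulTrain(list(v))
  tf <- tempfile(fileext = ".json")
  writeNyulModel(model, tf)
  back <- readNyulModel(tf)
  expect_equal(landmarks(back), landmarks(model), tolerance = 1e-12)
  expect_identical(percentileSchedule(back), percentileSchedule(model))
  unlink(tf)
})

test_that("adaptive equalization reduces exactly to the global oracle for one tile", {
  set.seed(9)
  arr <- array(rnorm(18 * 14 * 10, 100, 25), c(18, 14, 10))
  v <- mriVolume(arr)
  out <- aheEqualize(v, aheParams(tiles = c(1, 1, 1), bins = 64))
  oracle <- oracleGlobalHE(as.vector(arr), 64L)
  expect_identical(as.vector(volData(out)), oracle)
  # constant volumes pass through unchanged (single-bin identity rule)
  cst <- mriVolume(array(7, c(8, 8, 8)))
  expect_identical(volData(aheEqualize(cst)), volData(cst))
})

test_that("adaptive equalization is monotone, range-preserving and flattens histograms", {
  set.seed(10)
  arr <- array(runif(32 * 32 * 16, 10, 250), c(32, 32, 16))
  v <- mriVolume(arr)
  out <- volData(aheEqualize(v, aheParams(tiles = c(4, 4, 2), bins = 128)))
  expect_gte(min(out), min(arr) - 1e-9)
  expect_lte(max(out), max(arr) + 1e-9)
  # monotone within a tile: voxels before the first tile centers carry the
  # first tile's mapping with full weight, so their outputs must be ordered
  sub <- arr[1:4, 1:4, 1:4]; subo <- out[1:4, 1:4, 1:4]
  ordv <- order(sub)
  expect_true(all(diff(subo[ordv]) >= -1e-9))
  # uniform input stays approximately uniform after equalization
  br <- seq(min(out) - 1e-9, max(out) + 1e-9, length.out = 21)
  h <- hist(out, breaks = br, plot = FALSE)$counts
  ex <- length(out) / 20
  chisq <- sum((h - ex)^2 / ex)
  expect_lt(chisq, 3 * 20)
  expect_error(aheEqualize(v, aheParams(tiles = c(64, 4, 2))), "tiles")
})

test_that("the contrast limit caps the amplification of near-constant regions", {
  set.seed(11)
  # a near-constant core between two anchor intensities: plain equalization
  # stretches the core's tiny fluctuations across the range, the clipped
  # variant compresses that amplification
  n <- 16 * 16 * 8
  arr <- array(c(90, 110, rnorm(n - 2, 100, 0.5)), c(16, 16, 8))
  v <- mriVolume(arr)
  plain <- volData(aheEqualize(v, aheParams(tiles = c(1, 1, 1), bins = 32)))
  clipped <- volData(aheEqualize(v, aheParams(tiles = c(1, 1, 1), bins = 32,
                                              clipLimit = 0.05)))
  core <- seq_along(arr) > 2
  expect_lt(sd(clipped[core]), 0.5 * sd(plain[core]))
  expect_true(all(diff(clipped[order(arr)]) >= -1e-9))
})
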
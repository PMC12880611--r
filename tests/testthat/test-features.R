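test_that("band power integrates the PSD over the band", {
  f <- seq(0, 40, by = 0.25)
  flat <- rep(1, length(f))
  expect_equal(bandPower(f, flat, 8, 12), 4)
  expect_equal(bandPower(f, rep(0, length(f)), 0.5, 30), 0)
  # adjacent closed bands tile: [6,8] + [8,12] == [6,12]
  set.seed(3)
  p <- runif(length(f))
  expect_equal(bandPower(f, p, 6, 8) + bandPower(f, p, 8, 12),
               bandPower(f, p, 6, 12))
  # edges off the grid are interpolated
  expect_equal(bandPower(f, flat, 8.1, 11.9), 3.8)
  expect_error(bandPower(f, flat, 35, 45), "outside the spectral grid")
  expect_error(bandPower(f, flat, 12, 8), "loHz < hiHz")
})

test_that("a 10-Hz tone concentrates its power in the alpha band", {
  fs <- 178
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  w <- welchPSD(sin(2 * pi * 10 * t), fs)
  tot <- trapz(w$freqs, w$psd)
  sch <- defaultBandScheme()
  pw <- vapply(sch$bands, function(b) bandPower(w$freqs, w$psd, b[1], b[2]), 0)
  expect_gt(pw[["alpha"]] / tot, 0.95)
  for (b in c("delta", "high_theta", "beta"))
    expect_lt(pw[[b]] / tot, 0.02)
})

test_that("feature extraction normalizes to the simplex and drops degenerates", {
  # rectangular densities strictly inside each band's interior give known
  # band powers (4, 2, 1, 1); fine grid keeps trapezoid edge error ~1e-4
  f2 <- seq(0, 40, by = 0.01)
  p2 <- numeric(length(f2))
  p2[f2 >= 1 & f2 <= 3] <- 2          # delta power 4
  p2[f2 >= 6.2 & f2 <= 7.8] <- 1.25   # high-theta power 2
  p2[f2 >= 9 & f2 <= 11] <- 0.5       # alpha power 1
  p2[f2 >= 15 & f2 <= 25] <- 0.1      # beta power 1
  sp <- spectralEpochs(0, f2, matrix(p2, 1))
  feats <- extractFeatures(sp)
  r <- featureRatios(feats)[, 1]
  expect_equal(unname(r), c(0.5, 0.25, 0.125, 0.125), tolerance = 1e-3)
  expect_equal(sum(r), 1, tolerance = 1e-12)

  # all-zero epoch is degenerate: dropped with a message, error if none left
  two <- spectralEpochs(c(0, 28), f2, rbind(p2, 0))
  expect_message(kept <- extractFeatures(two), "degenerate")
  expect_equal(epochTimes(kept), 0)
  expect_error(suppressMessages(extractFeatures(
    spectralEpochs(0, f2, matrix(0, 1, length(f2))))), "nonzero power")
})

test_that("ratios are invariant to PSD scaling and to buffer-band power", {
  sc <- threeRegimeScenario(segS = 40, fs = 100, seed = 9)
  rec <- bandpassFilter(toMono(generateEEG(sc)$record), 0.5, 30)
  sp <- epochSpectra(rec, winS = 30, stepS = 28)
  base <- featureRatios(extractFeatures(sp))

  scaled <- spectralEpochs(epochTimes(sp), freqGrid(sp), psdMatrix(sp) * 7.3)
  expect_equal(featureRatios(extractFeatures(scaled)), base, tolerance = 1e-12)

  # pump arbitrary power into the 4-6 and 12-13 Hz buffers: nothing changes
  P <- psdMatrix(sp)
  f <- freqGrid(sp)
  buf <- (f > 4 + 1e-9 & f < 6 - 1e-9) | (f > 12 + 1e-9 & f < 13 - 1e-9)
  P[, buf] <- P[, buf] + 50
  expect_equal(featureRatios(extractFeatures(
    spectralEpochs(epochTimes(sp), f, P))), base, tolerance = 1e-12)
})

test_that("feature views project the simplex consistently", {
  feats <- depthFeatureSet(t(rbind(c(0.5, 0.1, 0.3, 0.1))), 0)
  expect_equal(unname(featureMatrix(feats, "paper2d")[1, ]), c(0.5, 0.4))

  set.seed(21)
  R <- simplexCloud(c(0.4, 0.2, 0.25, 0.15), 200)
  feats2 <- depthFeatureSet(t(R), seq_len(200))
  M4 <- featureMatrix(feats2, "full4d")
  expect_equal(unname(rowSums(M4)), rep(1, 200))
  M2 <- featureMatrix(feats2, "paper2d")
  expect_true(all(M2 >= 0))
  expect_true(all(rowSums(M2) <= 1 + 1e-12))
  # deterministic linear image of full4d
  expect_equal(M2[, 1], M4[, "delta"], ignore_attr = TRUE)
  expect_equal(M2[, 2], M4[, "alpha"] + M4[, "high_theta"],
               ignore_attr = TRUE)
})

test_that("feature CSV round trip preserves times and ratios", {
  set.seed(4)
  feats <- depthFeatureSet(t(simplexCloud(c(0.4, 0.2, 0.25, 0.15), 10)),
                           seq(0, by = 28, length.out = 10))
  p <- withr::local_tempfile(fileext = ".csv")
  writeFeatureCSV(feats, p)
  back <- readFeatureCSV(p)
  expect_equal(epochTimes(back), epochTimes(feats))
  expect_equal(featureRatios(back), featureRatios(feats), tolerance = 1e-6)
})

test_that("invalid feature sets are rejected by the validity method", {
  expect_error(depthFeatureSet(matrix(c(0.5, 0.5, 0.5, 0.5), 4, 1), 0),
               "sum to 1")
  expect_error(depthFeatureSet(matrix(c(-0.1, 0.5, 0.4, 0.2), 4, 1), 0),
               "\\[0, 1\\]")
})
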
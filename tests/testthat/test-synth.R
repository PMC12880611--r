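test_that("generation is deterministic given the seed", {
  sc <- threeRegimeScenario(segS = 30, fs = 100, seed = 42)
  g1 <- generateEEG(sc)
  g2 <- generateEEG(sc)
  expect_identical(signalMatrix(g1$record), signalMatrix(g2$record))
  g3 <- generateEEG(threeRegimeScenario(segS = 30, fs = 100, seed = 43))
  expect_false(identical(signalMatrix(g1$record), signalMatrix(g3$record)))
})

test_that("default regimes have the intended analytic spectral character", {
  reg <- defaultRegimes()
  ef <- vapply(reg, expectedRegimeFeature, numeric(4))
  # simplex
  expect_equal(unname(colSums(ef)), rep(1, 3), tolerance = 1e-12)
  # deep: delta strictly the largest component
  expect_true(all(ef["delta", "deep"] > ef[c("high_theta", "alpha", "beta"),
                                           "deep"]))
  # light: beta strictly greater than in proper and deep
  expect_gt(ef["beta", "light"], ef["beta", "proper"])
  expect_gt(ef["beta", "light"], ef["beta", "deep"])
  # pairwise delta-ratio separation of at least 0.2
  d <- sort(ef["delta", ])
  expect_true(all(diff(d) >= 0.2))
})

test_that("long-run spectra match each regime's intended band ordering", {
  fs <- 100
  for (nm in c("light", "proper", "deep")) {
    sc <- synthScenario(data.frame(duration_s = 600, regime = nm,
                                   transition_s = 0), fs = fs, seed = 17)
    rec <- bandpassFilter(toMono(generateEEG(sc)$record), 0.5, 30)
    feats <- extractFeatures(epochSpectra(rec, winS = 30, stepS = 28))
    med <- apply(featureRatios(feats), 1, median)
    expected <- expectedRegimeFeature(defaultRegimes()[[nm]],
                                      nyquistHz = fs / 2)
    expect_equal(unname(med), unname(expected), tolerance = 0.12)
    expect_equal(order(med), order(expected))
  }
})

test_that("a pure deep segment yields delta-dominant features end to end", {
  sc <- synthScenario(data.frame(duration_s = 600, regime = "deep",
                                 transition_s = 0), fs = 100, seed = 23)
  rec <- bandpassFilter(toMono(generateEEG(sc)$record), 0.5, 30)
  med <- apply(featureRatios(extractFeatures(
    epochSpectra(rec, winS = 30, stepS = 28))), 1, median)
  expect_true(all(med["delta"] > med[c("high_theta", "alpha", "beta")]))
})

test_that("per-regime signal variance is stable (no drift within segments)", {
  sc <- threeRegimeScenario(segS = 120, fs = 100, seed = 3, transS = 0)
  g <- generateEEG(sc)
  x <- signalMatrix(g$record)[, 1]
  fs <- 100
  for (k in 0:2) {
    seg <- x[(k * 120 * fs + 1):((k + 1) * 120 * fs)]
    # variance in 20-s thirds of the inner 60 s agrees within 2x
    v <- vapply(0:2, function(j)
      var(seg[(30 * fs + j * 20 * fs + 1):(30 * fs + (j + 1) * 20 * fs)]), 0)
    expect_lt(max(v) / min(v), 2)
  }
  # amplitude ordering deep > proper > light by construction
  rmsSeg <- vapply(0:2, function(k)
    rmsOf(x[(k * 120 * fs + 1):((k + 1) * 120 * fs)]), 0)
  expect_true(all(diff(rmsSeg) > 0))
})

test_that("injected artifacts are caught by the amplitude mask", {
  af <- data.frame(time_s = 50, amplitude_uV = 800, duration_s = 1)
  sc <- threeRegimeScenario(segS = 40, fs = 100, seed = 6, artifacts = af)
  g <- generateEEG(sc)
  m <- autoArtifactMask(toMono(g$record), ampThreshUv = 300, padS = 0.5)
  iv <- maskIntervals(m)
  expect_gte(nrow(iv), 1L)
  expect_true(any(iv[, 1] <= 50.5 & iv[, 2] >= 50.5))
})

test_that("depth-index surrogate maps regimes, lags and clips", {
  truth1 <- data.frame(t_s = seq(0, 99.9, by = 0.1), regime = "proper")
  s0 <- makePsiSurrogate(truth1, noiseSd = 0, lagS = 0)
  expect_true(all(s0@values == 50))

  truth2 <- data.frame(t_s = seq(0, 199.9, by = 0.1),
                       regime = rep(c("light", "deep"), each = 1000))
  lag <- makePsiSurrogate(truth2, noiseSd = 0, lagS = 30)
  # scripted transition at 100 s appears at 130 s in the surrogate
  expect_true(all(lag@values[lag@times <= 129] == 85))
  expect_true(all(lag@values[lag@times >= 131] == 25))

  noisy <- makePsiSurrogate(truth2, noiseSd = 500, lagS = 0, seed = 2)
  expect_true(all(noisy@values >= 0 & noisy@values <= 100))
})

test_that("generator fixtures round trip through the readers", {
  sc <- threeRegimeScenario(segS = 15, fs = 100, seed = 12)
  g <- generateEEG(sc, nChannels = 2)
  d <- withr::local_tempdir()
  writeEEGCsv(g$record, file.path(d, "synth.csv"))
  writeTruthCSV(g$truth, file.path(d, "truth.csv"))
  back <- readEEG(file.path(d, "synth.csv"))
  expect_equal(signalMatrix(back), signalMatrix(g$record),
               tolerance = 1e-8, ignore_attr = TRUE)
  tr <- read.csv(file.path(d, "truth.csv"))
  expect_equal(nrow(tr), nrow(g$truth))
  expect_equal(unique(tr$regime), c("light", "proper", "deep"))
})
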
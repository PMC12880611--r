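# shared fixtures: tiny recordings, scenarios and numeric helpers

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

rmsOf <- function(x) sqrt(mean(x^2))

# short three-regime scenario (one segment per regime), fs 100 by default
threeRegimeScenario <- function(segS = 120, fs = 100, seed = 1,
                                transS = 10, artifacts = NULL) {
  synthScenario(
    data.frame(duration_s = rep(segS, 3),
               regime = c("light", "proper", "deep"),
               transition_s = c(0, transS, transS)),
    fs = fs, seed = seed, artifacts = artifacts)
}

# sinusoid record
sineRecord <- function(freqHz, durS = 60, fs = 100, amp = 1) {
  t <- seq(0, durS - 1 / fs, by = 1 / fs)
  eegRecord(amp * sin(2 * pi * freqHz * t), fs = fs)
}

# constant-PSD spectral container
flatSpectra <- function(value = 1, times = 0, fmax = 40, df = 0.25) {
  f <- seq(0, fmax, by = df)
  spectralEpochs(times, f, matrix(value, length(times), length(f)))
}

# random simplex points around given 4-d centers
simplexCloud <- function(center, n, sd = 0.02) {
  raw <- abs(matrix(rnorm(n * 4, rep(center, each = n), sd), n, 4))
  raw / rowSums(raw)
}

# greedy centroid matching between two c x d matrices; returns permutation p
# such that B[p, ] aligns with A
matchCentroids <- function(A, B) {
  cc <- nrow(A)
  p <- integer(cc)
  used <- logical(cc)
  for (i in seq_len(cc)) {
    d <- colSums((t(B) - A[i, ])^2)
    d[used] <- Inf
    p[i] <- which.min(d)
    used[p[i]] <- TRUE
  }
  p
}

# majority ground-truth regime per epoch window [t, t + winS)
epochTruth <- function(truth, times, winS) {
  vapply(times, function(t0) {
    seg <- truth$regime[truth$t_s >= t0 & truth$t_s < t0 + winS]
    names(sort(table(seg), decreasing = TRUE))[1]
  }, "")
}

regimeToLabel <- c(light = "slight", proper = "proper", deep = "deep")
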
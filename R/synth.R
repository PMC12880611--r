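#' @include AllClasses.R spectral.R
NULL

#' Default spectral regimes of the synthetic anesthesia EEG
#'
#' Three generative depth states mirroring intraoperative frontal-EEG
#' physiology: a beta-rich `light` state, a `proper` state with prominent
#' alpha over a delta background (the sevoflurane/propofol maintenance
#' signature), and a delta-dominant `deep` state with attenuated alpha and
#' beta. `band_weights` give each narrowband oscillator's share of the
#' oscillatory power (delta 0.5-4, high-theta 6-8, alpha 8-12, beta 13-30 Hz);
#' `noise_floor` the 1/f pink-noise power relative to the oscillators (0.1 so
#' the buffer bands carry nonzero power); `amplitude_uV` the RMS scale.
#'
#' The weights are fixed module constants chosen so the regimes' expected
#' band-ratio features sit on the simplex with pairwise delta-ratio
#' separation of at least 0.2 (analytically, including the 1/f contribution:
#' delta ratios about 0.18, 0.41 and 0.71).
#'
#' @return Named list of regime specs (`light`, `proper`, `deep`).
#' @export
defaultRegimes <- function() {
  list(
    light = list(band_weights = c(delta = 0.15, high_theta = 0.10,
                                  alpha = 0.20, beta = 0.55),
                 noise_floor = 0.1, amplitude_uV = 20),
    proper = list(band_weights = c(delta = 0.40, high_theta = 0.15,
                                   alpha = 0.35, beta = 0.10),
                  noise_floor = 0.1, amplitude_uV = 30),
    deep = list(band_weights = c(delta = 0.72, high_theta = 0.10,
                                 alpha = 0.13, beta = 0.05),
                noise_floor = 0.1, amplitude_uV = 40)
  )
}

#' Expected band-ratio feature of a regime
#'
#' Analytic expectation of the normalized 4-band feature under a regime's
#' generative weights: oscillator power lands in its own band; pink-noise
#' power distributes across bands proportional to `log(hi/lo)` over the
#' 0.5 Hz - Nyquist span. Used as the generator's own oracle in tests.
#'
#' @param regime one entry of [defaultRegimes()].
#' @param nyquistHz upper edge of the pink-noise span (default 89, i.e.
#'   fs = 178).
#' @return Named 4-vector on the simplex (delta, high_theta, alpha, beta).
#' @export
expectedRegimeFeature <- function(regime, nyquistHz = 89) {
  bands <- defaultBandScheme()$bands
  pinkShare <- vapply(bands, function(b) log(b[2] / b[1]), 0) /
    log(nyquistHz / 0.5)
  raw <- regime$band_weights + regime$noise_floor * pinkShare
  raw / sum(raw)
}

#' Scripted recording scenario
#'
#' @param segments data.frame with columns `duration_s`, `regime` (light /
#'   proper / deep) and `transition_s` (linear cross-fade length at the
#'   segment's start; 0 for the first segment).
#' @param fs sampling rate, Hz (default 178).
#' @param seed RNG seed for the generator.
#' @param artifacts optional data.frame with columns `time_s`,
#'   `amplitude_uV`, `duration_s` of injected high-amplitude transients.
#' @return A scenario list consumed by [generateEEG()].
#' @export
synthScenario <- function(segments, fs = 178, seed = 1L, artifacts = NULL) {
  stopifnot(all(c("duration_s", "regime") %in% names(segments)))
  if (is.null(segments$transition_s)) segments$transition_s <- 0
  if (any(segments$duration_s <= 0)) stop("segment durations must be positive")
  if (!all(segments$regime %in% c("light", "proper", "deep")))
    stop("regimes must be light, proper or deep")
  list(segments = segments, fs = fs, seed = as.integer(seed),
       artifacts = artifacts)
}

# unit-variance band-limited Gaussian process (randomized phase via white
# noise input); a 4th-order Butterworth isolates the band
bandNoise <- function(n, fs, lo, hi) {
  pad <- as.integer(round(2 * fs))
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n + 2L * pad))
  x <- x[(pad + 1L):(pad + n)]        # drop filter edges
  x / stats::sd(x)
}

# unit-variance 1/f pink noise by FFT spectral shaping
pinkNoise <- function(n, fs, loHz = 0.5) {
  nf <- n %/% 2L + 1L
  f <- (seq_len(nf) - 1L) * fs / n
  amp <- 1 / sqrt(pmax(f, loHz))      # flat below loHz, 1/f density above
  amp[1] <- 0
  ph <- stats::runif(nf) * 2 * pi
  spec <- complex(modulus = amp, argument = ph)
  full <- c(spec, Conj(rev(spec[2:(n - nf + 1L)])))
  x <- Re(stats::fft(full, inverse = TRUE))
  x / stats::sd(x)
}

#' Generate a synthetic anesthesia-EEG recording
#'
#' The signal is a sum of four band-limited Gaussian oscillators (centered in
#' the delta, high-theta, alpha and beta bands) plus a 1/f pink-noise floor,
#' with per-band standard deviations following the active regime's weights.
#' Regime changes cross-fade the weights linearly over each segment's
#' `transition_s`. Optional artifact events inject Hann-windowed
#' high-amplitude transients. Deterministic given the scenario seed.
#'
#' @param scenario a [synthScenario()].
#' @param regimes regime map, default [defaultRegimes()].
#' @param nChannels number of (identical-statistics, independent-noise)
#'   channels to emit; default 1.
#' @return A list: `record` (an [EEGRecord-class]), `truth` (data.frame
#'   `t_s`, `regime` per sample: the scripted ground-truth depth timeline).
#' @export
generateEEG <- function(scenario, regimes = defaultRegimes(), nChannels = 1L) {
  fs <- scenario$fs
  seg <- scenario$segments
  n <- as.integer(round(sum(seg$duration_s) * fs))
  bands <- defaultBandScheme()$bands
  regNames <- c("light", "proper", "deep")

  # per-sample target weights with linear cross-fades at segment starts
  t <- (seq_len(n) - 1) / fs
  segStart <- cumsum(c(0, seg$duration_s))[seq_len(nrow(seg))]
  segIdx <- findInterval(t, segStart)
  truthRegime <- seg$regime[segIdx]
  W <- matrix(0, n, 4,
              dimnames = list(NULL, names(bands)))  # oscillator SD weights
  noiseW <- numeric(n); ampl <- numeric(n)
  for (i in seq_len(nrow(seg))) {
    rows <- which(segIdx == i)
    rg <- regimes[[seg$regime[i]]]
    wNew <- rg$band_weights
    nNew <- rg$noise_floor; aNew <- rg$amplitude_uV
    frac <- rep(1, length(rows))
    if (i > 1L && seg$transition_s[i] > 0) {
      prev <- regimes[[seg$regime[i - 1L]]]
      frac <- pmin((t[rows] - segStart[i]) / seg$transition_s[i], 1)
      W[rows, ] <- outer(1 - frac, regimes[[seg$regime[i - 1L]]]$band_weights) +
        outer(frac, wNew)
      noiseW[rows] <- (1 - frac) * prev$noise_floor + frac * nNew
      ampl[rows] <- (1 - frac) * prev$amplitude_uV + frac * aNew
    } else {
      W[rows, ] <- matrix(wNew, length(rows), 4, byrow = TRUE)
      noiseW[rows] <- nNew
      ampl[rows] <- aNew
    }
  }

  record <- withr::with_seed(scenario$seed, {
    chans <- vapply(seq_len(nChannels), function(ch) {
      osc <- vapply(seq_along(bands), function(b) {
        bandNoise(n, fs, bands[[b]][1], bands[[b]][2]) * sqrt(W[, b])
      }, numeric(n))
      x <- rowSums(osc) + pinkNoise(n, fs) * sqrt(noiseW)
      x <- x / sqrt(1 + noiseW) * ampl    # total RMS ~ amplitude_uV
      x
    }, numeric(n))
    if (!is.null(scenario$artifacts)) {
      af <- scenario$artifacts
      for (i in seq_len(nrow(af))) {
        a <- as.integer(round(af$time_s[i] * fs)) + 1L
        len <- max(2L, as.integer(round(af$duration_s[i] * fs)))
        b <- min(a + len - 1L, n)
        k <- b - a + 1L
        pulse <- af$amplitude_uV[i] *
          (0.5 - 0.5 * cos(2 * pi * seq_len(k) / (k + 1)))
        chans[a:b, ] <- chans[a:b, ] + pulse
      }
    }
    eegRecord(chans, fs = fs,
              channelNames = paste0("synth", seq_len(nChannels)),
              subjectId = "synthetic")
  })
  list(record = record,
       truth = data.frame(t_s = t, regime = truthRegime))
}

#' Synthetic depth-index trace from a ground-truth timeline
#'
#' Maps regimes to plateau index values (light 85, proper 50, deep 25),
#' applies a pure time lag (processed depth indices trail the EEG), adds
#' Gaussian noise and clips to `[0, 100]`. Display-only: a stand-in
#' comparison trace for the report's index panel, never an input to any
#' computation.
#'
#' @param truth data.frame `t_s`, `regime` from [generateEEG()].
#' @param noiseSd additive noise SD (index units).
#' @param lagS pure delay, seconds (>= 0).
#' @param stepS sampling interval of the emitted series, seconds.
#' @param seed RNG seed for the noise.
#' @return A [PsiSeries-class].
#' @export
makePsiSurrogate <- function(truth, noiseSd = 0, lagS = 0, stepS = 1,
                             seed = 1L) {
  stopifnot(lagS >= 0)
  plateau <- c(light = 85, proper = 50, deep = 25)
  times <- seq(min(truth$t_s), max(truth$t_s), by = stepS)
  src <- times - lagS
  idx <- findInterval(src, truth$t_s, all.inside = TRUE)
  vals <- plateau[truth$regime[idx]]
  vals[src < min(truth$t_s)] <- plateau[truth$regime[1]]
  vals <- withr::with_seed(as.integer(seed),
                           vals + stats::rnorm(length(vals), 0, noiseSd))
  psiSeries(times, pmin(pmax(vals, 0), 100))
}

#' Write generator ground truth as CSV
#'
#' @param truth data.frame `t_s`, `regime`.
#' @param path CSV path.
#' @export
writeTruthCSV <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
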
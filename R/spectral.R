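#' @include AllClasses.R artifact.R
NULL

#' Butterworth bandpass filtering
#'
#' Applies a Butterworth bandpass (default fourth-order, 0.5-30 Hz, matching
#' the slow-delta lower edge and the top of the beta band) to every channel.
#' By default the filter is run forward and backward (`filtfilt`), giving zero
#' net group delay at the cost of squaring the magnitude response; set
#' `zeroPhase = FALSE` for a causal single pass.
#'
#' @param record an [EEGRecord-class].
#' @param lowHz,highHz passband edges, Hz; `0 < lowHz < highHz < fs/2`.
#' @param order filter design order (per band edge, the SciPy convention: a
#'   bandpass of design order n has a 2n-order transfer function).
#' @param zeroPhase forward-backward application (default TRUE).
#' @return The filtered [EEGRecord-class]; an attached artifact mask is
#'   preserved.
#' @examples
#' rec <- eegRecord(rnorm(1000), fs = 100)
#' filt <- bandpassFilter(rec, 0.5, 30)
#' @export
bandpassFilter <- function(record, lowHz = 0.5, highHz = 30, order = 4,
                           zeroPhase = TRUE) {
  fs <- samplingRate(record)
  if (!(lowHz > 0 && lowHz < highHz)) stop("need 0 < lowHz < highHz")
  if (highHz >= fs / 2)
    stop("highHz must be below the Nyquist frequency fs/2 = ", fs / 2)
  if (order < 1) stop("filter order must be >= 1")
  bf <- signal::butter(order, c(lowHz, highHz) / (fs / 2), type = "pass")
  X <- signalMatrix(record)
  Y <- apply(X, 2, function(x) {
    if (zeroPhase) signal::filtfilt(bf, x) else signal::filter(bf, x)
  })
  out <- eegRecord(Y, fs = fs, t0 = record@t0,
                   channelNames = channelNames(record),
                   subjectId = subjectId(record))
  attr(out, "mask") <- attr(record, "mask")
  out
}

#' Slide fixed-length analysis windows over a recording
#'
#' Epochs start at `0, stepS, 2*stepS, ...`; a partial tail window is
#' discarded, and any epoch overlapping a masked artifact interval (the mask
#' attached by [applyMask()] or passed explicitly) is excluded. The default
#' 30-second window with a 2-second overlap between consecutive windows gives
#' `stepS = 28`.
#'
#' @param record a single-channel [EEGRecord-class].
#' @param winS window length, seconds.
#' @param stepS advance between consecutive window starts, seconds
#'   (`0 < stepS <= winS`).
#' @param mask optional [ArtifactMask-class]; defaults to the record's
#'   attached mask.
#' @return A list with `times` (kept epoch starts, s), `blocks` (list of
#'   sample vectors) and `nMasked` (epochs dropped by the mask). A recording
#'   shorter than one window yields zero epochs with a warning.
#' @export
makeEpochs <- function(record, winS = 30, stepS = 28, mask = NULL) {
  stopifnot(stepS > 0, stepS <= winS)
  fs <- samplingRate(record)
  if (winS * fs < 2) stop("window must span at least 2 samples")
  x <- signalMatrix(record)
  if (ncol(x) > 1L) stop("makeEpochs expects a single-channel record; see toMono()")
  x <- x[, 1]
  dur <- length(x) / fs
  if (dur < winS) {
    warning("recording (", round(dur, 2), " s) shorter than one ", winS,
            "-s window: no epochs")
    return(list(times = numeric(), blocks = list(), nMasked = 0L))
  }
  if (is.null(mask)) mask <- recordMask(record)
  iv <- maskIntervals(mask)
  starts <- seq(0, dur - winS, by = stepS)
  nwin <- as.integer(round(winS * fs))
  keep <- logical(length(starts))
  blocks <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    t0 <- starts[k]; t1 <- t0 + winS
    masked <- nrow(iv) > 0L && any(iv[, 1] < t1 & iv[, 2] > t0)
    if (masked) next
    a <- as.integer(round(t0 * fs)) + 1L
    blk <- x[a:(a + nwin - 1L)]
    if (any(!is.finite(blk))) next  # nan_fill policy: masked samples are NA
    keep[k] <- TRUE
    blocks[[k]] <- blk
  }
  list(times = starts[keep], blocks = blocks[keep],
       nMasked = sum(!keep))
}

#' Welch power spectral density of one epoch
#'
#' Averaged-periodogram estimate: the epoch is cut into Hann-tapered segments
#' (default 4 s, 50% overlap), each constant-detrended, and the one-sided
#' periodograms are averaged with density scaling, so that
#' \eqn{\int_0^{f_s/2} P(f)\,df} approximates the signal variance. The grid
#' includes the 0 and Nyquist endpoints.
#'
#' @param x numeric sample vector (one epoch).
#' @param fs sampling rate, Hz.
#' @param segS Welch segment length, seconds (default 4, i.e. 0.25 Hz
#'   resolution).
#' @param segOverlapFrac fractional overlap between segments (default 0.5).
#' @return A list with `freqs` (Hz) and `psd` (microV^2/Hz).
#' @examples
#' w <- welchPSD(rnorm(3000), fs = 100)
#' sum(diff(w$freqs) * (head(w$psd, -1) + tail(w$psd, -1)) / 2)  # ~ variance
#' @export
welchPSD <- function(x, fs, segS = 4, segOverlapFrac = 0.5) {
  ns <- as.integer(round(segS * fs))
  if (length(x) < ns)
    stop("epoch (", length(x), " samples) shorter than one Welch segment (",
         ns, ")")
  step <- max(1L, as.integer(round(ns * (1 - segOverlapFrac))))
  starts <- seq(1L, length(x) - ns + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, ns - 1) / ns)  # periodic Hann
  scale <- fs * sum(w^2)
  acc <- numeric(ns)
  for (s in starts) {
    seg <- x[s:(s + ns - 1L)]
    seg <- seg - mean(seg)
    acc <- acc + Mod(stats::fft(seg * w))^2
  }
  P <- acc / (length(starts) * scale)
  nf <- ns %/% 2L + 1L
  P1 <- P[seq_len(nf)]
  if (ns %% 2L == 0L) P1[2:(nf - 1L)] <- 2 * P1[2:(nf - 1L)]
  else P1[2:nf] <- 2 * P1[2:nf]
  list(freqs = (seq_len(nf) - 1L) * fs / ns, psd = P1)
}

#' Per-epoch spectra for a recording
#'
#' Convenience wrapper: windows the recording with [makeEpochs()] and runs
#' [welchPSD()] on every kept epoch.
#'
#' @inheritParams makeEpochs
#' @inheritParams welchPSD
#' @return A [SpectralEpochs-class] (with the number of mask-dropped epochs
#'   in the `nMasked` attribute).
#' @export
epochSpectra <- function(record, winS = 30, stepS = 28, mask = NULL,
                         segS = 4, segOverlapFrac = 0.5) {
  ep <- makeEpochs(record, winS = winS, stepS = stepS, mask = mask)
  fs <- samplingRate(record)
  if (length(ep$times) == 0L) {
    out <- spectralEpochs(numeric(), welchPSD(numeric(round(segS * fs)) + 0,
                                              fs, segS)$freqs,
                          matrix(0, 0, as.integer(round(segS * fs)) %/% 2L + 1L))
    attr(out, "nMasked") <- ep$nMasked
    return(out)
  }
  specs <- lapply(ep$blocks, welchPSD, fs = fs, segS = segS,
                  segOverlapFrac = segOverlapFrac)
  out <- spectralEpochs(ep$times, specs[[1]]$freqs,
                        do.call(rbind, lapply(specs, `[[`, "psd")))
  attr(out, "nMasked") <- ep$nMasked
  out
}

#' Density-spectral-array image
#'
#' Converts per-epoch PSDs to decibels (`10*log10`), clipping below at
#' `floorDb`, for the time-frequency panel of the depth report.
#'
#' @param epochs a [SpectralEpochs-class] (at least one epoch).
#' @param floorDb clipping floor in dB (default -40).
#' @param maxFreqHz optional upper frequency cut for display.
#' @return A [TimeFrequencyImage-class].
#' @export
dsaImage <- function(epochs, floorDb = -40, maxFreqHz = NULL) {
  if (length(epochTimes(epochs)) < 1L) stop("need at least one epoch")
  f <- freqGrid(epochs)
  P <- psdMatrix(epochs)
  if (!is.null(maxFreqHz)) {
    keep <- f <= maxFreqHz
    f <- f[keep]; P <- P[, keep, drop = FALSE]
  }
  db <- 10 * log10(pmax(P, 10^(floorDb / 10)))
  ord <- order(epochTimes(epochs))
  new("TimeFrequencyImage", times = epochTimes(epochs)[ord], freqs = f,
      powerDb = db[ord, , drop = FALSE], floorDb = floorDb)
}
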
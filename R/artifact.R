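#' @include AllClasses.R
NULL

#' Automatic amplitude-threshold artifact detection
#'
#' Flags every sample whose absolute amplitude exceeds the threshold, pads
#' each flagged run by `padS` seconds on both sides, and merges overlapping
#' intervals. An automated surrogate for epoch-level visual artifact
#' rejection: high-amplitude transients (movement, electrode pops, cautery)
#' dwarf cortical EEG, which rarely exceeds ~100 microvolts peak.
#'
#' @param record an [EEGRecord-class] (multi-channel allowed; a sample is
#'   flagged when any channel exceeds the threshold).
#' @param ampThreshUv amplitude threshold, microvolts (> 0). Default 300.
#' @param padS padding added around each flagged run, seconds.
#' @return An [ArtifactMask-class] with disjoint, sorted intervals clipped to
#'   `[0, duration]`.
#' @export
autoArtifactMask <- function(record, ampThreshUv = 300, padS = 0.5) {
  stopifnot(ampThreshUv > 0, padS >= 0)
  X <- signalMatrix(record)
  fs <- samplingRate(record)
  bad <- rowSums(abs(X) > ampThreshUv) > 0L
  if (!any(bad)) return(artifactMask())
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  iv <- cbind((starts[keep] - 1L) / fs - padS, ends[keep] / fs + padS)
  iv[, 1] <- pmax(iv[, 1], 0)
  iv[, 2] <- pmin(iv[, 2], duration(record))
  artifactMask(iv[, 1], iv[, 2])
}

#' Apply an artifact mask to a recording
#'
#' Two policies: `"drop_epochs"` leaves the samples untouched and attaches the
#' mask so that downstream windowing ([makeEpochs()]) discards any epoch
#' overlapping a masked interval (the default, matching epoch-level
#' exclusion); `"nan_fill"` replaces masked samples with `NA` in place.
#'
#' @param record an [EEGRecord-class].
#' @param mask an [ArtifactMask-class] whose intervals lie within the record.
#' @param policy `"drop_epochs"` or `"nan_fill"`.
#' @return An [EEGRecord-class]; under `drop_epochs` the mask travels in the
#'   `mask` attribute and is honored by [makeEpochs()].
#' @export
applyMask <- function(record, mask, policy = c("drop_epochs", "nan_fill")) {
  policy <- match.arg(policy)
  iv <- maskIntervals(mask)
  if (nrow(iv) && (any(iv[, 1] < 0) || any(iv[, 2] > duration(record) + 1e-9)))
    stop("mask interval lies outside the recording")
  if (policy == "drop_epochs") {
    attr(record, "mask") <- mask
    return(record)
  }
  X <- signalMatrix(record)
  fs <- samplingRate(record)
  for (i in seq_len(nrow(iv))) {
    a <- floor(iv[i, 1] * fs) + 1L
    b <- min(ceiling(iv[i, 2] * fs), nrow(X))
    X[a:b, ] <- NA_real_
  }
  out <- eegRecord(X, fs = fs, t0 = record@t0,
                   channelNames = channelNames(record),
                   subjectId = subjectId(record))
  attr(out, "mask") <- mask
  out
}

recordMask <- function(record) {
  m <- attr(record, "mask")
  if (is.null(m)) artifactMask() else m
}
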
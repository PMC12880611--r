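#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

DEPTH_BAND_NAMES <- c("delta", "high_theta", "alpha", "beta")
DEPTH_LABELS <- c("slight", "proper", "deep")

#' Single-subject EEG recording
#'
#' Holds a frontal EEG signal (one column per channel, microvolts), its
#' sampling rate and the recording start offset. This is the object every
#' preprocessing stage consumes and returns.
#'
#' @slot samples numeric matrix, samples x channels, in microvolts.
#' @slot fs sampling rate in Hz.
#' @slot t0 recording start, seconds.
#' @slot channelNames character vector, one per column.
#' @slot subjectId opaque subject identifier.
#'
#' @exportClass EEGRecord
setClass("EEGRecord",
  representation(
    samples = "matrix",
    fs = "numeric",
    t0 = "numeric",
    channelNames = "character",
    subjectId = "character"
  )
)

setValidity("EEGRecord", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(object@samples) < 1L)
    msg <- c(msg, "recording must contain at least one sample")
  if (ncol(object@samples) < 1L)
    msg <- c(msg, "recording must contain at least one channel")
  if (length(object@channelNames) != ncol(object@samples))
    msg <- c(msg, "one channel name per column required")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecord
#'
#' @param samples numeric vector (single channel) or samples x channels matrix,
#'   amplitudes in microvolts.
#' @param fs sampling rate (Hz), must be positive.
#' @param t0 recording start time in seconds (default 0).
#' @param channelNames optional channel names; defaults to `ch1`, `ch2`, ...
#' @param subjectId subject identifier string.
#' @return An [EEGRecord-class] object.
#' @examples
#' rec <- eegRecord(sin(2 * pi * 10 * seq(0, 1, by = 1 / 100)), fs = 100)
#' duration(rec)
#' @export
eegRecord <- function(samples, fs, t0 = 0, channelNames = NULL,
                      subjectId = "anonymous") {
  if (is.null(dim(samples))) samples <- matrix(as.numeric(samples), ncol = 1L)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (is.null(channelNames)) {
    channelNames <- if (!is.null(colnames(samples))) colnames(samples)
      else paste0("ch", seq_len(ncol(samples)))
  }
  colnames(samples) <- channelNames
  new("EEGRecord", samples = samples, fs = as.numeric(fs), t0 = as.numeric(t0),
      channelNames = channelNames, subjectId = subjectId)
}

#' Artifact mask: half-open rejected time intervals
#'
#' Canonical (sorted, merged, non-overlapping) set of `[start, end)` intervals
#' in seconds from recording start. Epochs overlapping a masked interval are
#' discarded during windowing.
#'
#' @slot intervals two-column numeric matrix (start_s, end_s).
#' @exportClass ArtifactMask
setClass("ArtifactMask", representation(intervals = "matrix"))

setValidity("ArtifactMask", function(object) {
  iv <- object@intervals
  if (ncol(iv) != 2L) return("intervals must have two columns (start_s, end_s)")
  if (nrow(iv) == 0L) return(TRUE)
  if (any(!is.finite(iv))) return("intervals must be finite")
  if (any(iv[, 1] >= iv[, 2])) return("each interval needs start_s < end_s")
  if (nrow(iv) > 1L) {
    if (any(diff(iv[, 1]) <= 0)) return("intervals must be sorted by start")
    if (any(iv[-1L, 1] < iv[-nrow(iv), 2])) return("intervals must not overlap")
  }
  TRUE
})

#' Construct an artifact mask
#'
#' Intervals are canonicalized: sorted by start, and overlapping or touching
#' intervals merged.
#'
#' @param starts,ends numeric vectors of equal length, interval bounds in
#'   seconds (half-open, `start < end`).
#' @return An [ArtifactMask-class].
#' @examples
#' artifactMask(c(10, 11), c(11.5, 14))  # merges into [10, 14)
#' @export
artifactMask <- function(starts = numeric(), ends = numeric()) {
  stopifnot(length(starts) == length(ends))
  iv <- cbind(start_s = as.numeric(starts), end_s = as.numeric(ends))
  new("ArtifactMask", intervals = canonicalizeIntervals(iv))
}

# sort by start, merge overlapping/abutting intervals
canonicalizeIntervals <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  if (any(iv[, 1] >= iv[, 2])) stop("each interval needs start_s < end_s")
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  if (nrow(iv) > 1L) for (i in 2:nrow(iv)) {
    last <- nrow(out)
    if (iv[i, 1] <= out[last, 2]) {
      out[last, 2] <- max(out[last, 2], iv[i, 2])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  colnames(out) <- c("start_s", "end_s")
  out
}

#' Patient State Index trace
#'
#' A display-only depth-index time series (0-100) used for side-by-side
#' visualization with cluster memberships; never enters any computation.
#'
#' @slot times numeric, strictly increasing timestamps (s).
#' @slot values numeric index values in `[0, 100]`.
#' @exportClass PsiSeries
setClass("PsiSeries", representation(times = "numeric", values = "numeric"))

setValidity("PsiSeries", function(object) {
  if (length(object@times) != length(object@values))
    return("times and values must have equal length")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (length(object@values) && any(object@values < 0 | object@values > 100))
    return("index values must lie in [0, 100]")
  TRUE
})

#' @param times,values timestamps (s, strictly increasing) and index values in
#'   `[0, 100]`.
#' @rdname PsiSeries-class
#' @export
psiSeries <- function(times, values) {
  new("PsiSeries", times = as.numeric(times), values = as.numeric(values))
}

#' Per-epoch Welch power spectral densities
#'
#' One row per analysis window: the one-sided PSD (microV^2/Hz) on a common
#' frequency grid, with the window start time.
#'
#' @slot times numeric epoch start times (s).
#' @slot freqs monotone frequency grid (Hz) spanning at least `[0.5, 30]`.
#' @slot psd epochs x frequencies matrix of nonnegative densities.
#' @exportClass SpectralEpochs
setClass("SpectralEpochs",
  representation(times = "numeric", freqs = "numeric", psd = "matrix"))

setValidity("SpectralEpochs", function(object) {
  msg <- character()
  if (nrow(object@psd) != length(object@times))
    msg <- c(msg, "one PSD row per epoch time required")
  if (ncol(object@psd) != length(object@freqs))
    msg <- c(msg, "one PSD column per grid frequency required")
  if (length(object@freqs) > 1L && any(diff(object@freqs) <= 0))
    msg <- c(msg, "frequency grid must be strictly increasing")
  if (length(object@psd) && any(object@psd < 0, na.rm = TRUE))
    msg <- c(msg, "PSD values must be nonnegative")
  if (length(msg)) msg else TRUE
})

spectralEpochs <- function(times, freqs, psd) {
  new("SpectralEpochs", times = as.numeric(times), freqs = as.numeric(freqs),
      psd = psd)
}

#' Time-frequency (density spectral array) image
#'
#' Decibel-scaled epoch-by-frequency power matrix for DSA-style plotting.
#'
#' @slot times epoch start times (s).
#' @slot freqs frequency grid (Hz).
#' @slot powerDb epochs x frequencies matrix, dB, clipped below at the floor.
#' @slot floorDb the clipping floor used (dB).
#' @exportClass TimeFrequencyImage
setClass("TimeFrequencyImage",
  representation(times = "numeric", freqs = "numeric", powerDb = "matrix",
                 floorDb = "numeric"))

#' Normalized band-power ratio features
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' whose `"ratios"` assay holds the 4 x epochs matrix of normalized band-power
#' ratios (rows `delta`, `high_theta`, `alpha`, `beta`; each column a point on
#' the 4-simplex), with epoch start times in `colData(x)$t_start_s`.
#'
#' @exportClass DepthFeatureSet
setClass("DepthFeatureSet", contains = "SummarizedExperiment")

setValidity("DepthFeatureSet", function(object) {
  m <- SummarizedExperiment::assay(object, "ratios")
  if (!identical(rownames(m), DEPTH_BAND_NAMES))
    return("assay rows must be delta, high_theta, alpha, beta")
  if (is.null(SummarizedExperiment::colData(object)$t_start_s))
    return("colData must carry t_start_s")
  if (ncol(m)) {
    if (any(!is.finite(m))) return("ratios must be finite")
    if (any(m < 0 | m > 1)) return("ratios must lie in [0, 1]")
    if (any(abs(colSums(m) - 1) > 1e-9))
      return("each epoch's ratios must sum to 1 (within 1e-9)")
  }
  TRUE
})

#' Construct a DepthFeatureSet
#'
#' @param ratios 4 x epochs matrix (rows delta, high_theta, alpha, beta), each
#'   column summing to 1.
#' @param times epoch start times in seconds.
#' @param subjectId optional subject identifier stored in metadata.
#' @return A [DepthFeatureSet-class].
#' @export
depthFeatureSet <- function(ratios, times, subjectId = "anonymous") {
  ratios <- as.matrix(ratios)
  rownames(ratios) <- DEPTH_BAND_NAMES
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ratios = ratios),
    colData = S4Vectors::DataFrame(t_start_s = as.numeric(times)))
  out <- new("DepthFeatureSet", se)
  S4Vectors::metadata(out)$subjectId <- subjectId
  validObject(out)
  out
}

#' Fitted Fuzzy C-Means model
#'
#' Centroids in feature space (one row per cluster), the fuzziness and
#' convergence settings they were fitted under, the final objective
#' \eqn{J_m = \sum_i \sum_k u_{ik}^m d_{ik}^2}, and the physiological
#' centroid-to-depth-label map assigned by [assignDepthLabels()].
#'
#' @slot centroids c x d numeric matrix.
#' @slot m fuzziness exponent (> 1).
#' @slot tol convergence threshold on the membership-matrix change.
#' @slot maxIter,nRestarts,seed fitting controls.
#' @slot objective final objective value of the winning restart.
#' @slot objectiveTrace per-iteration objective of the winning restart.
#' @slot converged FALSE when maxIter was hit before the tolerance.
#' @slot labelMap character of length c: "slight"/"proper"/"deep", or NA
#'   before labeling.
#' @slot featureSpace "full4d" or "paper2d".
#' @exportClass FCMModel
setClass("FCMModel",
  representation(
    centroids = "matrix", m = "numeric", tol = "numeric",
    maxIter = "integer", nRestarts = "integer", seed = "integer",
    objective = "numeric", objectiveTrace = "numeric",
    converged = "logical", labelMap = "character", featureSpace = "character"
  )
)

setValidity("FCMModel", function(object) {
  msg <- character()
  if (nrow(object@centroids) < 2L) msg <- c(msg, "need at least 2 clusters")
  if (any(!is.finite(object@centroids))) msg <- c(msg, "centroids must be finite")
  if (object@m <= 1) msg <- c(msg, "fuzziness exponent m must exceed 1")
  if (object@tol <= 0) msg <- c(msg, "tol must be positive")
  if (length(object@labelMap) != nrow(object@centroids))
    msg <- c(msg, "labelMap must have one entry per centroid")
  known <- is.na(object@labelMap) | object@labelMap %in% DEPTH_LABELS
  if (!all(known)) msg <- c(msg, "labels must be slight, proper or deep")
  if (!anyNA(object@labelMap) && nrow(object@centroids) == 3L &&
      anyDuplicated(object@labelMap))
    msg <- c(msg, "labelMap must be a bijection onto the three depth labels")
  if (length(msg)) msg else TRUE
})

#' Fuzzy membership trace for one recording
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' whose `"membership"` assay is the clusters x epochs membership matrix (each
#' column summing to 1); `colData` carries the epoch start time, the simplified
#' argmax depth label and its confidence (the maximal membership).
#'
#' @exportClass MembershipSeries
setClass("MembershipSeries", contains = "SummarizedExperiment")

setValidity("MembershipSeries", function(object) {
  U <- SummarizedExperiment::assay(object, "membership")
  cd <- SummarizedExperiment::colData(object)
  need <- c("t_start_s", "hard_label", "confidence")
  if (!all(need %in% colnames(cd)))
    return("colData must carry t_start_s, hard_label and confidence")
  if (ncol(U)) {
    if (any(U < -1e-12 | U > 1 + 1e-12)) return("memberships must lie in [0, 1]")
    if (any(abs(colSums(U) - 1) > 1e-9))
      return("membership columns must sum to 1 (within 1e-9)")
  }
  TRUE
})

membershipSeries <- function(U, times, hardLabel, confidence,
                             subjectId = "anonymous") {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(membership = U),
    colData = S4Vectors::DataFrame(
      t_start_s = as.numeric(times),
      hard_label = as.character(hardLabel),
      confidence = as.numeric(confidence)))
  out <- new("MembershipSeries", se)
  S4Vectors::metadata(out)$subjectId <- subjectId
  validObject(out)
  out
}
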
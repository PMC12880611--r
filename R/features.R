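#' @include AllClasses.R spectral.R
NULL

#' The depth-staging band scheme
#'
#' Four feature bands — delta (0.5-4 Hz), high-theta (6-8 Hz), alpha
#' (8-12 Hz), beta (13-30 Hz) — separated by deliberately excluded "spectral
#' buffer" ranges at 4-6 Hz and 12-13 Hz. Power in the buffers contributes to
#' no feature, which de-emphasizes the transitional low-theta / low-beta zones
#' whose power varies little across hypnotic states.
#'
#' @return A list with `bands` (named list of `c(lo, hi)` in Hz, in feature
#'   order) and `buffers` (excluded ranges).
#' @export
defaultBandScheme <- function() {
  list(
    bands = list(delta = c(0.5, 4), high_theta = c(6, 8),
                 alpha = c(8, 12), beta = c(13, 30)),
    buffers = list(c(4, 6), c(12, 13))
  )
}

#' Band power by trapezoidal integration
#'
#' Integrates an epoch's PSD over `[loHz, hiHz]` with the trapezoid rule on
#' the frequency grid. Adjacent closed bands tile without double counting
#' (the integral over \[6,8\] plus \[8,12\] equals the integral over \[6,12\]).
#'
#' @param freqs monotone frequency grid (Hz).
#' @param psd PSD values on the grid (microV^2/Hz).
#' @param loHz,hiHz band edges, `loHz < hiHz`, inside the grid span.
#' @return Band power in microV^2 (nonnegative).
#' @examples
#' f <- seq(0, 50, by = 0.25)
#' bandPower(f, rep(1, length(f)), 8, 12)  # 4
#' @export
bandPower <- function(freqs, psd, loHz, hiHz) {
  if (loHz >= hiHz) stop("need loHz < hiHz")
  if (loHz < min(freqs) - 1e-9 || hiHz > max(freqs) + 1e-9)
    stop("band [", loHz, ", ", hiHz, "] outside the spectral grid [",
         min(freqs), ", ", max(freqs), "]")
  # grid points inside the band, plus interpolated values at the exact edges
  inside <- freqs > loHz & freqs < hiHz
  f <- c(loHz, freqs[inside], hiHz)
  p <- c(stats::approx(freqs, psd, xout = loHz)$y, psd[inside],
         stats::approx(freqs, psd, xout = hiHz)$y)
  sum(diff(f) * (p[-length(p)] + p[-1]) / 2)
}

#' Normalized band-power ratio features
#'
#' For every epoch: integrate the PSD over the four feature bands and divide
#' each band power by the four-band sum, so the feature vector lies on the
#' 4-simplex (components in `[0,1]`, summing to 1). Power in the buffer
#' ranges contributes to nothing. Epochs whose four-band total is zero are
#' degenerate and dropped with a message.
#'
#' @param epochs a [SpectralEpochs-class].
#' @param scheme band scheme, see [defaultBandScheme()].
#' @param subjectId carried into the result's metadata.
#' @return A [DepthFeatureSet-class] (epochs as columns).
#' @export
extractFeatures <- function(epochs, scheme = defaultBandScheme(),
                            subjectId = "anonymous") {
  f <- freqGrid(epochs)
  P <- psdMatrix(epochs)
  n <- nrow(P)
  pw <- vapply(scheme$bands, function(b) {
    vapply(seq_len(n), function(i) bandPower(f, P[i, ], b[1], b[2]), 0)
  }, numeric(n))
  pw <- matrix(pw, nrow = n,
               dimnames = list(NULL, names(scheme$bands)))  # robust at n == 1
  tot <- rowSums(pw)
  ok <- tot > 0
  if (!all(ok))
    message("dropping ", sum(!ok), " degenerate epoch(s) with zero band power")
  if (!any(ok))
    stop("no epoch has nonzero power in the feature bands")
  ratios <- t(pw[ok, , drop = FALSE] / tot[ok])
  depthFeatureSet(ratios, epochTimes(epochs)[ok], subjectId = subjectId)
}

#' Feature matrix views
#'
#' `full4d` is the epochs x 4 matrix of (delta, high_theta, alpha, beta)
#' ratios; `paper2d` is the epochs x 2 projection used for the cluster
#' scatter: delta ratio on x, alpha + high-theta ratio on y (beta is implied
#' as `1 - x - y`). Rows keep epoch start times as rownames.
#'
#' @param features a [DepthFeatureSet-class].
#' @param view `"full4d"` or `"paper2d"`.
#' @return Numeric matrix, one row per epoch.
#' @export
featureMatrix <- function(features, view = c("full4d", "paper2d")) {
  view <- match.arg(view)
  R <- t(featureRatios(features))
  rownames(R) <- format(epochTimes(features), trim = TRUE)
  if (view == "full4d") return(R)
  cbind(delta = R[, "delta"],
        alpha_high_theta = R[, "alpha"] + R[, "high_theta"])
}

#' Read / write feature tables as CSV
#'
#' Columns `t_start_s, delta, high_theta, alpha, beta`.
#'
#' @param features a [DepthFeatureSet-class].
#' @param path CSV path.
#' @export
writeFeatureCSV <- function(features, path) {
  df <- data.frame(t_start_s = epochTimes(features),
                   t(featureRatios(features)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  df <- utils::read.csv(path)
  depthFeatureSet(t(as.matrix(df[, DEPTH_BAND_NAMES])), df$t_start_s)
}
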
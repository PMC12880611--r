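#' @include AllClasses.R eeg-io.R spectral.R features.R fcm.R
NULL

#' Default pipeline configuration
#'
#' Every stage parameter in one nested list, with the published method's
#' values as defaults: channel averaging before filtering; fourth-order
#' Butterworth 0.5-30 Hz zero-phase bandpass; 30-s analysis windows with 2 s
#' of overlap between consecutive windows (step 28 s); Welch segments of 4 s
#' at 50% overlap; the 4-band scheme with 4-6 and 12-13 Hz buffers; FCM with
#' c = 3, m = 2, tol = 0.005, 10 random restarts; automatic amplitude-
#' threshold artifact masking at 300 microvolts; no temporal smoothing.
#'
#' @param ... named overrides of top-level entries (partial nested lists are
#'   merged).
#' @return A named configuration list.
#' @export
defaultRunConfig <- function(...) {
  cfg <- list(
    version = 1L,
    filter = list(order = 4, low_hz = 0.5, high_hz = 30, zero_phase = TRUE),
    window = list(win_s = 30, step_s = 28),
    welch = list(seg_s = 4, overlap = 0.5),
    feature_space = "full4d",
    fcm = list(c = 3L, m = 2, tol = 0.005, max_iter = 300L,
               n_restarts = 10L, seed = 1L),
    artifact = list(auto = TRUE, amp_thresh_uV = 300, pad_s = 0.5),
    smoothing = list(half_width = 0L),
    dsa = list(floor_db = -40, max_freq_hz = 30)
  )
  mergeConfig(cfg, list(...))
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to
#' [defaultRunConfig()] values.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  known <- names(defaultRunConfig())
  bad <- setdiff(names(user), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(defaultRunConfig, user)
}

# io -> mono -> (auto mask) -> filter -> epochs -> PSD -> features
recordingFeatures <- function(record, config) {
  mono <- toMono(record)
  mask <- recordMask(record)
  if (isTRUE(config$artifact$auto)) {
    auto <- autoArtifactMask(mono, config$artifact$amp_thresh_uV,
                             config$artifact$pad_s)
    iv <- rbind(maskIntervals(mask), maskIntervals(auto))
    mask <- if (nrow(iv)) artifactMask(iv[, 1], iv[, 2]) else artifactMask()
  }
  filt <- bandpassFilter(mono, config$filter$low_hz, config$filter$high_hz,
                         config$filter$order, config$filter$zero_phase)
  spec <- epochSpectra(filt, winS = config$window$win_s,
                       stepS = config$window$step_s, mask = mask,
                       segS = config$welch$seg_s,
                       segOverlapFrac = config$welch$overlap)
  if (length(epochTimes(spec)) == 0L)
    return(list(features = NULL, spectra = spec,
                counts = c(epochs = 0L, masked = attr(spec, "nMasked"),
                           degenerate = 0L)))
  feats <- extractFeatures(spec, subjectId = subjectId(record))
  list(features = feats, spectra = spec,
       counts = c(epochs = ncol(feats), masked = attr(spec, "nMasked"),
                  degenerate = length(epochTimes(spec)) - ncol(feats)))
}

#' Fit the global depth model over a cohort
#'
#' Runs the full preprocessing chain on every recording (channel averaging,
#' optional automatic artifact masking, bandpass, windowing, Welch PSD,
#' band-ratio features), pools the feature matrices with equal weight, fits
#' the global Fuzzy C-Means model and labels its centroids physiologically.
#'
#' @param recordings list of [EEGRecord-class] objects (or file paths readable
#'   by [readEEG()]).
#' @param config pipeline configuration, see [defaultRunConfig()].
#' @param modelPath optional path; when given the labeled model is persisted
#'   as JSON.
#' @return A list: `model` (labeled [FCMModel-class]), `features` (per-
#'   recording [DepthFeatureSet-class] list), `pooled` (pooled feature
#'   matrix), `counts` (per-recording epoch accounting: kept, masked,
#'   degenerate).
#' @export
runFit <- function(recordings, config = defaultRunConfig(),
                   modelPath = NULL) {
  if (!length(recordings)) stop("need at least one recording")
  recordings <- lapply(recordings, function(r)
    if (is.character(r)) readEEG(r) else r)
  per <- lapply(recordings, recordingFeatures, config = config)
  counts <- do.call(rbind, lapply(per, `[[`, "counts"))
  rownames(counts) <- vapply(recordings, subjectId, "")
  featList <- Filter(Negate(is.null), lapply(per, `[[`, "features"))
  if (!length(featList))
    stop("no usable epochs in any recording:\n",
         paste(utils::capture.output(print(counts)), collapse = "\n"))
  pooled <- do.call(rbind, lapply(featList, featureMatrix,
                                  view = config$feature_space))
  if (nrow(pooled) < config$fcm$c)
    stop("cohort yields ", nrow(pooled), " epochs; need at least c = ",
         config$fcm$c)
  model <- fcmFit(pooled, c = config$fcm$c, m = config$fcm$m,
                  tol = config$fcm$tol, maxIter = config$fcm$max_iter,
                  nRestarts = config$fcm$n_restarts, seed = config$fcm$seed,
                  featureSpace = config$feature_space)
  if (config$fcm$c == 3L) model <- assignDepthLabels(model)
  if (!is.null(modelPath)) writeModelJSON(model, modelPath)
  list(model = model, features = featList, pooled = pooled, counts = counts)
}

#' Apply a fitted model to one recording
#'
#' Preprocesses the recording identically to [runFit()], computes fuzzy
#' memberships against the model's fixed centroids (no refitting), optionally
#' smooths, and assembles the synchronized report inputs: membership series,
#' DSA image and (optionally) a depth-index trace.
#'
#' @param record an [EEGRecord-class] or file path.
#' @param model a labeled [FCMModel-class] (or path to its JSON).
#' @param config pipeline configuration matching the fit.
#' @param psi optional [PsiSeries-class] or CSV path; unreadable files drop
#'   the index panel with a warning instead of failing.
#' @param outDir optional directory; when given, membership and feature CSVs
#'   are written there.
#' @return A list: `membership` ([MembershipSeries-class]), `features`,
#'   `dsa` ([TimeFrequencyImage-class]), `psi` (possibly NULL), `counts`.
#' @export
runApply <- function(record, model, config = defaultRunConfig(), psi = NULL,
                     outDir = NULL) {
  if (is.character(record)) record <- readEEG(record)
  if (is.character(model)) model <- readModelJSON(model)
  if (model@featureSpace != config$feature_space)
    stop("model feature space (", model@featureSpace,
         ") does not match the configuration (", config$feature_space, ")")
  per <- recordingFeatures(record, config)
  if (is.null(per$features))
    stop("recording yields no usable epochs (", per$counts[["masked"]],
         " masked)")
  series <- applyModel(per$features, model)
  if (config$smoothing$half_width > 0L)
    series <- smoothLabels(series, config$smoothing$half_width)
  if (is.character(psi)) {
    psi <- tryCatch(suppressWarnings(readPsi(psi)), error = function(e) {
      warning("depth-index trace unreadable, omitting panel: ",
              conditionMessage(e))
      NULL
    })
  }
  dsa <- dsaImage(per$spectra, floorDb = config$dsa$floor_db,
                  maxFreqHz = config$dsa$max_freq_hz)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeMembershipCSV(series, file.path(outDir, "membership.csv"))
    writeFeatureCSV(per$features, file.path(outDir, "features.csv"))
  }
  list(membership = series, features = per$features, dsa = dsa, psi = psi,
       counts = per$counts)
}
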
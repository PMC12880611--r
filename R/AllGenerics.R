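#' @include AllClasses.R
NULL

#' Accessors for DepthFCM objects
#'
#' Small accessor layer over the S4 containers: sampling rate, raw signal
#' matrix, durations, epoch times, feature ratios, centroids, memberships and
#' labels.
#'
#' @param x a DepthFCM object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecord", function(x) x@fs)

#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))
#' @rdname accessors
#' @export
setMethod("signalMatrix", "EEGRecord", function(x) x@samples)

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setMethod("channelNames", "EEGRecord", function(x) x@channelNames)

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setMethod("subjectId", "EEGRecord", function(x) x@subjectId)

#' @rdname accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))
#' @rdname accessors
#' @export
setMethod("duration", "EEGRecord", function(x) nrow(x@samples) / x@fs)

#' @rdname accessors
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))
#' @rdname accessors
#' @export
setMethod("epochTimes", "SpectralEpochs", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("epochTimes", "DepthFeatureSet",
          function(x) SummarizedExperiment::colData(x)$t_start_s)
#' @rdname accessors
#' @export
setMethod("epochTimes", "MembershipSeries",
          function(x) SummarizedExperiment::colData(x)$t_start_s)
#' @rdname accessors
#' @export
setMethod("epochTimes", "TimeFrequencyImage", function(x) x@times)

#' @rdname accessors
#' @export
setGeneric("freqGrid", function(x) standardGeneric("freqGrid"))
#' @rdname accessors
#' @export
setMethod("freqGrid", "SpectralEpochs", function(x) x@freqs)
#' @rdname accessors
#' @export
setMethod("freqGrid", "TimeFrequencyImage", function(x) x@freqs)

#' @rdname accessors
#' @export
setGeneric("psdMatrix", function(x) standardGeneric("psdMatrix"))
#' @rdname accessors
#' @export
setMethod("psdMatrix", "SpectralEpochs", function(x) x@psd)

#' @rdname accessors
#' @export
setGeneric("powerDb", function(x) standardGeneric("powerDb"))
#' @rdname accessors
#' @export
setMethod("powerDb", "TimeFrequencyImage", function(x) x@powerDb)

#' @rdname accessors
#' @export
setGeneric("featureRatios", function(x) standardGeneric("featureRatios"))
#' @rdname accessors
#' @export
setMethod("featureRatios", "DepthFeatureSet",
          function(x) SummarizedExperiment::assay(x, "ratios"))

#' @rdname accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @rdname accessors
#' @export
setMethod("centroids", "FCMModel", function(x) x@centroids)

#' @rdname accessors
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))
#' @rdname accessors
#' @export
setMethod("labelMap", "FCMModel", function(x) x@labelMap)

#' @rdname accessors
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))
#' @rdname accessors
#' @export
setMethod("objectiveValue", "FCMModel", function(x) x@objective)

#' @rdname accessors
#' @export
setGeneric("memberships", function(x) standardGeneric("memberships"))
#' @rdname accessors
#' @export
setMethod("memberships", "MembershipSeries",
          function(x) SummarizedExperiment::assay(x, "membership"))

#' @rdname accessors
#' @export
setGeneric("hardLabels", function(x) standardGeneric("hardLabels"))
#' @rdname accessors
#' @export
setMethod("hardLabels", "MembershipSeries",
          function(x) SummarizedExperiment::colData(x)$hard_label)

#' @rdname accessors
#' @export
setGeneric("confidence", function(x) standardGeneric("confidence"))
#' @rdname accessors
#' @export
setMethod("confidence", "MembershipSeries",
          function(x) SummarizedExperiment::colData(x)$confidence)

#' @rdname accessors
#' @export
setGeneric("maskIntervals", function(x) standardGeneric("maskIntervals"))
#' @rdname accessors
#' @export
setMethod("maskIntervals", "ArtifactMask", function(x) x@intervals)

setMethod("show", "EEGRecord", function(object) {
  cat(sprintf("EEGRecord '%s': %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              object@subjectId, ncol(object@samples), nrow(object@samples),
              object@fs, nrow(object@samples) / object@fs))
})

setMethod("show", "ArtifactMask", function(object) {
  tot <- if (nrow(object@intervals)) sum(object@intervals[, 2] - object@intervals[, 1]) else 0
  cat(sprintf("ArtifactMask: %d interval(s), %.2f s rejected\n",
              nrow(object@intervals), tot))
})

setMethod("show", "SpectralEpochs", function(object) {
  cat(sprintf("SpectralEpochs: %d epoch(s) x %d frequencies (%.2f-%.2f Hz)\n",
              length(object@times), length(object@freqs),
              min(object@freqs), max(object@freqs)))
})

setMethod("show", "FCMModel", function(object) {
  cat(sprintf("FCMModel: c=%d clusters in %s space, m=%g, tol=%g\n",
              nrow(object@centroids), object@featureSpace, object@m, object@tol))
  cat(sprintf("  objective J_m = %.6g (%sconverged, seed %d)\n",
              object@objective, if (object@converged) "" else "NOT ",
              object@seed))
  lab <- ifelse(is.na(object@labelMap), "<unlabeled>", object@labelMap)
  rn <- paste0(lab, " (", apply(round(object@centroids, 3), 1, paste,
                                collapse = ", "), ")")
  cat(paste0("  ", rn, collapse = "\n"), "\n")
})
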
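#' @include AllClasses.R edf.R
NULL

#' Read an EEG recording from EDF or CSV
#'
#' The CSV dialect is self-describing: an optional comment line `# fs=<Hz>`
#' followed by a header row of channel names, one column per channel, one row
#' per sample. EDF files carry their rate in the header. All selected channels
#' are returned at a single common sampling rate; EDF channels recorded at a
#' minority rate are resampled to the majority rate.
#'
#' @param path input file.
#' @param format `"edf"` or `"csv"`; default guesses from the file extension.
#' @param channelSelect optional channel names (or indices) to keep.
#' @param fs sampling rate override for CSV files that carry no `# fs=` line.
#' @return An [EEGRecord-class].
#' @examples
#' p <- tempfile(fileext = ".csv")
#' writeEEGCsv(eegRecord(cbind(a = rnorm(50), b = rnorm(50)), fs = 50), p)
#' readEEG(p)
#' @export
readEEG <- function(path, format = c("guess", "edf", "csv"),
                    channelSelect = NULL, fs = NULL) {
  format <- match.arg(format)
  if (format == "guess")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "edf") return(readEDF(path, channelSelect))

  if (!file.exists(path)) stop("CSV file not found: ", path)
  lines <- readLines(path, n = 2L)
  if (length(lines) == 0L) stop("empty CSV file: ", path)
  csvFs <- fs
  if (grepl("^#\\s*fs\\s*=", lines[1])) {
    csvFs <- as.numeric(sub("^#\\s*fs\\s*=\\s*", "", lines[1]))
  }
  if (is.null(csvFs) || is.na(csvFs) || csvFs <= 0)
    stop("CSV sampling rate unknown: provide fs= or a '# fs=<Hz>' line")
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (ncol(df) == 0L || nrow(df) == 0L) stop("CSV contains no samples: ", path)
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric value in CSV at row %d, column '%s'",
                   bad, names(df)[j]))
    }
  }
  X <- as.matrix(df)
  if (!is.null(channelSelect)) {
    sel <- if (is.numeric(channelSelect)) as.integer(channelSelect)
      else match(channelSelect, colnames(X))
    if (anyNA(sel) || length(sel) == 0L)
      stop("channel selection does not match CSV columns")
    X <- X[, sel, drop = FALSE]
  }
  eegRecord(X, fs = csvFs)
}

#' Write an EEG recording as self-describing CSV
#'
#' Writes a `# fs=<Hz>` comment line, a header of channel names, then one row
#' per sample. Round-trips exactly through [readEEG()] up to decimal printing.
#'
#' @param record an [EEGRecord-class].
#' @param path output file.
#' @param digits significant digits to print.
#' @return `path`, invisibly.
#' @export
writeEEGCsv <- function(record, path, digits = 10) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", samplingRate(record)), con)
  X <- signalMatrix(record)
  df <- as.data.frame(signif(X, digits))
  names(df) <- channelNames(record)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average channels into a 1-D signal
#'
#' Frontal-montage channels are reduced to a single trace by the plain
#' arithmetic mean at each time point (no weighting, no re-referencing);
#' sampling rate and start time are preserved. Idempotent on single-channel
#' recordings.
#'
#' @param record an [EEGRecord-class].
#' @return A single-channel [EEGRecord-class].
#' @export
toMono <- function(record) {
  X <- signalMatrix(record)
  if (ncol(X) == 1L) return(record)
  eegRecord(rowMeans(X), fs = samplingRate(record), t0 = record@t0,
            channelNames = "mono", subjectId = subjectId(record))
}

#' Read a depth-index (PSi) trace from CSV
#'
#' Expects two columns, timestamp (seconds) and index value in `[0, 100]`.
#'
#' @param path CSV file with columns `time_s,value` (header optional in that
#'   order).
#' @return A [PsiSeries-class].
#' @export
readPsi <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (ncol(df) < 2L) stop("PSi CSV needs two columns (time_s, value)")
  psiSeries(df[[1]], df[[2]])
}

#' @rdname readPsi
#' @param psi a [PsiSeries-class] to serialize.
#' @export
writePsi <- function(psi, path) {
  utils::write.csv(data.frame(time_s = psi@times, value = psi@values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write artifact masks as two-column CSV
#'
#' @param path CSV with columns `start_s,end_s`.
#' @return [readMask()] returns an [ArtifactMask-class].
#' @export
readMask <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (nrow(df) == 0L) return(artifactMask())
  artifactMask(df[[1]], df[[2]])
}

#' @rdname readMask
#' @param mask an [ArtifactMask-class].
#' @export
writeMask <- function(mask, path) {
  iv <- maskIntervals(mask)
  utils::write.csv(data.frame(start_s = iv[, 1], end_s = iv[, 2]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
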
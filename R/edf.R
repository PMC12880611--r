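#' @include AllClasses.R
NULL

# Minimal EDF (European Data Format) support: 16-bit integer signals, ASCII
# header, one header block of 256 bytes plus 256 per signal, data records of
# little-endian int16. Covers continuous recordings as exported by frontal
# EEG monitors; EDF+ annotation channels are not interpreted.

edfReadAscii <- function(con, n) {
  raw <- readBin(con, "raw", n = n)
  trimws(rawToChar(raw))
}

edfNum <- function(x) suppressWarnings(as.numeric(x))

#' Read an EDF file
#'
#' Parses the EDF header and all data records, converting digital values to
#' physical units via each signal's calibration fields. Signals whose
#' per-record sample counts imply different sampling rates are resampled
#' (polyphase) to the majority rate, with a message.
#'
#' @param path path to an EDF file.
#' @param channelSelect optional character vector of signal labels (or integer
#'   indices) to keep.
#' @return An [EEGRecord-class].
#' @seealso [writeEDF()], [readEEG()]
#' @export
readEDF <- function(path, channelSelect = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  version <- edfReadAscii(con, 8)
  patient <- edfReadAscii(con, 80)
  edfReadAscii(con, 80)  # recording id
  edfReadAscii(con, 8); edfReadAscii(con, 8)  # start date, time
  headerBytes <- edfNum(edfReadAscii(con, 8))
  edfReadAscii(con, 44)
  nRecords <- edfNum(edfReadAscii(con, 8))
  recordDur <- edfNum(edfReadAscii(con, 8))
  ns <- edfNum(edfReadAscii(con, 4))
  if (is.na(ns) || ns < 1 || is.na(nRecords) || is.na(recordDur) ||
      recordDur <= 0)
    stop("not a readable EDF header: ", path)
  if (!is.na(headerBytes) && headerBytes != 256 * (ns + 1))
    stop("corrupt EDF header (byte count mismatch): ", path)

  fld <- function(w) vapply(seq_len(ns), function(i) edfReadAscii(con, w), "")
  labels <- fld(16); fld(80)  # transducer
  fld(8)                      # physical dimension
  physMin <- edfNum(fld(8)); physMax <- edfNum(fld(8))
  digMin <- edfNum(fld(8)); digMax <- edfNum(fld(8))
  fld(80)                     # prefiltering
  spr <- edfNum(fld(8))       # samples per record
  fld(32)

  if (any(is.na(spr)) || any(spr < 1)) stop("invalid samples-per-record")
  recSamp <- sum(spr)
  dat <- readBin(con, "integer", n = recSamp * nRecords, size = 2,
                 signed = TRUE, endian = "little")
  if (length(dat) < recSamp * nRecords)
    stop("EDF data truncated: ", path)

  sel <- seq_len(ns)
  if (!is.null(channelSelect)) {
    sel <- if (is.numeric(channelSelect)) as.integer(channelSelect)
      else match(channelSelect, labels)
    if (anyNA(sel) || length(sel) == 0L)
      stop("channel selection does not match EDF signal labels")
  }

  offs <- c(0, cumsum(spr))
  gain <- (physMax - physMin) / (digMax - digMin)
  sigs <- lapply(sel, function(i) {
    idx <- as.vector(outer(offs[i] + seq_len(spr[i]),
                           (seq_len(nRecords) - 1L) * recSamp, `+`))
    (dat[idx] - digMin[i]) * gain[i] + physMin[i]
  })

  rates <- spr[sel] / recordDur
  fs <- as.numeric(names(sort(table(rates), decreasing = TRUE))[1])
  if (length(unique(rates)) > 1L) {
    message("resampling ", sum(rates != fs), " channel(s) to majority rate ",
            fs, " Hz")
    sigs <- lapply(seq_along(sigs), function(j) {
      if (rates[j] == fs) return(sigs[[j]])
      resampleToRate(sigs[[j]], rates[j], fs)
    })
    n <- min(lengths(sigs))
    sigs <- lapply(sigs, function(s) s[seq_len(n)])
  }
  eegRecord(do.call(cbind, sigs), fs = fs, channelNames = labels[sel],
            subjectId = if (nzchar(patient)) patient else "anonymous")
}

# rational polyphase resampling via signal::resample
resampleToRate <- function(x, from, to) {
  r <- to / from
  den <- 1e6
  frac <- round(r * den)
  g <- gcdInt(frac, den)
  signal::resample(x, p = frac / g, q = den / g)
}

gcdInt <- function(a, b) { while (b != 0) { t <- b; b <- a %% b; a <- t }; a }

edfPad <- function(x, w) formatC(substr(as.character(x), 1, w), width = -w)

#' Write an EDF file
#'
#' Serializes a recording as 16-bit EDF with one-second data records. Samples
#' are quantized onto the signal's physical range (the usual EDF precision
#' loss); the recording is truncated to a whole number of records.
#'
#' @param record an [EEGRecord-class]; the sampling rate must be a whole
#'   number of Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(record, path) {
  fs <- samplingRate(record)
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate (Hz)")
  fs <- as.integer(round(fs))
  X <- signalMatrix(record)
  nRecords <- nrow(X) %/% fs
  if (nRecords < 1L) stop("recording shorter than one 1-s EDF record")
  if (nRecords * fs < nrow(X))
    warning("truncating ", nrow(X) - nRecords * fs,
            " trailing sample(s) to fill whole EDF records")
  X <- X[seq_len(nRecords * fs), , drop = FALSE]
  ns <- ncol(X)

  # symmetric physical range per channel; reparse the 8-char field so the
  # scale used for quantization is exactly the scale a reader will recover
  physMaxStr <- vapply(seq_len(ns), function(i) {
    pm <- max(abs(X[, i]), 1e-6)
    edfPad(signif(pm * 1.0001, 6), 8)
  }, "")
  physMax <- as.numeric(physMaxStr)
  digMax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(edfPad(x, w), con, nchars = w, eos = NULL)
  wr("0", 8)
  wr(subjectId(record), 80)
  wr("DepthFCM export", 80)
  wr(format(Sys.Date(), "%d.%m.%y"), 8)
  wr("00.00.00", 8)
  wr(256 * (ns + 1), 8)
  wr("", 44)
  wr(nRecords, 8)
  wr(1, 8)
  wr(ns, 4)
  for (i in seq_len(ns)) wr(channelNames(record)[i], 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(paste0("-", physMaxStr[i]), 8)
  for (i in seq_len(ns)) wr(physMaxStr[i], 8)
  for (i in seq_len(ns)) wr(-digMax, 8)
  for (i in seq_len(ns)) wr(digMax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)

  dig <- vapply(seq_len(ns), function(i) {
    as.integer(round(X[, i] / physMax[i] * digMax))
  }, integer(nrow(X)))
  for (r in seq_len(nRecords)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns))
      writeBin(dig[rows, i], con, size = 2, endian = "little")
  }
  invisible(path)
}
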
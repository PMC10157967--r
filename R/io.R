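#' Construct a continuous recording
#'
#' A recording is a channels-by-samples matrix of potentials in microvolts
#' together with its sampling rate and condition metadata. All channels share
#' one length and one sampling rate.
#'
#' @param data numeric matrix, channels x samples (a plain vector is treated
#'   as one channel), in uV.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one label per channel.
#' @param group condition label (e.g. "darkness", "light", "control").
#' @param source provenance: a file path, or "synthetic".
#' @return an object of class `"eeg_recording"` with elements `data`, `fs`,
#'   `channel_labels`, `group`, `source` and derived `duration` (seconds).
#' @export
recording <- function(data, fs, channel_labels = NULL, group = NA_character_,
                      source = "synthetic") {
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, nrow = 1L)
  if (!is.matrix(data) || !is.numeric(data))
    stop_planeeg("'data' must be a numeric channels x samples matrix")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_planeeg("'fs' must be a single positive sampling rate in Hz")
  dimnames(data) <- NULL
  nch <- nrow(data)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nch))
  if (length(channel_labels) != nch)
    stop_planeeg("need one channel label per channel")
  structure(
    list(data = data, fs = fs, channel_labels = as.character(channel_labels),
         group = as.character(group), source = source,
         duration = ncol(data) / fs),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, x$duration))
  cat(sprintf("  group: %s   source: %s\n", x$group, x$source))
  invisible(x)
}

#' Read a continuous recording from disk
#'
#' Supports 16-bit EDF and delimited text. Text files may have a leading
#' time column (detected as strictly increasing and uniformly spaced), from
#' which the sampling rate is inferred when `fs` is not given; the delimiter
#' (tab or comma) is auto-detected. EDF files carry their own rate.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"edf"`, or `"text"`.
#' @param group condition label to attach.
#' @param fs sampling rate in Hz; required for text files without a time
#'   column, ignored for EDF.
#' @return an [recording()] object.
#' @export
read_recording <- function(path, format = c("auto", "edf", "text"),
                           group = NA_character_, fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_planeeg("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "text"
  }
  if (format == "edf") {
    edf <- read_edf(path)
    return(recording(edf$data, edf$fs, edf$channel_labels,
                     group = group, source = path))
  }
  ## delimited text
  line1 <- readLines(path, n = 1L)
  sep <- if (grepl("\t", line1)) "\t" else if (grepl(",", line1)) "," else ""
  header <- !grepl("^[-+0-9.eE \t,]+$", line1)
  tab <- utils::read.table(path, sep = sep, header = header)
  if (!all(vapply(tab, is.numeric, logical(1))))
    stop_planeeg("non-numeric columns in delimited recording: ", path)
  m <- as.matrix(tab)
  ## leading time column: strictly increasing, uniform spacing
  has_time <- ncol(m) >= 2L && all(diff(m[, 1]) > 0) &&
    diff(range(diff(m[, 1]))) < 1e-6 * mean(diff(m[, 1]))
  if (has_time) {
    dt <- mean(diff(m[, 1]))
    fs_file <- 1 / dt
    if (!is.null(fs) && abs(fs_file - fs) > 1e-6 * fs)
      stop_planeeg(sprintf("time column implies fs = %.6g Hz, but fs = %g given",
                           fs_file, fs))
    fs <- fs_file
    m <- m[, -1, drop = FALSE]
  }
  if (is.null(fs))
    stop_planeeg("sampling rate missing: text file has no time column; pass fs")
  labels <- if (header) colnames(m) else NULL
  recording(t(m), fs, labels, group = group, source = path)
}

#' Write a recording to disk
#'
#' Text output is tab-delimited with a time column in seconds followed by one
#' column per channel in uV. EDF output is standard 16-bit EDF.
#'
#' @param rec an [recording()] object.
#' @param path output file.
#' @param format `"text"` or `"edf"` (default by extension).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "text")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "text"
  if (format == "edf") {
    write_edf(rec$data, rec$fs, rec$channel_labels, path)
  } else {
    n <- ncol(rec$data)
    tab <- data.frame(time = (seq_len(n) - 1L) / rec$fs,
                      t(rec$data), check.names = FALSE)
    names(tab) <- c("time", rec$channel_labels)
    utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

## ---- EDF (European Data Format), 16-bit continuous ----
## Header: 256 ASCII bytes + 256 per signal; data records of int16 LE.
## Written with 1-second records when the sample count divides evenly,
## otherwise a single record holding the whole signal.

pad_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1L, width)
}

#' Write a channels-by-samples matrix as 16-bit EDF
#'
#' Each channel is scaled to its own physical range; quantization error is
#' at most half of one digital step (range / 2^16).
#'
#' @param data channels x samples numeric matrix, uV.
#' @param fs sampling rate, Hz (identical for all channels).
#' @param channel_labels labels, one per channel.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(data, fs, channel_labels, path) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  nch <- nrow(data); n <- ncol(data)
  if (n %% fs == 0 && n > fs) {
    spr <- as.integer(fs); nrec <- n %/% as.integer(fs); recdur <- 1
  } else {
    spr <- n; nrec <- 1L; recdur <- n / fs
  }
  pmin <- apply(data, 1, min); pmax <- apply(data, 1, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)                                   # version
  wr("X X X X", 80)                            # patient id (anonymous)
  wr("Startdate X X X X", 80)                  # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)         # date, time
  wr(256L * (1L + nch), 8)                     # header bytes
  wr("", 44)                                   # reserved
  wr(nrec, 8)
  wr(format(recdur, digits = 7), 8)
  wr(nch, 4)
  for (lab in channel_labels) wr(lab, 16)
  for (i in seq_len(nch)) wr("AgAgCl wire electrode", 80)
  for (i in seq_len(nch)) wr("uV", 8)
  for (i in seq_len(nch)) wr(format(pmin[i], digits = 7), 8)
  for (i in seq_len(nch)) wr(format(pmax[i], digits = 7), 8)
  for (i in seq_len(nch)) wr(-32768L, 8)
  for (i in seq_len(nch)) wr(32767L, 8)
  for (i in seq_len(nch)) wr("", 80)           # prefiltering
  for (i in seq_len(nch)) wr(spr, 8)
  for (i in seq_len(nch)) wr("", 32)           # reserved
  scale <- (pmax - pmin) / (32767 - (-32768))
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(nch)) {
      dig <- round((data[i, idx] - pmin[i]) / scale[i]) - 32768
      dig <- pmin(pmax(dig, -32768), 32767)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a 16-bit EDF file
#'
#' All signals must share one sampling rate (mixed per-channel rates are
#' rejected: the analysis operates on rectangular channel x sample arrays).
#'
#' @param path EDF file.
#' @return list with `data` (channels x samples, physical units), `fs`,
#'   `channel_labels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  nbytes <- as.integer(rd(8)); rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labs  <- vapply(seq_len(nch), function(i) rd(16), character(1))
  for (i in seq_len(nch)) rd(80)
  for (i in seq_len(nch)) rd(8)                # units
  pmin <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  pmax <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(nch)) rd(80)
  spr <- vapply(seq_len(nch), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(nch)) rd(32)
  if (length(unique(spr)) != 1L)
    stop_planeeg("EDF signals have mismatched per-channel sampling rates: ",
                 paste(unique(spr), collapse = ", "))
  fs <- spr[1] / recdur
  data <- matrix(0, nch, spr[1] * nrec)
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    for (i in seq_len(nch)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2L, endian = "little")
      data[i, idx] <- pmin[i] + (dig - dmin[i]) * scale[i]
    }
  }
  list(data = data, fs = fs, channel_labels = labs)
}
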
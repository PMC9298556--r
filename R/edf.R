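# Minimal EDF (European Data Format) support: enough of the standard for
# 16-channel continuous recordings with a uniform sampling rate. The writer
# emits one 1-second data record per second of signal, 16-bit samples with a
# symmetric physical range; the reader handles any EDF whose signal labels
# contain the 16 montage leads at a common sampling rate. EDF annotations,
# discontinuous (EDF+D) files and per-signal sampling rates are out of scope.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write an EEG recording to an EDF file
#'
#' Samples are quantized to 16 bits over a symmetric physical range covering
#' the data (physical dimension uV). The duration is truncated to a whole
#' number of 1-second data records.
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  fs <- as.integer(round(fs))
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1) stop("recording shorter than one data record", call. = FALSE)
  if (n_rec * fs < ncol(rec$data))
    warning("truncating ", ncol(rec$data) - n_rec * fs,
            " trailing samples to whole 1-s records")
  data <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  ns <- nrow(data)

  pm <- max(abs(data), 1e-6)
  pmax <- signif(pm * 1.01, 6)
  gain <- 32767 / pmax          # symmetric digital range [-32767, 32767]
  dig <- matrix(as.integer(round(data * gain)), nrow = ns)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)
  wr(rec$subject_id, 80)
  wr(paste0("Startdate 01-JAN-2000 synthetic label=",
            ifelse(is.na(rec$label), "NA", rec$label)), 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256 * (ns + 1), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr(1, 8)
  wr(ns, 4)
  for (lab in rec$channel_names) wr(paste("EEG", lab), 16)
  for (i in seq_len(ns)) wr("synthetic", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(format(-pmax), 8)
  for (i in seq_len(ns)) wr(format(pmax), 8)
  for (i in seq_len(ns)) wr(-32767, 8)
  for (i in seq_len(ns)) wr(32767, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns))
      writeBin(dig[i, idx], con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EEG recording from an EDF file
#'
#' The file must contain at least the 16 montage leads (labels matched
#' case-insensitively, `"EEG "` prefixes and reference suffixes such as
#' `-A1`/`-REF` stripped) all at one sampling rate; channels are reordered to
#' the canonical [EEG_MONTAGE] order and extra signals are dropped.
#'
#' @param path EDF file path.
#' @param label optional class label to attach (the writer also records it in
#'   the recording-id field, which is recovered when present).
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                                  # version
  patient <- rd(80)
  recid <- rd(80)
  rd(8); rd(8)                           # date, time
  rd(8); rd(44)                          # header bytes, reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)          # transducer
  for (i in seq_len(ns)) rd(8)           # physical dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmaxv <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)          # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)

  perm <- montage_permutation(labels)
  if (length(unique(spr[perm])) != 1)
    stop("montage channels have mixed sampling rates", call. = FALSE)
  fs <- spr[perm][1] / rec_dur

  raw <- matrix(0, ns, max(spr) * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      raw[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <- v
    }
  }
  gain <- (pmaxv - pmin) / (dmax - dmin)
  phys <- (raw - dmin) * gain + pmin
  data <- phys[perm, , drop = FALSE]

  if (is.null(label)) {
    m <- regmatches(recid, regexpr("label=[01]", recid))
    label <- if (length(m)) as.integer(sub("label=", "", m)) else NA_integer_
  }
  eeg_recording(data, fs, subject_id = patient, label = label)
}

#' Read an EEG recording from a delimited text file
#'
#' Accepts a 16-column (samples in rows) or 16-row numeric CSV/TSV, with an
#' optional header of channel names; channels are reordered to the canonical
#' montage order when a header is present, otherwise assumed already
#' canonical.
#'
#' @param path file path (delimiter inferred from content: comma or tab).
#' @param fs sampling rate in Hz (not stored in delimited files).
#' @param label optional class label.
#' @param subject_id subject identifier (defaults to the file name).
#' @return An [eeg_recording()].
#' @export
read_delimited <- function(path, fs, label = NA_integer_,
                           subject_id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  has_header <- {
    cells <- strsplit(first, sep, fixed = TRUE)[[1]]
    any(is.na(suppressWarnings(as.numeric(cells))))
  }
  df <- utils::read.table(path, header = has_header, sep = sep,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric cell in ", path, call. = FALSE)
  names_in <- if (has_header) colnames(df) else NULL
  if (ncol(m) == N_CHANNELS) {
    m <- t(m)
  } else if (nrow(m) == N_CHANNELS) {
    names_in <- NULL                     # row-major layout has no header names
  } else {
    stop("expected 16 channels, found ", ncol(m), " columns / ",
         nrow(m), " rows", call. = FALSE)
  }
  if (!is.null(names_in)) m <- m[montage_permutation(names_in), , drop = FALSE]
  eeg_recording(m, fs, subject_id = subject_id, label = label)
}
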
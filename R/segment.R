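# Sliding-window epoch extraction. Epochs of window_s seconds are cut every
# step_s seconds from recording onset; trailing samples that do not fill a
# whole window are dropped, so the count is floor((T/fs - window_s)/step_s)+1.
# Steps of 4/3/2/1 s on a 4-s window give overlap rates 0/25/50/75%.

#' Segment a recording into fixed-length epochs
#'
#' @param rec an [eeg_recording()].
#' @param window_s window length in seconds (4 by default).
#' @param step_s step between window starts in seconds; the conventional
#'   values 4, 3, 2, 1 correspond to 0, 25, 50, 75% overlap. Other positive
#'   values are accepted with a warning.
#' @return List of `eeg_epoch` objects, each holding `subject_id`, `label`,
#'   `start_s` and a channels-by-samples `data` matrix of exactly
#'   `window_s * fs` samples.
#' @export
segment <- function(rec, window_s = 4, step_s = 4) {
  stopifnot(inherits(rec, "eeg_recording"), window_s > 0, step_s > 0)
  if (!step_s %in% c(1, 2, 3, 4))
    warning("step_s = ", step_s, " is outside the conventional {1,2,3,4}")
  n <- ncol(rec$data)
  wlen <- round(window_s * rec$fs)
  if (n < wlen)
    stop("recording shorter than one ", window_s, "-s window", call. = FALSE)
  n_ep <- floor((n / rec$fs - window_s) / step_s) + 1
  lapply(seq_len(n_ep), function(i) {
    start_s <- (i - 1) * step_s
    j0 <- round(start_s * rec$fs)
    structure(list(subject_id = rec$subject_id, label = rec$label,
                   start_s = start_s,
                   data = rec$data[, (j0 + 1):(j0 + wlen), drop = FALSE]),
              class = "eeg_epoch")
  })
}

#' Number of epochs a recording yields
#'
#' Closed form `floor((T/fs - window_s)/step_s) + 1`.
#' @param duration_s recording duration, seconds.
#' @param window_s,step_s as in [segment()].
#' @export
n_epochs <- function(duration_s, window_s = 4, step_s = 4) {
  floor((duration_s - window_s) / step_s) + 1
}

#' Build an epoch dataset from a cohort
#'
#' Concatenates the sliding-window epochs of all recordings into one
#' `eeg_epoch_set`. To avoid duplicating overlapping samples, the set stores
#' the source recordings plus an index table (subject_id, label, start_s);
#' [epoch_data()] materializes any epoch's matrix on demand.
#'
#' @param cohort list of [eeg_recording()] objects sharing `fs` and channel
#'   order.
#' @param step_s window step in seconds.
#' @param window_s window length in seconds.
#' @param shuffle_seed if non-`NULL`, the epoch order is shuffled with this
#'   seed (the permutation is reproducible).
#' @return An `eeg_epoch_set` with fields `index` (data frame), `recordings`,
#'   `window_s`, `step_s`, `overlap_pct`, `fs`.
#' @export
build_dataset <- function(cohort, step_s = 4, window_s = 4,
                          shuffle_seed = NULL) {
  stopifnot(length(cohort) >= 1,
            all(vapply(cohort, inherits, TRUE, "eeg_recording")))
  fs <- unique(vapply(cohort, function(r) r$fs, 0))
  if (length(fs) != 1)
    stop("recordings have heterogeneous sampling rates: ",
         paste(fs, collapse = ", "), call. = FALSE)
  ord <- vapply(cohort, function(r) paste(r$channel_names, collapse = ","), "")
  if (length(unique(ord)) != 1)
    stop("recordings have heterogeneous channel orders", call. = FALSE)

  idx <- do.call(rbind, lapply(seq_along(cohort), function(k) {
    r <- cohort[[k]]
    ne <- n_epochs(duration_s(r), window_s, step_s)
    if (ne < 1) stop("recording ", r$subject_id, " shorter than one window",
                     call. = FALSE)
    data.frame(rec = k, subject_id = r$subject_id, label = r$label,
               start_s = (seq_len(ne) - 1) * step_s,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(shuffle_seed))
    idx <- with_seed(shuffle_seed, idx[sample.int(nrow(idx)), , drop = FALSE])
  rownames(idx) <- NULL
  structure(list(index = idx, recordings = cohort,
                 window_s = window_s, step_s = step_s,
                 overlap_pct = 100 * (window_s - step_s) / window_s,
                 fs = fs),
            class = "eeg_epoch_set")
}

#' @export
length.eeg_epoch_set <- function(x) nrow(x$index)

#' @export
print.eeg_epoch_set <- function(x, ...) {
  cat(sprintf(paste0("<eeg_epoch_set> %d epochs (%g-s window, %g-s step, ",
                     "%g%% overlap) from %d recordings @ %g Hz\n"),
              nrow(x$index), x$window_s, x$step_s, x$overlap_pct,
              length(x$recordings), x$fs))
  invisible(x)
}

#' Materialize one epoch's signal matrix
#'
#' @param es an `eeg_epoch_set` from [build_dataset()].
#' @param i epoch index in `es$index` order.
#' @return Channels-by-samples numeric matrix.
#' @export
epoch_data <- function(es, i) {
  row <- es$index[i, ]
  rec <- es$recordings[[row$rec]]
  wlen <- round(es$window_s * es$fs)
  j0 <- round(row$start_s * es$fs)
  rec$data[, (j0 + 1):(j0 + wlen), drop = FALSE]
}

#' Serialize an epoch set to a directory
#'
#' Writes `index.csv` (subject_id, label, start_s, file) plus one raw binary
#' file per epoch: 16 x (window_s*fs) doubles, column-major (sample-fastest),
#' little-endian, no header. [read_epochset()] inverts this layout.
#'
#' @param es an `eeg_epoch_set`.
#' @param dir output directory.
#' @return Invisibly, the index data frame written.
#' @export
write_epochset <- function(es, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("epoch%05d.bin", seq_len(length(es)))
  for (i in seq_len(length(es))) {
    con <- file(file.path(dir, files[i]), "wb")
    writeBin(as.vector(epoch_data(es, i)), con, endian = "little")
    close(con)
  }
  idx <- cbind(es$index[, c("subject_id", "label", "start_s")],
               file = files,
               window_s = es$window_s, step_s = es$step_s, fs = es$fs)
  utils::write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  invisible(idx)
}

#' Read an epoch set directory written by [write_epochset()]
#'
#' Epochs are materialized into per-epoch single-window recordings.
#'
#' @param dir directory containing `index.csv` and epoch files.
#' @return An `eeg_epoch_set`.
#' @export
read_epochset <- function(dir) {
  idx <- utils::read.csv(file.path(dir, "index.csv"), stringsAsFactors = FALSE)
  fs <- idx$fs[1]; window_s <- idx$window_s[1]; step_s <- idx$step_s[1]
  wlen <- round(window_s * fs)
  recs <- lapply(seq_len(nrow(idx)), function(i) {
    con <- file(file.path(dir, idx$file[i]), "rb")
    x <- readBin(con, "double", n = N_CHANNELS * wlen, endian = "little")
    close(con)
    eeg_recording(matrix(x, N_CHANNELS, wlen), fs,
                  subject_id = idx$subject_id[i], label = idx$label[i])
  })
  es <- build_dataset(recs, step_s = step_s, window_s = window_s)
  es$index$source_start_s <- idx$start_s   # position in the original recording
  es$step_s <- step_s
  es$overlap_pct <- 100 * (window_s - step_s) / window_s
  es
}
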
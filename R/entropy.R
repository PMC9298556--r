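# Time-by-frequency-band images of normalized spectral entropy. Each 4-s
# epoch channel (4000 samples at 1000 Hz) is analyzed in 17 Hann-tapered
# frames of 1024 samples hopped by 186 (floor((4000-1024)/186)+1 = 17),
# zero-padded to a 2048-point FFT (0.488-Hz spacing), and the squared-
# magnitude spectrum inside each of 17 contiguous 3-Hz bands ([0,3), [3,6),
# ..., [48,51) Hz) is renormalized to a probability vector whose Shannon
# entropy, divided by log2 of the band's point count, fills one cell of a
# 17x17 image in [0,1].

#' Time-frequency analysis grid
#'
#' Defines the short-time analysis producing 17x17 images from a 4-s epoch.
#' The defaults are one consistent reconstruction of a 17-frame / 17-band
#' grid at 3-Hz frequency resolution; all four numbers are configurable.
#'
#' @param frame_len samples per analysis frame.
#' @param hop samples between frame starts.
#' @param fft_len FFT length (frames are zero-padded to it).
#' @param n_time,n_freq image dimensions (frames x bands).
#' @param band_hz frequency band width in Hz.
#' @param fs sampling rate the grid is designed for.
#' @return An object of class `tf_grid`.
#' @export
tf_grid <- function(frame_len = 1024, hop = 186, fft_len = 2048,
                    n_time = 17, n_freq = 17, band_hz = 3, fs = 1000) {
  stopifnot(frame_len <= fft_len, hop >= 1, n_time >= 1, n_freq >= 2,
            band_hz > 0, fs > 0)
  if (n_freq * band_hz > fs / 2 + band_hz)
    stop("band grid extends beyond the Nyquist frequency", call. = FALSE)
  freqs <- seq(0, floor(fft_len / 2)) * fs / fft_len
  bands <- lapply(seq_len(n_freq) - 1, function(b)
    which(freqs >= b * band_hz & freqs < (b + 1) * band_hz))
  if (any(lengths(bands) < 2))
    stop("fewer than 2 FFT points in some band; increase fft_len", call. = FALSE)
  structure(list(frame_len = as.integer(frame_len), hop = as.integer(hop),
                 fft_len = as.integer(fft_len), n_time = as.integer(n_time),
                 n_freq = as.integer(n_freq), band_hz = band_hz, fs = fs,
                 bands = bands,
                 taper = 0.5 - 0.5 * cos(2 * pi * seq(0, frame_len - 1) /
                                           (frame_len - 1))),
            class = "tf_grid")
}

#' One-sided power spectrum of a frame
#'
#' `S(w) = |X(w)|^2` over non-negative frequencies of the `fft_len`-point
#' discrete Fourier transform of the (zero-padded) frame.
#'
#' @param frame real numeric vector, length at most `fft_len`.
#' @param fft_len transform length.
#' @return Nonnegative vector of length `fft_len/2 + 1`.
#' @export
power_spectrum <- function(frame, fft_len = length(frame)) {
  if (length(frame) == 0) stop("empty frame", call. = FALSE)
  if (length(frame) > fft_len) stop("frame longer than fft_len", call. = FALSE)
  padded <- c(frame, numeric(fft_len - length(frame)))
  Mod(stats::fft(padded)[seq_len(floor(fft_len / 2) + 1)])^2
}

#' Normalize a spectrum segment to a probability distribution
#'
#' `p(w) = S(w) / sum(S)`.
#'
#' @param S nonnegative spectrum values with at least one positive entry.
#' @return Probability vector summing to 1.
#' @export
spectral_prob <- function(S) {
  if (any(S < 0)) stop("negative spectrum values", call. = FALSE)
  tot <- sum(S)
  if (tot <= 0) stop("degenerate all-zero spectrum segment", call. = FALSE)
  S / tot
}

#' Normalized spectral entropy
#'
#' `Hn = -sum(p * log2(p)) / log2(N)` with the convention `0 * log2(0) = 0`;
#' the denominator is the maximum entropy of a uniform (white-noise-like)
#' spectrum, so `Hn` lies in `[0, 1]`.
#'
#' @param p probability vector of length `N >= 2`.
#' @return Scalar in `[0, 1]`.
#' @export
normalized_spectral_entropy <- function(p) {
  n <- length(p)
  if (n < 2) stop("need at least 2 probabilities (log2 N undefined)",
                  call. = FALSE)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("not a probability vector", call. = FALSE)
  nz <- p[p > 0]
  h <- -sum(nz * log2(nz))
  min(max(h / log2(n), 0), 1)
}

# Frame a channel signal into a (frame_len x n_time) tapered matrix.
frame_signal <- function(x, grid) {
  need <- (grid$n_time - 1) * grid$hop + grid$frame_len
  got <- floor((length(x) - grid$frame_len) / grid$hop) + 1
  if (length(x) < need || got != grid$n_time)
    stop("signal length ", length(x), " yields ", got,
         " frames, grid expects ", grid$n_time, call. = FALSE)
  starts <- (seq_len(grid$n_time) - 1) * grid$hop
  m <- vapply(starts, function(s) x[(s + 1):(s + grid$frame_len)],
              numeric(grid$frame_len))
  m * grid$taper
}

# Band powers for all frames: (n_freq x n_time) matrix of summed in-band
# spectral mass, plus the per-point spectra needed for entropy.
frame_spectra <- function(x, grid) {
  fm <- frame_signal(x, grid)
  padded <- rbind(fm, matrix(0, grid$fft_len - grid$frame_len, grid$n_time))
  Mod(stats::mvfft(padded)[seq_len(floor(grid$fft_len / 2) + 1), ,
                           drop = FALSE])^2
}

#' Spectral-entropy heat map of one epoch channel
#'
#' Cell `(t, b)` holds the normalized spectral entropy of the FFT-point
#' powers inside 3-Hz band `b` for frame `t`. All-zero bands are assigned 0
#' (a zero-power band is treated as perfectly ordered).
#'
#' @param x numeric signal of one epoch channel (4000 samples by default
#'   grid).
#' @param grid a [tf_grid()].
#' @return `n_time x n_freq` matrix in `[0, 1]` (time in rows, frequency
#'   bands in columns).
#' @export
entropy_heatmap <- function(x, grid = tf_grid()) {
  S <- frame_spectra(x, grid)
  out <- matrix(0, grid$n_time, grid$n_freq)
  for (b in seq_len(grid$n_freq)) {
    seg <- S[grid$bands[[b]], , drop = FALSE]
    nb <- nrow(seg)
    tot <- colSums(seg)
    pos <- tot > 0
    if (any(pos)) {
      p <- sweep(seg[, pos, drop = FALSE], 2, tot[pos], "/")
      pl <- p * log2(p)
      pl[p == 0] <- 0
      out[pos, b] <- pmin(pmax(-colSums(pl) / log2(nb), 0), 1)
    }
  }
  out
}

#' Band-power heat map (control representation)
#'
#' Cell `(t, b)` holds `log(1 + total band power)`, min-max normalized per
#' image to `[0, 1]`; an image with zero dynamic range maps to all zeros.
#'
#' @inheritParams entropy_heatmap
#' @return `n_time x n_freq` matrix in `[0, 1]`.
#' @export
power_heatmap <- function(x, grid = tf_grid()) {
  S <- frame_spectra(x, grid)
  bp <- t(vapply(grid$bands, function(idx) colSums(S[idx, , drop = FALSE]),
                 numeric(grid$n_time)))        # n_freq x n_time
  img <- t(log1p(bp))                          # n_time x n_freq
  rng <- range(img)
  if (diff(rng) == 0) return(matrix(0, grid$n_time, grid$n_freq))
  (img - rng[1]) / diff(rng)
}

#' Transform an epoch set into a feature tensor
#'
#' Computes one heat map per (epoch, channel); labels and subject ids are
#' carried through. The channel axis follows the canonical montage order.
#'
#' @param es an `eeg_epoch_set` from [build_dataset()].
#' @param grid a [tf_grid()].
#' @param kind `"entropy"` or `"power"`.
#' @return An object of class `feature_tensor`: list with `images`
#'   (`N x 16 x n_time x n_freq` array), `labels`, `subject_ids`, `kind`,
#'   `grid`.
#' @export
transform_epochset <- function(es, grid = tf_grid(), kind = c("entropy", "power")) {
  kind <- match.arg(kind)
  n <- length(es)
  images <- array(0, c(n, N_CHANNELS, grid$n_time, grid$n_freq))
  nt <- grid$n_time
  starts <- (seq_len(nt) - 1) * grid$hop
  sel <- as.vector(outer(seq_len(grid$frame_len), starts, `+`))
  keep <- floor(grid$fft_len / 2) + 1
  padded <- matrix(0, grid$fft_len, nt * N_CHANNELS)
  frame_rows <- seq_len(grid$frame_len)
  for (i in seq_len(n)) {
    ep <- epoch_data(es, i)
    if (ncol(ep) < (nt - 1) * grid$hop + grid$frame_len)
      stop("epoch ", i, ": signal shorter than the analysis grid",
           call. = FALSE)
    # all channels' tapered frames side by side: frame_len x (n_time * 16)
    padded[frame_rows, ] <- matrix(t(ep)[sel, ], grid$frame_len,
                                   nt * N_CHANNELS) * grid$taper
    S <- cplx_power_head(stats::mvfft(padded), keep)
    for (b in seq_len(grid$n_freq)) {
      seg <- S[grid$bands[[b]], , drop = FALSE]
      nb <- nrow(seg)
      tot <- colSums(seg)
      if (kind == "entropy") {
        cell <- numeric(ncol(seg))
        pos <- tot > 0
        if (any(pos)) {
          p <- sweep(seg[, pos, drop = FALSE], 2, tot[pos], "/")
          pl <- p * log2(p)
          pl[p == 0] <- 0
          cell[pos] <- pmin(pmax(-colSums(pl) / log2(nb), 0), 1)
        }
        images[i, , , b] <- matrix(cell, nt, N_CHANNELS, byrow = FALSE) |> t()
      } else {
        images[i, , , b] <- t(matrix(log1p(tot), nt, N_CHANNELS))
      }
    }
    if (kind == "power") {
      for (ch in seq_len(N_CHANNELS)) {
        img <- images[i, ch, , ]
        rng <- range(img)
        images[i, ch, , ] <- if (diff(rng) == 0) 0
                             else (img - rng[1]) / diff(rng)
      }
    }
  }
  structure(list(images = images,
                 labels = as.integer(es$index$label),
                 subject_ids = es$index$subject_id,
                 kind = kind, grid = grid),
            class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<feature_tensor> %d x %d x %d x %d (%s), %d/%d class 1/0\n",
              d[1], d[2], d[3], d[4], x$kind,
              sum(x$labels == 1), sum(x$labels == 0)))
  invisible(x)
}

#' Serialize a feature tensor to a directory
#'
#' `values.bin` holds the image array as doubles in R's native column-major
#' order for dimensions (epoch, channel, time, band), little-endian;
#' `meta.csv` holds labels and subject ids; `grid.json` the grid parameters.
#'
#' @param ft a `feature_tensor`.
#' @param dir output directory.
#' @export
write_features <- function(ft, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "values.bin"), "wb")
  writeBin(as.vector(ft$images), con, endian = "little")
  close(con)
  utils::write.csv(data.frame(subject_id = ft$subject_ids, label = ft$labels),
                   file.path(dir, "meta.csv"), row.names = FALSE)
  g <- ft$grid; g$bands <- NULL; g$taper <- NULL
  jsonlite::write_json(c(unclass(g), list(kind = ft$kind,
                                          dim = dim(ft$images))),
                       file.path(dir, "grid.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a feature tensor written by [write_features()]
#' @param dir directory path.
#' @return A `feature_tensor`.
#' @export
read_features <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "meta.csv"), stringsAsFactors = FALSE)
  g <- jsonlite::read_json(file.path(dir, "grid.json"), simplifyVector = TRUE)
  con <- file(file.path(dir, "values.bin"), "rb")
  vals <- readBin(con, "double", n = prod(g$dim), endian = "little")
  close(con)
  structure(list(images = array(vals, g$dim),
                 labels = meta$label, subject_ids = meta$subject_id,
                 kind = g$kind,
                 grid = tf_grid(g$frame_len, g$hop, g$fft_len, g$n_time,
                                g$n_freq, g$band_hz, g$fs)),
            class = "feature_tensor")
}
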
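# Independent oracles used to freeze expected values, deliberately written
# without reusing the package's computation paths.

# Direct O(N^2) discrete Fourier transform (definition-level; no stats::fft).
dft_brute <- function(x, n_out = length(x)) {
  n <- length(x)
  k <- seq_len(n_out) - 1
  E <- exp(-2i * pi * outer(k, seq_len(n) - 1) / n_out)
  # zero-padding to n_out: terms beyond length(x) contribute nothing
  as.vector(E[, seq_len(n), drop = FALSE] %*% x)
}

# Brute-force spectral-entropy heat map of one channel: frames, Hann taper,
# DFT by definition, band slicing and Shannon entropy written out plainly.
entropy_map_brute <- function(x, grid) {
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, grid$frame_len - 1) /
                             (grid$frame_len - 1))
  freqs <- (seq_len(floor(grid$fft_len / 2) + 1) - 1) * grid$fs / grid$fft_len
  out <- matrix(0, grid$n_time, grid$n_freq)
  for (t in seq_len(grid$n_time)) {
    s0 <- (t - 1) * grid$hop
    fr <- x[(s0 + 1):(s0 + grid$frame_len)] * taper
    X <- dft_brute(fr, grid$fft_len)[seq_len(floor(grid$fft_len / 2) + 1)]
    S <- Re(X)^2 + Im(X)^2
    for (b in seq_len(grid$n_freq)) {
      idx <- which(freqs >= (b - 1) * grid$band_hz & freqs < b * grid$band_hz)
      seg <- S[idx]
      if (sum(seg) > 0) {
        p <- seg / sum(seg)
        h <- 0
        for (pi_ in p) if (pi_ > 0) h <- h - pi_ * log2(pi_)
        out[t, b] <- h / log2(length(seg))
      }
    }
  }
  out
}

# Pairwise-comparison AUC: P(score_pos > score_neg) + 0.5 * P(tie).
auc_pairwise <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Two-sample KS statistic by explicit ECDF sweep over the pooled support.
ks_stat_brute <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  f1 <- vapply(grid, function(g) mean(x <= g), 0)
  f2 <- vapply(grid, function(g) mean(y <= g), 0)
  max(abs(f1 - f2))
}

# Amplitude of frequency f in a signal, from the periodogram.
tone_amp <- function(x, f, fs) {
  n <- length(x)
  2 * Mod(stats::fft(x))[round(f * n / fs) + 1] / n
}

# Small shared fixtures, built once per test run.
.fixtures <- new.env()

small_cohort <- function() {
  if (is.null(.fixtures$co)) {
    .fixtures$spec <- cohort_spec(3, 20, 1000,
                                  params_class0 = class_params(0.1),
                                  params_class1 = class_params(0.7),
                                  seed = 404)
    .fixtures$co <- generate_cohort(.fixtures$spec)
  }
  .fixtures$co
}

small_tensor <- function() {
  if (is.null(.fixtures$ft)) {
    es <- build_dataset(small_cohort(), step_s = 2)
    .fixtures$ft <- transform_epochset(es)
  }
  .fixtures$ft
}
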
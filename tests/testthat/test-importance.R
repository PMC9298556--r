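# The kernel-weight channel attribution: exact arithmetic of the published
# formulas, its algebraic properties, and weight extraction from fits.

fake_fit <- function(W) {
  # W: kernels x channels for one fold's conv0
  structure(list(arch = build_opt_model(),
                 params = list(conv0 = list(
                   W = array(t(W), c(1, 1, ncol(W), nrow(W)))))),
            class = "eeg_cnn_fit")
}

test_that("weights extract as (fold, kernel, channel) with montage names", {
  set.seed(21)
  Ws <- lapply(1:10, function(i) matrix(rnorm(8 * 16), 8, 16))
  kw <- extract_conv0_weights(lapply(Ws, fake_fit))
  expect_equal(dim(kw$W), c(10, 8, 16))
  expect_equal(dimnames(kw$W)[[3]], EEG_MONTAGE)
  expect_equal(kw$W[3, , ], Ws[[3]], ignore_attr = TRUE)
})

test_that("the base architecture is rejected for importance", {
  fit <- structure(list(arch = build_base_model(), params = list()),
                   class = "eeg_cnn_fit")
  expect_error(extract_conv0_weights(list(fit)), "opt-model")
})

test_that("worked examples reproduce the published formulas exactly", {
  # K = 2 folds, M = 2 kernels, single channel with |W| = {1, 1, 3, 3}
  W <- array(c(1, -1, -3, 3), c(2, 2, 1))
  rep1 <- channel_importance(W)
  expect_equal(rep1$Mn, 8 / 4)            # sum|W| / (M + K)
  expect_equal(rep1$Sn, 4 / 3)            # sum (|W| - Mn)^2 / (M + K - 1)
  expect_equal(rep1$Pn, 8 / 3)
  # conventional denominators
  rep2 <- channel_importance(W, variant = "mean_variance")
  expect_equal(rep2$Mn, 8 / 4)            # M*K happens to equal M+K here
  expect_equal(rep2$Sn, 4 / 3)
  # K = 3, M = 2 separates the two variants
  W2 <- array(2, c(3, 2, 1))
  expect_equal(channel_importance(W2)$Mn, 12 / 5)
  expect_equal(channel_importance(W2, "mean_variance")$Mn, 2)

  # equal |W| means zero spread hence zero importance
  Weq <- array(5, c(2, 2, 4))
  req <- channel_importance(Weq)
  expect_equal(req$Pn, rep(0, 4))
  expect_equal(req$rank, 1:4)             # tie broken by montage order

  Wz <- array(0, c(2, 2, 16))
  expect_equal(channel_importance(Wz)$Pn, rep(0, 16))
})

test_that("scaling all weights by c scales Mn, Sn, Pn by c, c^2, c^3", {
  set.seed(22)
  W <- array(rnorm(5 * 8 * 16), c(5, 8, 16))
  r1 <- channel_importance(W)
  r3 <- channel_importance(3 * W)
  expect_equal(r3$Mn, 3 * r1$Mn)
  expect_equal(r3$Sn, 9 * r1$Sn)
  expect_equal(r3$Pn, 27 * r1$Pn)
  expect_equal(r3$rank, r1$rank)
})

test_that("permuting channels permutes the scores identically", {
  set.seed(23)
  W <- array(rnorm(4 * 8 * 16), c(4, 8, 16))
  perm <- sample(16)
  r <- channel_importance(W)
  rp <- channel_importance(W[, , perm])
  expect_equal(rp$Pn, r$Pn[perm])
})

test_that("ranking is a permutation sorted by descending Pn", {
  set.seed(24)
  W <- array(rnorm(3 * 8 * 16), c(3, 8, 16),
             dimnames = list(NULL, NULL, EEG_MONTAGE))
  rep <- channel_importance(W)
  expect_setequal(rep$rank, 1:16)
  ord <- rank_channels(rep)
  pn <- rep$Pn[match(ord, rep$channel)]
  expect_true(all(diff(pn) <= 0))
  csv <- withr::local_tempfile(fileext = ".csv")
  rank_channels(rep, csv)
  tab <- utils::read.csv(csv)
  expect_equal(tab$channel, ord)
  expect_true(all(c("region", "Mn", "Sn", "Pn", "rank") %in% names(tab)))
})

test_that("weights survive fit serialization", {
  set.seed(25)
  fit <- fake_fit(matrix(rnorm(8 * 16), 8, 16))
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(fit, path)
  kw1 <- extract_conv0_weights(list(fit))
  kw2 <- extract_conv0_weights(list(readRDS(path)))
  expect_identical(kw1$W, kw2$W)
})
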
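# Spectral entropy math and the 17x17 heat maps.

test_that("normalized spectral entropy closed forms", {
  expect_equal(normalized_spectral_entropy(rep(1 / 7, 7)), 1.0)
  expect_equal(normalized_spectral_entropy(c(1, 0, 0, 0, 0)), 0.0)
  expect_equal(normalized_spectral_entropy(c(0.5, 0.5, 0, 0)), 0.5)
  expect_error(normalized_spectral_entropy(c(1)), "log2 N")
  expect_error(normalized_spectral_entropy(c(0.7, 0.7)), "probability")
})

test_that("spectral probabilities normalize and reject degenerate input", {
  expect_equal(spectral_prob(c(2, 2, 0, 0)), c(0.5, 0.5, 0, 0))
  expect_equal(spectral_prob(c(1, 2, 3)), c(1, 2, 3) / 6)
  set.seed(1)
  s <- rexp(100)
  expect_equal(sum(spectral_prob(s)), 1, tolerance = 1e-12)
  expect_error(spectral_prob(c(0, 0)), "zero")
  expect_error(spectral_prob(c(-1, 2)), "negative")
})

test_that("entropy is exactly invariant to spectrum rescaling", {
  set.seed(2)
  s <- rexp(24)
  expect_identical(normalized_spectral_entropy(spectral_prob(s)),
                   normalized_spectral_entropy(spectral_prob(1e7 * s)))
})

test_that("power spectrum matches the DFT definition", {
  expect_equal(power_spectrum(numeric(8)), numeric(5))
  # unit sinusoid at an exact bin: all mass in that bin
  n <- 64
  x <- sin(2 * pi * 5 * seq(0, n - 1) / n)
  S <- power_spectrum(x)
  expect_gt(S[6] / sum(S), 1 - 1e-6)
  # Parseval against the brute-force DFT on a random 32-sample vector
  set.seed(3)
  v <- rnorm(32)
  S2 <- power_spectrum(v)
  Xb <- dft_brute(v)
  expect_equal(sum(Mod(Xb)^2) / 32, sum(v^2), tolerance = 1e-9)
  expect_equal(S2, (Re(Xb)^2 + Im(Xb)^2)[1:17], tolerance = 1e-9)
  expect_error(power_spectrum(numeric(0)), "empty")
  expect_error(power_spectrum(rnorm(10), fft_len = 8), "longer")
})

test_that("heat maps are 17x17 in [0,1] and match the brute-force oracle", {
  g <- tf_grid()
  set.seed(4)
  x <- rnorm(4000)
  img <- entropy_heatmap(x, g)
  expect_equal(dim(img), c(17L, 17L))
  expect_true(all(img >= 0 & img <= 1))
  expect_lt(max(abs(img - entropy_map_brute(x, g))), 1e-9)
  expect_error(entropy_heatmap(rnorm(1000), g), "frames")
})

test_that("white noise scores high entropy; a tone lowers its band", {
  g <- tf_grid()
  set.seed(5)
  grand <- mean(vapply(1:20, function(i) mean(entropy_heatmap(rnorm(4000), g)),
                       0))
  # frozen Monte-Carlo oracle mean 0.876 (n = 100 run, se ~ 0.001)
  expect_equal(grand, 0.876, tolerance = 0.01)
  expect_gt(grand, 0.8)
  tone <- sin(2 * pi * 10 * seq_len(4000) / 1000)
  b <- floor(10 / 3) + 1                 # band [9,12) holds 10 Hz
  tone_band <- mean(entropy_heatmap(tone, g)[, b])
  noise_band <- mean(vapply(1:20, function(i)
    mean(entropy_heatmap(rnorm(4000), g)[, b]), 0))
  expect_lt(tone_band, noise_band - 0.03)
})

test_that("all-zero signal maps to all-zero entropy by convention", {
  expect_equal(entropy_heatmap(numeric(4000)), matrix(0, 17, 17))
})

test_that("power heat maps normalize per image", {
  g <- tf_grid()
  expect_equal(power_heatmap(numeric(4000), g), matrix(0, 17, 17))
  tone <- sin(2 * pi * 10 * seq_len(4000) / 1000)
  img <- power_heatmap(tone, g)
  b <- floor(10 / 3) + 1
  expect_equal(max(img), 1)
  expect_true(all(img[, b] >= apply(img[, -b], 1, max)))
  # near-invariance to amplitude rescaling (log1p breaks exactness)
  set.seed(6)
  x <- rnorm(4000)
  expect_lt(max(abs(power_heatmap(2 * x, g) - power_heatmap(x, g))), 0.05)
})

test_that("tensor transform carries labels and shows the class contrast", {
  ft <- small_tensor()
  n <- length(ft$labels)
  expect_equal(dim(ft$images), c(n, 16, 17, 17))
  expect_true(all(ft$images >= 0 & ft$images <= 1))
  expect_equal(sort(unique(ft$labels)), c(0L, 1L))
  m <- entropy_by_channel(ft)
  expect_lt(mean(m[ft$labels == 1, ]), mean(m[ft$labels == 0, ]))
  # per-channel transform agrees with the batched path
  ep <- epoch_data(build_dataset(small_cohort(), step_s = 2), 3)
  expect_equal(ft$images[3, 5, , ], entropy_heatmap(ep[5, ]))
})

test_that("feature tensors round-trip through serialization", {
  ft <- small_tensor()
  dir <- withr::local_tempdir()
  write_features(ft, dir)
  back <- read_features(dir)
  expect_equal(back$images, ft$images)
  expect_equal(back$labels, ft$labels)
  expect_equal(back$kind, "entropy")
})

test_that("grid invariants are enforced", {
  expect_equal(floor((4000 - 1024) / 186) + 1, 17)  # default frame geometry
  expect_error(tf_grid(frame_len = 256, fft_len = 512, band_hz = 1),
               "fewer than 2")
  expect_error(tf_grid(n_freq = 300), "Nyquist")
})
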
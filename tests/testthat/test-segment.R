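# Sliding-window segmentation: the closed-form epoch count, the
# step/overlap mapping, and contiguity with the source recording.

test_that("epoch counts follow floor((T - window)/step) + 1 on a grid", {
  fs <- 100
  for (dur in c(4, 5, 9, 17, 60, 121)) {
    rec <- eeg_recording(matrix(rnorm(16 * dur * fs), 16), fs)
    for (step in 1:4) {
      eps <- suppressWarnings(segment(rec, step_s = step))
      expect_length(eps, floor((dur - 4) / step) + 1)
      expect_equal(n_epochs(dur, 4, step), length(eps))
    }
  }
  expect_equal(n_epochs(900, 4, 4), 225)
  expect_equal(n_epochs(900, 4, 1), 897)
  expect_equal(n_epochs(60, 4, 1), 57)
})

test_that("step maps to the conventional overlap rates", {
  rec <- eeg_recording(matrix(rnorm(16 * 2000), 16), 100)
  for (pair in list(c(4, 0), c(3, 25), c(2, 50), c(1, 75))) {
    es <- build_dataset(list(rec), step_s = pair[1])
    expect_equal(es$overlap_pct, pair[2])
  }
})

test_that("every epoch is a contiguous slice of its source", {
  rec <- generate_recording(class_params(0.3), 12, 200, seed = 8,
                            subject_id = "S9", label = 1L)
  eps <- segment(rec, step_s = 2)
  for (e in eps) {
    j0 <- round(e$start_s * rec$fs)
    expect_identical(e$data, rec$data[, (j0 + 1):(j0 + 4 * rec$fs)])
    expect_equal(e$label, 1L)
    expect_equal(dim(e$data), c(16L, 4 * 200L))
  }
})

test_that("build_dataset concatenates with provenance and shuffles stably", {
  co <- generate_cohort(cohort_spec(3, 8, 200, seed = 2))
  es <- build_dataset(co, step_s = 4)
  expect_length(es, 6 * n_epochs(8, 4, 4))
  expect_setequal(unique(es$index$subject_id),
                  vapply(co, function(r) r$subject_id, ""))
  s1 <- build_dataset(co, step_s = 4, shuffle_seed = 42)
  s2 <- build_dataset(co, step_s = 4, shuffle_seed = 42)
  expect_identical(s1$index, s2$index)
  expect_false(identical(s1$index$start_s, es$index$start_s) &&
                 identical(s1$index$subject_id, es$index$subject_id))
})

test_that("epoch counts scale with step (57 vs 14 per 60-s subject)", {
  co <- generate_cohort(cohort_spec(1, 60, 100, seed = 4))
  expect_length(build_dataset(co, step_s = 1), 2 * 57)
  expect_length(build_dataset(co, step_s = 4), 2 * 15)
})

test_that("invalid segmentation inputs are rejected", {
  rec <- eeg_recording(matrix(rnorm(16 * 300), 16), 100)  # 3 s
  expect_error(segment(rec), "window")
  expect_warning(
    segment(eeg_recording(matrix(rnorm(16 * 1000), 16), 100), step_s = 2.5),
    "conventional")
  a <- eeg_recording(matrix(rnorm(16 * 800), 16), 100)
  b <- eeg_recording(matrix(rnorm(16 * 800), 16), 200)
  expect_error(build_dataset(list(a, b), step_s = 4), "heterogeneous")
})

test_that("epoch sets round-trip through the directory layout", {
  co <- generate_cohort(cohort_spec(1, 8, 100, seed = 12))
  es <- build_dataset(co, step_s = 2)
  dir <- withr::local_tempdir()
  write_epochset(es, dir)
  expect_true(file.exists(file.path(dir, "index.csv")))
  back <- read_epochset(dir)
  expect_equal(length(back), length(es))
  expect_equal(back$overlap_pct, 50)
  for (i in seq_len(length(es)))
    expect_equal(epoch_data(back, i), epoch_data(es, i), ignore_attr = TRUE)
})
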
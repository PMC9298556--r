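# Fold construction, the six classification metrics, ROC averaging, and the
# Kolmogorov-Smirnov comparison.

test_that("folds partition the items with the 81/9/10 split", {
  for (seed in 1:3) {
    folds <- kfold_split(100, k = 10, seed = seed)
    tests <- sort(unlist(lapply(folds, `[[`, "test")))
    expect_equal(tests, 1:100)
    for (f in folds) {
      expect_length(f$test, 10)
      expect_length(f$val, 9)
      expect_length(f$learn, 81)
      expect_equal(sort(c(f$learn, f$val, f$test)), 1:100)
    }
  }
  expect_identical(kfold_split(57, 10, seed = 4), kfold_split(57, 10, seed = 4))
  expect_error(kfold_split(5, 10))
})

test_that("subject-mode folds never split a subject", {
  ids <- rep(sprintf("S%02d", 1:12), each = 7)
  folds <- kfold_split(length(ids), k = 10, seed = 2, mode = "subject",
                       subject_ids = ids)
  for (f in folds) {
    expect_length(intersect(ids[f$test], ids[c(f$learn, f$val)]), 0)
    expect_length(intersect(ids[f$val], ids[f$learn]), 0)
  }
  expect_error(kfold_split(40, k = 10, mode = "subject",
                           subject_ids = rep(c("a", "b"), 20)),
               "at least k")
})

test_that("metrics match closed forms on the worked confusion table", {
  # TP = 8, FN = 2, TN = 9, FP = 1
  labels <- c(rep(1, 10), rep(0, 10))
  pred <- c(rep(1, 8), rep(0, 2), rep(0, 9), 1)
  m <- compute_metrics(labels, pred)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$precision, 8 / 9)
  expect_equal(m$f1, 2 * (8 / 9) * 0.8 / ((8 / 9) + 0.8))
  expect_equal(unname(m$confusion), c(8, 1, 9, 2))
})

test_that("zero-denominator metrics are NA, not zero", {
  m <- compute_metrics(c(0, 0, 0), c(0, 0, 0))
  expect_true(is.na(m$precision))
  expect_true(is.na(m$sensitivity))
  expect_equal(m$specificity, 1)
})

test_that("metric identity holds on random confusion tables", {
  set.seed(8)
  for (i in 1:20) {
    n1 <- sample(5:50, 1); n0 <- sample(5:50, 1)
    labels <- c(rep(1, n1), rep(0, n0))
    pred <- sample(0:1, n1 + n0, replace = TRUE)
    m <- compute_metrics(labels, pred)
    expect_equal(m$accuracy,
                 (m$sensitivity * n1 + m$specificity * n0) / (n1 + n0))
  }
})

test_that("AUC matches the pairwise brute-force oracle", {
  expect_equal(compute_metrics(c(0, 0, 1, 1), c(0, 0, 1, 1),
                               c(0.1, 0.2, 0.8, 0.9))$auc, 1.0)
  set.seed(9)
  labels <- sample(0:1, 1000, replace = TRUE)
  scores <- runif(1000)
  m <- compute_metrics(labels, as.integer(scores > 0.5), scores)
  expect_equal(m$auc, auc_pairwise(labels, scores), tolerance = 1e-12)
  expect_equal(m$auc, 0.5, tolerance = 0.06)
  # ties handled like the pairwise convention
  sc <- round(runif(400), 1)
  lb <- sample(0:1, 400, replace = TRUE)
  expect_equal(compute_metrics(lb, as.integer(sc > 0.5), sc)$auc,
               auc_pairwise(lb, sc), tolerance = 1e-12)
})

test_that("vertical ROC averaging behaves at its boundaries", {
  f1 <- list(labels = c(0, 0, 1, 1), scores = c(0.1, 0.6, 0.4, 0.9))
  avg1 <- average_roc(list(f1))
  r1 <- eegsent:::roc_points(f1$labels, f1$scores)
  expect_equal(avg1$tpr,
               stats::approx(r1$fpr, r1$tpr, xout = avg1$fpr,
                             ties = max, rule = 2)$y)
  perfect <- list(labels = c(0, 0, 1, 1), scores = c(0.1, 0.2, 0.8, 0.9))
  avg2 <- average_roc(list(perfect, perfect))
  expect_equal(avg2$tpr[avg2$fpr == 0][1], 1)
  set.seed(10)
  folds <- lapply(1:5, function(i)
    list(labels = sample(0:1, 40, replace = TRUE), scores = runif(40)))
  aucs <- vapply(folds, function(f) auc_pairwise(f$labels, f$scores), 0)
  avg <- average_roc(folds)
  auc_avg <- eegsent:::trapezoid_auc(avg$fpr, avg$tpr)
  expect_gte(auc_avg, min(aucs) - 0.02)
  expect_lte(auc_avg, max(aucs) + 0.02)
  expect_warning(average_roc(list(f1, list(labels = c(1, 1), scores = c(0.5, 0.6)))),
                 "single-class")
})

test_that("KS statistic matches the brute-force ECDF sweep", {
  x <- c(1, 2, 3); y <- c(1, 2, 3)
  expect_equal(suppressWarnings(ks_compare(x, y))$statistic, 0)
  expect_equal(suppressWarnings(ks_compare(1:5, 6:10))$statistic, 1)
  set.seed(12)
  a <- rnorm(50); b <- rnorm(50)
  r <- ks_compare(a, b)
  expect_equal(r$statistic, ks_stat_brute(a, b), tolerance = 1e-12)
  expect_warning(ks_compare(rnorm(3), rnorm(50)), "unreliable")
  expect_error(ks_compare(numeric(0), rnorm(5)), "empty")
})

test_that("per-channel KS on a contrasted cohort rejects on all channels", {
  ft <- small_tensor()
  ks <- ks_compare(ft)
  expect_equal(nrow(ks), 16)
  expect_equal(ks$channel, EEG_MONTAGE)
  expect_true(all(ks$p_value < 0.01))
})
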
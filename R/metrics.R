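# Fold construction, classification metrics, ROC handling, and the
# two-sample Kolmogorov-Smirnov comparison of per-channel entropy values.

#' Build 10-fold cross-validation splits
#'
#' Each fold's test set is 1/10 of the items; the remaining 9/10 are split
#' into a learning partition (81% of all items) and a validation partition
#' (9%) used for early stopping. `mode = "epoch"` shuffles epochs freely (so
#' epochs of one subject can appear on both sides of a fold — optimistic when
#' epochs overlap); `mode = "subject"` assigns whole subjects to folds.
#'
#' @param n_items number of items (epochs).
#' @param k number of folds.
#' @param seed shuffle seed.
#' @param mode `"epoch"` or `"subject"`.
#' @param subject_ids required for subject mode: one id per item.
#' @return List of `k` folds, each with `fold`, `learn`, `val`, `test`
#'   integer index vectors (disjoint; their union is all items).
#' @export
kfold_split <- function(n_items, k = 10, seed = 1,
                        mode = c("epoch", "subject"), subject_ids = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_items >= k)
  with_seed(seed, {
    if (mode == "epoch") {
      # random permutation cut into k nearly equal folds
      perm <- sample.int(n_items)
      fold_of <- integer(n_items)
      fold_of[perm] <- rep(seq_len(k), length.out = n_items)
    } else {
      if (is.null(subject_ids) || length(subject_ids) != n_items)
        stop("subject mode needs subject_ids for every item", call. = FALSE)
      subj <- unique(subject_ids)
      if (length(subj) < k)
        stop("subject mode needs at least k = ", k, " subjects", call. = FALSE)
      sperm <- sample(subj)
      sfold <- rep(seq_len(k), length.out = length(subj))
      fold_of <- sfold[match(subject_ids, sperm)]
    }
    lapply(seq_len(k), function(f) {
      test <- which(fold_of == f)
      rest <- which(fold_of != f)
      if (mode == "epoch") {
        rest <- sample(rest)
        n_val <- max(1, round(length(rest) * 0.1))
      } else {
        rest_subj <- sample(unique(subject_ids[rest]))
        n_vs <- max(1, round(length(rest_subj) * 0.1))
        val_subj <- rest_subj[seq_len(n_vs)]
        rest <- c(rest[subject_ids[rest] %in% val_subj],
                  rest[!subject_ids[rest] %in% val_subj])
        n_val <- sum(subject_ids[rest] %in% val_subj)
      }
      list(fold = f, val = sort(rest[seq_len(n_val)]),
           learn = sort(rest[-seq_len(n_val)]), test = sort(test))
    })
  })
}

#' Classification metrics for one fold
#'
#' Accuracy, precision, specificity, sensitivity (recall), F1 and AUC for a
#' binary problem with class 1 positive. Ratios with a zero denominator are
#' reported as `NA`, not 0. AUC is the trapezoidal area under the empirical
#' ROC curve of the class-1 scores.
#'
#' @param labels true 0/1 labels.
#' @param pred predicted 0/1 labels.
#' @param scores class-1 probabilities (for ROC/AUC); optional.
#' @return List with the six metrics, the confusion counts and the ROC
#'   points.
#' @export
compute_metrics <- function(labels, pred, scores = NULL) {
  stopifnot(length(labels) == length(pred))
  tp <- sum(labels == 1 & pred == 1); fn <- sum(labels == 1 & pred == 0)
  tn <- sum(labels == 0 & pred == 0); fp <- sum(labels == 0 & pred == 1)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe(tp, tp + fp)
  sensitivity <- safe(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(sensitivity) ||
            precision + sensitivity == 0) NA_real_
        else 2 * precision * sensitivity / (precision + sensitivity)
  roc <- NULL; auc <- NA_real_
  if (!is.null(scores) && length(unique(labels)) == 2) {
    roc <- roc_points(labels, scores)
    auc <- trapezoid_auc(roc$fpr, roc$tpr)
  }
  list(accuracy = safe(tp + tn, length(labels)),
       precision = precision,
       specificity = safe(tn, tn + fp),
       sensitivity = sensitivity,
       f1 = f1, auc = auc,
       confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
       roc = roc)
}

# Empirical ROC curve: one point per distinct score threshold, from (0,0)
# to (1,1), scores ranked descending (class 1 positive).
roc_points <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  tpr <- cumsum(lab == 1) / sum(lab == 1)
  fpr <- cumsum(lab == 0) / sum(lab == 0)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)   # last point of each tie block
  data.frame(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep]))
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Vertically averaged ROC curve across folds
#'
#' Each fold's ROC is linearly interpolated onto a fixed false-positive-rate
#' grid (0 to 1 by 0.01) and the true-positive rates are averaged. Folds
#' whose test set contains a single class are excluded with a warning.
#'
#' @param folds list of lists with `labels` and `scores` per fold.
#' @param grid false-positive-rate grid.
#' @return Data frame with `fpr`, `tpr` (mean) and `sd`.
#' @export
average_roc <- function(folds, grid = seq(0, 1, by = 0.01)) {
  stopifnot(length(folds) >= 1)
  curves <- list()
  for (i in seq_along(folds)) {
    f <- folds[[i]]
    if (length(unique(f$labels)) < 2) {
      warning("fold ", i, " has a single-class test set; excluded from ROC")
      next
    }
    r <- roc_points(f$labels, f$scores)
    curves[[length(curves) + 1]] <-
      stats::approx(r$fpr, r$tpr, xout = grid, ties = max, rule = 2)$y
  }
  if (!length(curves)) stop("no fold with both classes", call. = FALSE)
  m <- do.call(cbind, curves)
  data.frame(fpr = grid, tpr = rowMeans(m),
             sd = apply(m, 1, stats::sd))
}

#' Per-channel mean entropy of every epoch
#'
#' Averages each heat map over its cells, giving one value per (epoch,
#' channel) — the pooled per-channel samples used for group comparisons.
#'
#' @param ft a `feature_tensor`.
#' @return `N x 16` matrix with montage channel names as columns.
#' @export
entropy_by_channel <- function(ft) {
  m <- apply(ft$images, c(1, 2), mean)
  colnames(m) <- EEG_MONTAGE
  m
}

#' Two-sample Kolmogorov-Smirnov comparison per channel
#'
#' Compares the class-0 and class-1 distributions of per-channel values with
#' the two-sample KS test (statistic = sup |ECDF0 - ECDF1|, asymptotic
#' p-value). Given a `feature_tensor`, the per-channel mean entropies from
#' [entropy_by_channel()] are compared; given two numeric vectors, those are
#' compared directly.
#'
#' @param x a `feature_tensor`, or a numeric vector (group 0).
#' @param y ignored for a tensor; numeric vector (group 1) otherwise.
#' @return Data frame with `channel`, `statistic`, `p_value`.
#' @export
ks_compare <- function(x, y = NULL) {
  one <- function(a, b, name) {
    if (length(a) == 0 || length(b) == 0)
      stop("empty group in KS comparison", call. = FALSE)
    if (length(a) < 5 || length(b) < 5)
      warning("fewer than 5 values in a group; KS p-value unreliable")
    kt <- suppressWarnings(stats::ks.test(a, b))
    data.frame(channel = name, statistic = unname(kt$statistic),
               p_value = kt$p.value, stringsAsFactors = FALSE)
  }
  if (inherits(x, "feature_tensor")) {
    vals <- entropy_by_channel(x)
    cls <- x$labels
    do.call(rbind, lapply(seq_len(ncol(vals)), function(j)
      one(vals[cls == 0, j], vals[cls == 1, j], colnames(vals)[j])))
  } else {
    one(x, y, "values")
  }
}

#' 10-fold cross-validated training and evaluation
#'
#' Trains one model per fold with [train_model()], evaluates the six metrics
#' on each fold's held-out test epochs, and aggregates mean and standard
#' deviation (n-1 denominator) across folds, plus the vertically averaged
#' ROC curve.
#'
#' @param arch a `cnn_arch`.
#' @param tensor a `feature_tensor`.
#' @param k number of folds.
#' @param cfg a [train_config()]; fold `f` trains with seed
#'   `cfg$seed + f - 1`.
#' @param mode fold mode, see [kfold_split()].
#' @param keep_fits keep the fitted models (needed for channel importance).
#' @param verbose print fold progress.
#' @return A `cv_result`: `per_fold` metrics data frame, `summary`
#'   (mean/sd), `roc` (averaged curve), `fits` (if kept), `traces`.
#' @export
cross_validate <- function(arch, tensor, k = 10, cfg = train_config(),
                           mode = c("epoch", "subject"), keep_fits = TRUE,
                           verbose = FALSE) {
  mode <- match.arg(mode)
  if (mode == "epoch")
    message("epoch-mode folds can share subjects between train and test; ",
            "use mode = \"subject\" for subject-level generalization")
  n <- dim(tensor$images)[1]
  splits <- kfold_split(n, k, seed = cfg$seed, mode = mode,
                        subject_ids = tensor$subject_ids)
  metric_names <- c("accuracy", "precision", "specificity", "sensitivity",
                    "f1", "auc")
  per_fold <- list(); rocs <- list(); fits <- list(); traces <- list()
  for (f in seq_len(k)) {
    cfg_f <- cfg; cfg_f$seed <- cfg$seed + f - 1L
    fit <- train_model(arch, tensor, splits[[f]], cfg_f)
    pr <- predict(fit, tensor, splits[[f]]$test)
    lab <- tensor$labels[splits[[f]]$test]
    m <- compute_metrics(lab, pr$pred, pr$prob1)
    per_fold[[f]] <- data.frame(fold = f, t(unlist(m[metric_names])),
                                best_epoch = fit$best_epoch,
                                stopped_epoch = fit$stopped_epoch,
                                val_accuracy = fit$best_val_accuracy)
    rocs[[f]] <- list(labels = lab, scores = pr$prob1)
    traces[[f]] <- cbind(fold = f, fit$traces)
    if (keep_fits) fits[[f]] <- fit
    if (verbose)
      message(sprintf("fold %2d/%d: test accuracy %.4f (best epoch %d)",
                      f, k, m$accuracy, fit$best_epoch))
  }
  per_fold <- do.call(rbind, per_fold)
  summary <- data.frame(
    metric = metric_names,
    mean = vapply(metric_names, function(m) mean(per_fold[[m]], na.rm = TRUE), 0),
    sd = vapply(metric_names, function(m) stats::sd(per_fold[[m]], na.rm = TRUE), 0))
  rownames(summary) <- NULL
  structure(list(arch_name = arch$name, mode = mode, k = k,
                 per_fold = per_fold, summary = summary,
                 roc = average_roc(rocs), fold_scores = rocs,
                 fits = if (keep_fits) fits,
                 traces = do.call(rbind, traces)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s-model, %d-fold (%s mode)\n",
              x$arch_name, x$k, x$mode))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}
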
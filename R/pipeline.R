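# End-to-end orchestration: cohort -> preprocessing -> segmentation ->
# feature images -> cross-validated training -> metrics, ROC, traces,
# channel importance -- with every artifact listed in a hashed manifest so a
# rerun with the same configuration and seed reproduces files exactly.

#' Assemble a pipeline run configuration
#'
#' @param input either an [cohort_spec()] (synthetic cohort) or a directory
#'   of EDF files with a `manifest.csv` (as written by [write_cohort_edf()]).
#' @param out_dir output directory for run artifacts.
#' @param step_s segmentation step in seconds (4/3/2/1 = 0/25/50/75%
#'   overlap).
#' @param representation `"entropy"` or `"power"` heat maps.
#' @param architecture `"base"`, `"opt"` or `"both"`.
#' @param bandpass length-2 passband in Hz, or `NULL` to skip filtering
#'   (synthetic cohorts are already band-limited by construction).
#' @param mains_hz notch frequency, or `NULL` to skip the notch.
#' @param grid a [tf_grid()].
#' @param train a [train_config()].
#' @param k,cv_mode cross-validation folds and mode (see [kfold_split()]).
#' @param seed root seed for fold assignment and training.
#' @return A `run_config` list.
#' @export
run_config <- function(input, out_dir, step_s = 1,
                       representation = c("entropy", "power"),
                       architecture = c("both", "base", "opt"),
                       bandpass = NULL, mains_hz = NULL,
                       grid = tf_grid(), train = train_config(),
                       k = 10, cv_mode = "epoch", seed = 1) {
  structure(list(input = input, out_dir = out_dir, step_s = step_s,
                 representation = match.arg(representation),
                 architecture = match.arg(architecture),
                 bandpass = bandpass, mains_hz = mains_hz,
                 grid = grid, train = train, k = k, cv_mode = cv_mode,
                 seed = as.integer(seed)),
            class = "run_config")
}

load_cohort <- function(input) {
  if (inherits(input, "eeg_cohort_spec")) return(generate_cohort(input))
  if (is.character(input) && dir.exists(input)) {
    mf <- file.path(input, "manifest.csv")
    files <- if (file.exists(mf)) {
      man <- utils::read.csv(mf, stringsAsFactors = FALSE)
      file.path(input, man$file)
    } else list.files(input, "\\.edf$", full.names = TRUE, ignore.case = TRUE)
    if (!length(files)) stop("no EDF files under ", input, call. = FALSE)
    return(lapply(files, read_edf))
  }
  stop("input must be a cohort_spec or an EDF directory", call. = FALSE)
}

#' Run the full pipeline
#'
#' Executes synthesize/ingest, optional preprocessing, segmentation at the
#' configured overlap, heat-map transformation, cross-validated training of
#' the requested architecture(s), metric aggregation, the per-channel KS
#' comparison, and (for the opt-model) channel-importance scoring. All
#' outputs land in `config$out_dir` together with `config.json` (the
#' reproducibility record) and `manifest.csv` (file names + MD5 hashes).
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return Invisibly, a list with the `cv_result`s, the feature tensor and
#'   the importance report (when computed).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[eegsent] ", ...)

  say("loading cohort")
  cohort <- load_cohort(config$input)
  if (!is.null(config$bandpass))
    cohort <- lapply(cohort, bandpass_filter,
                     low_hz = config$bandpass[1], high_hz = config$bandpass[2])
  if (!is.null(config$mains_hz))
    cohort <- lapply(cohort, notch_filter, mains_hz = config$mains_hz)

  say("segmenting (step ", config$step_s, " s)")
  es <- build_dataset(cohort, step_s = config$step_s)
  say(length(es), " epochs; computing ", config$representation, " maps")
  ft <- transform_epochset(es, config$grid, config$representation)

  ks <- if (config$representation == "entropy" &&
            length(unique(ft$labels)) == 2) ks_compare(ft)

  archs <- switch(config$architecture,
                  both = list(build_base_model(), build_opt_model()),
                  base = list(build_base_model()),
                  opt = list(build_opt_model()))
  cfg <- config$train; cfg$seed <- config$seed
  results <- list()
  for (arch in archs) {
    say("training ", arch$name, "-model, ", config$k, "-fold CV")
    results[[arch$name]] <- suppressMessages(
      cross_validate(arch, ft, k = config$k, cfg = cfg,
                     mode = config$cv_mode, verbose = verbose))
  }

  imp <- if ("opt" %in% names(results)) {
    channel_importance(extract_conv0_weights(results$opt$fits))
  }

  # ---- artifacts ----
  od <- config$out_dir
  utils::write.csv(es$index[, c("subject_id", "label", "start_s")],
                   file.path(od, "dataset_index.csv"), row.names = FALSE)
  if (!is.null(ks)) utils::write.csv(ks, file.path(od, "ks_by_channel.csv"),
                                     row.names = FALSE)
  metrics <- lapply(results, function(r) {
    s <- stats::setNames(split(r$summary[c("mean", "sd")],
                               seq_len(nrow(r$summary))), r$summary$metric)
    lapply(s, function(row) list(mean = row$mean, sd = row$sd))
  })
  jsonlite::write_json(metrics, file.path(od, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(results)) {
    r <- results[[nm]]
    utils::write.csv(r$per_fold, file.path(od, paste0("per_fold_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(r$roc, file.path(od, paste0("roc_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(r$traces, file.path(od, paste0("traces_", nm, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(imp))
    utils::write.csv(imp[order(imp$rank), ],
                     file.path(od, "importance.csv"), row.names = FALSE)

  record <- list(
    run_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("eegsent")),
    r_version = R.version.string,
    seed = config$seed, step_s = config$step_s,
    representation = config$representation,
    architecture = config$architecture, k = config$k,
    cv_mode = config$cv_mode,
    train = unclass(config$train),
    input = if (inherits(config$input, "eeg_cohort_spec"))
      list(kind = "synthetic",
           n_per_class = config$input$n_per_class,
           duration_s = config$input$duration_s, fs = config$input$fs,
           seed = config$input$seed,
           narrowband_fraction = c(config$input$params_class0$narrowband_fraction,
                                   config$input$params_class1$narrowband_fraction))
    else list(kind = "edf_dir", path = config$input))
  jsonlite::write_json(record, file.path(od, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- setdiff(list.files(od), "manifest.csv")
  utils::write.csv(data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(od, files)))),
    file.path(od, "manifest.csv"), row.names = FALSE)

  invisible(list(results = results, tensor = ft, importance = imp, ks = ks))
}

#' Overlap-rate sweep
#'
#' Trains one architecture at each segmentation step (4, 3, 2, 1 s by
#' default, i.e. 0/25/50/75% overlap) on the same cohort and tabulates the
#' cross-validated mean accuracy, mirroring the overlap-rate comparison of
#' the segmentation study.
#'
#' @param cohort list of [eeg_recording()]s.
#' @param steps segmentation steps in seconds.
#' @param arch a `cnn_arch` (base model by default).
#' @param cfg a [train_config()].
#' @param k folds.
#' @param grid a [tf_grid()].
#' @return Data frame: `step_s`, `overlap_pct`, `n_epochs`, `accuracy_mean`,
#'   `accuracy_sd`, `auc_mean`.
#' @export
overlap_sweep <- function(cohort, steps = c(4, 3, 2, 1),
                          arch = build_base_model(), cfg = train_config(),
                          k = 10, grid = tf_grid()) {
  rows <- lapply(steps, function(s) {
    es <- build_dataset(cohort, step_s = s)
    ft <- transform_epochset(es, grid)
    cv <- suppressMessages(cross_validate(arch, ft, k = k, cfg = cfg,
                                          keep_fits = FALSE))
    sm <- cv$summary
    data.frame(step_s = s, overlap_pct = 100 * (4 - s) / 4,
               n_epochs = length(es),
               accuracy_mean = sm$mean[sm$metric == "accuracy"],
               accuracy_sd = sm$sd[sm$metric == "accuracy"],
               auc_mean = sm$mean[sm$metric == "auc"])
  })
  do.call(rbind, rows)
}
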
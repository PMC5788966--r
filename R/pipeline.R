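# End-to-end orchestration: simulate (or read SNIRF) -> preprocess ->
# features -> ROI reduction -> classification -> report. One master seed is
# fanned out deterministically to per-subject simulation seeds so any
# subject can be re-run in isolation.

#' Pipeline configuration
#'
#' Bundles every stage's parameters. Input is either the synthetic generator
#' (`n_subjects` sessions from `sim`) or a set of SNIRF files with a
#' channel-to-ROI map.
#'
#' @param n_subjects Number of simulated subjects (default 5).
#' @param sim A [sim_config()] template; its seed is replaced per subject by
#'   a sub-seed derived from `seed`.
#' @param channels_per_roi Montage size knob (default 7 = the 42-channel
#'   layout).
#' @param snirf_paths Optional character vector of SNIRF files (one per
#'   subject); overrides the generator.
#' @param roi_map Channel-to-ROI table for SNIRF input.
#' @param filter [filter_spec()].
#' @param band [band_spec()] for coherence averaging.
#' @param epoch_len,step,max_epochs,keep Epoching geometry.
#' @param iqr_factor Artifact-correction IQR factor (NA disables).
#' @param sets Feature sets to evaluate ("both", "single", "pairs").
#' @param alpha Significance level for the chance threshold.
#' @param shrinkage Fixed LDA shrinkage or NULL (analytic).
#' @param global_zscore Whole-set z-scoring instead of per-fold (default
#'   FALSE; see [evaluate_features()]).
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 5, sim = sim_config(),
                            channels_per_roi = 7,
                            snirf_paths = NULL, roi_map = NULL,
                            filter = filter_spec(), band = band_spec(),
                            epoch_len = 200, step = 60, max_epochs = 12,
                            keep = 80, iqr_factor = 1.5,
                            sets = "both", alpha = 0.05,
                            shrinkage = NULL, global_zscore = FALSE,
                            seed = 1L) {
  structure(list(
    n_subjects = as.integer(n_subjects), sim = sim,
    channels_per_roi = channels_per_roi,
    snirf_paths = snirf_paths, roi_map = roi_map,
    filter = filter, band = band,
    epoch_len = epoch_len, step = step, max_epochs = max_epochs,
    keep = keep, iqr_factor = iqr_factor,
    sets = sets, alpha = alpha, shrinkage = shrinkage,
    global_zscore = global_zscore, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @param montage Montage the config will run on (default built from the
#'   config).
#' @return Tibble of issues (`field`, `issue`); zero rows iff the config is
#'   self-consistent.
#' @export
validate_config <- function(config, montage = NULL) {
  if (is.null(montage)) {
    montage <- default_montage(channels_per_roi = config$channels_per_roi)
  }
  fs <- montage_sfreq(montage)
  issues <- list()
  add <- function(field, msg) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(field = field, issue = msg)
  }
  if (config$band$high >= fs / 2) {
    add("band", sprintf("band upper edge %.4g Hz is not below Nyquist (%.4g Hz)",
                        config$band$high, fs / 2))
  }
  if (config$filter$low_cut >= fs / 2) {
    add("filter", "low-pass cutoff is not below Nyquist")
  }
  needed <- (config$max_epochs - 1) * config$step + config$epoch_len
  floor_samples <- floor(config$sim$duration_floor * fs)
  if (floor_samples < needed) {
    add("sim.duration_floor", sprintf(
      "landing floor %.3gs (%d samples) cannot fit %d epochs (%d samples needed)",
      config$sim$duration_floor, floor_samples, config$max_epochs, needed
    ))
  }
  if (config$keep > config$epoch_len) {
    add("keep", "kept window longer than the epoch")
  }
  if (!is.null(config$snirf_paths) && is.null(config$roi_map)) {
    add("roi_map", "SNIRF input requires a channel-to-ROI map")
  }
  ok <- tryCatch({ validate_sim_config(config$sim); TRUE },
                 error = function(e) { add("sim", conditionMessage(e)); FALSE })
  invisible(ok)
  dplyr::bind_rows(issues) %||%
    tibble::tibble(field = character(0), issue = character(0))
}

# deterministic sub-seed fan-out (kept below 2^31)
derive_seed <- function(master, subject, stage = 0L) {
  (as.double(master) * 7919 + subject * 104729 + stage * 131) %% 2147483629
}

#' Run the analysis for one session
#'
#' Preprocess -> oxygenation + connectivity features -> ROI reduction ->
#' feature matrices -> CV evaluation. Used by [run_pipeline()] for each
#' subject, and directly useful for a single recording.
#'
#' @param session A `fnirs_session`.
#' @param config A [pipeline_config()].
#' @return List: `epochs`, `oxy_roi`, `conn_roi`, `features`, `cv`
#'   (a `cv_results` tibble), `warnings` (character).
#' @export
run_session <- function(session, config = pipeline_config()) {
  warn_log <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warn_log <<- c(warn_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  epochs <- collect(preprocess_session(
    session, filter = config$filter, iqr_factor = config$iqr_factor,
    epoch_len = config$epoch_len, step = config$step,
    max_epochs = config$max_epochs
  ))
  oxy <- collect(extract_oxygenation(epochs, keep = config$keep))
  conn <- collect(extract_connectivity(epochs, band = config$band,
                                       keep = config$keep))
  part <- roi_partition(session$montage)
  oxy_roi <- collect(reduce_oxygenation(oxy, part))
  conn_roi <- collect(reduce_connectivity(conn, part))
  feats <- build_feature_matrices(oxy_roi, conn_roi)
  cv <- collect(evaluate_features(
    feats, sets = config$sets, shrinkage = config$shrinkage,
    global_zscore = config$global_zscore, alpha = config$alpha
  ))
  list(epochs = epochs, oxy_roi = oxy_roi, conn_roi = conn_roi,
       features = feats, cv = cv, warnings = warn_log)
}

#' Run the full multi-subject pipeline
#'
#' Simulates (or reads) each subject's session, runs the per-session
#' analysis, and aggregates: per-subject fold-mean accuracies, then the
#' group mean across subjects per feature set and chromophore. Reruns with
#' the same config are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; if given, writes
#'   `accuracies.csv` (rows = feature sets, per-subject and average columns),
#'   `cv_folds.csv` (per-fold accuracies) and `run_report.json`.
#' @return List of class `pipeline_result`: `per_fold` (tibble with
#'   `subject`), `per_subject` (fold means), `summary` (group means with
#'   `chance_threshold` and `significant`), `chance_threshold`, `report`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  issues <- validate_config(config)
  if (nrow(issues) > 0) {
    stop("invalid configuration:\n", paste0("  - ", issues$field, ": ",
                                            issues$issue, collapse = "\n"))
  }
  montage <- default_montage(channels_per_roi = config$channels_per_roi)
  use_snirf <- !is.null(config$snirf_paths)
  n_subj <- if (use_snirf) length(config$snirf_paths) else config$n_subjects

  per_fold <- list()
  warnings_all <- list()
  thr <- NULL
  for (s in seq_len(n_subj)) {
    session <- if (use_snirf) {
      read_snirf(config$snirf_paths[s], roi_map = config$roi_map)
    } else {
      cfg_s <- config$sim
      cfg_s$seed <- as.integer(derive_seed(config$seed, s))
      simulate_session(cfg_s, montage)
    }
    res <- run_session(session, config)
    thr <- attr(res$cv, "chance_threshold")
    per_fold[[s]] <- dplyr::mutate(tibble::as_tibble(res$cv), subject = s)
    if (length(res$warnings) > 0) {
      warnings_all[[length(warnings_all) + 1L]] <- tibble::tibble(
        subject = s, message = unique(res$warnings)
      )
    }
  }
  per_fold <- dplyr::bind_rows(per_fold)
  per_subject <- per_fold |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                     .by = c("subject", "feature_set", "chromophore"))
  summary_tbl <- per_subject |>
    dplyr::summarise(sd_across_subjects = stats::sd(.data$mean_accuracy),
                     mean_accuracy = mean(.data$mean_accuracy),
                     .by = c("feature_set", "chromophore")) |>
    dplyr::select("feature_set", "chromophore", "mean_accuracy",
                  "sd_across_subjects") |>
    dplyr::mutate(chance_threshold = thr,
                  significant = 100 * .data$mean_accuracy > thr) |>
    dplyr::arrange(dplyr::desc(.data$mean_accuracy))

  report <- list(
    package_version = as.character(utils::packageVersion("fnirsbci")),
    seed = config$seed,
    n_subjects = n_subj,
    n_channels = nrow(montage),
    n_channel_pairs = nrow(channel_pairs(montage)),
    n_roi = length(unique(montage$roi)),
    n_roi_pairs = n_roi_pairs(length(unique(montage$roi))),
    epochs_per_subject = config$max_epochs * 2 * config$sim$landings_per_condition,
    chance_threshold_percent = thr,
    alpha = config$alpha,
    band_hz = c(config$band$low, config$band$high),
    warnings = if (length(warnings_all) > 0) dplyr::bind_rows(warnings_all)
               else tibble::tibble(subject = integer(0), message = character(0))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wide <- per_subject |>
      tidyr::pivot_wider(names_from = "subject", values_from = "mean_accuracy",
                         names_prefix = "subject_") |>
      dplyr::mutate(average = rowMeans(dplyr::pick(dplyr::starts_with("subject_"))))
    utils::write.csv(wide, file.path(out_dir, "accuracies.csv"),
                     row.names = FALSE)
    utils::write.csv(per_fold, file.path(out_dir, "cv_folds.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  structure(list(per_fold = per_fold, per_subject = per_subject,
                 summary = summary_tbl, chance_threshold = thr,
                 report = report),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d subjects, %d feature sets x %d chromophores; chance level %.1f%%\n",
    x$report$n_subjects, length(unique(x$summary$feature_set)),
    length(unique(x$summary$chromophore)), x$chance_threshold
  ))
  print(utils::head(x$summary, 10))
  invisible(x)
}

#' Group-level summary of a pipeline run
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @return The summary tibble (group mean accuracy per feature set and
#'   chromophore, with the chance threshold).
#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) {
  x$summary
}

#' Plot pipeline group accuracies
#' @param object A `pipeline_result`.
#' @param top Show the top `top` feature sets (default 20).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pipeline_result
#' @export
autoplot.pipeline_result <- function(object, top = 20, ...) {
  keep_sets <- object$summary |>
    dplyr::summarise(m = max(.data$mean_accuracy), .by = "feature_set") |>
    dplyr::arrange(dplyr::desc(.data$m)) |>
    dplyr::slice_head(n = top)
  df <- dplyr::semi_join(object$summary, keep_sets, by = "feature_set")
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$feature_set, .data$mean_accuracy),
    y = .data$mean_accuracy, fill = .data$chromophore
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = object$chance_threshold / 100,
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Group mean CV accuracy") +
    ggplot2::theme_minimal()
}
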
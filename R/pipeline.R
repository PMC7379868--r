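#' Default end-to-end run configuration
#'
#' Nested list mirroring the pipeline stages (simulation, preprocessing,
#' feature extraction, ensemble, evaluation). A single master seed is fanned
#' out deterministically into per-stage seeds, so each stage is
#' independently replayable. `ensemble$M = "auto"` searches the
#' [subset_size_ladder()] and reports the best subset size.
#'
#' @param seed Master seed.
#' @return A named list (schema version 1).
#' @export
default_config <- function(seed = 1L) {
  list(schema_version = 1,
       seed = as.integer(seed),
       synthdata = list(n_channels = 16,
                        sample_rate = 13.3,
                        n_trials_per_class = 30,
                        task_duration = 10,
                        rest_range = c(24, 26),
                        hrf_amplitude_hbo = 0.05,
                        hrf_amplitude_hbr = -0.015,
                        responsive_channel_fraction = 0.5),
       preprocess = list(filter = list(low = 0.01, high = 0.09, order = 6),
                         epoch = list(window = c(-1, 15),
                                      baseline = c(-1, 0))),
       features = list(set = "AVG", type = 4, slp_method = "ols"),
       ensemble = list(M = "auto", N = 100),
       evaluate = list(R = 10, K = 10, strong = "linear_svm", df = 10,
                       fdr_q = 0.05, n_grid = c(1, seq(5, 100, by = 5)),
                       curve = FALSE))
}

check_config <- function(config) {
  template <- default_config()
  extra <- setdiff(names(config), names(template))
  if (length(extra)) {
    abort(paste0("Unknown config key(s): ", paste(extra, collapse = ", "), "."))
  }
  for (section in intersect(names(config), names(template))) {
    if (is.list(template[[section]]) && !is.null(names(template[[section]]))) {
      extra <- setdiff(names(config[[section]]), names(template[[section]]))
      if (length(extra)) {
        abort(paste0("Unknown key(s) in config section '", section, "': ",
                     paste(extra, collapse = ", "), "."))
      }
    }
  }
  invisible(TRUE)
}

merge_config <- function(config) {
  check_config(config)
  out <- default_config()
  for (nm in names(config)) {
    out[[nm]] <- if (is.list(out[[nm]]) && is.list(config[[nm]])) {
      modifyList(out[[nm]], config[[nm]])
    } else {
      config[[nm]]
    }
  }
  out
}

#' Run the full simulation-to-comparison pipeline
#'
#' Executes, under one configuration: session simulation, optical-density to
#' chromophore conversion, zero-phase band-pass filtering, epoch
#' segmentation and baseline correction, feature extraction, repeated
#' stratified k-fold cross-validation of the random-subspace ensemble over
#' the subset-size ladder and of the strong learner on identical partitions,
#' and the corrected t-test between the best ensemble and the strong
#' learner. With `evaluate$curve = TRUE` it also traces accuracy and
#' FDR-adjusted significance along the learner-count grid. Deterministic
#' given the configuration: the master seed is expanded into fixed
#' per-stage seeds (simulation, subset drawing, partitioning, tie-breaks).
#'
#' @param config A configuration list (see [default_config()]); partial
#'   lists are completed with defaults. A path to a YAML file is also
#'   accepted.
#' @return A `nirs_run` bundle: the merged config, stage seeds, feature
#'   dimensionality, per-M ladder accuracies, best M, both `cv_result`s,
#'   the `corrected_t` comparison, and optionally the `learner_curve`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- merge_config(config)
  stage_seeds <- with_seed(config$seed,
                           sample.int(.Machine$integer.max, 4))
  names(stage_seeds) <- c("synth", "ensemble", "cv", "tie")

  params <- do.call(session_params,
                    c(config$synthdata, list(seed = stage_seeds[["synth"]])))
  flt <- config$preprocess$filter
  epo <- config$preprocess$epoch
  epochs <- simulate_session(params) %>%
    od_to_chromophores() %>%
    nirs_bandpass(low = flt$low, high = flt$high, order = flt$order) %>%
    segment_epochs(window = epo$window) %>%
    baseline_correct(ref = epo$baseline)
  feats <- build_feature_matrix(epochs,
                                features = config$features$set,
                                scheme = window_scheme(config$features$type),
                                slp_method = config$features$slp_method)
  D <- ncol(feats) - 2L

  ev <- config$evaluate
  folds <- make_folds(feats$label, R = ev$R, K = ev$K,
                      seed = stage_seeds[["cv"]])
  Ms <- if (identical(config$ensemble$M, "auto")) {
    subset_size_ladder(D)
  } else {
    as.integer(config$ensemble$M)
  }
  cv_by_m <- purrr::map(Ms, function(m) {
    repeated_kfold(feats,
                   learner_subspace(m, N = config$ensemble$N,
                                    seed = stage_seeds[["ensemble"]]),
                   folds = folds)
  })
  ladder <- tibble(M = Ms,
                   accuracy = vapply(cv_by_m,
                                     function(cv) 1 - mean(cv$losses$loss),
                                     numeric(1)))
  best <- which.max(ladder$accuracy)
  cv_strong <- repeated_kfold(feats, learner_strong(ev$strong), folds = folds)
  comparison <- corrected_t_test(cv_by_m[[best]], cv_strong, df = ev$df)

  curve <- NULL
  if (isTRUE(ev$curve)) {
    curve <- compare_over_learner_counts(feats, M = ladder$M[best],
                                         N = config$ensemble$N,
                                         n_grid = ev$n_grid,
                                         strong_kind = ev$strong,
                                         ensemble_seed = stage_seeds[["ensemble"]],
                                         df = ev$df, fdr_q = ev$fdr_q,
                                         folds = folds)
  }
  structure(list(config = config,
                 stage_seeds = stage_seeds,
                 D = D,
                 ladder = ladder,
                 best_M = ladder$M[best],
                 cv_ensemble = cv_by_m[[best]],
                 cv_strong = cv_strong,
                 comparison = comparison,
                 curve = curve),
            class = "nirs_run")
}

#' Write a pipeline results bundle to disk
#'
#' Writes, under `dir`: per-fold loss tables for the best ensemble and the
#' strong learner (`losses_ensemble.csv`, `losses_strong.csv`), the ladder
#' accuracies (`ladder.csv`), the learner-count curve if present
#' (`curve.csv`), and a deterministic summary (`summary.json`) with the
#' stage seeds, feature dimensionality, best subset size, accuracies, and
#' the corrected-test fields.
#'
#' @param run A `nirs_run` bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(run, dir) {
  stopifnot(inherits(run, "nirs_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$cv_ensemble$losses,
                   file.path(dir, "losses_ensemble.csv"), row.names = FALSE)
  utils::write.csv(run$cv_strong$losses,
                   file.path(dir, "losses_strong.csv"), row.names = FALSE)
  utils::write.csv(run$ladder, file.path(dir, "ladder.csv"),
                   row.names = FALSE)
  if (!is.null(run$curve)) {
    utils::write.csv(as.data.frame(run$curve), file.path(dir, "curve.csv"),
                     row.names = FALSE)
  }
  summary <- list(schema_version = run$config$schema_version,
                  seed = run$config$seed,
                  stage_seeds = as.list(run$stage_seeds),
                  D = run$D,
                  best_M = run$best_M,
                  ensemble_accuracy = 1 - mean(run$cv_ensemble$losses$loss),
                  strong_accuracy = 1 - mean(run$cv_strong$losses$loss),
                  corrected_t = unclass(tidy(run$comparison)))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.nirs_run <- function(x, ...) {
  cat("<nirs_run> D = ", x$D, ", best M = ", x$best_M, "\n", sep = "")
  cat(sprintf("  ensemble accuracy %.3f vs %s %.3f\n",
              1 - mean(x$cv_ensemble$losses$loss),
              x$config$evaluate$strong,
              1 - mean(x$cv_strong$losses$loss)))
  cat(sprintf("  corrected t = %.3f, p = %.4g\n",
              x$comparison$t, x$comparison$p))
  invisible(x)
}
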
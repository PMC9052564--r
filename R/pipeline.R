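#' Pipeline configuration
#'
#' Bundles every stage's parameters for an end-to-end run on a synthetic
#' cohort (or a cohort directory written by [write_cohort()]).
#'
#' @param cohort a [synthetic_cohort_config()] (ignored when
#'   `cohort_directory` is given).
#' @param cohort_directory optional directory with a written cohort.
#' @param extraction an [extraction_config()].
#' @param correlation_threshold cluster cut for [cluster_features()].
#' @param variance_threshold meta-feature variance filter.
#' @param grid candidate model grid, default [default_model_grid()].
#' @param signature_size meta-features in the signature (default 5).
#' @param cv_folds cross-validation folds (default 5).
#' @param seed master seed; the cohort seed and fold seed derive from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = synthetic_cohort_config(),
                            cohort_directory = NULL,
                            extraction = extraction_config(),
                            correlation_threshold = 0.95,
                            variance_threshold = 0.3,
                            grid = default_model_grid(),
                            signature_size = 5L,
                            cv_folds = 5L,
                            seed = 1L) {
  stopifnot(correlation_threshold > 0, correlation_threshold <= 1,
            variance_threshold >= 0, signature_size >= 1L, cv_folds >= 2L)
  structure(list(cohort = cohort, cohort_directory = cohort_directory,
                 extraction = extraction,
                 correlation_threshold = correlation_threshold,
                 variance_threshold = variance_threshold, grid = grid,
                 signature_size = as.integer(signature_size),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys mirror the [pipeline_config()] arguments;
#' `cohort:` holds [synthetic_cohort_config()] fields and
#' `model_families:` restricts [default_model_grid()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- do.call(synthetic_cohort_config, y$cohort %||% list())
  grid <- if (!is.null(y$model_families))
    default_model_grid(unlist(y$model_families)) else default_model_grid()
  pipeline_config(
    cohort = cohort,
    cohort_directory = y$cohort_directory,
    correlation_threshold = y$correlation_threshold %||% 0.95,
    variance_threshold = y$variance_threshold %||% 0.3,
    grid = grid,
    signature_size = y$signature_size %||% 5L,
    cv_folds = y$cv_folds %||% 5L,
    seed = y$seed %||% 1L)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the whole pipeline end to end
#'
#' Generate (or load) the two cohorts, extract the 1150-feature table, fit
#' the reduction on the training cohort only, select the signature by
#' forward selection with fivefold cross-validation, validate the frozen
#' model on the external cohort, and return a manifest sufficient to re-run
#' the identical analysis. Deterministic given the config seed.
#'
#' @param config a [pipeline_config()].
#' @return list (`run_manifest`): config echo, selected signature summary,
#'   per-fold CV AUCs, validation AUC and ROC, stage timings.
#' @export
run_end_to_end <- function(config = pipeline_config()) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timings[[name]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  cases <- stage("cohort", {
    if (!is.null(config$cohort_directory)) read_cohort(config$cohort_directory)
    else {
      cohort_cfg <- unclass(config$cohort)
      cohort_cfg$seed <- config$seed
      generate_cohort(do.call(synthetic_cohort_config, cohort_cfg))
    }
  })
  tick("cohort")
  feats <- stage("extract", extract_cohort(cases, config$extraction))
  tick("extract")
  train <- feats[feats$cohort == "A", , drop = FALSE]
  valid <- feats[feats$cohort == "B", , drop = FALSE]
  if (nrow(train) == 0L || nrow(valid) == 0L)
    stop("stage 'split' failed: both cohorts A and B must be non-empty")
  reducer <- stage("reduce", fit_reducer(
    train, correlation_threshold = config$correlation_threshold,
    variance_threshold = config$variance_threshold))
  x_train <- stage("reduce", apply_reducer(reducer, train))
  x_valid <- stage("reduce", apply_reducer(reducer, valid))
  tick("reduce")
  signature <- stage("train", select_signature(
    x_train, train$label, grid = config$grid,
    signature_size = config$signature_size, folds = config$cv_folds,
    seed = config$seed))
  tick("train")
  report <- stage("validate", validate_external(signature, x_valid,
                                                valid$label))
  tick("validate")
  list(
    config = list(seed = config$seed,
                  correlation_threshold = config$correlation_threshold,
                  variance_threshold = config$variance_threshold,
                  signature_size = config$signature_size,
                  cv_folds = config$cv_folds,
                  cohort = if (is.null(config$cohort_directory))
                    unclass(config$cohort) else NULL,
                  cohort_directory = config$cohort_directory,
                  grid = vapply(config$grid, `[[`, character(1), "label")),
    n_train = nrow(train), n_validation = nrow(valid),
    n_features = nrow(feature_catalogue()),
    n_metafeatures = length(reducer$projector$names),
    signature = list(features = signature$features,
                     model = signature$spec$label,
                     fold_aucs = unname(signature$fold_aucs),
                     mean_cv_auc = signature$mean_cv_auc,
                     sd_cv_auc = signature$sd_cv_auc),
    validation = list(auc = report$auc, n = report$n,
                      scores = unname(report$scores)),
    reducer = reducer, signature_object = signature,
    timings = as.list(timings))
}

#' Write a run manifest as JSON
#'
#' Fitted R objects (`reducer`, `signature_object`) are dropped; everything
#' needed to replay the run (config, seeds, signature, AUCs, scores) is kept.
#' Timings are stored under `timings` so two runs of the same config can be
#' compared after removing that entry.
#'
#' @param manifest a [run_end_to_end()] result.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  keep <- manifest[setdiff(names(manifest),
                           c("reducer", "signature_object"))]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
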
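#' Pipeline configuration
#'
#' Defaults follow the study conditions the package targets: a 4:1
#' stratified train/test split, 5-fold cross-validated lasso selection with
#' the one-standard-error rule, five base learners under 10-fold
#' cross-validation, expected-rank scalarization of out-of-fold
#' probabilities, Wald `p < 0.05` for retaining base models, and tripartite
#' score cutoffs derived on the training set (fixed cutoffs, e.g. 2.24 and
#' 6.00, may be supplied instead).
#'
#' @param seed master integer seed.
#' @param test_fraction held-out fraction (default 0.2).
#' @param stratified stratify the split by risk group (default `TRUE`).
#' @param fit_scaler_on_train fit min-max statistics on the training subset
#'   only (leak-free variant) instead of on the full cohort before the
#'   split (default `FALSE`, matching the usual single-pass preprocessing
#'   of retrospective cohorts).
#' @param lasso_folds,lasso_rule lasso CV folds and penalty rule.
#' @param models base learners (see [available_learners()]).
#' @param cv_folds base-learner CV folds (default 10).
#' @param scalarization,importance see [train_base_models()].
#' @param in_sample use in-sample rather than out-of-fold meta-features.
#' @param alpha Wald threshold for independent predictors.
#' @param cutoffs `NULL` to derive from training scores, or
#'   a [risk_cutoffs()].
#' @param n_boot bootstrap resamples for the metric panel.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, test_fraction = 0.2, stratified = TRUE,
                            fit_scaler_on_train = FALSE,
                            lasso_folds = 5L, lasso_rule = "one_se",
                            models = available_learners(), cv_folds = 10L,
                            scalarization = "expected_rank",
                            importance = "native", in_sample = FALSE,
                            alpha = 0.05, cutoffs = NULL, n_boot = 200L) {
  if (!is.null(cutoffs) && !inherits(cutoffs, "risk_cutoffs")) {
    stop("cutoffs must be a risk_cutoffs object or NULL", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), test_fraction = test_fraction,
                 stratified = stratified,
                 fit_scaler_on_train = fit_scaler_on_train,
                 lasso_folds = lasso_folds, lasso_rule = lasso_rule,
                 models = models, cv_folds = cv_folds,
                 scalarization = scalarization, importance = importance,
                 in_sample = in_sample, alpha = alpha, cutoffs = cutoffs,
                 n_boot = n_boot),
            class = "pipeline_config")
}

#' Run the full nomogram pipeline
#'
#' Executes the end-to-end workflow on a labeled cohort: truncation and
#' min-max normalization; lasso feature selection; stratified 4:1 split;
#' base-learner training with out-of-fold stacking; ordinal-regression
#' selection of independent base models; model-axis nomogram; feature
#' mapping onto clinical axes and the stacked clinical-feature nomogram; a
#' reference clinical nomogram fitted directly on the selected features;
#' score cutoffs; and the evaluation panel on the held-out set.
#'
#' @param cohort a labeled [cohort_table()] on the original measurement
#'   scale, or `NULL` to simulate `n_simulate` patients from
#'   [builtin_profile()].
#' @param config a [pipeline_config()].
#' @param cap_rules truncation rules (default [default_cap_rules()]; rules
#'   for absent features are skipped).
#' @param n_simulate cohort size when simulating (default 500).
#' @param out_dir optional directory; when given, every stage artifact is
#'   written as delimited text together with a run manifest.
#' @return A `pipeline_result` list with all intermediate artifacts
#'   (`cohort`, `norm_stats`, `lasso`, `selected`, `split`, `ensemble`,
#'   `stack`, `clinic_fit`, `clinic_nomogram`, `cutoffs`, `scores`,
#'   `evaluation`).
#' @export
run_pipeline <- function(cohort = NULL, config = pipeline_config(),
                         cap_rules = default_cap_rules(),
                         n_simulate = 500L, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_stage <- function(...) message(sprintf(...))
  if (is.null(cohort)) {
    log_stage("stage simulate: n=%d, seed=%d", n_simulate, config$seed)
    cohort <- generate_cohort(builtin_profile(), n = n_simulate,
                              seed = config$seed)
  }
  if (is.null(cohort$risk) || anyNA(cohort$risk)) {
    stop("pipeline requires a fully labeled cohort", call. = FALSE)
  }

  ## stage A: preprocessing
  cohort <- apply_truncation(cohort, cap_rules, skip_missing = TRUE)
  if ("Interleukin-10" %in% feature_names(cohort)) {
    cohort <- drop_feature(cohort, "Interleukin-10")
  }
  log_stage("stage preprocess: %d patients x %d features",
            n_patients(cohort), length(feature_names(cohort)))
  if (config$fit_scaler_on_train) {
    split0 <- split_train_test(cohort, config$test_fraction,
                               seed = config$seed,
                               stratified = config$stratified)
    nrm <- min_max_normalize(split0$train)
    train_full <- nrm$table
    test_full <- min_max_normalize(split0$test, nrm$stats)$table
    norm_stats <- nrm$stats
    ## lasso on training data only in the leak-free variant
    lasso <- fit_lasso_path(train_full, folds = config$lasso_folds,
                            seed = config$seed)
  } else {
    nrm <- min_max_normalize(cohort)
    norm_stats <- nrm$stats
    lasso <- fit_lasso_path(nrm$table, folds = config$lasso_folds,
                            seed = config$seed)
    split0 <- split_train_test(nrm$table, config$test_fraction,
                               seed = config$seed,
                               stratified = config$stratified)
    train_full <- split0$train
    test_full <- split0$test
  }

  ## stage B: feature selection + split
  selected <- select_features(lasso, rule = config$lasso_rule)
  if (length(selected) < 2L) {
    warning("lasso kept fewer than 2 features; falling back to rule 'min'",
            call. = FALSE)
    selected <- select_features(lasso, rule = "min")
  }
  log_stage("stage select: %d features (%s)", length(selected),
            paste(selected, collapse = ", "))
  keep_cols <- function(tb) {
    cohort_table(tb$features[, selected, drop = FALSE], risk = tb$risk,
                 patient_id = tb$patient_id)
  }
  train <- keep_cols(train_full)
  test <- keep_cols(test_full)
  log_stage("stage split: train %d / test %d", n_patients(train),
            n_patients(test))

  ## stage C: base learners, stacking, nomograms
  ensemble <- train_base_models(train, models = config$models,
                                folds = config$cv_folds, seed = config$seed,
                                scalarization = config$scalarization,
                                importance = config$importance,
                                in_sample = config$in_sample)
  stack <- build_stacked_nomogram(ensemble, alpha = config$alpha)
  log_stage("stage stack: kept models %s",
            paste(stack$kept_models, collapse = ", "))
  clinic_sel <- multivariate_select(train$features, train$risk,
                                    alpha = config$alpha)
  clinic_nom <- build_nomogram(clinic_sel$fit,
                               axis_ranges(train, clinic_sel$kept))

  ## scores: clinic-ML nomogram operates on FMA-mapped meta-features
  meta_test <- predict(ensemble, test)[, stack$kept_models, drop = FALSE]
  cf_test <- fma_convert(FI = stack$fma$FI, MV = meta_test)$CF
  cf_test <- cf_test[, stack$clinic_ml_fit$covariate_names, drop = FALSE]
  score_train <- predict(stack$clinic_ml_fit, stack$fma$CF, type = "lp")
  score_test <- predict(stack$clinic_ml_fit, cf_test, type = "lp")
  cutoffs <- config$cutoffs %||% derive_cutoffs(score_train, train$risk)
  log_stage("stage cutoffs: c1=%.3f c2=%.3f", cutoffs$c1, cutoffs$c2)

  ## stage D: evaluation on the held-out set
  prob_cml <- predict(stack$clinic_ml_fit, cf_test, type = "probs")
  prob_clinic <- predict(clinic_sel$fit,
                         test$features[, clinic_sel$kept, drop = FALSE],
                         type = "probs")
  prob_xgb <- if ("xgb" %in% config$models) {
    predict(ensemble, test, type = "prob")$xgb
  } else NULL
  evaluation <- list(
    clinic_ml = metric_panel(test$risk, prob_cml, n_boot = config$n_boot,
                             seed = config$seed),
    clinic = metric_panel(test$risk, prob_clinic, n_boot = config$n_boot,
                          seed = config$seed),
    xgb = if (!is.null(prob_xgb))
      metric_panel(test$risk, prob_xgb, n_boot = config$n_boot,
                   seed = config$seed),
    dca = decision_curve(test$risk, 1 - prob_cml[, 1]),
    delong_clinic_vs_cml = delong_test(
      as.integer(test$risk >= 2L),
      1 - prob_cml[, 1],
      1 - prob_clinic[, 1])
  )
  result <- structure(
    list(config = config, cohort = cohort, norm_stats = norm_stats,
         lasso = lasso, selected = selected,
         split = list(train = train, test = test), ensemble = ensemble,
         stack = stack, clinic_fit = clinic_sel$fit,
         clinic_selection = clinic_sel, clinic_nomogram = clinic_nom,
         cutoffs = cutoffs,
         scores = list(train = score_train, test = score_test,
                       train_class = classify(score_train, cutoffs),
                       test_class = classify(score_test, cutoffs)),
         evaluation = evaluation),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

## persist diffable delimited-text artifacts plus a manifest
write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  write_cohort(result$split$train, file.path(out_dir, "train.csv"))
  write_cohort(result$split$test, file.path(out_dir, "test.csv"))
  tsv(data.frame(feature = result$selected), "selected_features.tsv")
  tsv(data.frame(lambda = result$lasso$lambda_grid,
                 cv_mse = result$lasso$cv_mse,
                 cv_se = result$lasso$cv_se), "lasso_cv.tsv")
  tsv(cbind(data.frame(feature = rownames(result$ensemble$importances)),
            as.data.frame(result$ensemble$importances)), "importances.tsv")
  tsv(as.data.frame(result$ensemble$meta_features), "meta_features.tsv")
  tsv(result$stack$selection$table, "stacking_regression.tsv")
  tsv(result$clinic_selection$table, "clinic_regression.tsv")
  write_nomogram(result$stack$clinic_ml_nomogram,
                 file.path(out_dir, "clinic_ml_nomogram.tsv"))
  write_nomogram(result$clinic_nomogram,
                 file.path(out_dir, "clinic_nomogram.tsv"))
  for (nm in c("clinic_ml", "clinic", "xgb")) {
    if (!is.null(result$evaluation[[nm]])) {
      tsv(result$evaluation[[nm]], paste0("metrics_", nm, ".tsv"))
    }
  }
  tsv(result$evaluation$dca, "dca.tsv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("nomostack")),
    seed = result$config$seed,
    config = result$config[setdiff(names(result$config), "cutoffs")],
    cutoffs = list(c1 = result$cutoffs$c1, c2 = result$cutoffs$c2),
    n_train = n_patients(result$split$train),
    n_test = n_patients(result$split$test),
    selected_features = result$selected,
    kept_models = result$stack$kept_models)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  train/test:", n_patients(x$split$train), "/",
      n_patients(x$split$test), "\n")
  cat("  selected features:", paste(x$selected, collapse = ", "), "\n")
  cat("  kept models:", paste(x$stack$kept_models, collapse = ", "), "\n")
  cat(sprintf("  cutoffs: %.3f / %.3f\n", x$cutoffs$c1, x$cutoffs$c2))
  cat("  test-set metrics (clinic-ML nomogram):\n")
  print(x$evaluation$clinic_ml, digits = 3)
  invisible(x)
}
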
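#' Macro one-vs-rest confusion metrics
#'
#' Per-class one-vs-rest sensitivity (recall), specificity and F1 for a
#' three-level ordinal classification, macro-averaged over the classes
#' present in `y` (absent classes contribute nothing and the average is
#' renormalized).
#'
#' @param y true ordinal labels 1/2/3.
#' @param yhat predicted labels of the same length.
#' @return List with scalars `sensitivity`, `specificity`, `f1` and the
#'   `per_class` data frame.
#' @export
confusion_metrics <- function(y, yhat) {
  y <- as.integer(y); yhat <- as.integer(yhat)
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  present <- sort(unique(y))
  rows <- lapply(present, function(k) {
    tp <- sum(y == k & yhat == k)
    fn <- sum(y == k & yhat != k)
    fp <- sum(y != k & yhat == k)
    tn <- sum(y != k & yhat != k)
    sens <- tp / (tp + fn)
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
    data.frame(class = k, sensitivity = sens, specificity = spec, f1 = f1)
  })
  per_class <- do.call(rbind, rows)
  list(sensitivity = mean(per_class$sensitivity),
       specificity = mean(per_class$specificity, na.rm = TRUE),
       f1 = mean(per_class$f1),
       per_class = per_class)
}

#' Two-sample AUC by the Mann-Whitney statistic
#'
#' Probability that a random event score exceeds a random non-event score,
#' with ties counted one half (midrank correction).
#'
#' @param pos scores of the positive (event) group.
#' @param neg scores of the negative group.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(pos, neg) {
  n1 <- length(pos); n0 <- length(neg)
  if (n1 == 0L || n0 == 0L) stop("both groups must be non-empty",
                                 call. = FALSE)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Multiclass AUC
#'
#' `"macro_ovr"`: unweighted mean of the three one-vs-rest AUCs, each
#' computed from that class's predicted probability column; classes absent
#' from `y` are skipped with a warning.  `"ordinal_score"`: AUC of a scalar
#' score for the low vs \{intermediate, high\} dichotomization (the same
#' dichotomization decision-curve analysis uses).
#'
#' @param y ordinal labels 1/2/3.
#' @param prob patients-by-3 probability matrix (`macro_ovr`) or a numeric
#'   score vector (`ordinal_score`).
#' @param scheme `"macro_ovr"` or `"ordinal_score"`.
#' @return AUC in `[0, 1]`.
#' @export
multiclass_auc <- function(y, prob, scheme = c("macro_ovr", "ordinal_score")) {
  scheme <- match.arg(scheme)
  y <- as.integer(y)
  if (scheme == "ordinal_score") {
    s <- as.numeric(prob)
    return(auc_mann_whitney(s[y >= 2], s[y == 1]))
  }
  prob <- as.matrix(prob)
  if (ncol(prob) != 3L) stop("macro_ovr needs a 3-column probability matrix",
                             call. = FALSE)
  aucs <- vapply(1:3, function(k) {
    if (!any(y == k) || all(y == k)) return(NA_real_)
    auc_mann_whitney(prob[y == k, k], prob[y != k, k])
  }, numeric(1))
  if (anyNA(aucs)) warning("class(es) absent; macro average over present ",
                           "classes", call. = FALSE)
  mean(aucs, na.rm = TRUE)
}

## DeLong structural components: V10 (per case) and V01 (per control)
delong_components <- function(pos, neg) {
  psi <- function(x, yv) (sum(yv < x) + 0.5 * sum(yv == x)) / length(yv)
  list(v10 = vapply(pos, psi, numeric(1), yv = neg),
       v01 = vapply(neg, function(yv) {
         (sum(pos > yv) + 0.5 * sum(pos == yv)) / length(pos)
       }, numeric(1)))
}

#' DeLong test for two correlated AUCs
#'
#' Nonparametric comparison of the AUCs of two scores measured on the same
#' patients, using DeLong's structural-components estimator of
#' `var(AUC_a - AUC_b)` (variances plus covariance of the paired placement
#' values) and a two-sided normal reference for `z`.
#'
#' @param y_binary binary labels (0/1, logical, or a factor with the event
#'   as the higher level).
#' @param score_a,score_b paired score vectors.
#' @return List with `auc_a`, `auc_b`, `var_diff`, `z`, `p`.
#' @export
delong_test <- function(y_binary, score_a, score_b) {
  y <- as.integer(as.factor(y_binary)) - 1L
  if (!all(y %in% 0:1) || !any(y == 1) || !any(y == 0)) {
    stop("y_binary must contain both classes", call. = FALSE)
  }
  if (length(score_a) != length(y) || length(score_b) != length(y)) {
    stop("scores and labels must be paired", call. = FALSE)
  }
  ca <- delong_components(score_a[y == 1], score_a[y == 0])
  cb <- delong_components(score_b[y == 1], score_b[y == 0])
  auc_a <- mean(ca$v10); auc_b <- mean(cb$v10)
  m <- sum(y == 1); n <- sum(y == 0)
  s10 <- stats::var(cbind(ca$v10, cb$v10))
  s01 <- stats::var(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (identical(score_a, score_b) || isTRUE(all.equal(score_a, score_b,
                                                      tolerance = 0))) {
    return(list(auc_a = auc_a, auc_b = auc_b, var_diff = 0, z = 0, p = 1))
  }
  if (var_diff <= 0) stop("degenerate DeLong variance (scores tied)",
                          call. = FALSE)
  z <- (auc_a - auc_b) / sqrt(var_diff)
  list(auc_a = auc_a, auc_b = auc_b, var_diff = var_diff, z = z,
       p = 2 * pnorm(-abs(z)))
}

#' Calibration curve with bootstrap optimism correction
#'
#' Apparent curve: patients are grouped into equal-count bins of predicted
#' event probability; each bin contributes (mean predicted probability,
#' observed event fraction).  Bias-corrected curve: the standard bootstrap
#' optimism recipe — refit on a resample, evaluate the resample-fitted
#' model's bin-wise calibration on both the resample and the original data,
#' average the difference over `n_boot` resamples, and subtract it from the
#' apparent curve.
#'
#' @param predict_fn function(cohort) -> predicted event probabilities, from
#'   the model under assessment.
#' @param refit_fn function(cohort) -> a new `predict_fn` fitted to that
#'   cohort (the refit closure used on resamples).
#' @param data a labeled `cohort_table`.
#' @param target event definition: `"p_ge_intermediate"` (default;
#'   intermediate-or-high vs low) or `"p_high"`.
#' @param bins number of equal-count bins (default 10; must not exceed
#'   `n/2`).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return Data frame with per-bin `pred` (mean predicted), `obs_apparent`
#'   and `obs_corrected`.
#' @export
calibration_curve <- function(predict_fn, refit_fn, data,
                              target = c("p_ge_intermediate", "p_high"),
                              bins = 10L, n_boot = 1000L, seed = 1L) {
  target <- match.arg(target)
  n <- n_patients(data)
  if (bins > n / 2) stop("bins must not exceed n/2", call. = FALSE)
  event <- if (target == "p_high") as.integer(data$risk == 3L) else
    as.integer(data$risk >= 2L)
  p_app <- predict_fn(data)
  edges <- stats::quantile(p_app, seq(0, 1, length.out = bins + 1L),
                           names = FALSE)
  edges[1] <- -Inf; edges[length(edges)] <- Inf
  edges <- unique(edges)
  bin_of <- function(p) cut(p, edges, labels = FALSE)
  n_bins <- length(edges) - 1L
  curve_on <- function(p, ev) {
    b <- bin_of(p)
    pred <- vapply(seq_len(n_bins), function(k) {
      if (any(b == k)) mean(p[b == k]) else NA_real_
    }, numeric(1))
    obs <- vapply(seq_len(n_bins), function(k) {
      if (any(b == k)) mean(ev[b == k]) else NA_real_
    }, numeric(1))
    data.frame(pred = pred, obs = obs)
  }
  app <- curve_on(p_app, event)
  optimism <- matrix(0, nrow(app), 1)
  if (n_boot > 0L) {
    opt_sum <- rep(0, nrow(app))
    opt_n <- rep(0, nrow(app))
    with_seed(seed, {
      for (b in seq_len(n_boot)) {
        idx <- sample.int(n, n, replace = TRUE)
        boot_w <- subset_rows_dup(data, idx)
        fit_b <- tryCatch(refit_fn(boot_w), error = function(e) NULL)
        if (is.null(fit_b)) next
        ev_b <- if (target == "p_high") as.integer(boot_w$risk == 3L) else
          as.integer(boot_w$risk >= 2L)
        cb_boot <- curve_on(fit_b(boot_w), ev_b)
        cb_orig <- curve_on(fit_b(data), event)
        ok <- !is.na(cb_boot$obs) & !is.na(cb_orig$obs)
        opt_sum[ok] <- opt_sum[ok] + (cb_boot$obs - cb_orig$obs)[ok]
        opt_n[ok] <- opt_n[ok] + 1
      }
    })
    optimism <- ifelse(opt_n > 0, opt_sum / opt_n, 0)
  }
  data.frame(pred = app$pred, obs_apparent = app$obs,
             obs_corrected = app$obs - optimism, row.names = NULL)
}

## resample that tolerates duplicated rows (fresh ids)
subset_rows_dup <- function(table, idx) {
  cohort_table(table$features[idx, , drop = FALSE],
               risk = if (is.null(table$risk)) NULL else table$risk[idx],
               feature_meta = table$feature_meta)
}

#' Decision-curve analysis
#'
#' Net benefit of calling patients positive when their predicted event
#' probability reaches a threshold `t`:
#' `NB(t) = TP/n - FP/n * t/(1 - t)`, compared with the treat-all policy
#' `prevalence - (1 - prevalence) * t/(1 - t)` and treat-none (0).  The
#' event is the \{intermediate, high\} dichotomization of the ordinal
#' outcome unless binary labels are supplied directly.
#'
#' @param y ordinal labels 1/2/3 (dichotomized as `y >= 2`) or binary 0/1.
#' @param p_event predicted event probabilities in `[0, 1]`.
#' @param thresholds threshold grid in (0, 1); default 0.01..0.80 by 0.01.
#' @return A `decision_curve` data frame with columns `threshold`,
#'   `net_benefit_model`, `net_benefit_all`, `net_benefit_none`.
#' @export
decision_curve <- function(y, p_event, thresholds = seq(0.01, 0.80, 0.01)) {
  y <- as.integer(y)
  event <- if (all(y %in% 0:1)) y else as.integer(y >= 2L)
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (any(p_event < 0 | p_event > 1)) {
    stop("p_event must lie in [0, 1]", call. = FALSE)
  }
  n <- length(event)
  prev <- mean(event)
  nb <- vapply(thresholds, function(t) {
    pos <- p_event >= t
    (sum(pos & event == 1L) - sum(pos & event == 0L) * t / (1 - t)) / n
  }, numeric(1))
  structure(data.frame(threshold = thresholds,
                       net_benefit_model = nb,
                       net_benefit_all = prev - (1 - prev) *
                         thresholds / (1 - thresholds),
                       net_benefit_none = 0),
            class = c("decision_curve", "data.frame"))
}

#' Percentile bootstrap confidence interval for a metric
#'
#' Class-stratified resampling: indices are resampled within each level of
#' `strata` so every resample keeps the class composition.  The interval is
#' the 2.5/97.5 percentile of the resampled metric.
#'
#' @param metric_fn function(indices) -> scalar metric, where `indices`
#'   index the original observations.
#' @param n number of observations.
#' @param strata optional vector of length `n` defining resampling strata
#'   (e.g. the true labels).
#' @param n_boot resamples (default 1000); `n_boot = 1` degenerates to a
#'   point interval with a warning.
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return List with `point`, `ci_low`, `ci_high`, `n_boot`, `n_failed`.
#' @export
bootstrap_ci <- function(metric_fn, n, strata = NULL, n_boot = 1000L,
                         seed = 1L, conf = 0.95) {
  point <- metric_fn(seq_len(n))
  if (n_boot < 2L) {
    warning("n_boot < 2: degenerate interval", call. = FALSE)
    return(list(point = point, ci_low = point, ci_high = point,
                n_boot = n_boot, n_failed = 0L))
  }
  groups <- if (is.null(strata)) list(seq_len(n)) else
    split(seq_len(n), strata)
  vals <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(groups, function(g) {
        g[sample.int(length(g), length(g), replace = TRUE)]
      }), use.names = FALSE)
      tryCatch(metric_fn(idx), error = function(e) NA_real_)
    }, numeric(1))
  })
  n_failed <- sum(is.na(vals))
  if (n_failed > 0.05 * n_boot) {
    stop("metric failed on more than 5% of resamples", call. = FALSE)
  }
  q <- stats::quantile(vals, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       na.rm = TRUE, names = FALSE)
  list(point = point, ci_low = q[1], ci_high = q[2], n_boot = n_boot,
       n_failed = n_failed)
}

#' Metric panel for an ordinal classifier
#'
#' Computes macro sensitivity/specificity/F1 and macro one-vs-rest AUC with
#' stratified percentile-bootstrap confidence intervals — the standard
#' performance table for a three-level risk model.
#'
#' @param y ordinal labels.
#' @param prob patients-by-3 probability matrix.
#' @param yhat optional predicted labels (defaults to the max-probability
#'   class).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return Data frame with one row per metric: point estimate and CI.
#' @export
metric_panel <- function(y, prob, yhat = NULL, n_boot = 1000L, seed = 1L) {
  y <- as.integer(y)
  prob <- as.matrix(prob)
  yhat <- yhat %||% max.col(prob)
  metrics <- list(
    sensitivity = function(i) confusion_metrics(y[i], yhat[i])$sensitivity,
    specificity = function(i) confusion_metrics(y[i], yhat[i])$specificity,
    f1 = function(i) confusion_metrics(y[i], yhat[i])$f1,
    auc = function(i) multiclass_auc(y[i], prob[i, , drop = FALSE],
                                     "macro_ovr")
  )
  rows <- lapply(names(metrics), function(nm) {
    ci <- bootstrap_ci(metrics[[nm]], length(y), strata = y,
                       n_boot = n_boot, seed = seed)
    data.frame(metric = nm, point = ci$point, ci_low = ci$ci_low,
               ci_high = ci$ci_high, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
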
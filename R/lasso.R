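#' L1-penalized feature selection for an ordinal outcome
#'
#' Codes the ordinal outcome numerically (1/2/3) and fits a squared-error
#' lasso path over a log-spaced penalty grid, with k-fold cross-validated
#' mean-squared error used to choose the penalty.  Both the CV-minimizing
#' penalty (`lambda_min`) and the parsimonious one-standard-error penalty
#' (`lambda_1se`) are recorded; [select_features()] extracts the active set
#' at either.  Solving the penalized least-squares path is delegated to
#' coordinate descent via \pkg{glmnet}.
#'
#' @param table labeled, normalized [cohort_table()].
#' @param folds number of CV folds (default 5).
#' @param seed integer seed controlling fold assignment.
#' @param grid_size number of penalty values on the grid (default 100).
#' @param lambda_min_ratio ratio of the smallest to the largest grid
#'   penalty; the default spans four decades below the smallest
#'   all-zero-coefficient penalty.
#' @return A `lasso_result` with components `lambda_grid` (decreasing),
#'   `coef_path` (feature-by-lambda matrix, no intercept), `intercepts`,
#'   `cv_mse`/`cv_se`, `lambda_min`, `lambda_1se`, `foldid`, and the
#'   training design (`x`, `y`) for diagnostics.
#' @export
fit_lasso_path <- function(table, folds = 5L, seed = 1L, grid_size = 100L,
                           lambda_min_ratio = 1e-4) {
  if (is.null(table$risk) || anyNA(table$risk)) {
    stop("lasso selection requires complete risk labels", call. = FALSE)
  }
  x <- table$features
  y <- as.numeric(table$risk)
  if (nrow(x) <= folds) stop("fewer rows than CV folds", call. = FALSE)
  foldid <- stratified_folds(table$risk, folds, seed)
  if (stats::var(y) == 0) {
    ## constant outcome: the whole path is zero at any penalty
    warning("constant outcome: all lasso coefficients are zero",
            call. = FALSE)
    lambda <- 10^seq(0, -4, length.out = grid_size)
    beta <- matrix(0, ncol(x), grid_size,
                   dimnames = list(colnames(x), NULL))
    return(structure(list(lambda_grid = lambda, coef_path = beta,
                          intercepts = rep(mean(y), grid_size),
                          cv_mse = rep(0, grid_size),
                          cv_se = rep(0, grid_size),
                          lambda_min = lambda[1], lambda_1se = lambda[1],
                          foldid = foldid, feature_names = colnames(x),
                          x = x, y = y),
                     class = "lasso_result"))
  }
  ## features arrive min-max normalized, so no internal re-standardization
  fit <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                        nlambda = grid_size,
                        lambda.min.ratio = lambda_min_ratio,
                        standardize = FALSE, thresh = 1e-12)
  cv <- glmnet::cv.glmnet(x, y, family = "gaussian", alpha = 1,
                          lambda = fit$lambda, foldid = foldid,
                          standardize = FALSE, thresh = 1e-12,
                          type.measure = "mse")
  beta <- as.matrix(fit$beta)
  colnames(beta) <- NULL
  structure(list(lambda_grid = fit$lambda,
                 coef_path = beta,
                 intercepts = as.numeric(fit$a0),
                 cv_mse = cv$cvm, cv_se = cv$cvsd,
                 lambda_min = cv$lambda.min, lambda_1se = cv$lambda.1se,
                 foldid = foldid, feature_names = colnames(x),
                 x = x, y = y),
            class = "lasso_result")
}

#' @export
print.lasso_result <- function(x, ...) {
  cat(sprintf("<lasso_result> %d features, %d lambdas; lambda_min=%.4g (%d kept), lambda_1se=%.4g (%d kept)\n",
              nrow(x$coef_path), length(x$lambda_grid),
              x$lambda_min, length(select_features(x, "min")),
              x$lambda_1se, length(select_features(x, "one_se"))))
  invisible(x)
}

## deterministic label-stratified fold assignment
stratified_folds <- function(labels, folds, seed) {
  with_seed(seed, {
    foldid <- integer(length(labels))
    for (g in unique(labels)) {
      ix <- which(labels == g)
      foldid[ix] <- sample(rep_len(seq_len(folds), length(ix)))
    }
    foldid
  })
}

#' Features selected at a penalty rule
#'
#' @param result a `lasso_result`.
#' @param rule `"one_se"` (default: largest penalty with CV error within one
#'   standard error of the minimum — the parsimonious choice) or `"min"`
#'   (CV-error-minimizing penalty).
#' @param tol coefficients with absolute value at or below `tol` count as
#'   zero.
#' @return Character vector of selected feature names, in input-column
#'   order; a warning (not an error) is raised when the selection is empty.
#' @export
select_features <- function(result, rule = c("one_se", "min"), tol = 1e-10) {
  rule <- match.arg(rule)
  lambda <- switch(rule, one_se = result$lambda_1se, min = result$lambda_min)
  j <- which.min(abs(result$lambda_grid - lambda))
  keep <- abs(result$coef_path[, j]) > tol
  out <- result$feature_names[keep]
  if (length(out) == 0L) {
    warning("lasso selected no features at rule '", rule, "'", call. = FALSE)
  }
  out
}

#' Karush-Kuhn-Tucker residuals of a lasso path
#'
#' Diagnostic used to verify path optimality: for the penalized objective
#' `(1/2n) * RSS + lambda * ||beta||_1`, a solution must satisfy
#' `|x_j'(y - yhat)/n| <= lambda` for inactive features and
#' `x_j'(y - yhat)/n = lambda * sign(beta_j)` for active ones.  Returns, per
#' grid point, the largest violation of these conditions.
#'
#' @param result a `lasso_result`.
#' @return Numeric vector of maximal KKT violations, one per lambda.
#' @export
lasso_kkt_violation <- function(result) {
  x <- result$x
  y <- result$y
  n <- nrow(x)
  vapply(seq_along(result$lambda_grid), function(j) {
    lam <- result$lambda_grid[j]
    b <- result$coef_path[, j]
    r <- y - result$intercepts[j] - drop(x %*% b)
    g <- drop(crossprod(x, r)) / n
    active <- b != 0
    v_inactive <- if (any(!active)) max(pmax(abs(g[!active]) - lam, 0)) else 0
    v_active <- if (any(active)) max(abs(g[active] - lam * sign(b[active]))) else 0
    ## intercept optimality: mean residual is zero
    max(v_inactive, v_active, abs(mean(r)))
  }, numeric(1))
}
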
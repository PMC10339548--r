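## ---------------------------------------------------------------------------
## Proportional-odds (cumulative-logit) ordinal logistic regression
##
## Model: P(Y <= k | x) = plogis(theta_k - x'beta), k = 1..K-1, with
## strictly increasing thresholds theta and slopes shared across levels, so
## positive beta means higher risk.  Fitted by maximum likelihood with an
## analytic gradient; thresholds are kept ordered through the monotone
## reparameterization theta_k = theta_1 + sum_{j<=k} exp(delta_j).
## ---------------------------------------------------------------------------

## raw parameter vector: c(beta (p), theta_1, delta_2..delta_{K-1})
olr_unpack <- function(par, p, K) {
  beta <- par[seq_len(p)]
  t1 <- par[p + 1L]
  theta <- if (K > 2L) t1 + c(0, cumsum(exp(par[(p + 2L):(p + K - 1L)]))) else t1
  list(beta = beta, theta = theta)
}

## negative log-likelihood and gradient in terms of (beta, theta) directly
olr_nll_theta <- function(beta, theta, X, y, K, ridge = 0) {
  eta <- drop(X %*% beta)
  Fmat <- cbind(0, plogis(outer(-eta, theta, `+`)), 1)   # F_0..F_K per row
  pr <- Fmat[cbind(seq_along(y), y + 1L)] - Fmat[cbind(seq_along(y), y)]
  -sum(log(pmax(pr, 1e-300))) + ridge * sum(beta^2) / 2
}

olr_grad_theta <- function(beta, theta, X, y, K, ridge = 0) {
  eta <- drop(X %*% beta)
  theta_ext <- c(theta, Inf)            # theta_K = +Inf
  Fy <- plogis(theta_ext[y] - eta)      # F_{y}
  Fy1 <- ifelse(y > 1L, plogis(theta_ext[pmax(y - 1L, 1L)] - eta), 0)
  pr <- pmax(Fy - Fy1, 1e-300)
  fy <- Fy * (1 - Fy)     # logistic densities at the two cut points
  fy1 <- Fy1 * (1 - Fy1)
  ## d logp / d eta = -(f_y - f_{y-1}) / p
  dl_deta <- -(fy - fy1) / pr
  g_beta <- -unname(drop(crossprod(X, dl_deta))) + ridge * beta
  g_theta <- numeric(K - 1L)
  for (k in seq_len(K - 1L)) {
    g_theta[k] <- -sum(ifelse(y == k, fy / pr, 0) -
                       ifelse(y == k + 1L, fy1 / pr, 0))
  }
  c(g_beta, g_theta)
}

#' Fit a proportional-odds ordinal logistic regression
#'
#' Maximizes the cumulative-logit log-likelihood
#' `sum(log(plogis(theta_y - x'beta) - plogis(theta_{y-1} - x'beta)))`
#' (with `theta_0 = -Inf`, `theta_K = +Inf`) by quasi-Newton (BFGS) from a
#' zero start, using the analytic gradient.  The parameter covariance is the
#' inverse observed information; when the design is rank-deficient the
#' covariance falls back to a pseudo-inverse with a warning (linear
#' predictors remain well defined, individual coefficients are not).  An
#' optional ridge penalty `ridge/2 * ||beta||^2` is available for
#' identifiability on deliberately collinear designs.
#'
#' @param X numeric matrix (patients x covariates) with column names.
#' @param y integer ordinal labels `1..K` (all levels present).
#' @param ridge nonnegative L2 penalty on `beta` (default 0: plain MLE).
#' @param maxit,grad_tol optimizer controls: iteration cap and convergence
#'   threshold on the gradient infinity norm.
#' @return An `olr_fit` with `beta`, ordered `theta`, `cov` (covariance of
#'   `c(beta, theta)`), `loglik`, `se`, `covariate_names`, `n`,
#'   `convergence` diagnostics.
#' @export
fit_olr <- function(X, y, ridge = 0, maxit = 500L, grad_tol = 1e-6) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.integer(y)
  K <- max(y)
  if (K < 2L || !all(seq_len(K) %in% y)) {
    stop("all ordinal levels 1..K (K >= 2) must be present in y",
         call. = FALSE)
  }
  if (nrow(X) != length(y)) stop("X and y sizes differ", call. = FALSE)
  consts <- apply(X, 2, function(c) max(c) == min(c))
  if (any(consts) && ridge == 0) {
    stop("constant covariate(s): ",
         paste(colnames(X)[consts], collapse = ", "), call. = FALSE)
  }
  p <- ncol(X)
  npar <- p + K - 1L
  fn <- function(par) {
    u <- olr_unpack(par, p, K)
    olr_nll_theta(u$beta, u$theta, X, y, K, ridge)
  }
  gr <- function(par) {
    u <- olr_unpack(par, p, K)
    g <- olr_grad_theta(u$beta, u$theta, X, y, K, ridge)
    ## chain rule through the monotone threshold reparameterization
    gt <- g[(p + 1L):npar]
    out <- numeric(npar)
    out[seq_len(p)] <- g[seq_len(p)]
    out[p + 1L] <- sum(gt)
    if (K > 2L) {
      for (j in 2L:(K - 1L)) {
        out[p + j] <- exp(par[p + j]) * sum(gt[j:(K - 1L)])
      }
    }
    out
  }
  start <- rep(0, npar)
  opt <- stats::optim(start, fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-14))
  u <- olr_unpack(opt$par, p, K)
  ## Newton polish in the (beta, theta) parameterization, using the
  ## observed information (central finite differences of the analytic
  ## gradient), until the gradient infinity norm meets tolerance
  grad_bt <- function(v) {
    olr_grad_theta(v[seq_len(p)], v[(p + 1L):npar], X, y, K, ridge)
  }
  nll_bt <- function(v) {
    olr_nll_theta(v[seq_len(p)], v[(p + 1L):npar], X, y, K, ridge)
  }
  fd_hessian <- function(v) {
    H <- matrix(0, npar, npar)
    h <- 1e-5 * pmax(abs(v), 1)
    for (j in seq_len(npar)) {
      e <- numeric(npar); e[j] <- h[j]
      H[, j] <- (grad_bt(v + e) - grad_bt(v - e)) / (2 * h[j])
    }
    (H + t(H)) / 2
  }
  par_bt <- c(u$beta, u$theta)
  H <- fd_hessian(par_bt)
  for (it in 1:25) {
    g <- grad_bt(par_bt)
    if (max(abs(g)) < grad_tol / 10) break
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    cand <- par_bt - step
    ## backtrack if the step overshoots or breaks threshold ordering
    s <- 1
    while (s > 1e-4 &&
           (any(diff(cand[(p + 1L):npar]) <= 0) && K > 2L ||
            !is.finite(nll_bt(cand)) || nll_bt(cand) > nll_bt(par_bt) + 1e-9)) {
      s <- s / 2
      cand <- par_bt - s * step
    }
    if (max(abs(cand - par_bt)) == 0) break
    par_bt <- cand
    H <- fd_hessian(par_bt)
  }
  u <- list(beta = par_bt[seq_len(p)], theta = par_bt[(p + 1L):npar])
  if (any(!is.finite(par_bt))) {
    worst <- colnames(X)[which.max(abs(u$beta))]
    stop("coefficient divergence (possible separation) on covariate: ",
         worst, call. = FALSE)
  }
  grad_norm <- max(abs(grad_bt(par_bt)))
  if (grad_norm >= grad_tol) {
    warning(sprintf("OLR gradient norm %.2e above tolerance %.0e",
                    grad_norm, grad_tol), call. = FALSE)
  }
  cov <- tryCatch(solve(H), error = function(e) {
    warning("singular information matrix; covariance from pseudo-inverse",
            call. = FALSE)
    MASS::ginv(H)
  })
  nm <- c(colnames(X), paste0("theta_", seq_len(K - 1L)))
  dimnames(cov) <- list(nm, nm)
  ## separation: a coefficient that is huge on the standardized scale yet
  ## carries no Wald information (SE of the same order or larger)
  if (ridge == 0) {
    sds <- apply(X, 2, stats::sd)
    se_beta <- sqrt(pmax(diag(cov)[seq_len(p)], 0))
    std_beta <- abs(u$beta) * sds
    suspect <- is.finite(std_beta) & std_beta > 10 &
      (!is.finite(se_beta) | se_beta == 0 |
         abs(u$beta) / pmax(se_beta, 1e-300) < 1.96)
    if (any(suspect)) {
      stop("coefficient divergence (possible separation) on covariate: ",
           colnames(X)[which(suspect)[1]], call. = FALSE)
    }
  }
  structure(list(beta = setNames(u$beta, colnames(X)),
                 theta = u$theta, cov = cov,
                 se = setNames(sqrt(pmax(diag(cov), 0)), nm),
                 loglik = -nll_bt(par_bt), n = length(y), K = K,
                 covariate_names = colnames(X), ridge = ridge,
                 grad_norm = grad_norm, convergence = opt$convergence),
            class = "olr_fit")
}

#' @export
print.olr_fit <- function(x, ...) {
  cat(sprintf("<olr_fit> n=%d, K=%d, loglik=%.3f\n", x$n, x$K, x$loglik))
  print(round(rbind(beta = x$beta), 4))
  cat("theta:", paste(round(x$theta, 4), collapse = " < "), "\n")
  invisible(x)
}

#' Predictions from a proportional-odds fit
#'
#' @param object an `olr_fit`.
#' @param newdata numeric matrix with the fitted covariate columns.
#' @param type `"probs"` (class-probability matrix), `"class"` (most
#'   probable level) or `"lp"` (linear predictor `x'beta`).
#' @param ... unused.
#' @return As selected by `type`.
#' @export
predict.olr_fit <- function(object, newdata, type = c("probs", "class", "lp"),
                            ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  X <- X[, object$covariate_names, drop = FALSE]
  eta <- drop(X %*% object$beta)
  if (type == "lp") return(eta)
  K <- object$K
  Fmat <- cbind(plogis(outer(-eta, object$theta, `+`)), 1)
  probs <- cbind(Fmat[, 1, drop = FALSE],
                 Fmat[, -1, drop = FALSE] - Fmat[, -K, drop = FALSE])
  colnames(probs) <- as.character(seq_len(K))
  if (type == "probs") probs else max.col(probs)
}

#' Wald odds-ratio table for a fitted OLR
#'
#' One row per covariate: `OR = exp(beta)`, 95 percent Wald interval
#' `exp(beta +/- 1.96 se)` and the two-sided Wald p-value.  ORs are on the
#' scale of the covariates as supplied to the fit.
#'
#' @param fit an `olr_fit`.
#' @return Data frame with columns `name`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
or_table <- function(fit) {
  p <- length(fit$beta)
  se <- fit$se[seq_len(p)]
  z <- fit$beta / se
  data.frame(name = fit$covariate_names,
             odds_ratio = exp(fit$beta),
             ci_low = exp(fit$beta - 1.959964 * se),
             ci_high = exp(fit$beta + 1.959964 * se),
             p_value = 2 * pnorm(-abs(z)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Univariate ordinal-regression screen
#'
#' Fits one single-covariate proportional-odds model per listed covariate
#' and reports Wald odds ratios, intervals and p-values.  Covariates whose
#' fit fails (e.g. separation) yield an `NA` row with a warning; the screen
#' continues.  No multiplicity correction is applied.
#'
#' @param X numeric matrix or labeled `cohort_table`.
#' @param y ordinal labels (ignored when `X` is a cohort).
#' @param covariates covariate names to screen (default: all columns).
#' @return Data frame, one [or_table()] row per covariate.
#' @export
univariate_screen <- function(X, y = NULL, covariates = NULL) {
  if (inherits(X, "cohort_table")) {
    y <- X$risk
    X <- X$features
  }
  X <- as.matrix(X)
  covariates <- covariates %||% colnames(X)
  rows <- lapply(covariates, function(nm) {
    tryCatch(or_table(fit_olr(X[, nm, drop = FALSE], y)),
             error = function(e) {
               warning("univariate fit failed for ", nm, ": ",
                       conditionMessage(e), call. = FALSE)
               data.frame(name = nm, odds_ratio = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          p_value = NA_real_, stringsAsFactors = FALSE)
             })
  })
  do.call(rbind, rows)
}

#' Multivariate fit with independent-predictor selection
#'
#' Fits the full multivariate proportional-odds model, flags covariates with
#' Wald `p < alpha` as independent predictors, and refits on that subset.
#' A collinearity warning is emitted beforehand when any variance inflation
#' factor exceeds 10.
#'
#' @param X numeric matrix or labeled `cohort_table`.
#' @param y ordinal labels (ignored when `X` is a cohort).
#' @param alpha Wald significance threshold (default 0.05).
#' @return List with `fit` (refit on kept covariates), `kept` (names),
#'   `full_fit`, and `table` (the full-model [or_table()]).
#' @export
multivariate_select <- function(X, y = NULL, alpha = 0.05) {
  if (inherits(X, "cohort_table")) {
    y <- X$risk
    X <- X$features
  }
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least 2 covariates", call. = FALSE)
  v <- vif(X)
  if (any(!is.finite(v)) || any(v > 10)) {
    warning("high collinearity among covariates (VIF > 10): ",
            paste(colnames(X)[!is.finite(v) | v > 10], collapse = ", "),
            call. = FALSE)
  }
  full <- fit_olr(X, y)
  tab <- or_table(full)
  kept <- tab$name[tab$p_value < alpha]
  if (length(kept) == 0L) {
    stop("no covariate reaches p < ", alpha, "; empty model", call. = FALSE)
  }
  refit <- if (length(kept) == ncol(X)) full else
    fit_olr(X[, kept, drop = FALSE], y)
  list(fit = refit, kept = kept, full_fit = full, table = tab)
}

#' Variance inflation factors
#'
#' `VIF_i = 1 / (1 - R2_i)` where `R2_i` comes from the ordinary
#' least-squares regression of covariate `i` on the remaining covariates
#' plus an intercept.  Perfectly collinear covariates report `Inf` rather
#' than raising an error.
#'
#' @param X numeric matrix with at least two columns.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("VIF needs at least 2 covariates", call. = FALSE)
  out <- vapply(seq_len(ncol(X)), function(i) {
    r2 <- summary(stats::lm(X[, i] ~ X[, -i, drop = FALSE]))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  setNames(out, colnames(X))
}
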
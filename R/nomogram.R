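#' Build a point-scale nomogram from a proportional-odds fit
#'
#' Each covariate axis maps its value affinely to points: the axis's
#' zero-point end is its protective extreme (the low end for a
#' risk-increasing coefficient, the high end for a protective one), and the
#' axis with the widest effect `|beta| * (hi - lo)` spans exactly 100
#' points.  Total points and the model's linear predictor `eta = x'beta`
#' are affine images of one another (`score_map`), and class probabilities
#' follow from `P(Y <= k) = plogis(theta_k - eta)`.
#'
#' @param fit an [fit_olr()] result.
#' @param ranges matrix or data frame with rownames = covariates and
#'   columns `lo`, `hi` covering the data; defaults should be the observed
#'   training min/max (see [axis_ranges()]).
#' @return A `nomogram` object with per-axis affine point maps, the
#'   total-points/linear-predictor bijection and a 101-row
#'   points-to-probability table.
#' @export
build_nomogram <- function(fit, ranges) {
  stopifnot(inherits(fit, "olr_fit"))
  ranges <- as.matrix(ranges)
  if (is.null(rownames(ranges))) {
    if (nrow(ranges) != length(fit$covariate_names)) {
      stop("ranges must have one row per covariate", call. = FALSE)
    }
    rownames(ranges) <- fit$covariate_names
  }
  ranges <- ranges[fit$covariate_names, , drop = FALSE]
  colnames(ranges) <- c("lo", "hi")
  if (any(ranges[, "hi"] <= ranges[, "lo"])) {
    stop("zero-width axis range for: ",
         paste(fit$covariate_names[ranges[, "hi"] <= ranges[, "lo"]],
               collapse = ", "), call. = FALSE)
  }
  beta <- fit$beta
  width <- abs(beta) * (ranges[, "hi"] - ranges[, "lo"])
  delta <- max(width)
  if (delta <= 0) stop("all coefficients are zero; no nomogram", call. = FALSE)
  ref <- ifelse(beta >= 0, ranges[, "lo"], ranges[, "hi"])  # 0-point end
  axes <- data.frame(name = fit$covariate_names,
                     lo = ranges[, "lo"], hi = ranges[, "hi"],
                     beta = as.numeric(beta), ref = as.numeric(ref),
                     max_points = 100 * width / delta,
                     row.names = NULL, stringsAsFactors = FALSE)
  eta_min <- sum(beta * ref)
  total_max <- sum(axes$max_points)
  grid <- seq(0, total_max, length.out = 101L)
  eta_grid <- eta_min + grid * delta / 100
  Fm <- cbind(plogis(outer(-eta_grid, fit$theta, `+`)), 1)
  prob <- cbind(Fm[, 1], Fm[, 2] - Fm[, 1], 1 - Fm[, 2])
  colnames(prob) <- c("p_low", "p_intermediate", "p_high")
  structure(list(axes = axes, theta = fit$theta, delta = delta,
                 eta_min = eta_min, total_max = total_max,
                 prob_table = data.frame(total_points = grid, prob)),
            class = "nomogram")
}

#' @export
print.nomogram <- function(x, ...) {
  cat(sprintf("<nomogram> %d axes, total points 0..%.1f\n",
              nrow(x$axes), x$total_max))
  print(x$axes, digits = 4)
  invisible(x)
}

#' Observed per-covariate axis ranges
#' @param X numeric matrix or `cohort_table`.
#' @param covariates optional subset of columns.
#' @return Matrix with columns `lo`, `hi` (per-column min/max).
#' @export
axis_ranges <- function(X, covariates = NULL) {
  if (inherits(X, "cohort_table")) X <- X$features
  X <- as.matrix(X)
  if (!is.null(covariates)) X <- X[, covariates, drop = FALSE]
  cbind(lo = apply(X, 2, min), hi = apply(X, 2, max))
}

## per-axis points for a record matrix (rows = patients)
axis_points <- function(nomogram, X) {
  ax <- nomogram$axes
  pts <- vapply(seq_len(nrow(ax)), function(i) {
    100 * ax$beta[i] * (X[, ax$name[i]] - ax$ref[i]) / nomogram$delta
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) pts <- matrix(pts, nrow = 1)
  colnames(pts) <- ax$name
  pts
}

#' Score patients with a nomogram
#'
#' Returns the predictive score — the linear predictor `eta = x'beta` — of
#' each record, together with its total points (the two are affinely
#' equivalent).  Values outside an axis range are clipped to the range with
#' a warning.
#'
#' @param nomogram a [build_nomogram()] object.
#' @param records `cohort_table`, matrix or data frame covering all axes.
#' @return Data frame with columns `eta` and `total_points`.
#' @export
score <- function(nomogram, records) {
  X <- if (inherits(records, "cohort_table")) records$features else
    as.matrix(records)
  ax <- nomogram$axes
  missing <- setdiff(ax$name, colnames(X))
  if (length(missing)) stop("records lack axis value(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  X <- X[, ax$name, drop = FALSE]
  lo <- matrix(ax$lo, nrow(X), nrow(ax), byrow = TRUE)
  hi <- matrix(ax$hi, nrow(X), nrow(ax), byrow = TRUE)
  if (any(X < lo) || any(X > hi)) {
    warning("axis value(s) outside range clipped", call. = FALSE)
    X <- pmin(pmax(X, lo), hi)
  }
  pts <- rowSums(axis_points(nomogram, X))
  data.frame(eta = nomogram$eta_min + pts * nomogram$delta / 100,
             total_points = pts)
}

#' Convert total points to a linear predictor (and back)
#' @param nomogram a `nomogram`.
#' @param total_points numeric vector of total points.
#' @return Linear-predictor values.
#' @export
points_to_eta <- function(nomogram, total_points) {
  nomogram$eta_min + total_points * nomogram$delta / 100
}

#' @rdname points_to_eta
#' @param eta linear-predictor values.
#' @return Total points.
#' @export
eta_to_points <- function(nomogram, eta) {
  (eta - nomogram$eta_min) * 100 / nomogram$delta
}

#' Feature-mapping algorithm: project model axes onto clinical features
#'
#' Given the per-model scalarized predictions `MV` (one nomogram axis value
#' per retained model `j`) and the models' normalized feature importances
#' `FI` (columns on the simplex), computes for each patient the
#' clinical-feature values
#' `CF_i = sum_j FI[i, j] * MV[j]`.
#' Because every importance column sums to one, the transform conserves
#' mass: `sum_i CF_i = sum_j MV_j` exactly.  The clinical-feature nomogram
#' is then obtained by refitting the ordinal regression on the `CF` matrix
#' (see [build_stacked_nomogram()]).
#'
#' @param ensemble an [train_base_models()] fit, or `NULL` when `FI` and
#'   `MV` are given directly.
#' @param kept_models names of the retained models (the independent
#'   predictors from [multivariate_select()]).
#' @param FI,MV optional explicit importance matrix (features x models) and
#'   meta-feature matrix (patients x models); extracted from `ensemble` by
#'   default.
#' @return An `fma_result` with `CF` (patients x features), `FI`, `MV`.
#' @export
fma_convert <- function(ensemble = NULL, kept_models = NULL, FI = NULL,
                        MV = NULL) {
  if (!is.null(ensemble)) {
    stopifnot(inherits(ensemble, "ensemble_fit"))
    kept_models <- kept_models %||% ensemble$model_names
    FI <- FI %||% ensemble$importances[, kept_models, drop = FALSE]
    MV <- MV %||% ensemble$meta_features[, kept_models, drop = FALSE]
  }
  FI <- as.matrix(FI)
  MV <- as.matrix(MV)
  if (!is.null(kept_models)) {
    FI <- FI[, kept_models, drop = FALSE]
    MV <- MV[, kept_models, drop = FALSE]
  }
  if (ncol(FI) != ncol(MV)) stop("FI and MV disagree on model count",
                                 call. = FALSE)
  if (any(FI < -1e-12) || any(abs(colSums(FI) - 1) > 1e-9)) {
    stop("importance columns must be simplex vectors (nonnegative, sum 1)",
         call. = FALSE)
  }
  CF <- MV %*% t(FI)
  colnames(CF) <- rownames(FI)
  structure(list(CF = CF, FI = FI, MV = MV), class = "fma_result")
}

#' Risk cutoffs on the predictive-score scale
#' @param c1,c2 lower and upper cutoff, `c1 < c2`.
#' @return A `risk_cutoffs` object.
#' @export
risk_cutoffs <- function(c1, c2) {
  stopifnot_scalar_number(c1, "c1")
  stopifnot_scalar_number(c2, "c2")
  if (!(c1 < c2)) stop("cutoffs must satisfy c1 < c2", call. = FALSE)
  structure(list(c1 = c1, c2 = c2), class = "risk_cutoffs")
}

#' Classify predictive scores into the three risk groups
#'
#' Boundary convention (closed on the lower class): `score <= c1` is low,
#' `c1 < score <= c2` intermediate, `score > c2` high.
#'
#' @param scores numeric vector of predictive scores.
#' @param cutoffs a [risk_cutoffs()] object.
#' @return Integer labels 1/2/3.
#' @export
classify <- function(scores, cutoffs) {
  stopifnot(inherits(cutoffs, "risk_cutoffs"))
  ifelse(scores <= cutoffs$c1, 1L, ifelse(scores <= cutoffs$c2, 2L, 3L))
}

#' Derive tripartite cutoffs from training scores
#'
#' Grid search over pairs of candidate cutoffs (midpoints between
#' consecutive distinct score values, thinned to at most `max_candidates`)
#' maximizing the macro-averaged per-class recall (balanced accuracy) of
#' the induced classification.  Ties resolve to the smaller `c1`, then the
#' smaller `c2`.
#'
#' @param scores numeric predictive scores.
#' @param labels ordinal labels 1/2/3 (all three present).
#' @param max_candidates cap on the candidate grid size (default 200).
#' @return A [risk_cutoffs()] with attributes `balanced_accuracy` and
#'   `accuracy`.
#' @export
derive_cutoffs <- function(scores, labels, max_candidates = 200L) {
  labels <- as.integer(labels)
  if (!all(1:3 %in% labels)) stop("all three classes must be present",
                                  call. = FALSE)
  us <- sort(unique(scores))
  if (length(us) < 3L) stop("degenerate scores: fewer than 3 distinct values",
                            call. = FALSE)
  cand <- (us[-1] + us[-length(us)]) / 2
  if (length(cand) > max_candidates) {
    cand <- unique(stats::quantile(cand, seq(0, 1, length.out = max_candidates),
                                   names = FALSE, type = 7))
  }
  ## cumulative class counts at each candidate: recall terms in O(1) per pair
  n_k <- tabulate(labels, 3L)
  below <- vapply(1:3, function(k) {
    vapply(cand, function(c) sum(scores[labels == k] <= c), numeric(1))
  }, numeric(length(cand)))
  best <- c(-Inf, NA, NA)
  for (i in seq_along(cand)) {
    r1 <- below[i, 1] / n_k[1]
    js <- seq_along(cand)[seq_along(cand) > i]
    if (!length(js)) next
    r2 <- (below[js, 2] - below[i, 2]) / n_k[2]
    r3 <- (n_k[3] - below[js, 3]) / n_k[3]
    bal <- (r1 + r2 + r3) / 3
    j <- which.max(bal)           # first maximum: smallest c2
    if (bal[j] > best[1] + 1e-12) best <- c(bal[j], cand[i], cand[js[j]])
  }
  out <- risk_cutoffs(best[2], best[3])
  pred <- classify(scores, out)
  attr(out, "balanced_accuracy") <- best[1]
  attr(out, "accuracy") <- mean(pred == labels)
  out
}

#' Stacked clinical-feature ("clinic-ML") nomogram
#'
#' End-to-end construction of the stacked nomogram: selects the independent
#' base models by multivariate ordinal regression on the meta-features,
#' builds the model-axis nomogram, maps model axes onto clinical features
#' with [fma_convert()], and refits the ordinal regression on the mapped
#' `CF` matrix to obtain a nomogram whose axes are clinical features.
#' Because `CF` has rank at most the number of retained models, the refit
#' uses a small ridge penalty for coefficient identifiability
#' (predictive scores are unaffected by the choice within the null space).
#' Alternatively (`method = "analytic"`) the clinical-axis coefficients are
#' taken as `FI %*% beta_ML` without a refit.
#'
#' @param ensemble an [train_base_models()] fit.
#' @param alpha Wald threshold for retaining base models (default 0.05).
#' @param ridge ridge penalty for the rank-deficient CF refit
#'   (default 1e-4).
#' @param method `"refit"` (default) or `"analytic"`.
#' @return List with `ml_fit` (OLR on retained meta-features), `ml_nomogram`,
#'   `kept_models`, `fma` (the [fma_convert()] result), `clinic_ml_fit`,
#'   `clinic_ml_nomogram`, and `selection` (the [multivariate_select()]
#'   output).
#' @export
build_stacked_nomogram <- function(ensemble, alpha = 0.05, ridge = 1e-4,
                                   method = c("refit", "analytic")) {
  method <- match.arg(method)
  stopifnot(inherits(ensemble, "ensemble_fit"))
  y <- ensemble$y_int
  sel <- multivariate_select(ensemble$meta_features, y, alpha = alpha)
  kept <- sel$kept
  ml_fit <- sel$fit
  ml_nom <- build_nomogram(ml_fit,
                           axis_ranges(ensemble$meta_features, kept))
  fma <- fma_convert(ensemble, kept_models = kept)
  if (method == "refit") {
    clinic_fit <- fit_olr(fma$CF, y, ridge = ridge)
  } else {
    ## coefficients mapped analytically; thresholds (and a common scale)
    ## recalibrated by a one-covariate fit on the induced score
    beta_clinic <- drop(fma$FI %*% ml_fit$beta[kept])
    eta0 <- drop(fma$CF %*% beta_clinic)
    cal <- fit_olr(matrix(eta0, ncol = 1, dimnames = list(NULL, "eta")), y)
    clinic_fit <- fit_olr(fma$CF, y, ridge = ridge)
    clinic_fit$beta[] <- beta_clinic * cal$beta[1]
    clinic_fit$theta <- cal$theta
  }
  rng <- axis_ranges(fma$CF)
  ## guard vanishing-width CF axes (a feature no model weighs)
  degenerate <- rng[, "hi"] - rng[, "lo"] <= 1e-12
  if (any(degenerate)) {
    keep_ax <- rownames(rng)[!degenerate]
    clinic_fit <- fit_olr(fma$CF[, keep_ax, drop = FALSE], y, ridge = ridge)
    rng <- rng[keep_ax, , drop = FALSE]
  }
  clinic_nom <- build_nomogram(clinic_fit, rng)
  list(ml_fit = ml_fit, ml_nomogram = ml_nom, kept_models = kept,
       fma = fma, clinic_ml_fit = clinic_fit,
       clinic_ml_nomogram = clinic_nom, selection = sel)
}

#' Serialize a nomogram as a delimited-text bundle
#'
#' Writes a single TSV bundle holding the model parameters (at full
#' precision, so reading back is bit-exact), the per-axis point tables at
#' 101 grid values, and the total-points-to-probability table.
#'
#' @param nomogram a `nomogram`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_nomogram <- function(nomogram, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ax <- nomogram$axes
  writeLines("# nomostack nomogram v1", con)
  writeLines(paste0("theta\t",
                    paste(format_full(nomogram$theta), collapse = "\t")), con)
  writeLines(paste0("delta\t", format_full(nomogram$delta)), con)
  writeLines(paste0("eta_min\t", format_full(nomogram$eta_min)), con)
  writeLines("[axes]", con)
  writeLines("name\tlo\thi\tbeta\tref", con)
  for (i in seq_len(nrow(ax))) {
    writeLines(paste(ax$name[i], format_full(ax$lo[i]), format_full(ax$hi[i]),
                     format_full(ax$beta[i]), format_full(ax$ref[i]),
                     sep = "\t"), con)
  }
  writeLines("[axis_points]", con)
  writeLines("name\tvalue\tpoints", con)
  for (i in seq_len(nrow(ax))) {
    vals <- seq(ax$lo[i], ax$hi[i], length.out = 101L)
    pts <- 100 * ax$beta[i] * (vals - ax$ref[i]) / nomogram$delta
    writeLines(paste(ax$name[i], format_full(vals), format_full(pts),
                     sep = "\t"), con)
  }
  writeLines("[prob_table]", con)
  pt <- nomogram$prob_table
  writeLines(paste(names(pt), collapse = "\t"), con)
  for (i in seq_len(nrow(pt))) {
    writeLines(paste(vapply(pt[i, ], format_full, ""), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a nomogram bundle written by [write_nomogram()]
#' @param path bundle file.
#' @return A `nomogram` object equal to the one serialized.
#' @export
read_nomogram <- function(path) {
  lines <- readLines(path)
  get_scalar <- function(key) {
    as.numeric(strsplit(grep(paste0("^", key, "\t"), lines,
                             value = TRUE)[1], "\t")[[1]][-1])
  }
  theta <- get_scalar("theta")
  delta <- get_scalar("delta")
  eta_min <- get_scalar("eta_min")
  sec <- function(name) which(lines == paste0("[", name, "]"))
  i_ax <- sec("axes"); i_ap <- sec("axis_points"); i_pt <- sec("prob_table")
  ax <- utils::read.table(text = lines[(i_ax + 1L):(i_ap - 1L)], sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  width <- abs(ax$beta) * (ax$hi - ax$lo)
  ax$max_points <- 100 * width / delta
  pt <- utils::read.table(text = lines[(i_pt + 1L):length(lines)], sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  structure(list(axes = ax, theta = theta, delta = delta, eta_min = eta_min,
                 total_max = sum(ax$max_points), prob_table = pt),
            class = "nomogram")
}
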
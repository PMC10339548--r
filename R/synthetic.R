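#' Built-in per-risk-group feature profile
#'
#' Per-group marginal summary statistics (mean, SD) for the 41-feature
#' peripheral-lymphocyte / clinical-chemistry panel, for the three ordinal
#' risk groups of a 157-patient training cohort with group sizes 47/38/72
#' (low/intermediate/high).  Skewed serum biomarkers (PSA, alkaline
#' phosphatase, lactate dehydrogenase, creatinine, ALT, interleukins,
#' TNF-alpha) are drawn from moment-matched lognormal distributions; the
#' remaining markers are Gaussian, clamped at physiological floors (0 for
#' counts and percentages) and caps (100 for percentages).  Measurement
#' truncation limits (PSA ceiling 1000; ALT, IL-6 and IL-1b detection floors
#' of 5, 1.5 and 5) are applied during generation, mirroring how such values
#' are recorded by the laboratory.
#'
#' @param n default cohort size for [generate_cohort()].
#' @param seed default RNG seed stored in the spec.
#' @return A `cohort_spec` list with elements `n`, `group_weights`,
#'   `profiles` (per-feature data frame with group means/SDs, family, floor,
#'   cap and unit), `correlation` (`NULL`: independent features) and `seed`.
#' @export
builtin_profile <- function(n = 157L, seed = 1L) {
  ## name, unit, family, floor, cap, mean/sd per group (low, int, high)
  p <- read.table(header = TRUE, sep = ";", strip.white = TRUE,
                  stringsAsFactors = FALSE, text = "
name; unit; family; floor; cap; m1; s1; m2; s2; m3; s3
Age; years; normal; 18; 100; 63.23; 8.18; 65.53; 7.10; 68.57; 7.42
PSA; ng/mL; lognormal; 0; 1000; 7.56; 7.24; 12.67; 9.50; 199.62; 312.92
Neutrophil percentage; %; normal; 0; 100; 65.96; 11.34; 58.69; 10.44; 60.51; 9.04
Neutrophils; 10^9/L; normal; 0; Inf; 4.60; 2.05; 3.55; 1.80; 3.72; 1.55
Lymphocyte percentage; %; normal; 0; 100; 23.33; 9.44; 29.32; 9.25; 26.65; 7.77
Lymphocytes; 10^9/L; normal; 0; Inf; 1.52; 0.65; 1.64; 0.57; 1.53; 0.42
Hemoglobin; g/L; normal; 0; Inf; 134.13; 16.14; 137.16; 11.84; 128.82; 15.81
ALT; U/L; lognormal; 5; Inf; 21.72; 13.18; 19.13; 12.07; 18.83; 14.52
Alkaline phosphatase; U/L; lognormal; 0; Inf; 73.62; 29.75; 67.87; 15.89; 229.25; 556.22
Lactate dehydrogenase; U/L; lognormal; 0; Inf; 168.89; 37.15; 157.05; 34.14; 200.83; 129.90
Serum creatinine; mmol/L; lognormal; 0; Inf; 91.04; 64.35; 83.82; 12.77; 87.03; 43.40
T cells (%); %; normal; 0; 100; 67.57; 8.16; 67.44; 9.43; 67.92; 10.43
T cells (/ul); /uL; normal; 0; Inf; 1059.34; 370.24; 1100.29; 325.67; 996.01; 266.54
B cells (%); %; normal; 0; 100; 12.74; 5.69; 12.55; 6.07; 11.54; 5.20
B cells (/ul); /uL; normal; 0; Inf; 211.09; 152.39; 208.21; 136.04; 167.58; 79.30
Th cells (%); %; normal; 0; 100; 42.65; 7.65; 42.38; 8.95; 44.44; 8.96
Th cells (/ul); /uL; normal; 0; Inf; 677.06; 276.78; 686.00; 213.15; 649.42; 189.27
Ts cells (%); %; normal; 0; 100; 22.14; 7.31; 20.36; 5.49; 19.94; 6.61
Ts cells (/ul); /uL; normal; 0; Inf; 339.81; 132.66; 336.53; 151.08; 295.56; 125.80
NK cells (%); %; normal; 0; 100; 18.86; 8.17; 19.27; 9.26; 19.76; 10.84
NK cells (/ul); /uL; normal; 0; Inf; 297.21; 165.47; 317.00; 186.65; 308.47; 237.42
T+B+NK cells (%); %; normal; 0; 100; 99.17; 0.74; 99.26; 0.58; 99.23; 0.61
T+B+NK cells (/ul); /uL; normal; 0; Inf; 1567.64; 557.32; 1625.50; 441.12; 1472.07; 404.37
Th/Ts; ratio; normal; 0; Inf; 2.17; 0.88; 2.24; 0.79; 2.55; 1.19
Th CD28+ (/Th); %; normal; 0; 100; 94.44; 7.14; 93.92; 7.51; 94.91; 6.98
Ts CD28+ (/Ts); %; normal; 0; 100; 59.28; 20.46; 56.62; 16.45; 59.17; 16.55
Activated T cells (/ul); /uL; normal; 0; Inf; 17.16; 6.34; 18.68; 6.24; 17.98; 6.45
Activated Ts cells/Ts (%); %; normal; 0; 100; 40.53; 13.36; 46.01; 11.88; 46.21; 13.16
Naive Th cells/Th (%); %; normal; 0; 100; 32.64; 13.23; 32.58; 10.86; 32.27; 15.08
Memory Th cells/Th (%); %; normal; 0; 100; 67.36; 13.23; 67.42; 10.86; 67.87; 15.23
Regulatory T cells (/ul); /uL; normal; 0; Inf; 3.52; 1.15; 4.17; 1.47; 3.83; 1.08
Naive regulatory T cells (/ul); /uL; normal; 0; Inf; 0.69; 0.39; 0.87; 0.66; 0.74; 0.38
Induced regulatory T cells (/ul); /uL; normal; 0; Inf; 2.83; 0.90; 3.30; 1.03; 3.09; 0.88
IFN-g+CD4+ T cells/Th (%); %; normal; 0; 100; 21.89; 7.82; 22.33; 8.92; 20.73; 8.17
IFN-g+CD8+ T cells/Ts (%); %; normal; 0; 100; 60.66; 17.63; 61.97; 13.45; 63.57; 14.93
IFN-g+NK cells/NK (%); %; normal; 0; 100; 76.37; 14.31; 73.49; 14.85; 74.46; 15.25
Interleukin-1b; pg/mL; lognormal; 5; Inf; 6.55; 4.06; 5.92; 3.05; 8.69; 8.10
Interleukin-2R; U/mL; lognormal; 0; Inf; 427.45; 189.32; 444.39; 149.37; 572.76; 425.87
Interleukin-6; pg/mL; lognormal; 1.5; Inf; 3.79; 4.86; 4.99; 13.06; 9.87; 14.87
Interleukin-8; pg/mL; lognormal; 0; Inf; 18.28; 21.49; 31.45; 41.75; 30.67; 41.55
TNF-a; pg/mL; lognormal; 0; Inf; 16.88; 20.70; 19.12; 28.35; 21.59; 38.68
")
  cohort_spec(n = n,
              group_weights = c(47, 38, 72) / 157,
              profiles = p,
              correlation = NULL,
              seed = seed)
}

#' Construct a cohort specification
#'
#' @param n number of patients to draw.
#' @param group_weights nonnegative weights for the three ordinal risk
#'   groups (normalized to sum 1).
#' @param profiles data frame with one row per feature and columns `name`,
#'   `unit`, `family` (`"normal"` or `"lognormal"`), `floor`, `cap`, and
#'   `m1,s1,m2,s2,m3,s3` (mean/SD per group, low to high).
#' @param correlation optional symmetric positive semi-definite feature
#'   correlation matrix with unit diagonal, applied through a Gaussian
#'   copula; `NULL` (default) draws features independently.
#' @param seed integer RNG seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n, group_weights, profiles, correlation = NULL,
                        seed = 1L) {
  stopifnot(n >= 1, length(group_weights) == 3, all(group_weights >= 0),
            sum(group_weights) > 0)
  need <- c("name", "family", "floor", "cap", "m1", "s1", "m2", "s2",
            "m3", "s3")
  if (!all(need %in% names(profiles))) {
    stop("profiles lacks columns: ",
         paste(setdiff(need, names(profiles)), collapse = ", "),
         call. = FALSE)
  }
  if (any(!profiles$family %in% c("normal", "lognormal"))) {
    stop("family must be 'normal' or 'lognormal'", call. = FALSE)
  }
  sds <- as.matrix(profiles[, c("s1", "s2", "s3")])
  if (any(sds < 0)) stop("profile SDs must be nonnegative", call. = FALSE)
  if (any(profiles$floor > profiles$cap)) {
    stop("floor must not exceed cap", call. = FALSE)
  }
  lnorm <- profiles$family == "lognormal"
  if (any(lnorm & as.matrix(profiles[, c("m1", "m2", "m3")]) <= 0)) {
    stop("lognormal features need strictly positive means", call. = FALSE)
  }
  if (!is.null(correlation)) {
    m <- nrow(profiles)
    if (!is.matrix(correlation) || any(dim(correlation) != m) ||
        max(abs(correlation - t(correlation))) > 1e-8 ||
        max(abs(diag(correlation) - 1)) > 1e-8) {
      stop("correlation must be a symmetric matrix with unit diagonal",
           call. = FALSE)
    }
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop("correlation matrix is not positive semi-definite", call. = FALSE)
    }
  }
  structure(list(n = as.integer(n),
                 group_weights = group_weights / sum(group_weights),
                 profiles = profiles, correlation = correlation,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

## lognormal parameters matching a target mean/sd
lognormal_params <- function(m, s) {
  sdlog2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Generate a synthetic cohort
#'
#' Draws each patient's risk group from the specification's group weights,
#' then each feature from the group's marginal distribution (through a
#' Gaussian copula when a correlation matrix is supplied), and finally
#' clamps values at the configured floors/caps — emulating detection-limit
#' and assay-ceiling recording.  Deterministic given the seed.
#'
#' @param spec a [cohort_spec()] (e.g. from [builtin_profile()]).
#' @param n optional override of `spec$n`.
#' @param seed optional override of `spec$seed`.
#' @return A labeled [cohort_table()].
#' @export
generate_cohort <- function(spec, n = NULL, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- as.integer(n %||% spec$n)
  seed <- as.integer(seed %||% spec$seed)
  p <- spec$profiles
  m <- nrow(p)
  with_seed(seed, {
    group <- sample.int(3L, n, replace = TRUE, prob = spec$group_weights)
    ## copula: correlated standard normals -> uniforms -> marginal quantiles
    z <- matrix(stats::rnorm(n * m), n, m)
    if (!is.null(spec$correlation)) {
      ev <- eigen(spec$correlation, symmetric = TRUE)
      root <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
      z <- z %*% root
    }
    u <- stats::pnorm(z)
    feats <- matrix(NA_real_, n, m, dimnames = list(NULL, p$name))
    for (j in seq_len(m)) {
      mu <- c(p$m1[j], p$m2[j], p$m3[j])[group]
      sig <- c(p$s1[j], p$s2[j], p$s3[j])[group]
      x <- if (p$family[j] == "lognormal") {
        lp <- lognormal_params(mu, sig)
        stats::qlnorm(u[, j], lp$meanlog, lp$sdlog)
      } else {
        stats::qnorm(u[, j], mu, sig)
      }
      feats[, j] <- pmin(pmax(x, p$floor[j]), p$cap[j])
    }
    cohort_table(feats, risk = group,
                 feature_meta = data.frame(name = p$name, unit = p$unit,
                                           stringsAsFactors = FALSE))
  })
}
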
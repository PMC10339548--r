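## small fitted objects built by hand: an olr_fit is just its parameters
fake_fit <- function(beta, theta = c(-1, 1)) {
  structure(list(beta = beta, theta = theta, K = length(theta) + 1L,
                 covariate_names = names(beta), n = 0L,
                 se = rep(NA_real_, length(beta) + length(theta)),
                 cov = NULL, loglik = NA_real_),
            class = "olr_fit")
}

test_that("a single-axis nomogram spans 0..100 points and maps back to eta", {
  fit <- fake_fit(c(x = 1))
  nom <- build_nomogram(fit, cbind(lo = 0, hi = 1))
  expect_equal(nom$axes$max_points, 100)
  s <- score(nom, matrix(c(0, 0.25, 1), ncol = 1,
                         dimnames = list(NULL, "x")))
  expect_equal(s$total_points, c(0, 25, 100))
  expect_equal(s$eta, c(0, 0.25, 1))
})

test_that("protective covariates score zero points at their high end", {
  fit <- fake_fit(c(x = -2))
  nom <- build_nomogram(fit, cbind(lo = 0, hi = 1))
  s <- score(nom, matrix(c(0, 1), ncol = 1, dimnames = list(NULL, "x")))
  expect_equal(s$total_points, c(100, 0))
  ## points decrease as the value increases
  expect_equal(s$eta, c(0, -2))
})

test_that("relative axis lengths follow coefficient magnitude and ranges", {
  fit <- fake_fit(c(a = 2, b = 1))
  nom <- build_nomogram(fit, cbind(lo = c(0, 0), hi = c(1, 1)))
  expect_equal(nom$axes$max_points, c(100, 50))
  ## exactly one axis reaches 100
  expect_equal(sum(abs(nom$axes$max_points - 100) < 1e-12), 1L)
  ## round trip through points recovers eta
  withr::local_seed(2)
  recs <- matrix(runif(2000), ncol = 2, dimnames = list(NULL, c("a", "b")))
  s <- score(nom, recs)
  eta_direct <- drop(recs %*% c(2, 1))
  expect_equal(s$eta, eta_direct, tolerance = 1e-9)
  expect_equal(points_to_eta(nom, s$total_points), eta_direct,
               tolerance = 1e-9)
  expect_equal(eta_to_points(nom, s$eta), s$total_points, tolerance = 1e-9)
})

test_that("probability table rows are simplex and risk is monotone in points", {
  fit <- fake_fit(c(a = 1.3, b = -0.6), theta = c(-0.5, 1.2))
  nom <- build_nomogram(fit, cbind(lo = c(-1, 0), hi = c(2, 3)))
  pt <- nom$prob_table
  expect_equal(rowSums(pt[, -1]), rep(1, nrow(pt)), tolerance = 1e-9)
  expect_true(all(diff(pt$p_high) >= -1e-12))
  expect_true(all(diff(pt$p_low) <= 1e-12))
  ## degenerate range refused
  expect_error(build_nomogram(fit, cbind(lo = c(0, 0), hi = c(0, 3))),
               "zero-width")
})

test_that("out-of-range records are clipped with a warning", {
  fit <- fake_fit(c(x = 1))
  nom <- build_nomogram(fit, cbind(lo = 0, hi = 1))
  expect_warning(s <- score(nom, matrix(2, 1, 1,
                                        dimnames = list(NULL, "x"))),
                 "clipped")
  expect_equal(s$eta, 1)
  expect_error(score(nom, matrix(1, 1, 1, dimnames = list(NULL, "y"))),
               "lack axis")
})

test_that("the feature mapping conserves the total axis mass", {
  withr::local_seed(77)
  for (rep in 1:50) {
    M <- sample(2:8, 1)
    N <- sample(1:5, 1)
    FI <- vapply(seq_len(N), function(j) rsimplex(M), numeric(M))
    rownames(FI) <- paste0("feat", seq_len(M))
    MV <- matrix(runif(3 * N, 1, 3), 3, N)
    res <- fma_convert(FI = FI, MV = MV)
    expect_equal(rowSums(res$CF), rowSums(MV), tolerance = 1e-12)
  }
})

test_that("feature mapping handles identity and shared-value cases", {
  FI <- matrix(c(1, 0, 0), 3, 1, dimnames = list(c("a", "b", "c"), "m"))
  MV <- matrix(c(1.4, 2.2), 2, 1)
  res <- fma_convert(FI = FI, MV = MV)
  expect_equal(res$CF[, "a"], c(1.4, 2.2))
  expect_equal(res$CF[, "b"], c(0, 0))
  ## all models agreeing on a constant c: CF_i = c * rowSums(FI)
  FI2 <- cbind(m1 = c(0.2, 0.3, 0.5), m2 = c(0.6, 0.1, 0.3))
  rownames(FI2) <- c("a", "b", "c")
  MV2 <- matrix(2, 1, 2)
  res2 <- fma_convert(FI = FI2, MV = MV2)
  expect_equal(drop(res2$CF), 2 * rowSums(FI2), tolerance = 1e-12)
  ## non-simplex importances refused
  expect_error(fma_convert(FI = FI2 * 2, MV = MV2), "simplex")
})

test_that("classification respects the cutoff boundary convention", {
  cuts <- risk_cutoffs(2.24, 6.00)
  expect_equal(classify(2.24, cuts), 1L)
  expect_equal(classify(7.1, cuts), 3L)
  expect_equal(classify(c(1, 3, 9), cuts), c(1L, 2L, 3L))
  expect_equal(classify(6.00, cuts), 2L)
  ## monotone: larger score never lowers the class
  withr::local_seed(4)
  s <- sort(rnorm(200, 4, 3))
  expect_true(all(diff(classify(s, cuts)) >= 0))
  expect_error(risk_cutoffs(6, 2.24), "c1 < c2")
})

test_that("derived cutoffs land in the gaps of separated classes", {
  scores <- c(1.0, 1.2, 1.4, 3.0, 3.2, 3.4, 8.0, 8.2)
  labels <- c(1, 1, 1, 2, 2, 2, 3, 3)
  cuts <- derive_cutoffs(scores, labels)
  expect_gt(cuts$c1, 1.4); expect_lt(cuts$c1, 3.0)
  expect_gt(cuts$c2, 3.4); expect_lt(cuts$c2, 8.0)
  expect_equal(attr(cuts, "balanced_accuracy"), 1)
  expect_error(derive_cutoffs(rep(1, 9), labels), "degenerate")
})

test_that("shuffled labels yield near-chance cutoff accuracy, real ones monotone group means", {
  withr::local_seed(14)
  scores <- c(rnorm(80, 0), rnorm(80, 2), rnorm(80, 5))
  labels <- rep(1:3, each = 80)
  cuts <- derive_cutoffs(scores, labels)
  groups <- classify(scores, cuts)
  means <- tapply(scores, groups, mean)
  expect_true(all(diff(means) > 0))
  shuf <- sample(labels)
  cuts_s <- derive_cutoffs(scores, shuf)
  expect_lt(attr(cuts_s, "balanced_accuracy"), 0.55)
})

test_that("nomogram serialization round-trips bit-exactly", {
  fit <- fake_fit(c(a = pi / 3, b = -exp(1) / 5), theta = c(-0.123, 1.456))
  nom <- build_nomogram(fit, cbind(lo = c(-1.5, 0), hi = c(2.25, 3)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_nomogram(nom, path)
  nom2 <- read_nomogram(path)
  expect_identical(nom2$theta, nom$theta)
  expect_identical(nom2$delta, nom$delta)
  expect_identical(nom2$eta_min, nom$eta_min)
  expect_identical(nom2$axes$beta, nom$axes$beta)
  expect_equal(nom2$prob_table, nom$prob_table, tolerance = 0)
  ## scoring through the deserialized object is identical
  rec <- matrix(c(0.3, 1.1), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_identical(score(nom2, rec), score(nom, rec))
})

test_that("the stacked nomogram pipeline keeps rankings through the mapping", {
  co <- make_blobs(60L, sd = 1.2, seed = 19)
  ens <- train_base_models(co, models = c("dt", "rf", "xgb"), folds = 5,
                           seed = 3)
  st <- suppressWarnings(build_stacked_nomogram(ens, alpha = 1.0))
  expect_true(all(st$kept_models %in% c("dt", "rf", "xgb")))
  ## clinic-ML scores track the ML-axis scores monotonically
  eta_ml <- predict(st$ml_fit,
                    ens$meta_features[, st$kept_models, drop = FALSE],
                    type = "lp")
  eta_cml <- predict(st$clinic_ml_fit,
                     st$fma$CF[, st$clinic_ml_fit$covariate_names,
                               drop = FALSE], type = "lp")
  expect_gt(cor(eta_ml, eta_cml, method = "spearman"), 0.95)
})
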
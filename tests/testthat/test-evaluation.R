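test_that("confusion metrics match hand counts", {
  y <- rep(1:3, each = 10)
  expect_equal(confusion_metrics(y, y)[c("sensitivity", "specificity", "f1")],
               list(sensitivity = 1, specificity = 1, f1 = 1))
  ## constant 'high' prediction recalls one class only
  m <- confusion_metrics(y, rep(3L, 30))
  expect_equal(m$sensitivity, 1 / 3)
  ## binary collapse cross-checked against a hand-built 2x2 table
  yb <- c(1, 1, 1, 3, 3, 3, 3, 1)
  yh <- c(1, 3, 1, 3, 3, 1, 3, 1)
  mb <- confusion_metrics(yb, yh)
  ## class 1: TP=3 FN=1 FP=1 TN=3; class 3: TP=3 FN=1 FP=1 TN=3
  expect_equal(mb$sensitivity, 3 / 4)
  expect_equal(mb$specificity, 3 / 4)
  expect_equal(mb$f1, 3 / 4)
  expect_error(confusion_metrics(y, y[-1]), "length")
})

test_that("Mann-Whitney AUC equals exhaustive pair counting", {
  ## fixed 6-observation toy with a tie
  pos <- c(3, 5, 5)
  neg <- c(1, 5, 4)
  expect_equal(auc_mann_whitney(pos, neg), auc_bruteforce(pos, neg))
  withr::local_seed(23)
  for (rep in 1:30) {
    n1 <- sample(2:25, 1); n0 <- sample(2:25, 1)
    pos <- sample(1:10, n1, replace = TRUE)   # heavy ties
    neg <- sample(1:10, n0, replace = TRUE)
    expect_equal(auc_mann_whitney(pos, neg), auc_bruteforce(pos, neg))
  }
})

test_that("multiclass AUC behaves at the extremes and under the null", {
  y <- rep(1:3, each = 20)
  prob_perfect <- diag(3)[y, ]
  expect_equal(multiclass_auc(y, prob_perfect, "macro_ovr"), 1)
  expect_equal(multiclass_auc(y, seq_along(y), "ordinal_score"), 1)
  withr::local_seed(31)
  y_null <- sample(1:3, 2000, replace = TRUE)
  s_null <- rnorm(2000)
  expect_lt(abs(multiclass_auc(y_null, s_null, "ordinal_score") - 0.5), 0.03)
  ## absent class is skipped with a warning
  y2 <- rep(c(1L, 3L), 10)
  p2 <- matrix(runif(60), 20, 3); p2 <- p2 / rowSums(p2)
  expect_warning(a <- multiclass_auc(y2, p2, "macro_ovr"), "absent")
  expect_true(a >= 0 && a <= 1)
})

test_that("DeLong test handles identical scores and is antisymmetric", {
  withr::local_seed(6)
  y <- rep(0:1, each = 40)
  a <- rnorm(80) + y
  b <- 0.5 * a + rnorm(80, 0, 0.5)
  same <- delong_test(y, a, a)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  ab <- delong_test(y, a, b)
  ba <- delong_test(y, b, a)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  expect_gte(ab$var_diff, 0)
  expect_error(delong_test(y, rep(1, 80), rep(1, 80) + 0e0), NA)
})

test_that("DeLong agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(41)
  y <- rep(0:1, each = 60)
  a <- rnorm(120) + 0.8 * y
  b <- rnorm(120) + 0.4 * y
  ours <- delong_test(y, a, b)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                        pROC::roc(y, b, quiet = TRUE), method = "delong")
  expect_equal(abs(ours$z), abs(unname(ref$statistic)), tolerance = 1e-9)
  expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-9)
})

test_that("DeLong null p-values are uniform", {
  pvals <- vapply(1:500, function(s) {
    withr::with_seed(10000 + s, {
      y <- rep(0:1, each = 100)
      common <- rnorm(200)
      a <- common + rnorm(200)
      b <- common + rnorm(200)
      delong_test(y, a, b)$p
    })
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("DeLong variance tracks a bootstrap of the AUC difference", {
  withr::local_seed(52)
  y <- rep(0:1, each = 75)
  a <- rnorm(150) + 1.0 * y
  b <- 0.6 * a + rnorm(150, 0, 0.8)
  ours <- delong_test(y, a, b)
  boot <- withr::with_seed(99, vapply(1:2000, function(i) {
    idx1 <- sample(which(y == 1), replace = TRUE)
    idx0 <- sample(which(y == 0), replace = TRUE)
    auc_mann_whitney(a[idx1], a[idx0]) - auc_mann_whitney(b[idx1], b[idx0])
  }, numeric(1)))
  expect_lt(abs(ours$var_diff - var(boot)) / var(boot), 0.15)
})

test_that("decision curves obey their closed forms", {
  ## perfect predictor: NB(t) = prevalence everywhere
  y <- rep(c(1L, 3L), c(60, 40))
  p <- as.numeric(y == 3L)
  dc <- decision_curve(y, p)
  expect_equal(dc$net_benefit_model, rep(0.4, nrow(dc)), tolerance = 1e-12)
  expect_equal(dc$net_benefit_none, rep(0, nrow(dc)))
  ## treat-all crosses zero at t = prevalence
  f <- function(t) 0.4 - 0.6 * t / (1 - t)
  expect_equal(dc$net_benefit_all, f(dc$threshold), tolerance = 1e-12)
  expect_lt(abs(f(0.4)), 1e-12)
  ## random predictor never beats max(treat-all, 0) by more than noise
  withr::local_seed(61)
  worst <- vapply(1:100, function(i) {
    yy <- sample(rep(c(0L, 1L), c(120, 80)))
    pp <- runif(200)
    d <- decision_curve(yy, pp)
    max(d$net_benefit_model - pmax(d$net_benefit_all, 0))
  }, numeric(1))
  expect_lt(mean(worst), 0.05)
  expect_error(decision_curve(y, p, thresholds = c(0.5, 1)), "inside")
  expect_error(decision_curve(y, p * 2), "p_event")
})

test_that("stratified percentile bootstrap covers a known mean", {
  withr::local_seed(71)
  covered <- vapply(1:100, function(i) {
    x <- rnorm(80, mean = 2)
    ci <- bootstrap_ci(function(idx) mean(x[idx]), n = 80, n_boot = 200,
                       seed = i)
    ci$ci_low <= 2 && 2 <= ci$ci_high
  }, logical(1))
  expect_gt(mean(covered), 0.85)
  expect_lt(mean(covered), 1.0)
})

test_that("bootstrap_ci is deterministic and degenerates gracefully", {
  x <- rnorm(50)
  ci1 <- bootstrap_ci(function(idx) mean(x[idx]), 50, n_boot = 100, seed = 5)
  ci2 <- bootstrap_ci(function(idx) mean(x[idx]), 50, n_boot = 100, seed = 5)
  expect_identical(ci1, ci2)
  expect_warning(ci0 <- bootstrap_ci(function(idx) mean(x[idx]), 50,
                                     n_boot = 1, seed = 1), "degenerate")
  expect_equal(ci0$ci_low, ci0$point)
  expect_error(bootstrap_ci(function(idx) stop("no"), 50, n_boot = 100,
                            seed = 1), "resamples|no")
})

test_that("calibration curves behave for constant and well-specified models", {
  ## constant prediction collapses to one bin at (0.5, prevalence)
  co <- make_cohort(c(30L, 30L, 30L))
  cal <- calibration_curve(function(d) rep(0.5, n_patients(d)),
                           function(d) function(dd) rep(0.5, n_patients(dd)),
                           co, bins = 10, n_boot = 0, seed = 1)
  cal <- cal[!is.na(cal$pred), ]
  expect_equal(nrow(cal), 1L)
  expect_equal(cal$pred, 0.5)
  expect_equal(cal$obs_apparent, 2 / 3)
  ## predictions equal to the true event probabilities sit near the diagonal
  withr::local_seed(81)
  n <- 2000
  x <- rnorm(n)
  p_true <- plogis(x)
  risk <- 1L + rbinom(n, 1, p_true) * sample(1:2, n, replace = TRUE)
  dat <- cohort_table(cbind(x = x), risk = ifelse(risk > 3, 3L, risk))
  pfun <- function(d) plogis(d$features[, "x"])
  cal2 <- calibration_curve(pfun, function(d) pfun, dat, bins = 10,
                            n_boot = 0, seed = 1)
  expect_lt(max(abs(cal2$pred - cal2$obs_apparent), na.rm = TRUE), 0.08)
  expect_error(calibration_curve(pfun, function(d) pfun, dat, bins = 2000,
                                 n_boot = 0, seed = 1), "bins")
})

test_that("optimism correction pulls overfit calibration away from the apparent curve", {
  ## tiny sample + flexible learner = optimism; the corrected curve must
  ## sit farther from the diagonal than the apparent one
  worse <- vapply(1:5, function(s) {
    withr::with_seed(90 + s, {
      n <- 60
      x <- matrix(rnorm(n * 15), n, 15,
                  dimnames = list(NULL, paste0("v", 1:15)))
      co <- cohort_table(x, risk = sample(rep(1:3, each = n / 3)))
      refit <- function(d) {
        df <- data.frame(d$features, yy = as.integer(d$risk >= 2))
        m <- suppressWarnings(glm(yy ~ ., data = df, family = binomial))
        function(dd) {
          suppressWarnings(predict(m, data.frame(dd$features),
                                   type = "response"))
        }
      }
      cal <- calibration_curve(refit(co), refit, co, bins = 5,
                               n_boot = 40, seed = 3)
      dev_app <- mean(abs(cal$obs_apparent - cal$pred), na.rm = TRUE)
      dev_cor <- mean(abs(cal$obs_corrected - cal$pred), na.rm = TRUE)
      dev_cor > dev_app
    })
  }, logical(1))
  expect_true(all(worse))
})

test_that("the metric panel reports coherent intervals", {
  withr::local_seed(97)
  y <- rep(1:3, each = 30)
  prob <- diag(3)[y, ] * 0.7 + 0.1
  prob <- prob + matrix(runif(270, 0, 0.15), 90, 3)
  prob <- prob / rowSums(prob)
  pan <- metric_panel(y, prob, n_boot = 100, seed = 2)
  expect_setequal(pan$metric, c("sensitivity", "specificity", "f1", "auc"))
  expect_true(all(pan$ci_low <= pan$point + 1e-12))
  expect_true(all(pan$point <= pan$ci_high + 1e-12))
  expect_true(all(pan$point >= 0 & pan$point <= 1))
})
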
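test_that("read_cohort drops incomplete rows and reports the count", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,PSA,Age,risk",
               "A,4.2,61,1", "B,,72,3", "C,9.9,55,1", "D,130,68,3",
               "E,7.7,63,2"), path)
  expect_message(co <- read_cohort(path), "dropped 1 row")
  expect_equal(n_patients(co), 4L)
  expect_equal(attr(co, "n_dropped"), 1L)
  expect_equal(co$patient_id, c("A", "C", "D", "E"))
  expect_equal(co$risk, c(1L, 1L, 3L, 2L))
  expect_setequal(feature_names(co), c("PSA", "Age"))
})

test_that("read_cohort rejects header-only and missing files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("patient_id,PSA,Age,risk", path)
  expect_error(read_cohort(path), "empty cohort")
  expect_error(read_cohort(file.path(tempdir(), "nope.csv")), "cannot read")
})

test_that("cohort round-trips through write_cohort/read_cohort", {
  co <- make_cohort(c(5L, 5L, 5L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  co2 <- read_cohort(path)
  expect_equal(co2$features, co$features, tolerance = 1e-12)
  expect_equal(co2$risk, co$risk)
  expect_equal(co2$patient_id, co$patient_id)
})

test_that("truncation caps, floors, leaves in-range values, and is idempotent", {
  feats <- cbind(PSA = c(1500, 999.9, 3), `Interleukin-6` = c(0.8, 2.0, 1.5),
                 Age = c(60, 70, 80))
  co <- cohort_table(feats)
  rules <- list(cap_rule("PSA", "upper_cap", 1000),
                cap_rule("Interleukin-6", "lower_floor", 1.5))
  tr <- apply_truncation(co, rules)
  expect_equal(tr$features[, "PSA"], c(1000, 999.9, 3))
  expect_equal(tr$features[, "Interleukin-6"], c(1.5, 2.0, 1.5))
  expect_equal(tr$features[, "Age"], c(60, 70, 80))
  ## input untouched, operation idempotent
  expect_equal(unname(co$features[1, "PSA"]), 1500)
  expect_equal(apply_truncation(tr, rules)$features, tr$features)
  expect_error(apply_truncation(co, list(cap_rule("ALT", "lower_floor", 5))),
               "absent feature")
})

test_that("drop_feature removes exactly one column and guards repeats", {
  withr::local_seed(1)
  feats <- matrix(runif(42 * 5), 5, 42,
                  dimnames = list(NULL, c(paste0("f", 1:41),
                                          "Interleukin-10")))
  co <- cohort_table(feats)
  co2 <- drop_feature(co, "Interleukin-10")
  expect_equal(length(feature_names(co2)), 41L)
  expect_equal(nrow(co2$feature_meta), 41L)
  expect_error(drop_feature(co2, "Interleukin-10"), "absent feature")
})

test_that("min-max normalization matches its definition and is invertible", {
  co <- cohort_table(cbind(a = c(2, 4, 6), b = c(3, 3, 3)))
  expect_warning(nr <- min_max_normalize(co), "constant")
  expect_equal(nr$table$features[, "a"], c(0, 0.5, 1))
  expect_equal(nr$table$features[, "b"], c(0, 0, 0))
  ## round trip on non-constant features
  back <- denormalize(nr$table, nr$stats)
  expect_equal(back$features[, "a"], c(2, 4, 6), tolerance = 1e-12)
  ## larger random cohort, exact inverse
  co2 <- make_cohort(c(10L, 10L, 10L))
  nr2 <- min_max_normalize(co2)
  expect_true(all(nr2$table$features >= 0 & nr2$table$features <= 1))
  expect_equal(denormalize(nr2$table, nr2$stats)$features, co2$features,
               tolerance = 1e-12)
})

test_that("reusing normalization stats on held-out data clips to [0, 1]", {
  train <- cohort_table(cbind(a = c(2, 4, 6)))
  nr <- min_max_normalize(train)
  test <- cohort_table(cbind(a = c(1, 5, 10)))
  out <- min_max_normalize(test, nr$stats)$table
  expect_equal(out$features[, "a"], c(0, 0.75, 1))
})

test_that("guideline risk labeler applies the standard thresholds", {
  expect_equal(assign_risk_label(5, 1, "T1c"), 1L)
  expect_equal(assign_risk_label(25, 1, "T1c"), 3L)
  expect_equal(assign_risk_label(12, 2, "T2a"), 2L)
  ## any single high-risk criterion suffices
  expect_equal(assign_risk_label(c(5, 5), c(4, 1), c("T1c", "T2c")),
               c(3L, 3L))
  ## intermediate when neither low nor high rule fires
  expect_equal(assign_risk_label(5, 2, "T1c"), 2L)
  expect_error(assign_risk_label(5, 6, "T1c"), "ISUP")
  expect_error(assign_risk_label(5, 1, "T9"), "stage")
})

test_that("stratified 4:1 split reproduces per-group half-up rounding", {
  co <- make_cohort(c(59L, 48L, 90L))
  sp <- split_train_test(co, 0.2, seed = 3, stratified = TRUE)
  expect_equal(n_patients(sp$train), 157L)
  expect_equal(n_patients(sp$test), 40L)
  expect_equal(as.integer(table(sp$test$risk)), c(12L, 10L, 18L))
  expect_equal(as.integer(table(sp$train$risk)), c(47L, 38L, 72L))
})

test_that("splits are disjoint, exhaustive, seed-reproducible and id-safe", {
  co <- make_cohort(c(20L, 15L, 25L))
  sp1 <- split_train_test(co, 0.2, seed = 9)
  sp2 <- split_train_test(co, 0.2, seed = 9)
  expect_identical(sp1$test$patient_id, sp2$test$patient_id)
  ids <- c(sp1$train$patient_id, sp1$test$patient_id)
  expect_setequal(ids, co$patient_id)
  expect_equal(length(ids), n_patients(co))
  ## patient-label pairing survives the split
  for (part in sp1) {
    ix <- match(part$patient_id, co$patient_id)
    expect_equal(part$risk, co$risk[ix])
    expect_equal(part$features, co$features[ix, , drop = FALSE])
  }
  ## unstratified small case
  co10 <- make_cohort(c(4L, 3L, 3L))
  sp10 <- split_train_test(co10, 0.2, seed = 1, stratified = FALSE)
  expect_equal(n_patients(sp10$test), 2L)
  expect_equal(n_patients(sp10$train), 8L)
  ## tiny stratum
  expect_error(split_train_test(make_cohort(c(1L, 5L, 5L)), 0.2, seed = 1),
               "stratum")
  expect_error(split_train_test(co, 1.2, seed = 1), "test_fraction")
})

test_that("preprocessing config round-trips through YAML", {
  co <- make_cohort(c(5L, 5L, 5L))
  nr <- min_max_normalize(co)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_preprocess_config(path, rules = default_cap_rules(),
                          stats = nr$stats)
  cfg <- read_preprocess_config(path)
  expect_equal(length(cfg$rules), 4L)
  expect_equal(cfg$rules[[1]]$feature_name, "PSA")
  expect_equal(cfg$rules[[1]]$threshold, 1000)
  expect_equal(cfg$stats$min, nr$stats$min, tolerance = 1e-15)
  expect_equal(cfg$stats$max, nr$stats$max, tolerance = 1e-15)
  ## stats read back are usable
  out <- min_max_normalize(co, cfg$stats)
  expect_equal(out$table$features, nr$table$features, tolerance = 1e-12)
})
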
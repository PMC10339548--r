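#' Cohort tables
#'
#' A `cohort_table` is the package's central data container: a patient-by-
#' feature matrix of finite numeric clinical measurements, an optional
#' ordinal risk label per patient (1 = low, 2 = intermediate, 3 = high), and
#' per-feature metadata (unit, truncation rule).  All preprocessing
#' operations take and return `cohort_table` objects and never modify their
#' input.
#'
#' @param features numeric matrix or data frame, rows = patients, named
#'   columns = features.
#' @param risk optional integer vector of ordinal labels in `1:3` (`NA`
#'   allowed for unlabeled patients).
#' @param patient_id optional character vector of identifiers; generated as
#'   `"P0001"`, ... when absent.
#' @param feature_meta optional data frame with columns `name` and `unit`.
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(features, risk = NULL, patient_id = NULL,
                         feature_meta = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(colnames(features))) {
    stop("feature columns must be named", call. = FALSE)
  }
  if (anyDuplicated(colnames(features))) {
    stop("duplicate feature names", call. = FALSE)
  }
  n <- nrow(features)
  if (is.null(patient_id)) {
    patient_id <- sprintf("P%04d", seq_len(n))
  }
  patient_id <- as.character(patient_id)
  if (length(patient_id) != n) stop("patient_id length mismatch", call. = FALSE)
  if (anyDuplicated(patient_id)) stop("duplicate patient ids", call. = FALSE)
  if (!is.null(risk)) {
    risk <- as.integer(risk)
    if (length(risk) != n) stop("risk length mismatch", call. = FALSE)
    bad <- !is.na(risk) & !(risk %in% 1:3)
    if (any(bad)) {
      stop("risk labels must be 1 (low), 2 (intermediate) or 3 (high)",
           call. = FALSE)
    }
  }
  if (is.null(feature_meta)) {
    feature_meta <- data.frame(name = colnames(features), unit = "",
                               stringsAsFactors = FALSE)
  }
  if (!all(colnames(features) %in% feature_meta$name)) {
    stop("feature_meta does not cover every feature", call. = FALSE)
  }
  feature_meta <- feature_meta[match(colnames(features), feature_meta$name), ,
                               drop = FALSE]
  rownames(feature_meta) <- NULL
  structure(
    list(patient_id = patient_id, features = features, risk = risk,
         feature_meta = feature_meta),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  nlab <- if (is.null(x$risk)) 0L else sum(!is.na(x$risk))
  cat(sprintf("<cohort_table> %d patients x %d features (%d labeled)\n",
              nrow(x$features), ncol(x$features), nlab))
  if (nlab > 0L) {
    tab <- table(factor(x$risk, levels = 1:3,
                        labels = c("low", "intermediate", "high")))
    cat("  risk:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$features)

#' Number of patients in a cohort
#' @param table a `cohort_table`.
#' @return Integer row count.
#' @export
n_patients <- function(table) nrow(table$features)

#' Feature names of a cohort
#' @param table a `cohort_table`.
#' @return Character vector of feature (column) names.
#' @export
feature_names <- function(table) colnames(table$features)

## row-subset keeping id/label pairing intact
subset_rows <- function(table, idx) {
  cohort_table(table$features[idx, , drop = FALSE],
               risk = if (is.null(table$risk)) NULL else table$risk[idx],
               patient_id = table$patient_id[idx],
               feature_meta = table$feature_meta)
}

#' Read a delimited cohort file
#'
#' Reads a header-bearing delimited text file into a [cohort_table()].  Rows
#' containing any missing or non-numeric feature value are dropped (the
#' cohort-assembly convention here excludes incomplete records rather than
#' imputing them) and the exclusion count is reported via `message()` and the
#' `"n_dropped"` attribute.
#'
#' @param path file path.
#' @param sep field separator (default comma; use `"\t"` for TSV).
#' @param id_col,risk_col names of the optional identifier and ordinal
#'   outcome columns.  All remaining columns are treated as features.
#' @param schema optional character vector of required feature names; an
#'   error is raised if any is missing from the header.
#' @return A `cohort_table`; attribute `n_dropped` holds the number of
#'   excluded rows.
#' @export
read_cohort <- function(path, sep = ",", id_col = "patient_id",
                        risk_col = "risk", schema = NULL) {
  if (!file.exists(path)) stop("cannot read cohort file: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"), quote = "\"",
                           comment.char = "")
  feat_cols <- setdiff(names(raw), c(id_col, risk_col))
  if (!is.null(schema)) {
    missing <- setdiff(schema, feat_cols)
    if (length(missing)) {
      stop("cohort file lacks required features: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  if (nrow(raw) == 0L) stop("empty cohort: file has a header but no rows",
                            call. = FALSE)
  feats <- as.matrix(raw[, feat_cols, drop = FALSE])
  suppressWarnings(storage.mode(feats) <- "double")
  keep <- stats::complete.cases(feats)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(sprintf("read_cohort: dropped %d row(s) with missing/non-numeric values",
                    n_dropped))
  }
  if (!any(keep)) stop("empty cohort: no rows survive quality control",
                       call. = FALSE)
  risk <- NULL
  if (risk_col %in% names(raw)) {
    risk <- suppressWarnings(as.integer(raw[[risk_col]]))
  }
  ids <- if (id_col %in% names(raw)) as.character(raw[[id_col]]) else NULL
  out <- cohort_table(feats[keep, , drop = FALSE],
                      risk = if (is.null(risk)) NULL else risk[keep],
                      patient_id = if (is.null(ids)) NULL else ids[keep])
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a cohort to delimited text
#' @param table a `cohort_table`.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path, sep = ",") {
  df <- data.frame(patient_id = table$patient_id, check.names = FALSE)
  df <- cbind(df, as.data.frame(table$features, check.names = FALSE))
  if (!is.null(table$risk)) df$risk <- table$risk
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Truncation (cap/floor) rules
#'
#' Measurement-driven truncation: assay ceilings are expressed as upper caps
#' (values above the threshold are recorded at the threshold) and detection
#' limits as lower floors.  At most one rule per feature.
#'
#' @param feature_name feature the rule applies to.
#' @param kind `"upper_cap"` or `"lower_floor"`.
#' @param threshold finite numeric threshold in feature units.
#' @return A `cap_rule` object.
#' @export
cap_rule <- function(feature_name, kind = c("upper_cap", "lower_floor"),
                     threshold) {
  kind <- match.arg(kind)
  stopifnot_scalar_number(threshold, "threshold")
  structure(list(feature_name = feature_name, kind = kind,
                 threshold = threshold), class = "cap_rule")
}

#' Default truncation rules for the prostate-cancer immunophenotype panel
#'
#' PSA is capped at 1000 ng/mL (assay ceiling); ALT, Interleukin-6 and
#' Interleukin-1b are floored at their measurement detection limits of 5,
#' 1.5 and 5 respectively.
#' @return A list of [cap_rule()] objects.
#' @export
default_cap_rules <- function() {
  list(cap_rule("PSA", "upper_cap", 1000),
       cap_rule("ALT", "lower_floor", 5),
       cap_rule("Interleukin-6", "lower_floor", 1.5),
       cap_rule("Interleukin-1b", "lower_floor", 5))
}

#' Apply truncation rules to a cohort
#'
#' @param table a `cohort_table`.
#' @param rules list of [cap_rule()] objects; rules naming features absent
#'   from `table` raise an error unless `skip_missing = TRUE`.
#' @param skip_missing silently ignore rules for absent features.
#' @return A new `cohort_table` with values truncated; idempotent.
#' @export
apply_truncation <- function(table, rules, skip_missing = FALSE) {
  if (inherits(rules, "cap_rule")) rules <- list(rules)
  feats <- table$features
  seen <- character(0)
  for (rule in rules) {
    nm <- rule$feature_name
    if (!nm %in% colnames(feats)) {
      if (skip_missing) next
      stop("truncation rule names absent feature: ", nm, call. = FALSE)
    }
    if (nm %in% seen) stop("multiple truncation rules for feature: ", nm,
                           call. = FALSE)
    seen <- c(seen, nm)
    x <- feats[, nm]
    feats[, nm] <- switch(rule$kind,
                          upper_cap = pmin(x, rule$threshold),
                          lower_floor = pmax(x, rule$threshold))
  }
  cohort_table(feats, risk = table$risk, patient_id = table$patient_id,
               feature_meta = table$feature_meta)
}

#' Drop a feature column
#' @param table a `cohort_table`.
#' @param name feature to remove.
#' @return The cohort with one fewer feature; metadata updated.
#' @export
drop_feature <- function(table, name) {
  if (!name %in% colnames(table$features)) {
    stop("cannot drop absent feature: ", name, call. = FALSE)
  }
  keep <- setdiff(colnames(table$features), name)
  cohort_table(table$features[, keep, drop = FALSE], risk = table$risk,
               patient_id = table$patient_id,
               feature_meta = table$feature_meta[
                 table$feature_meta$name %in% keep, , drop = FALSE])
}

#' Min-max normalization
#'
#' Rescales every feature to `[0, 1]` as `(x - min) / (max - min)`.  When
#' `stats` is supplied (e.g. statistics fitted on a training cohort applied
#' to held-out data) the same affine map is reused and the result is clipped
#' to `[0, 1]`.  Constant features map to 0 with a warning rather than being
#' dropped, so downstream selection can discard them on its own evidence.
#'
#' @param table a `cohort_table`.
#' @param stats optional `norm_stats` object from a previous call.
#' @return A list with elements `table` (normalized cohort) and `stats`
#'   (a `norm_stats` data frame of per-feature min/max, reusable and
#'   invertible via [denormalize()]).
#' @export
min_max_normalize <- function(table, stats = NULL) {
  feats <- table$features
  if (is.null(stats)) {
    if (nrow(feats) == 0L) stop("cannot fit normalization on an empty cohort",
                                call. = FALSE)
    stats <- structure(
      data.frame(name = colnames(feats),
                 min = apply(feats, 2, min),
                 max = apply(feats, 2, max),
                 stringsAsFactors = FALSE, row.names = NULL),
      class = c("norm_stats", "data.frame"))
    clip <- FALSE
  } else {
    if (!identical(sort(stats$name), sort(colnames(feats)))) {
      stop("normalization stats do not match cohort features", call. = FALSE)
    }
    clip <- TRUE
  }
  stats <- stats[match(colnames(feats), stats$name), , drop = FALSE]
  rng <- stats$max - stats$min
  const <- rng == 0
  if (any(const)) {
    warning("constant feature(s) normalized to 0: ",
            paste(stats$name[const], collapse = ", "), call. = FALSE)
  }
  scaled <- sweep(feats, 2, stats$min, `-`)
  scaled <- sweep(scaled, 2, ifelse(const, 1, rng), `/`)
  scaled[, const] <- 0
  if (clip) scaled <- pmin(pmax(scaled, 0), 1)
  out <- cohort_table(scaled, risk = table$risk,
                      patient_id = table$patient_id,
                      feature_meta = table$feature_meta)
  list(table = out, stats = stats)
}

#' Invert a min-max normalization
#' @param table normalized `cohort_table`.
#' @param stats the `norm_stats` used to normalize.
#' @return A `cohort_table` on the original scale (constant features return
#'   at their stored minimum).
#' @export
denormalize <- function(table, stats) {
  stats <- stats[match(colnames(table$features), stats$name), , drop = FALSE]
  feats <- sweep(table$features, 2, stats$max - stats$min, `*`)
  feats <- sweep(feats, 2, stats$min, `+`)
  cohort_table(feats, risk = table$risk, patient_id = table$patient_id,
               feature_meta = table$feature_meta)
}

#' Guideline-style tripartite risk labels
#'
#' Standard three-tier prostate-cancer risk assignment from PSA, ISUP grade
#' group and clinical T stage: low risk when PSA < 10 ng/mL, ISUP 1 and
#' stage at most T2a; high risk when PSA > 20 ng/mL, ISUP >= 4 or stage T2c
#' or beyond; intermediate otherwise.  This is a convenience labeler with
#' the field's conventional thresholds; cohorts labeled by other criteria
#' can supply labels directly.
#'
#' @param psa PSA in ng/mL (vectorized).
#' @param isup_grade ISUP grade group, integers 1-5.
#' @param stage_code clinical T stage code, one of `"T1a"`, `"T1b"`, `"T1c"`,
#'   `"T2a"`, `"T2b"`, `"T2c"`, `"T3a"`, `"T3b"`, `"T4"`.
#' @return Integer labels: 1 low, 2 intermediate, 3 high.
#' @export
assign_risk_label <- function(psa, isup_grade, stage_code) {
  stages <- c("T1a", "T1b", "T1c", "T2a", "T2b", "T2c", "T3a", "T3b", "T4")
  n <- max(length(psa), length(isup_grade), length(stage_code))
  psa <- rep_len(psa, n)
  isup_grade <- rep_len(as.integer(isup_grade), n)
  stage_code <- rep_len(as.character(stage_code), n)
  if (any(!is.finite(psa) | psa < 0)) {
    stop("PSA must be finite and nonnegative", call. = FALSE)
  }
  if (any(!isup_grade %in% 1:5)) {
    stop("ISUP grade group must be an integer in 1..5", call. = FALSE)
  }
  stage_ord <- match(stage_code, stages)
  if (anyNA(stage_ord)) {
    stop("unknown stage code: ",
         paste(unique(stage_code[is.na(stage_ord)]), collapse = ", "),
         call. = FALSE)
  }
  t2a <- match("T2a", stages)
  t2c <- match("T2c", stages)
  high <- psa > 20 | isup_grade >= 4 | stage_ord >= t2c
  low <- !high & psa < 10 & isup_grade == 1 & stage_ord <= t2a
  ifelse(high, 3L, ifelse(low, 1L, 2L))
}

## per-stratum test size: round half away from zero, matching 4:1-style
## splits where e.g. strata 59/48/90 at 0.2 give 12/10/18 test patients
round_half_up <- function(x) floor(x + 0.5)

#' Train/test split
#'
#' Random partition of a cohort into disjoint, exhaustive train and test
#' subsets.  With `stratified = TRUE` (default) the split is performed per
#' risk group, each group contributing `round(n_g * test_fraction)` test
#' patients (half-up rounding), so e.g. a 197-patient cohort with groups
#' 59/48/90 at `test_fraction = 0.2` yields per-group test counts 12/10/18
#' and a 157/40 overall split.
#'
#' @param table labeled `cohort_table` (labels required when stratified).
#' @param test_fraction fraction held out, in (0, 1); default 0.2 (a 4:1
#'   train:test ratio).
#' @param seed integer seed; the same seed reproduces the same partition.
#' @param stratified stratify by risk label (default) or split completely at
#'   random.
#' @return A list with `cohort_table` elements `train` and `test`.
#' @export
split_train_test <- function(table, test_fraction = 0.2, seed = 1L,
                             stratified = TRUE) {
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- n_patients(table)
  idx_test <- with_seed(seed, {
    if (stratified) {
      if (is.null(table$risk) || anyNA(table$risk)) {
        stop("stratified split requires complete risk labels", call. = FALSE)
      }
      groups <- split(seq_len(n), table$risk)
      if (any(lengths(groups) < 2L)) {
        stop("every stratum needs at least 2 patients to split", call. = FALSE)
      }
      unlist(lapply(groups, function(ix) {
        k <- round_half_up(length(ix) * test_fraction)
        k <- max(min(k, length(ix) - 1L), 0L)
        sample(ix, k)
      }), use.names = FALSE)
    } else {
      sample(seq_len(n), round_half_up(n * test_fraction))
    }
  })
  idx_test <- sort(idx_test)
  idx_train <- setdiff(seq_len(n), idx_test)
  list(train = subset_rows(table, idx_train),
       test = subset_rows(table, idx_test))
}

#' Serialize truncation rules and normalization statistics
#'
#' Writes cap rules and/or normalization min/max statistics to a
#' human-readable YAML file so a preprocessing configuration fitted on one
#' cohort can be re-applied to another.
#'
#' @param path output file.
#' @param rules optional list of [cap_rule()] objects.
#' @param stats optional `norm_stats` object.
#' @return `path`, invisibly.
#' @export
write_preprocess_config <- function(path, rules = NULL, stats = NULL) {
  obj <- list()
  if (!is.null(rules)) {
    obj$cap_rules <- lapply(rules, function(r) {
      list(feature = r$feature_name, kind = r$kind, threshold = r$threshold)
    })
  }
  if (!is.null(stats)) {
    obj$normalization <- lapply(seq_len(nrow(stats)), function(i) {
      list(feature = stats$name[i], min = stats$min[i], max = stats$max[i])
    })
  }
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' Read a preprocessing configuration written by [write_preprocess_config()]
#' @param path YAML file path.
#' @return A list with elements `rules` (list of `cap_rule`) and `stats`
#'   (`norm_stats` or `NULL`).
#' @export
read_preprocess_config <- function(path) {
  obj <- yaml::read_yaml(path)
  rules <- lapply(obj$cap_rules, function(r) {
    cap_rule(r$feature, r$kind, r$threshold)
  })
  stats <- NULL
  if (!is.null(obj$normalization)) {
    stats <- structure(
      data.frame(name = vapply(obj$normalization, `[[`, "", "feature"),
                 min = vapply(obj$normalization, `[[`, 0, "min"),
                 max = vapply(obj$normalization, `[[`, 0, "max"),
                 stringsAsFactors = FALSE),
      class = c("norm_stats", "data.frame"))
  }
  list(rules = rules, stats = stats)
}
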
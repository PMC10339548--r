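## ---------------------------------------------------------------------------
## Base-learner registry
##
## Each entry provides fit(x, y) -> model and prob(model, x) -> n x K matrix
## of class probabilities (columns in level order), plus an optional native
## importance extractor.  All learners receive the same min-max-normalized
## design, so tree learners run unscaled and the SVM disables its internal
## scaling.
## ---------------------------------------------------------------------------

learner_registry <- function() {
  list(
    svm = list(
      fit = function(x, y) {
        e1071::svm(x = x, y = y, probability = TRUE, kernel = "radial",
                   scale = FALSE)
      },
      prob = function(model, x) {
        p <- attr(predict(model, x, probability = TRUE), "probabilities")
        p[, model$levels, drop = FALSE]
      },
      importance = NULL                       # no native attribution
    ),
    dt = list(
      fit = function(x, y) {
        df <- as.data.frame(x)
        names(df) <- make.names(colnames(x), unique = TRUE)
        df$.y <- y
        rpart::rpart(.y ~ ., data = df, method = "class",
                     control = rpart::rpart.control(cp = 0.01, xval = 0))
      },
      prob = function(model, x) {
        df <- as.data.frame(x)
        names(df) <- make.names(colnames(x), unique = TRUE)
        predict(model, df, type = "prob")
      },
      importance = function(model, feature_names) {
        imp <- setNames(numeric(length(feature_names)),
                        make.names(feature_names, unique = TRUE))
        vi <- model$variable.importance
        if (!is.null(vi)) imp[names(vi)] <- vi
        setNames(as.numeric(imp), feature_names)
      }
    ),
    rf = list(
      fit = function(x, y) {
        randomForest::randomForest(x = x, y = y, ntree = 500)
      },
      prob = function(model, x) {
        predict(model, x, type = "prob")
      },
      importance = function(model, feature_names) {
        vi <- randomForest::importance(model)[, "MeanDecreaseGini"]
        setNames(as.numeric(vi[feature_names]), feature_names)
      }
    ),
    xgb = list(
      fit = function(x, y) {
        xgboost::xgboost(x, y, nrounds = 100L, max_depth = 3L,
                         learning_rate = 0.3, nthreads = 1L, verbosity = 0L)
      },
      prob = function(model, x) {
        predict(model, x, type = "response")
      },
      importance = function(model, feature_names) {
        imp <- setNames(numeric(length(feature_names)), feature_names)
        tab <- xgboost::xgb.importance(model = model)
        imp[tab$Feature] <- tab$Gain
        imp
      }
    ),
    ada = list(
      fit = function(x, y) adaboost_fit(x, y),
      prob = function(model, x) predict(model, x),
      importance = function(model, feature_names) {
        adaboost_importance(model)
      }
    )
  )
}

#' Names of the available base learners
#' @return `c("svm", "dt", "rf", "xgb", "ada")`: radial-kernel support
#'   vector machine, CART decision tree, random forest, gradient-boosted
#'   trees and SAMME AdaBoost.
#' @export
available_learners <- function() names(learner_registry())

clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1)

## learner back ends return rows summing to 1 only within float slop;
## renormalize so downstream simplex invariants hold exactly
normalize_rows <- function(p) p / rowSums(p)

oof_logloss <- function(probs, y_int) {
  -mean(log(clamp_prob(probs[cbind(seq_along(y_int), y_int)])))
}

#' Train the stacked base-learner ensemble
#'
#' Fits each requested classifier under stratified k-fold cross-validation
#' to obtain an out-of-fold (OOF) class-probability vector for every
#' training patient — each patient is predicted exactly once, by a model
#' that never saw it — then refits each classifier on the full training set
#' for test-time use.  OOF probabilities are scalarized (see [scalarize()])
#' into the per-model meta-features that feed the ordinal stacking
#' regression, and per-model normalized feature-importance vectors are
#' extracted for the feature-mapping step.
#'
#' @param train labeled [cohort_table()].
#' @param models character subset of [available_learners()].
#' @param folds CV folds (default 10).
#' @param seed integer seed covering fold assignment and all stochastic
#'   learners.
#' @param scalarization `"expected_rank"` (default) or `"prob_high"`;
#'   see [scalarize()].
#' @param importance `"native"` (model's own attribution; the SVM, which has
#'   none, falls back to permutation) or `"permutation"` for all models.
#' @param importance_repeats permutation repeats (default 10).
#' @param in_sample use refit in-sample predictions instead of OOF
#'   predictions as meta-features (more optimistic; default `FALSE`).
#' @return An `ensemble_fit` with `model_names`, per-model `oof_probs`,
#'   `meta_features` (patients x models), `importances` (features x models,
#'   columns on the simplex), refit models and fold models.
#' @export
train_base_models <- function(train, models = available_learners(),
                              folds = 10L, seed = 1L,
                              scalarization = c("expected_rank", "prob_high"),
                              importance = c("native", "permutation"),
                              importance_repeats = 10L,
                              in_sample = FALSE) {
  scalarization <- match.arg(scalarization)
  importance <- match.arg(importance)
  registry <- learner_registry()
  unknown <- setdiff(models, names(registry))
  if (length(unknown)) stop("unknown learner(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  if (is.null(train$risk) || anyNA(train$risk)) {
    stop("training cohort must be fully labeled", call. = FALSE)
  }
  y <- factor(train$risk, levels = 1:3)
  if (min(table(y)) < folds) {
    stop("a class has fewer members than folds; reduce `folds` so every ",
         "fold contains all classes", call. = FALSE)
  }
  x <- train$features
  n <- nrow(x)
  foldid <- stratified_folds(train$risk, folds, seed)
  fits <- with_seed(seed + 1L, {
    lapply(models, function(mn) {
      lrn <- registry[[mn]]
      oof <- matrix(NA_real_, n, 3, dimnames = list(NULL, levels(y)))
      fold_models <- vector("list", folds)
      for (f in seq_len(folds)) {
        hold <- foldid == f
        fm <- lrn$fit(x[!hold, , drop = FALSE], droplevels(y[!hold]))
        fold_models[[f]] <- fm
        p <- lrn$prob(fm, x[hold, , drop = FALSE])
        oof[hold, colnames(p)] <- p
      }
      oof[is.na(oof)] <- 0
      oof <- normalize_rows(oof)
      refit <- lrn$fit(x, y)
      list(name = mn, oof = oof, refit = refit, fold_models = fold_models)
    })
  })
  names(fits) <- models
  oof_probs <- lapply(fits, `[[`, "oof")
  source_probs <- if (in_sample) {
    lapply(models, function(mn) {
      normalize_rows(registry[[mn]]$prob(fits[[mn]]$refit, x))
    })
  } else {
    oof_probs
  }
  meta <- vapply(source_probs, scalarize, numeric(n), method = scalarization)
  colnames(meta) <- models
  ens <- structure(
    list(model_names = models, levels = levels(y),
         oof_probs = oof_probs, meta_features = meta,
         refit = lapply(fits, `[[`, "refit"),
         fold_models = lapply(fits, `[[`, "fold_models"),
         foldid = foldid, x = x, y_int = as.integer(y),
         scalarization = scalarization, in_sample = in_sample,
         seed = seed),
    class = "ensemble_fit")
  imp <- matrix(vapply(models, function(mn) {
    feature_importance(ens, mn, method = importance,
                       repeats = importance_repeats, seed = seed + 2L)
  }, numeric(ncol(x))), nrow = ncol(x),
  dimnames = list(colnames(x), models))
  ens$importances <- imp
  ens
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat(sprintf("<ensemble_fit> %d models (%s), %d patients, %d-fold OOF, scalarization=%s\n",
              length(x$model_names), paste(x$model_names, collapse = ","),
              nrow(x$meta_features), max(x$foldid), x$scalarization))
  invisible(x)
}

#' Scalarize a class-probability matrix
#'
#' Collapses a three-class probability vector to the single covariate used
#' on a nomogram axis.  `"expected_rank"` returns the expected ordinal level
#' `1*p1 + 2*p2 + 3*p3` (range `[1, 3]`, preserves ordering information);
#' `"prob_high"` returns the high-risk probability `p3`.
#'
#' @param probs numeric matrix, rows = patients, 3 columns summing to 1.
#' @param method `"expected_rank"` or `"prob_high"`.
#' @return Numeric vector, one value per patient.
#' @export
scalarize <- function(probs, method = c("expected_rank", "prob_high")) {
  method <- match.arg(method)
  probs <- as.matrix(probs)
  if (ncol(probs) != 3L) stop("probs must have 3 columns", call. = FALSE)
  if (any(probs < -1e-9) || any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("probability rows must be nonnegative and sum to 1", call. = FALSE)
  }
  switch(method,
         expected_rank = drop(probs %*% c(1, 2, 3)),
         prob_high = probs[, 3])
}

#' Normalized feature importance of a trained base learner
#'
#' Returns a nonnegative vector over the training features summing to 1
#' (a simplex vector, as the feature-mapping algorithm requires).
#' `"native"` uses the model's own attribution (tree impurity reduction or
#' boosting gain); models without one (the SVM) fall back to permutation
#' with a warning.  `"permutation"` shuffles one feature at a time
#' (`repeats` times) and scores the increase in out-of-fold log-loss,
#' flooring negative raw importances at zero before normalizing; if no
#' feature is informative the vector is uniform.
#'
#' @param ensemble an `ensemble_fit`.
#' @param model name of the model within the ensemble.
#' @param method `"native"` or `"permutation"`.
#' @param repeats permutation repeats (default 10).
#' @param seed integer seed for the permutations.
#' @return Named numeric vector on the simplex (sums to 1).
#' @export
feature_importance <- function(ensemble, model,
                               method = c("native", "permutation"),
                               repeats = 10L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(ensemble, "ensemble_fit"))
  if (!model %in% ensemble$model_names) {
    stop("model not in ensemble: ", model, call. = FALSE)
  }
  registry <- learner_registry()
  feature_names <- colnames(ensemble$x)
  if (method == "native") {
    extractor <- registry[[model]]$importance
    if (is.null(extractor)) {
      warning("model '", model,
              "' has no native importance; using permutation", call. = FALSE)
      method <- "permutation"
    } else {
      raw <- extractor(ensemble$refit[[model]], feature_names)
    }
  }
  if (method == "permutation") {
    raw <- permutation_importance(ensemble, model, repeats, seed)
  }
  raw <- pmax(raw, 0)
  if (sum(raw) <= 0) raw <- rep(1, length(raw))
  setNames(raw / sum(raw), feature_names)
}

## mean increase in out-of-fold log-loss when one feature is shuffled
permutation_importance <- function(ensemble, model, repeats, seed) {
  registry <- learner_registry()
  prob_fn <- registry[[model]]$prob
  fold_models <- ensemble$fold_models[[model]]
  foldid <- ensemble$foldid
  x <- ensemble$x
  y_int <- ensemble$y_int
  levels_ <- ensemble$levels
  oof_for <- function(xmat) {
    oof <- matrix(0, nrow(xmat), 3, dimnames = list(NULL, levels_))
    for (f in seq_along(fold_models)) {
      hold <- foldid == f
      p <- prob_fn(fold_models[[f]], xmat[hold, , drop = FALSE])
      oof[hold, colnames(p)] <- p
    }
    oof
  }
  base <- oof_logloss(oof_for(x), y_int)
  with_seed(seed, {
    vapply(seq_len(ncol(x)), function(j) {
      mean(vapply(seq_len(repeats), function(r) {
        xp <- x
        xp[, j] <- sample(xp[, j])
        oof_logloss(oof_for(xp), y_int) - base
      }, numeric(1)))
    }, numeric(1))
  })
}

#' Meta-features for new data from the refit base models
#'
#' @param object an `ensemble_fit`.
#' @param newdata a `cohort_table` or numeric matrix with the training
#'   feature columns.
#' @param type `"meta"` (scalarized matrix, default) or `"prob"` (list of
#'   per-model probability matrices).
#' @param ... unused.
#' @return Matrix of meta-features (patients x models) or list of
#'   probability matrices.
#' @export
predict.ensemble_fit <- function(object, newdata, type = c("meta", "prob"),
                                 ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "cohort_table")) newdata$features else
    as.matrix(newdata)
  x <- x[, colnames(object$x), drop = FALSE]
  registry <- learner_registry()
  probs <- lapply(object$model_names, function(mn) {
    p <- registry[[mn]]$prob(object$refit[[mn]], x)
    normalize_rows(p[, object$levels, drop = FALSE])
  })
  names(probs) <- object$model_names
  if (type == "prob") return(probs)
  meta <- vapply(probs, scalarize, numeric(nrow(x)),
                 method = object$scalarization)
  if (nrow(x) == 1L) meta <- matrix(meta, nrow = 1,
                                    dimnames = list(NULL, object$model_names))
  colnames(meta) <- object$model_names
  meta
}
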
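#' Multiclass AdaBoost (SAMME) over shallow classification trees
#'
#' Stagewise additive boosting with the multiclass exponential-loss weight
#' update: at each round a depth-limited \pkg{rpart} tree is fitted under
#' the current case weights, its weighted error `e` determines the stage
#' weight `alpha = log((1 - e)/e) + log(K - 1)`, and misclassified cases are
#' up-weighted.  Rounds with `e >= 1 - 1/K` (no better than chance) stop the
#' loop; a perfect round keeps a large finite stage weight and stops early.
#'
#' @param x numeric feature matrix.
#' @param y factor outcome (any number of classes >= 2).
#' @param n_rounds maximum boosting rounds (default 50).
#' @param maxdepth tree depth per round (default 3).
#' @return An `adaboost` object with the fitted trees, stage weights and
#'   class levels.
#' @export
adaboost_fit <- function(x, y, n_rounds = 50L, maxdepth = 3L) {
  y <- droplevels(as.factor(y))
  K <- nlevels(y)
  stopifnot(K >= 2)
  df <- as.data.frame(x)
  names(df) <- make.names(colnames(x), unique = TRUE)
  n <- nrow(df)
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    df$.y <- y
    tree <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                         control = rpart::rpart.control(maxdepth = maxdepth,
                                                        cp = 0, minsplit = 5,
                                                        xval = 0))
    pred <- predict(tree, df, type = "class")
    miss <- pred != y
    err <- sum(w[miss]) / sum(w)
    if (err >= 1 - 1 / K) {
      if (length(trees) == 0L) {        # keep one tree even if weak
        trees[[1]] <- tree
        alphas <- 1e-3
      }
      break
    }
    alpha <- if (err <= 0) log(1e10) else log((1 - err) / err) + log(K - 1)
    trees[[length(trees) + 1L]] <- tree
    alphas <- c(alphas, alpha)
    if (err <= 0) break
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  structure(list(trees = trees, alphas = alphas, levels = levels(y),
                 feature_names = colnames(x)),
            class = "adaboost")
}

#' Class-probability predictions from a SAMME ensemble
#'
#' Probabilities are the stage-weight-normalized vote shares of the
#' constituent trees.
#'
#' @param object an `adaboost` fit.
#' @param newdata numeric feature matrix with the training columns.
#' @param ... unused.
#' @return Matrix of class probabilities (rows sum to 1), columns in level
#'   order.
#' @export
predict.adaboost <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)
  names(df) <- make.names(object$feature_names, unique = TRUE)
  K <- length(object$levels)
  votes <- matrix(0, nrow(df), K, dimnames = list(NULL, object$levels))
  for (m in seq_along(object$trees)) {
    pred <- predict(object$trees[[m]], df, type = "class")
    votes[cbind(seq_len(nrow(df)), as.integer(pred))] <-
      votes[cbind(seq_len(nrow(df)), as.integer(pred))] + object$alphas[m]
  }
  votes / rowSums(votes)
}

## stage-weighted sum of per-tree impurity importances
adaboost_importance <- function(object) {
  imp <- setNames(numeric(length(object$feature_names)),
                  make.names(object$feature_names, unique = TRUE))
  for (m in seq_along(object$trees)) {
    vi <- object$trees[[m]]$variable.importance
    if (!is.null(vi)) imp[names(vi)] <- imp[names(vi)] + object$alphas[m] * vi
  }
  setNames(as.numeric(imp), object$feature_names)
}
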
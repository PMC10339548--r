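## Shared fixture builders; everything is generated in code.

## deterministic labeled cohort with exact per-group sizes
make_cohort <- function(group_sizes = c(59L, 48L, 90L), seed = 11L) {
  risk <- rep(1:3, times = group_sizes)
  n <- length(risk)
  withr::with_seed(seed, {
    feats <- cbind(PSA = exp(rnorm(n, 1 + risk, 0.8)),
                   Age = rnorm(n, 60 + 2 * risk, 6),
                   Marker = runif(n))
    cohort_table(feats, risk = risk)
  })
}

## three well-separated Gaussian blobs (linearly separable classes)
make_blobs <- function(n_per_class = 100L, sd = 0.5, seed = 5L) {
  centers <- rbind(c(0, 0), c(4, 0), c(0, 4))
  withr::with_seed(seed, {
    risk <- rep(1:3, each = n_per_class)
    feats <- centers[risk, ] + matrix(rnorm(2 * length(risk), 0, sd),
                                      ncol = 2)
    colnames(feats) <- c("f1", "f2")
    cohort_table(feats, risk = risk)
  })
}

## draw from a proportional-odds model P(Y <= k) = plogis(theta_k - x'beta)
simulate_po <- function(n, beta, theta, seed = NULL) {
  draw <- function() {
    p <- length(beta)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    eta <- drop(X %*% beta)
    u <- runif(n)
    y <- rep(1L, n)
    for (k in seq_along(theta)) y <- y + (u > plogis(theta[k] - eta))
    list(X = X, y = y)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

## random simplex vector of length m
rsimplex <- function(m) {
  w <- rexp(m)
  w / sum(w)
}

## brute-force AUC by counting all (pos, neg) pairs, ties = 1/2
auc_bruteforce <- function(pos, neg) {
  s <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(s)
}
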
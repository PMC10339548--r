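#' @importFrom stats plogis qlogis rnorm qnorm pnorm qlnorm runif sd quantile
#'   optim lm coef predict var rbinom complete.cases setNames aggregate
#'   p.adjust rank median
#' @importFrom utils read.table write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed
#'
#' All stochastic routines in the package funnel their seed through this
#' helper so the caller's RNG stream is left untouched.
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}

## format doubles so they survive a text round trip bit-exactly
format_full <- function(x) sprintf("%.17g", x)
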
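#' @importFrom rlang %||% abort warn .data
#' @importFrom stats rnorm rbinom rpois rgamma runif plogis qnorm pnorm
#' @importFrom stats sd var median quantile complete.cases model.matrix
#' @importFrom stats dnorm dpois dgamma pchisq pf pt p.adjust uniroot rlnorm
#' @importFrom stats gaussian poisson Gamma reformulate setNames cor coef lm
NULL

# deterministic child-seed derivation so pipeline stages can be re-run
# independently; kept strictly below 2^31 - 1
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index))
  as.integer((abs(seed) * 48271 + index * 16807) %% 2147483629L)
}

assert_count <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    abort(sprintf("`%s` must be a single positive integer.", name))
  }
  as.integer(x)
}

assert_fraction <- function(x, name = deparse(substitute(x)), open_left = FALSE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || x > 1) {
    abort(sprintf("`%s` must be a fraction in %s0, 1].", name,
                  if (open_left) "(" else "["))
  }
  as.numeric(x)
}
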
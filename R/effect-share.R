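#' Local gradients of a partial effect on the integer score grid
#'
#' Central differences `(est(s+1) - est(s-1)) / 2` at interior scores and
#' one-sided differences at the endpoints, so a quadratic is differentiated
#' exactly at interior points and an affine effect yields a constant
#' gradient everywhere. For log-link models the response-scale estimates are
#' used by default, matching the back-transform-before-interpretation
#' convention.
#'
#' @param pe A [partial_effect()] on a complete integer grid (0..30 for
#'   LSNS), or a bare numeric vector of estimates on consecutive integer
#'   scores.
#' @param scale `"response"` (default; identical to link scale for identity
#'   links) or `"link"`.
#' @return Numeric vector of per-score gradients, same length as the grid.
#' @export
#' @examples
#' local_gradients((0:30)^2)  # interior gradients 2 * s, exactly
local_gradients <- function(pe, scale = c("response", "link")) {
  scale <- match.arg(scale)
  if (inherits(pe, "partial_effect")) {
    g <- pe$grid
    if (!isTRUE(all.equal(diff(g), rep(1, length(g) - 1))))
      abort("partial effect must be evaluated on a complete unit-spaced grid.")
    est <- if (scale == "response" && attr(pe, "link") == "log")
      pe$response_estimate else pe$estimate
  } else {
    est <- as.numeric(pe)
  }
  n <- length(est)
  if (n < 3) abort("need at least 3 grid points.")
  grad <- numeric(n)
  grad[1] <- est[2] - est[1]
  grad[n] <- est[n] - est[n - 1]
  grad[2:(n - 1)] <- (est[3:n] - est[1:(n - 2)]) / 2
  grad
}

#' Share of the total absolute effect below the isolation cutoff
#'
#' Weights each score's absolute local gradient by the score's relative
#' frequency and splits the total between scores below the cutoff (the
#' socially isolated, scores 0..cutoff-1) and the rest:
#' `share_below = sum_{s < cutoff} |g(s)| f(s) / sum_s |g(s)| f(s)`.
#' Under a perfectly linear effect the share below equals the frequency mass
#' below the cutoff; under a threshold-only effect it is 1.
#'
#' @param gradients Per-score gradients on the full grid (scores
#'   `0:(length - 1)`).
#' @param frequencies Per-score relative frequencies (non-negative; are
#'   normalized to sum to 1).
#' @param cutoff Isolation cutoff (default 12; scores strictly below count
#'   as isolated).
#' @param signed If `TRUE`, aggregate signed gradients instead of absolute
#'   values (sensitivity variant).
#' @return Tibble with `share_below` and `share_above` (summing to 1), or
#'   `NA` shares when every gradient is zero.
#' @export
#' @examples
#' f <- c(rep(0.2 / 12, 12), rep(0.8 / 19, 19))
#' share_below_cutoff(rep(1, 31), f)  # linear effect: share_below = 0.20
share_below_cutoff <- function(gradients, frequencies, cutoff = 12,
                               signed = FALSE) {
  if (length(gradients) != length(frequencies))
    abort("gradients and frequencies must have equal length.")
  if (any(frequencies < 0)) abort("frequencies must be non-negative.")
  tot_f <- sum(frequencies)
  if (tot_f <= 0) abort("frequencies sum to zero.")
  f <- frequencies / tot_f
  g <- if (signed) gradients else abs(gradients)
  wm <- g * f
  tot <- sum(wm)
  scores <- seq_along(g) - 1
  if (tot == 0) {
    warn("all gradients are zero; the effect share is undefined.")
    return(tibble::tibble(share_below = NA_real_, share_above = NA_real_))
  }
  below <- sum(wm[scores < cutoff]) / tot
  tibble::tibble(share_below = below, share_above = 1 - below)
}

#' Effect-share decomposition of a fitted exposure smooth
#'
#' End-to-end wrapper: extracts the partial effect of the exposure smooth on
#' the 0..30 grid, computes local gradients (response scale for log links),
#' takes score frequencies from the fit's analysis rows (optionally
#' weight-adjusted), and splits the total absolute effect at the isolation
#' cutoff.
#'
#' @param fit A `gamm_fit` whose exposure enters as a smooth.
#' @param term Exposure smooth (default `"s(lsns)"`).
#' @param cutoff Isolation cutoff (default 12).
#' @param data Data the fit was computed on (used for empirical score
#'   frequencies); defaults to reconstructing frequencies from the stored
#'   design rows.
#' @param weighted Use the fit's observation weights in the frequency
#'   vector?
#' @param scale,signed Passed to [local_gradients()] /
#'   [share_below_cutoff()].
#' @return Object of class `effect_share`: tibble with one row per score
#'   (`score`, `estimate`, `gradient`, `frequency`, `weighted_magnitude`)
#'   and the shares in the `"shares"` attribute (also accessible via
#'   `glance()`).
#' @export
effect_share <- function(fit, term = "s(lsns)", cutoff = 12, data = NULL,
                         weighted = FALSE, scale = c("response", "link"),
                         signed = FALSE) {
  scale <- match.arg(scale)
  term <- normalize_smooth_term(fit, term)
  var <- fit$bases[[term]]$spec$variable
  pe <- partial_effect(fit, term, grid = 0:30)
  grads <- local_gradients(pe, scale = scale)
  x <- if (!is.null(data)) data[[var]][fit$rows] else fit$bases[[term]]$xvals
  w <- if (weighted) fit$prior_weights else rep(1, length(x))
  freq <- vapply(0:30, function(s) sum(w[x == s]), numeric(1))
  freq <- freq / sum(freq)
  shares <- share_below_cutoff(grads, freq, cutoff = cutoff, signed = signed)
  est <- if (scale == "response" && fit$spec$link == "log")
    pe$response_estimate else pe$estimate
  out <- tibble::tibble(score = 0:30, estimate = est, gradient = grads,
                        frequency = freq,
                        weighted_magnitude = abs(grads) * freq)
  structure(out, class = c("effect_share", class(out)), shares = shares,
            cutoff = cutoff, term = term)
}

#' @method glance effect_share
#' @export
glance.effect_share <- function(x, ...) attr(x, "shares")
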
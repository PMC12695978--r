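#' Specify a penalized smooth term
#'
#' A P-spline smooth: cubic B-spline basis on equally spaced knots with a
#' second-order difference penalty. The penalty null space contains the
#' linear trend, so an infinitely penalized smooth collapses to a straight
#' line; the sum-to-zero identifiability constraint is absorbed into the
#' basis (column centering plus dropping one dimension), leaving k-1 free
#' coefficients.
#'
#' @param variable Name of the covariate column.
#' @param k Basis dimension before the constraint (default 10; escalate to
#'   20 when the oversmoothing diagnostic flags the term).
#' @param penalty_order Difference order of the penalty (2).
#' @return A `smooth_spec` object.
#' @export
#' @examples smooth_spec("age", k = 10)
smooth_spec <- function(variable, k = 10, penalty_order = 2) {
  stopifnot(is.character(variable), length(variable) == 1L)
  k <- assert_count(k)
  if (k < 4) abort("`k` must be at least 4.")
  structure(list(variable = variable, k = k,
                 penalty_order = as.integer(penalty_order), centered = TRUE),
            class = "smooth_spec")
}

#' Build the constrained P-spline design block and penalty
#'
#' Constructs the cubic B-spline basis on `k` equally spaced knots over the
#' covariate range, the `k x k` second-order difference penalty
#' `t(D2) %*% D2`, and the centered, constraint-reduced versions used in
#' fitting (an `n x (k-1)` design block and `(k-1) x (k-1)` penalty).
#'
#' @param x Covariate values (at least `k` distinct values).
#' @param spec A [smooth_spec()].
#' @param weights Optional non-negative observation weights used for the
#'   centering constraint, so that the weighted mean of the smooth over the
#'   observed covariate distribution is zero.
#' @return List with `design`, `penalty`, `raw_basis`, `raw_penalty`,
#'   `knots`, `colmeans`, `Z` (constraint transform), `xmin`, `xmax`, `spec`.
#' @export
build_basis <- function(x, spec, weights = NULL) {
  if (!inherits(spec, "smooth_spec")) abort("`spec` must be a smooth_spec.")
  x <- as.numeric(x)
  if (anyNA(x)) abort("covariate for a smooth may not contain NA at build time.")
  k <- spec$k
  if (length(unique(x)) < k)
    abort(sprintf(
      "smooth `%s`: only %d distinct values for k = %d; reduce k.",
      spec$variable, length(unique(x)), k))
  xmin <- min(x); xmax <- max(x)
  h <- (xmax - xmin) / (k - 3)
  knots <- xmin + h * seq.int(-3L, k)  # k + 4 equally spaced knots
  if (knots[k + 1] < xmax) knots[k + 1] <- xmax  # fp guard at the boundary
  B <- splines::splineDesign(knots, x, ord = 4)
  D2 <- diff(diag(k), differences = spec$penalty_order)
  S_raw <- crossprod(D2)
  w <- weights %||% rep(1, length(x))
  cm <- colSums(B * w) / sum(w)
  Bc <- sweep(B, 2, cm)
  Z <- qr.Q(qr(matrix(1, k, 1)), complete = TRUE)[, -1, drop = FALSE]
  design <- Bc %*% Z
  penalty <- crossprod(Z, S_raw %*% Z)
  penalty <- (penalty + t(penalty)) / 2
  list(design = design, penalty = penalty, raw_basis = B, raw_penalty = S_raw,
       knots = knots, colmeans = cm, Z = Z, xmin = xmin, xmax = xmax,
       spec = spec)
}

# evaluate the constrained basis at new covariate values; values outside the
# training range are clamped to the boundary and flagged
basis_predict <- function(basis, xnew) {
  xnew <- as.numeric(xnew)
  extrapolated <- xnew < basis$xmin | xnew > basis$xmax
  xc <- pmin(pmax(xnew, basis$xmin), basis$xmax)
  B <- splines::splineDesign(basis$knots, xc, ord = 4)
  X <- sweep(B, 2, basis$colmeans) %*% basis$Z
  list(X = X, extrapolated = extrapolated)
}
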
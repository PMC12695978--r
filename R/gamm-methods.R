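#' Approximate Wald test for a smooth term
#'
#' Tests the null that the smooth contribution is zero (beyond what the
#' penalty null space absorbs elsewhere) with a rank-truncated Wald
#' statistic: the smooth block's coefficients against the pseudo-inverse of
#' their posterior covariance at rank `r = round(edf)` clamped to
#' `[1, k - 1]`. The reference distribution is chi-squared for Poisson
#' (known scale) and a scaled F for gaussian/gamma (estimated dispersion).
#'
#' @param fit A `gamm_fit`.
#' @param term Smooth term label, e.g. `"s(lsns)"`, or the bare variable
#'   name.
#' @return A p-value in `[0, 1]`.
#' @export
smooth_pvalue <- function(fit, term) {
  term <- normalize_smooth_term(fit, term)
  idx <- fit$term_map[[term]]
  beta <- fit$coefficients[idx]
  V <- fit$covariance[idx, idx, drop = FALSE]
  eg <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (max(eg$values) <= 0)
    abort("degenerate covariance for the smooth block.")
  km1 <- length(idx)
  r <- min(max(1L, as.integer(round(fit$edf_by_term[[term]]))), km1)
  pos <- which(eg$values > max(eg$values) * 1e-10)
  if (length(pos) < r) r <- length(pos)
  proj <- drop(crossprod(eg$vectors[, seq_len(r), drop = FALSE], beta))
  stat <- sum(proj^2 / eg$values[seq_len(r)])
  if (fit$spec$family == "poisson") {
    pchisq(stat, df = r, lower.tail = FALSE)
  } else {
    pf(stat / r, r, max(fit$n_obs - fit$edf_total, 1), lower.tail = FALSE)
  }
}

normalize_smooth_term <- function(fit, term) {
  if (!grepl("^s\\(", term)) term <- paste0("s(", term, ")")
  if (!term %in% names(fit$bases))
    abort(sprintf("`%s` is not a smooth term of this fit.", term))
  term
}

#' One-sided test for a linear exposure coefficient
#'
#' For base models in which the exposure enters linearly, tests the
#' directional hypothesis that more social contact relates to better
#' outcomes (the expected direction of the coefficient is supplied by the
#' caller, accounting for negated gamma outcomes).
#'
#' @param fit A `gamm_fit`.
#' @param term Parametric term name.
#' @param direction `"positive"` or `"negative"`: the alternative's sign.
#' @return One-sided p-value.
#' @export
linear_pvalue <- function(fit, term, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  idx <- fit$term_map[[term]]
  if (is.null(idx) || length(idx) != 1L)
    abort(sprintf("`%s` is not a single-column parametric term.", term))
  est <- fit$coefficients[idx]
  se <- sqrt(fit$covariance[idx, idx])
  tt <- est / se
  df <- max(fit$n_obs - fit$edf_total, 1)
  if (direction == "positive") pt(tt, df, lower.tail = FALSE) else pt(tt, df)
}

#' Extract the centered partial effect of a smooth term
#'
#' Evaluates the smooth's centered contribution to the linear predictor on a
#' grid, with pointwise standard errors from the Bayesian posterior
#' covariance. For log-link models a response-scale column `exp(estimate)`
#' is added (with delta-method standard errors), matching the convention of
#' back-transforming estimates before interpretation. Grid points outside
#' the training range are clamped to the boundary and flagged.
#'
#' @param fit A `gamm_fit`.
#' @param term Smooth term label or variable name.
#' @param grid Grid values; defaults to every integer between the observed
#'   bounds when the covariate is integer-valued (e.g. 0..30 for LSNS),
#'   otherwise a 100-point sequence.
#' @return A tibble of class `partial_effect` with columns `grid`,
#'   `estimate`, `se`, `extrapolated` (plus `response_estimate`,
#'   `response_se` under a log link); the full grid covariance is kept in
#'   the `"covariance"` attribute.
#' @export
partial_effect <- function(fit, term, grid = NULL) {
  term <- normalize_smooth_term(fit, term)
  bs <- fit$bases[[term]]
  if (is.null(grid)) {
    grid <- if (isTRUE(all.equal(bs$xmin %% 1, 0)) &&
                isTRUE(all.equal(bs$xmax %% 1, 0)))
      seq(bs$xmin, bs$xmax) else seq(bs$xmin, bs$xmax, length.out = 100)
  }
  bp <- basis_predict(bs, grid)
  idx <- fit$term_map[[term]]
  beta <- fit$coefficients[idx]
  V <- fit$covariance[idx, idx, drop = FALSE]
  est <- drop(bp$X %*% beta)
  covg <- bp$X %*% V %*% t(bp$X)
  se <- sqrt(pmax(diag(covg), 0))
  out <- tibble::tibble(grid = as.numeric(grid), estimate = est, se = se,
                        extrapolated = bp$extrapolated)
  if (fit$spec$link == "log") {
    out$response_estimate <- exp(est)
    out$response_se <- exp(est) * se
  }
  structure(out, class = c("partial_effect", class(out)),
            covariance = covg, link = fit$spec$link, term = term,
            family = fit$spec$family)
}

#' Compare a smooth-exposure (full) model against its linear (base) version
#'
#' Deviance test between two nested fits on the same rows: chi-squared for
#' Poisson, F with the full model's estimated dispersion for gaussian/gamma.
#' The degrees of freedom are the difference in total effective degrees of
#' freedom, floored at 0.5 to avoid degenerate boundary tests. The full
#' model is `preferred` only when the test is significant at `alpha` AND its
#' BIC is lower (conjunctive rule).
#'
#' @param full,base `gamm_fit` objects on identical rows and outcome.
#' @param alpha Significance level (default 0.05).
#' @return A tibble with `p`, `delta_bic` (BIC base - BIC full, positive
#'   favours the full model), `df`, `preferred` (`"full"` or `"base"`).
#' @export
compare_models <- function(full, base, alpha = 0.05) {
  if (!identical(full$spec$outcome, base$spec$outcome) ||
      full$n_obs != base$n_obs || !identical(full$rows, base$rows))
    abort("models must share the outcome and exactly the same rows.")
  df <- max(full$edf_total - base$edf_total, 0.5)
  ddev <- max(base$deviance - full$deviance, 0)
  p <- if (full$spec$family == "poisson") {
    pchisq(ddev, df, lower.tail = FALSE)
  } else {
    pf((ddev / df) / full$scale, df,
       max(full$n_obs - full$edf_total, 1), lower.tail = FALSE)
  }
  delta_bic <- base$bic - full$bic
  tibble::tibble(p = p, delta_bic = delta_bic, df = df,
                 preferred = if (p < alpha && delta_bic > 0) "full" else "base")
}

#' Worst-case concurvity of each smooth term
#'
#' For each smooth block, the squared largest canonical correlation between
#' its (centered, constrained) design columns and the span of all other
#' dense model columns -- the nonparametric analogue of multicollinearity.
#' Values near 1 mean the smooth is almost entirely expressible by the rest
#' of the model.
#'
#' @param fit A `gamm_fit`.
#' @return Named numeric vector in `[0, 1]`, one value per smooth.
#' @export
concurvity <- function(fit) {
  out <- numeric(0)
  for (nm in names(fit$bases)) {
    idx <- fit$term_map[[nm]]
    Xs <- fit$X[, idx, drop = FALSE]
    Xo <- fit$X[, -idx, drop = FALSE]
    Qo <- qr.Q(qr(Xo))
    C <- crossprod(Qo, Xs)
    G <- crossprod(Xs)
    ev <- eigen(solve(G + diag(1e-10, ncol(G)), crossprod(C)),
                only.values = TRUE)$values
    out[nm] <- min(max(Re(ev)), 1)
  }
  out
}

#' Variance inflation factors of the parametric terms
#'
#' Classic VIFs `1 / (1 - R^2)` from auxiliary regressions of each
#' parametric design column on the other parametric columns (intercept
#' included as regressor, not assessed). Perfect collinearity is reported as
#' `Inf`.
#'
#' @param fit A `gamm_fit` with at least two parametric terms, or a numeric
#'   design matrix.
#' @return Named numeric vector of VIFs.
#' @export
vif_terms <- function(fit) {
  X <- if (inherits(fit, "gamm_fit")) {
    idx <- unlist(fit$term_map[setdiff(names(fit$term_map), "(Intercept)")])
    idx <- setdiff(idx, unlist(fit$term_map[names(fit$bases)]))
    fit$X[, idx, drop = FALSE]
  } else as.matrix(fit)
  if (ncol(X) < 2) abort("VIFs need at least two parametric columns.")
  vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> setNames(colnames(X))
}

#' Oversmoothing check for each smooth term
#'
#' Flags smooths whose effective degrees of freedom approach the basis
#' ceiling (`edf > 0.9 * (k - 1)`), indicating the basis dimension may be
#' constraining the fit; the pipeline responds by refitting flagged terms
#' with `k = 20`.
#'
#' @param fit A `gamm_fit`.
#' @return Tibble with `term`, `edf`, `k_prime` (`k - 1`), `flag`.
#' @export
check_oversmoothing <- function(fit) {
  tibble::tibble(
    term = names(fit$bases),
    edf = unname(fit$edf_by_term[names(fit$bases)]),
    k_prime = vapply(fit$bases, function(b) b$spec$k - 1, numeric(1)),
    flag = .data$edf > 0.9 * .data$k_prime
  )
}

#' Tidy a fitted penalized additive mixed model
#'
#' Parametric terms are reported with estimate, standard error, t/z
#' statistic and two-sided p-value; smooth terms with their effective
#' degrees of freedom and approximate Wald p-value.
#'
#' @param x A `gamm_fit`.
#' @param ... Unused.
#' @return A tibble, one row per term.
#' @method tidy gamm_fit
#' @export
tidy.gamm_fit <- function(x, ...) {
  par_terms <- setdiff(names(x$term_map), names(x$bases))
  rows <- purrr::map(par_terms, function(tm) {
    idx <- x$term_map[[tm]]
    purrr::map(idx, function(j) {
      est <- x$coefficients[j]
      se <- sqrt(x$covariance[j, j])
      stat <- est / se
      df <- max(x$n_obs - x$edf_total, 1)
      tibble::tibble(term = names(x$coefficients)[j], type = "parametric",
                     estimate = unname(est), std_error = unname(se),
                     statistic = unname(stat),
                     p_value = 2 * pt(abs(stat), df, lower.tail = FALSE),
                     edf = NA_real_)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  sm <- purrr::map(names(x$bases), function(nm) {
    tibble::tibble(term = nm, type = "smooth", estimate = NA_real_,
                   std_error = NA_real_, statistic = NA_real_,
                   p_value = unname(x$smooth_pvalues[nm]),
                   edf = unname(x$edf_by_term[nm]))
  }) |> dplyr::bind_rows()
  dplyr::bind_rows(rows, sm)
}

#' Model-level summary of a fitted penalized additive mixed model
#'
#' @param x A `gamm_fit`.
#' @param ... Unused.
#' @return One-row tibble with deviance, log-likelihood, BIC, total edf,
#'   dispersion, observation count and convergence status.
#' @method glance gamm_fit
#' @export
glance.gamm_fit <- function(x, ...) {
  tibble::tibble(deviance = x$deviance, log_likelihood = x$log_likelihood,
                 bic = x$bic, edf_total = x$edf_total, scale = x$scale,
                 n_obs = x$n_obs, converged = x$converged,
                 iterations = x$iterations)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
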
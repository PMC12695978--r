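#' Declare a penalized additive mixed model
#'
#' Describes a model of the form
#' `g(E[y]) = parametric terms + sum of smooth terms (+ participant random
#' intercept)` for one of three exponential families. Family/link pairs
#' follow the analysis design: gaussian/identity, Poisson/log, gamma with
#' log or identity link. The random intercept is represented as a
#' ridge-penalized dummy-coefficient block (the classic ridge-BLUP
#' equivalence), its penalty selected together with the smoothing
#' parameters.
#'
#' @param outcome Outcome column name.
#' @param family `"gaussian"`, `"poisson"` or `"gamma"`.
#' @param link Link function; defaults to the family's canonical choice
#'   (identity, log, log).
#' @param parametric Character vector of parametric term columns (factors
#'   and logicals are expanded via `model.matrix`).
#' @param smooths List of [smooth_spec()] objects.
#' @param random_intercept Include a per-participant random intercept?
#' @param id Participant identifier column.
#' @param weights Optional column of positive observation weights
#'   multiplying each row's likelihood contribution.
#' @return A `model_spec` object.
#' @export
#' @examples
#' model_spec("y", parametric = "gender",
#'            smooths = list(smooth_spec("age"), smooth_spec("lsns")))
model_spec <- function(outcome,
                       family = c("gaussian", "poisson", "gamma"),
                       link = NULL,
                       parametric = character(),
                       smooths = list(),
                       random_intercept = TRUE,
                       id = "participant_id",
                       weights = NULL) {
  family <- match.arg(family)
  link <- link %||% switch(family, gaussian = "identity", poisson = "log",
                           gamma = "log")
  ok <- switch(family,
               gaussian = link == "identity",
               poisson = link == "log",
               gamma = link %in% c("log", "identity"))
  if (!ok) abort(sprintf("link `%s` is not supported for family `%s`.",
                         link, family))
  if (!all(vapply(smooths, inherits, TRUE, "smooth_spec")))
    abort("`smooths` must be a list of smooth_spec objects.")
  sm_vars <- vapply(smooths, `[[`, "", "variable")
  if (anyDuplicated(sm_vars)) abort("duplicate smooth variables.")
  if (any(sm_vars %in% parametric))
    abort("a variable may enter as a smooth or a parametric term, not both.")
  structure(list(outcome = outcome, family = family, link = link,
                 parametric = parametric, smooths = smooths,
                 random_intercept = isTRUE(random_intercept), id = id,
                 weights = weights),
            class = "model_spec")
}

fam_object <- function(family, link) {
  switch(family,
         gaussian = gaussian(link),
         poisson = poisson(link),
         gamma = Gamma(link))
}

# --- weighted-least-squares machinery with the random-intercept block
# absorbed through its diagonal Schur complement ------------------------

# cross-products of the working model; `id` is an integer grouping vector
# (or NULL when there is no random intercept)
wls_pieces <- function(X, w, z, id, q) {
  sw <- sqrt(w)
  A0 <- crossprod(X * sw)
  uf <- drop(crossprod(X, w * z))
  out <- list(A0 = A0, uf = uf, yy = sum(w * z^2), n = length(z))
  if (!is.null(id)) {
    out$Bq <- rowsum(X * w, id, reorder = TRUE)            # q x p
    out$d <- drop(rowsum(w, id, reorder = TRUE))
    out$ub <- drop(rowsum(w * z, id, reorder = TRUE))
  }
  out
}

# solve the penalized normal equations for fixed penalties; returns the
# dense-block coefficients, random effects, edf decomposition and the
# working residual sum of squares
ridge_solve <- function(pc, P, lam_re) {
  p <- ncol(pc$A0)
  if (!is.null(pc$Bq)) {
    e <- pc$d + lam_re
    BqE <- pc$Bq / e
    A0eff <- pc$A0 - crossprod(pc$Bq, BqE)
    rhs <- pc$uf - drop(crossprod(BqE, pc$ub))
  } else {
    A0eff <- pc$A0
    rhs <- pc$uf
  }
  Aeff <- A0eff + P
  ch <- tryCatch(chol(Aeff), error = function(e2) chol(Aeff + diag(1e-7, p)))
  M <- chol2inv(ch)
  beta <- drop(M %*% rhs)
  edf_dense <- rowSums(M * A0eff)   # diag(M %*% A0eff), both symmetric
  out <- list(beta = beta, M = M, edf_dense = edf_dense)
  qf <- drop(crossprod(beta, pc$A0 %*% beta))
  fit_dot <- sum(beta * pc$uf)
  if (!is.null(pc$Bq)) {
    b <- (pc$ub - drop(pc$Bq %*% beta)) / e
    diagBMB <- rowSums((pc$Bq %*% M) * pc$Bq)
    out$b <- b
    out$edf_re <- sum(pc$d / e) - lam_re * sum(diagBMB / e^2)
    qf <- qf + 2 * sum(drop(pc$Bq %*% beta) * b) + sum(pc$d * b^2)
    fit_dot <- fit_dot + sum(b * pc$ub)
  } else {
    out$edf_re <- 0
  }
  out$edf_total <- sum(edf_dense) + out$edf_re
  out$rss_w <- max(pc$yy - 2 * fit_dot + qf, 0)
  out
}

# penalized IRLS at fixed smoothing parameters
pirls <- function(X, y, fam, pw, P, id, lam_re,
                  maxit = 200, tol = 1e-8) {
  n <- length(y)
  mu <- switch(fam$family,
               gaussian = y,
               poisson = y + 0.1,
               Gamma = pmax(y, max(y) * 1e-6))
  eta <- fam$linkfun(mu)
  dev <- sum(fam$dev.resids(y, mu, pw))
  sol <- NULL
  converged <- FALSE
  iter <- 0
  while (iter < maxit) {
    iter <- iter + 1
    mu.eta <- fam$mu.eta(eta)
    w <- pw * mu.eta^2 / fam$variance(mu)
    z <- eta + (y - mu) / mu.eta
    pc <- wls_pieces(X, w, z, id, NULL)
    sol_new <- ridge_solve(pc, P, lam_re)
    eta_new <- drop(X %*% sol_new$beta)
    if (!is.null(id)) eta_new <- eta_new + sol_new$b[id]
    # step halving on invalid or diverging steps
    ok <- FALSE
    for (h in 0:30) {
      eta_try <- if (h == 0) eta_new else (eta_new + eta) / 2
      mu_try <- fam$linkinv(eta_try)
      valid <- all(is.finite(mu_try)) && fam$validmu(mu_try)
      if (valid) {
        dev_try <- sum(fam$dev.resids(y, mu_try, pw))
        if (is.finite(dev_try) && (iter == 1 || dev_try <= dev * (1 + 1e-4) ||
                                   h == 30)) {
          eta_new <- eta_try; mu <- mu_try; dev_new <- dev_try; ok <- TRUE
          break
        }
      }
      eta_new <- eta_try
    }
    if (!ok)
      abort("penalized IRLS produced an invalid mean despite step halving; the linear predictor overflows the link's domain.")
    rel <- abs(dev_new - dev) / (abs(dev_new) + 0.1)
    eta <- eta_new
    dev <- dev_new
    sol <- sol_new
    sol$w <- w; sol$z <- z
    if (rel < tol) { converged <- TRUE; break }
  }
  list(sol = sol, eta = eta, mu = mu, dev = dev, iter = iter,
       converged = converged)
}

# GCV (unknown scale) or UBRE-style (poisson, scale 1) criterion on the
# frozen working model
sp_criterion <- function(pc, P, lam_re, family) {
  sol <- ridge_solve(pc, P, lam_re)
  n <- pc$n
  if (family == "poisson") {
    sol$rss_w / n + 2 * sol$edf_total / n
  } else {
    n * sol$rss_w / (n - sol$edf_total)^2
  }
}

# coordinate-wise grid + golden-section search over log10 smoothing
# parameters (smooth penalties first, random-intercept ridge last)
select_lambda <- function(pc, S_emb, has_re, family,
                          loglam = NULL, grid = seq(-4, 8, length.out = 25),
                          sweeps = 2, tol = 0.01) {
  nsp <- length(S_emb) + has_re
  if (nsp == 0) return(numeric(0))
  loglam <- loglam %||% rep(0, nsp)
  build_P <- function(ll) {
    P <- matrix(0, ncol(pc$A0), ncol(pc$A0))
    for (j in seq_along(S_emb)) P <- P + 10^ll[j] * S_emb[[j]]
    P
  }
  crit_at <- function(ll) {
    lam_re <- if (has_re) 10^ll[nsp] else 0
    sp_criterion(pc, build_P(ll), lam_re, family)
  }
  golden <- function(f, lo, hi) {
    gr <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
    f1 <- f(c1); f2 <- f(c2)
    while (b - a > tol) {
      if (f1 <= f2) { b <- c2; c2 <- c1; f2 <- f1
        c1 <- b - gr * (b - a); f1 <- f(c1)
      } else { a <- c1; c1 <- c2; f1 <- f2
        c2 <- a + gr * (b - a); f2 <- f(c2) }
    }
    (a + b) / 2
  }
  step <- grid[2] - grid[1]
  for (sweep in seq_len(sweeps)) {
    for (j in seq_len(nsp)) {
      f1 <- function(v) { ll <- loglam; ll[j] <- v; crit_at(ll) }
      vals <- vapply(grid, f1, numeric(1))
      best <- grid[which.min(vals)]
      loglam[j] <- golden(f1, best - step, best + step)
    }
  }
  loglam
}

#' Fit a penalized additive mixed model
#'
#' Fits the model by penalized iteratively reweighted least squares. With
#' `lambda = NULL` the smoothing parameters (one per smooth plus one for the
#' random-intercept ridge block) are selected by minimizing GCV (gaussian,
#' gamma) or a UBRE-style criterion (Poisson) on the converged working
#' model, by a coordinate-wise grid plus golden-section search with two
#' outer performance-iteration sweeps. The random-intercept block is
#' absorbed analytically (its weighted cross-product is diagonal), so
#' cohorts with thousands of participants remain cheap.
#'
#' @param data Data frame; rows with missing values in any used column are
#'   dropped.
#' @param spec A [model_spec()].
#' @param lambda Optional named numeric vector of fixed smoothing parameters
#'   (names `"s(var)"` per smooth and `"(random)"`); `NULL` selects them.
#' @param maxit,tol PIRLS iteration cap and relative deviance tolerance.
#' @return An object of class `gamm_fit`; see [tidy.gamm_fit()],
#'   [glance.gamm_fit()], [partial_effect()], [compare_models()].
#' @export
#' @examples
#' d <- sample_cohort(cohort_config(150, seed = 2), list(y = shape_spec("A")))
#' f <- fit_gamm(d, model_spec("y", parametric = "gender",
#'                             smooths = list(smooth_spec("age", k = 6))))
fit_gamm <- function(data, spec, lambda = NULL, maxit = 200, tol = 1e-8) {
  if (!inherits(spec, "model_spec")) abort("`spec` must be a model_spec.")
  sm_vars <- vapply(spec$smooths, `[[`, "", "variable")
  used <- unique(c(spec$outcome, spec$parametric, sm_vars,
                   if (spec$random_intercept) spec$id, spec$weights))
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols))
    abort(paste0("column(s) missing from data: ",
                 paste(missing_cols, collapse = ", ")))
  rows <- complete.cases(data[used])
  d <- data[rows, used, drop = FALSE]
  y <- as.numeric(d[[spec$outcome]])
  n <- length(y)
  fam <- fam_object(spec$family, spec$link)
  if (spec$family == "gamma" && any(y <= 0))
    abort("gamma-family outcomes must be strictly positive.")
  pw <- if (is.null(spec$weights)) rep(1, n) else as.numeric(d[[spec$weights]])
  if (any(pw <= 0)) abort("observation weights must be positive.")

  # dense design: intercept + parametric expansion + smooth blocks
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  term_map <- list(`(Intercept)` = 1L)
  for (tm in spec$parametric) {
    v <- d[[tm]]
    if (is.character(v)) v <- factor(v)
    if (is.factor(v)) v <- droplevels(v)
    constant <- (is.factor(v) && nlevels(v) < 2) ||
      (!is.factor(v) && sd(as.numeric(v)) == 0)
    if (constant) {
      warn(sprintf("parametric term `%s` is constant on the analysis rows; dropped.", tm))
      next
    }
    mm <- model.matrix(~v)[, -1, drop = FALSE]
    colnames(mm) <- if (ncol(mm) == 1) tm else
      paste0(tm, sub("^v", "", colnames(mm)))
    term_map[[tm]] <- ncol(X) + seq_len(ncol(mm))
    X <- cbind(X, mm)
  }
  bases <- list()
  S_emb <- list()
  for (ss in spec$smooths) {
    bs <- build_basis(d[[ss$variable]], ss, weights = pw)
    bs$xvals <- as.numeric(d[[ss$variable]])
    nm <- paste0("s(", ss$variable, ")")
    idx <- ncol(X) + seq_len(ncol(bs$design))
    term_map[[nm]] <- idx
    colnames(bs$design) <- paste0(nm, ".", seq_len(ncol(bs$design)))
    X <- cbind(X, bs$design)
    bases[[nm]] <- bs
  }
  p <- ncol(X)
  if (n < 10 * (p + 0)) {
    if (n <= p) abort("more coefficients than rows; reduce model complexity.")
    warn(sprintf("only %d rows for %d dense coefficients.", n, p))
  }
  for (nm in names(bases)) {
    S <- matrix(0, p, p)
    idx <- term_map[[nm]]
    S[idx, idx] <- bases[[nm]]$penalty
    S_emb[[nm]] <- S
  }
  id <- NULL; q <- 0
  if (spec$random_intercept) {
    idf <- factor(d[[spec$id]])
    id <- as.integer(idf)
    q <- nlevels(idf)
  }
  has_re <- spec$random_intercept

  penalty_names <- c(names(S_emb), if (has_re) "(random)")
  if (!is.null(lambda)) {
    if (!all(penalty_names %in% names(lambda)))
      abort(paste0("`lambda` must name every penalty: ",
                   paste(penalty_names, collapse = ", ")))
    loglam <- log10(lambda[penalty_names])
  } else {
    loglam <- rep(0, length(penalty_names))
  }
  build_P <- function(ll) {
    P <- matrix(0, p, p)
    for (j in seq_along(S_emb)) P <- P + 10^ll[j] * S_emb[[j]]
    P
  }
  lam_re_of <- function(ll) if (has_re) unname(10^ll[length(ll)]) else 0

  ft <- pirls(X, y, fam, pw, build_P(loglam), id, lam_re_of(loglam),
              maxit = maxit, tol = tol)
  if (is.null(lambda) && length(penalty_names)) {
    for (outer in 1:2) {
      pc <- wls_pieces(X, ft$sol$w, ft$sol$z, id, q)
      loglam <- select_lambda(pc, S_emb, has_re, spec$family, loglam = loglam)
      ft <- pirls(X, y, fam, pw, build_P(loglam), id, lam_re_of(loglam),
                  maxit = maxit, tol = tol)
      if (spec$family == "gaussian" && spec$link == "identity") break
    }
  }
  if (!ft$converged)
    warn(sprintf("PIRLS did not converge in %d iterations.", maxit))

  sol <- ft$sol
  edf_total <- sol$edf_total
  mu <- ft$mu
  pearson <- sum(pw * (y - mu)^2 / fam$variance(mu))
  scale <- switch(spec$family,
                  poisson = 1,
                  pearson / max(n - edf_total, 1))
  dev <- ft$dev
  ll <- switch(spec$family,
    gaussian = {
      rss <- sum(pw * (y - mu)^2)
      -0.5 * n * (log(2 * pi * rss / n) + 1) + 0.5 * sum(log(pw))
    },
    poisson = sum(pw * dpois(round(y), mu, log = TRUE)),
    gamma = {
      alpha <- 1 / scale
      sum(pw * dgamma(y, shape = alpha, rate = alpha / mu, log = TRUE))
    })
  bic <- -2 * ll + log(n) * edf_total

  edf_by_term <- vapply(term_map, function(idx) sum(sol$edf_dense[idx]),
                        numeric(1))
  if (has_re) edf_by_term <- c(edf_by_term, "(random)" = unname(sol$edf_re))
  coefs <- setNames(sol$beta, colnames(X))
  Vp <- sol$M * scale
  dimnames(Vp) <- list(colnames(X), colnames(X))

  fit <- structure(list(
    spec = spec, coefficients = coefs, covariance = Vp,
    ranef = if (has_re) setNames(sol$b, levels(factor(d[[spec$id]]))),
    lambda = setNames(10^loglam, penalty_names),
    edf_by_term = edf_by_term, edf_total = edf_total,
    deviance = dev, log_likelihood = ll, scale = scale,
    n_obs = n, bic = bic, converged = ft$converged, iterations = ft$iter,
    fitted = mu, linear_predictor = ft$eta, y = y,
    prior_weights = pw, working_weights = sol$w,
    term_map = term_map, bases = bases, X = X,
    id = if (has_re) id, rows = which(rows)
  ), class = "gamm_fit")
  fit$smooth_pvalues <- vapply(names(bases), function(nm)
    smooth_pvalue(fit, nm), numeric(1))
  fit
}

#' @export
print.gamm_fit <- function(x, ...) {
  cat("<gamm_fit> ", x$spec$outcome, " ~ ", sep = "")
  cat(paste(c(x$spec$parametric,
              paste0("s(", vapply(x$spec$smooths, `[[`, "", "variable"), ")"),
              if (x$spec$random_intercept) "(1 | id)"), collapse = " + "), "\n")
  cat(sprintf("  family %s(%s), n = %d, edf = %.2f, deviance = %.4g, BIC = %.4g\n",
              x$spec$family, x$spec$link, x$n_obs, x$edf_total, x$deviance,
              x$bic))
  if (!x$converged) cat("  (PIRLS did not converge)\n")
  invisible(x)
}
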
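#' Simplified multiple imputation by chained equations
#'
#' Produces `m` completed copies of a cohort table by chained equations:
#' continuous columns are imputed by Bayesian linear regression draws
#' (posterior draw of the residual variance and coefficients, then noise),
#' binary columns by Bernoulli draws from a logistic regression with an
#' approximate normal posterior draw of the coefficients. Columns are
#' visited in order of ascending missingness for a fixed number of cycles;
#' observed cells are never modified. This is a deliberately lean scheme
#' (no predictive mean matching); downstream analyses are run per imputation
#' and reported as ranges, not pooled.
#'
#' @param table Cohort tibble; missingness only in covariates/outcomes, not
#'   in `participant_id`, `wave` or `lsns`.
#' @param m Number of completed tables (default 5).
#' @param seed Optional integer seed.
#' @param predictors Columns used as regressors (default: `lsns`, `age` and
#'   a male indicator plus all columns being imputed).
#' @param cycles Chained-equation cycles per imputation (default 10).
#' @param max_missing Refuse columns with a higher missing fraction.
#' @return An object of class `imputed_set`: list with elements `m`,
#'   `tables` (list of completed tibbles) and `models` (per-column model
#'   descriptions).
#' @export
impute_chained <- function(table, m = 5, seed = NULL,
                           predictors = NULL, cycles = 10,
                           max_missing = 0.8) {
  m <- assert_count(m)
  if (!is.null(seed)) set.seed(as.integer(seed))
  key_cols <- c("participant_id", "wave", "lsns")
  if (any(vapply(intersect(key_cols, names(table)),
                 function(cl) anyNA(table[[cl]]), TRUE)))
    abort("id, wave and exposure columns must be complete.")

  frac_na <- vapply(table, function(x) mean(is.na(x)), numeric(1))
  target <- names(frac_na)[frac_na > 0]
  too_bad <- target[frac_na[target] > max_missing]
  if (length(too_bad))
    abort(paste0("column(s) with more than ", round(100 * max_missing),
                 "% missing cannot be imputed: ", paste(too_bad, collapse = ", ")))
  target <- target[order(frac_na[target])]

  base_pred <- predictors %||% intersect(c("lsns", "age"), names(table))
  X_base <- cbind(`(Intercept)` = 1,
                  as.matrix(dplyr::mutate(table[base_pred],
                                          dplyr::across(dplyr::everything(),
                                                        as.numeric))))
  if ("gender" %in% names(table))
    X_base <- cbind(X_base, male = as.numeric(table$gender == "male"))

  is_binary <- vapply(target, function(cl) {
    v <- table[[cl]][!is.na(table[[cl]])]
    is.logical(table[[cl]]) || all(v %in% c(0, 1))
  }, TRUE)
  models <- setNames(ifelse(is_binary, "logistic regression draw",
                            "Bayesian linear regression draw"), target)
  if (length(target) == 0)
    return(structure(list(m = m, tables = replicate(m, table, simplify = FALSE),
                          models = models), class = "imputed_set"))

  impute_once <- function() {
    filled <- table
    # initial fill: random draws from observed values
    for (cl in target) {
      nas <- is.na(filled[[cl]])
      obs <- filled[[cl]][!nas]
      filled[[cl]][nas] <- sample(obs, sum(nas), replace = TRUE)
    }
    for (cyc in seq_len(cycles)) {
      for (cl in target) {
        others <- setdiff(target, cl)
        X <- X_base
        if (length(others))
          X <- cbind(X, as.matrix(dplyr::mutate(filled[others],
                                                dplyr::across(dplyr::everything(),
                                                              as.numeric))))
        nas <- is.na(table[[cl]])
        yobs <- as.numeric(table[[cl]][!nas])
        Xo <- X[!nas, , drop = FALSE]
        Xm <- X[nas, , drop = FALSE]
        # drop constant columns to keep the normal equations well posed
        keep <- c(TRUE, apply(Xo[, -1, drop = FALSE], 2,
                              function(v) sd(v) > 0))
        Xo <- Xo[, keep, drop = FALSE]; Xm <- Xm[, keep, drop = FALSE]
        p <- ncol(Xo)
        if (is_binary[[cl]]) {
          g <- suppressWarnings(stats::glm.fit(Xo, yobs,
                                               family = stats::binomial()))
          R <- chol(crossprod(Xo * sqrt(g$weights)) + diag(1e-8, p))
          bdraw <- g$coefficients + backsolve(R, rnorm(p))
          draws <- runif(sum(nas)) < plogis(as.numeric(Xm %*% bdraw))
          filled[[cl]][nas] <- if (is.logical(table[[cl]])) draws else
            as.numeric(draws)
        } else {
          XtX <- crossprod(Xo) + diag(1e-8, p)
          bhat <- solve(XtX, crossprod(Xo, yobs))
          res <- yobs - Xo %*% bhat
          df <- max(length(yobs) - p, 2)
          sig2 <- sum(res^2) / stats::rchisq(1, df)
          bdraw <- bhat + backsolve(chol(XtX), rnorm(p)) * sqrt(sig2)
          draw <- as.numeric(Xm %*% bdraw) + rnorm(sum(nas), 0, sqrt(sig2))
          if (is.integer(table[[cl]]))
            draw <- as.integer(round(draw))
          filled[[cl]][nas] <- draw
        }
      }
    }
    filled
  }

  structure(list(m = m,
                 tables = replicate(m, impute_once(), simplify = FALSE),
                 models = models),
            class = "imputed_set")
}

#' @export
print.imputed_set <- function(x, ...) {
  cat("<imputed_set>", x$m, "completed tables,",
      length(x$models), "imputed column(s)\n")
  invisible(x)
}
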
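#' The seven study outcomes and their model families
#'
#' One row per outcome: the analysis column it is modelled on (after
#' measurement derivation), its family/link, whether it belongs to the
#' cognitive-aging family of tests (FDR-corrected together), the expected
#' direction of the linear exposure coefficient ("more social contact is
#' related to better outcomes", accounting for the negate-shift transform of
#' memory and processing speed), and the tier-2 covariate set.
#'
#' @return A tibble with columns `outcome`, `column`, `family`, `link`,
#'   `cognitive_family`, `direction`, `tier2` (list-column of covariate
#'   names), `row_filter` (list-column of QC filter columns).
#' @export
outcome_specs <- function() {
  mri_cog <- c("education_score", "bmi", "diabetes", "hypertension",
               "cesd_asinh")
  mental <- c("ses_score", "bmi", "diabetes", "hypertension")
  tibble::tibble(
    outcome = c("hcv", "wmhv", "executive", "memory", "processing_speed",
                "gad7", "cesd"),
    column = c("hcv_adj", "wmhv", "executive", "memory_shift",
               "processing_speed_shift", "gad7", "cesd"),
    family = c("gaussian", "gamma", "gaussian", "gamma", "gamma",
               "poisson", "poisson"),
    link = c("identity", "log", "identity", "log", "identity", "log", "log"),
    cognitive_family = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    direction = c("positive", "negative", "positive", "negative",
                  "negative", "negative", "negative"),
    tier2 = list(mri_cog, c(mri_cog, "icv_raw", "ventricular_enlargement"),
                 mri_cog, mri_cog, mri_cog, mental, mental),
    row_filter = list("mri_qc_ok", c("mri_qc_ok", "flair_qc_ok"),
                      NULL, NULL, NULL, NULL, NULL)
  )
}

outcome_row <- function(outcome) {
  os <- outcome_specs()
  if (outcome == "y")
    return(tibble::tibble(outcome = "y", column = "y", family = "gaussian",
                          link = "identity", cognitive_family = FALSE,
                          direction = "positive", tier2 = list(character()),
                          row_filter = list(NULL)))
  row <- os[os$outcome == outcome, ]
  if (nrow(row) == 0) abort(sprintf("unknown outcome `%s`.", outcome))
  row
}

# model specs for the full (smooth exposure) and base (linear exposure)
# models of one outcome at one covariate tier
build_model_pair <- function(outcome, tier = 1, k = 10, weighted = TRUE,
                             exposure = "lsns") {
  row <- outcome_row(outcome)
  covs <- if (tier == 2) row$tier2[[1]] else character()
  common <- list(outcome = row$column, family = row$family, link = row$link,
                 random_intercept = TRUE, id = "participant_id",
                 weights = if (weighted) "weight")
  full <- do.call(model_spec, c(common, list(
    parametric = c("gender", covs),
    smooths = list(smooth_spec("age", k = k), smooth_spec(exposure, k = k)))))
  base <- do.call(model_spec, c(common, list(
    parametric = c("gender", exposure, covs),
    smooths = list(smooth_spec("age", k = k)))))
  list(full = full, base = base, direction = row$direction)
}

#' Fit full and base models for one outcome across imputations
#'
#' For each completed table: applies the outcome's QC row filters, fits the
#' full (smooth exposure) and base (linear exposure) models at the requested
#' covariate tier, compares them, and extracts the exposure partial effect.
#' When the oversmoothing diagnostic flags the exposure or age smooth, both
#' are refit with basis dimension 20 (`escalate_k = TRUE`).
#'
#' @param imputed An `imputed_set` (from [impute_chained()]), or a single
#'   data frame (treated as one "imputation", e.g. the observed-data
#'   sensitivity analysis).
#' @param outcome Outcome name (row of [outcome_specs()], or `"y"` for the
#'   generic simulated outcome).
#' @param tier Covariate tier, 1 or 2.
#' @param weighted Apply SES weights (column `weight`)?
#' @param k Basis dimension for the age and exposure smooths.
#' @param escalate_k Refit flagged smooths with `k = 20`?
#' @param alpha Significance level for the model comparison.
#' @return Tibble, one row per imputation: `imputation`, `p_smooth` (full
#'   model exposure smooth), `p_linear_onesided` (base model, directional),
#'   `linear_sign_flag` (TRUE when the linear coefficient contradicts the
#'   expected direction), `p_anova`, `delta_bic`, `preferred`, plus
#'   list-columns `full_fit`, `base_fit`, `partial_effect`, `comparison`.
#' @export
run_outcome <- function(imputed, outcome, tier = 1, weighted = TRUE,
                        k = 10, escalate_k = TRUE, alpha = 0.05) {
  tables <- if (inherits(imputed, "imputed_set")) imputed$tables else
    list(imputed)
  row <- outcome_row(outcome)
  filters <- row$row_filter[[1]]
  pair <- build_model_pair(outcome, tier = tier, k = k, weighted = weighted)
  needed <- unique(c(pair$full$outcome, pair$full$parametric,
                     pair$base$parametric, "age", "participant_id",
                     if (weighted) "weight"))
  purrr::imap_dfr(tables, function(tab, i) {
    miss <- setdiff(needed, names(tab))
    if (length(miss))
      abort(paste0("outcome `", outcome, "` needs missing column(s): ",
                   paste(miss, collapse = ", ")))
    for (fc in filters) tab <- tab[tab[[fc]] %in% TRUE, ]
    full <- fit_gamm(tab, pair$full)
    base <- fit_gamm(tab, pair$base)
    if (escalate_k) {
      flags <- check_oversmoothing(full)
      if (any(flags$flag)) {
        pair20 <- build_model_pair(outcome, tier = tier, k = 20,
                                   weighted = weighted)
        full <- fit_gamm(tab, pair20$full)
        base <- fit_gamm(tab, pair20$base)
      }
    }
    cmp <- compare_models(full, base, alpha = alpha)
    pe <- partial_effect(full, "s(lsns)", grid = 0:30)
    lin <- linear_pvalue(base, "lsns", direction = pair$direction)
    coef_sign <- sign(base$coefficients[["lsns"]])
    expected <- if (pair$direction == "positive") 1 else -1
    tibble::tibble(
      imputation = i, outcome = outcome, tier = tier,
      p_smooth = unname(full$smooth_pvalues[["s(lsns)"]]),
      p_linear_onesided = lin,
      linear_sign_flag = coef_sign != expected,
      p_anova = cmp$p, delta_bic = cmp$delta_bic, preferred = cmp$preferred,
      full_fit = list(full), base_fit = list(base),
      partial_effect = list(pe), comparison = list(cmp))
  })
}

#' Benjamini-Hochberg correction within the cognitive-aging family
#'
#' Applies BH FDR correction to the exposure-smooth p-values of the five
#' cognitive-aging outcomes (HCV, WMHV, executive functions, memory,
#' processing speed); mental-health outcomes (GAD7, CESD) pass through
#' uncorrected. Intended per imputation and per model tier.
#'
#' @param pvals Named numeric vector of p-values (names are outcomes).
#' @param family_outcomes Outcomes forming the family (default from
#'   [outcome_specs()]).
#' @return Named numeric vector of q-values in the same order.
#' @export
#' @examples
#' fdr_family(c(hcv = 0.01, wmhv = 0.02, executive = 0.03,
#'              memory = 0.04, processing_speed = 0.05, gad7 = 0.04))
fdr_family <- function(pvals, family_outcomes = NULL) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    abort("p-values must lie in [0, 1].")
  fam <- family_outcomes %||%
    outcome_specs()$outcome[outcome_specs()$cognitive_family]
  q <- pvals
  in_fam <- names(pvals) %in% fam
  q[in_fam] <- p.adjust(pvals[in_fam], method = "BH")
  q
}

#' Classify the exposure-outcome shape as hypothesis A, B or C
#'
#' Formalizes the qualitative shape assessment: when the model comparison
#' prefers the base (linear) model the verdict is `"A"`. Otherwise the mean
#' local gradient of the partial effect below (scores 0..cutoff-1) and at or
#' above the cutoff is computed with delta-method confidence intervals from
#' the grid covariance; `"C"` when the above-cutoff CI contains zero while
#' the below-cutoff CI excludes it, `"B"` when both exclude zero and the
#' below/above mean-gradient magnitude ratio exceeds `ratio_threshold`, and
#' `"inconclusive"` otherwise.
#'
#' @param comparison Output of [compare_models()].
#' @param pe A [partial_effect()] on the 0..30 grid.
#' @param cutoff Isolation cutoff (default 12).
#' @param ratio_threshold Below/above gradient-magnitude ratio required for
#'   `"B"` (default 1.5).
#' @param level CI level (default 0.95).
#' @return One-row tibble: `hypothesis`, mean gradients, standard errors and
#'   CIs below/above, `ratio`.
#' @export
classify_shape <- function(comparison, pe, cutoff = 12,
                           ratio_threshold = 1.5, level = 0.95) {
  if (!inherits(pe, "partial_effect")) abort("`pe` must be a partial_effect.")
  if (!isTRUE(all.equal(pe$grid, as.numeric(0:30))))
    abort("partial effect must be on the integer grid 0..30.")
  V <- attr(pe, "covariance")
  est <- pe$estimate
  if (attr(pe, "link") == "log") {
    J <- diag(exp(est))
    est <- exp(est)
    V <- J %*% V %*% J
  }
  n <- length(est)
  L <- matrix(0, n, n)
  L[1, 1:2] <- c(-1, 1)
  L[n, (n - 1):n] <- c(-1, 1)
  for (s in 2:(n - 1)) L[s, c(s - 1, s + 1)] <- c(-0.5, 0.5)
  below <- which(0:30 < cutoff)
  above <- which(0:30 >= cutoff)
  a_b <- colMeans(L[below, , drop = FALSE])
  a_a <- colMeans(L[above, , drop = FALSE])
  mb <- sum(a_b * est); ma <- sum(a_a * est)
  se_b <- sqrt(max(drop(a_b %*% V %*% a_b), 0))
  se_a <- sqrt(max(drop(a_a %*% V %*% a_a), 0))
  if (se_b == 0 || se_a == 0)
    abort("degenerate standard errors for the gradient summaries.")
  zq <- qnorm(1 - (1 - level) / 2)
  ci_b <- mb + c(-1, 1) * zq * se_b
  ci_a <- ma + c(-1, 1) * zq * se_a
  excl0 <- function(ci) ci[1] > 0 || ci[2] < 0
  ratio <- abs(mb) / max(abs(ma), .Machine$double.eps)
  hyp <- if (comparison$preferred == "base") {
    "A"
  } else if (!excl0(ci_a) && excl0(ci_b)) {
    "C"
  } else if (excl0(ci_a) && excl0(ci_b) && ratio > ratio_threshold) {
    "B"
  } else {
    "inconclusive"
  }
  tibble::tibble(hypothesis = hyp,
                 grad_below = mb, se_below = se_b,
                 ci_below_lo = ci_b[1], ci_below_hi = ci_b[2],
                 grad_above = ma, se_above = se_a,
                 ci_above_lo = ci_a[1], ci_above_hi = ci_a[2],
                 ratio = ratio)
}

#' Stratified sensitivity refits
#'
#' Refits the full pipeline for one outcome within strata (no cross-stratum
#' smoothing): by gender, retirement age (65), median socioeconomic score,
#' marital status, living alone, or completion of both waves. Strata smaller
#' than `min_rows` are skipped with a warning.
#'
#' @param imputed An `imputed_set` or single table.
#' @param outcome Outcome name.
#' @param stratifier One of `"gender"`, `"age65"`, `"ses_median"`,
#'   `"married"`, `"living_alone"`, `"completers"`.
#' @param min_rows Minimum rows per stratum (default 200).
#' @param ... Passed to [run_outcome()].
#' @return Tibble binding per-stratum [run_outcome()] results with a
#'   `stratum` column.
#' @export
stratified_run <- function(imputed, outcome,
                           stratifier = c("gender", "age65", "ses_median",
                                          "married", "living_alone",
                                          "completers"),
                           min_rows = 200, ...) {
  stratifier <- match.arg(stratifier)
  tables <- if (inherits(imputed, "imputed_set")) imputed$tables else
    list(imputed)
  strata_of <- function(tab) {
    switch(stratifier,
      gender = split(seq_len(nrow(tab)), tab$gender),
      age65 = split(seq_len(nrow(tab)),
                    ifelse(tab$age >= 65, "age>=65", "age<65")),
      ses_median = split(seq_len(nrow(tab)),
                         ifelse(tab$ses_score >= median(tab$ses_score,
                                                        na.rm = TRUE),
                                "ses_high", "ses_low")),
      married = split(seq_len(nrow(tab)),
                      ifelse(tab$married, "married", "unmarried")),
      living_alone = split(seq_len(nrow(tab)),
                           ifelse(tab$living_alone, "alone", "cohabitating")),
      completers = {
        n_waves <- table(tab$participant_id)
        split(seq_len(nrow(tab)),
              ifelse(n_waves[as.character(tab$participant_id)] == 2,
                     "completers", "single_wave"))
      })
  }
  labels <- names(strata_of(tables[[1]]))
  purrr::map_dfr(labels, function(lb) {
    sub_tabs <- purrr::map(tables, function(tab) {
      tab[strata_of(tab)[[lb]], , drop = FALSE]
    })
    if (nrow(sub_tabs[[1]]) < min_rows) {
      warn(sprintf("stratum `%s` has fewer than %d rows; skipped.",
                   lb, min_rows))
      return(NULL)
    }
    sub <- if (inherits(imputed, "imputed_set"))
      structure(list(m = length(sub_tabs), tables = sub_tabs,
                     models = imputed$models), class = "imputed_set")
    else sub_tabs[[1]]
    dplyr::mutate(run_outcome(sub, outcome, ...), stratum = lb,
                  .before = 1)
  })
}
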
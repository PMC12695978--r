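#' Configuration for the nonlinearity-detection power study
#'
#' @param n_reps Number of simulation replicates.
#' @param n_per_rep Baseline participants per replicate (the study's MRI
#'   subcohort size, 2600, is the reference point).
#' @param truth A [shape_spec()] giving the ground-truth exposure-outcome
#'   shape.
#' @param family Outcome family for the simulated outcome (the generic
#'   unit-scale outcome `y` is used for gaussian; `gad7` for Poisson; `wmhv`
#'   for gamma).
#' @param effect_amplitude Multiplier on the truth's slopes (1 = as
#'   specified; 0 turns the exposure effect into a null).
#' @param alpha Test level for detection (default 0.05).
#' @param detection_rule `"anova_p"` (nonlinearity declared when the
#'   smooth-vs-linear comparison p-value is below `alpha`) or
#'   `"anova_p_and_bic"` (additionally requires a lower BIC for the full
#'   model).
#' @param retention Follow-up retention of the simulated cohorts.
#' @param seed Integer seed; replicates use derived child seeds.
#' @return A `power_config` list.
#' @export
power_config <- function(n_reps = 200, n_per_rep = 2600,
                         truth = shape_spec("B"),
                         family = c("gaussian", "poisson", "gamma"),
                         effect_amplitude = 1, alpha = 0.05,
                         detection_rule = c("anova_p", "anova_p_and_bic"),
                         retention = 0.55, seed = 1L) {
  n_reps <- assert_count(n_reps)
  n_per_rep <- assert_count(n_per_rep)
  family <- match.arg(family)
  detection_rule <- match.arg(detection_rule)
  stopifnot(inherits(truth, "shape_spec"), alpha > 0, alpha < 1,
            effect_amplitude >= 0)
  structure(list(n_reps = n_reps, n_per_rep = n_per_rep, truth = truth,
                 family = family, effect_amplitude = effect_amplitude,
                 alpha = alpha, detection_rule = detection_rule,
                 retention = retention, seed = as.integer(seed)),
            class = "power_config")
}

scale_shape <- function(truth, amplitude) {
  if (amplitude == 1) return(truth)
  s <- unclass(truth)
  s$slope_above <- s$slope_above * amplitude
  s$slope_below <- s$slope_below * amplitude
  if (amplitude == 0 || s$hypothesis == "A") {
    structure(list(hypothesis = "A", cutoff = s$cutoff,
                   slope_above = s$slope_above, slope_below = s$slope_above),
              class = "shape_spec")
  } else {
    structure(s, class = "shape_spec")
  }
}

#' Simulation power analysis for nonlinearity detection
#'
#' For each replicate: generates a two-wave cohort under the configured
#' ground-truth shape, fits the tier-1 full (smooth exposure) and base
#' (linear exposure) models, and records the smooth-vs-linear comparison.
#' Detection follows the configured rule; replicates whose fits fail to
#' converge are counted and excluded, never silently dropped.
#'
#' @param config A [power_config()].
#' @param keep_partial_effects Keep each replicate's exposure partial effect
#'   (needed by [shape_readability_check()])? Default `TRUE`.
#' @return An object of class `power_result`: list with `detection_rate`,
#'   `false_nonlinearity_rate` (identical to the detection rate when the
#'   truth is linear, `NA` otherwise), `beta` (type-II error,
#'   `1 - detection_rate`, for nonlinear truths), binomial 95% CI,
#'   `n_nonconverged`, and a per-replicate tibble `reps`.
#' @export
run_power <- function(config, keep_partial_effects = TRUE) {
  if (!inherits(config, "power_config")) abort("`config` must be a power_config.")
  truth <- scale_shape(config$truth, config$effect_amplitude)
  outcome <- switch(config$family, gaussian = "y", poisson = "gad7",
                    gamma = "wmhv")
  reps <- purrr::map_dfr(seq_len(config$n_reps), function(r) {
    cc <- cohort_config(config$n_per_rep, retention = config$retention,
                        seed = child_seed(config$seed, r))
    tab <- sample_cohort(cc, setNames(list(truth), outcome))
    pair <- build_model_pair(outcome, tier = 1, weighted = FALSE)
    res <- tryCatch({
      full <- fit_gamm(tab, pair$full)
      base <- fit_gamm(tab, pair$base)
      cmp <- compare_models(full, base, alpha = config$alpha)
      pe <- if (keep_partial_effects) list(partial_effect(full, "s(lsns)",
                                                          grid = 0:30))
            else list(NULL)
      tibble::tibble(rep = r, converged = full$converged && base$converged,
                     p = cmp$p, delta_bic = cmp$delta_bic,
                     preferred = cmp$preferred,
                     partial_effect = pe, comparison = list(cmp))
    }, error = function(e) {
      tibble::tibble(rep = r, converged = FALSE, p = NA_real_,
                     delta_bic = NA_real_, preferred = NA_character_,
                     partial_effect = list(NULL), comparison = list(NULL))
    })
    res
  })
  ok <- reps[reps$converged %in% TRUE, ]
  detected <- if (config$detection_rule == "anova_p") {
    ok$p < config$alpha
  } else {
    ok$p < config$alpha & ok$delta_bic > 0
  }
  rate <- mean(detected)
  ci <- stats::binom.test(sum(detected), length(detected))$conf.int
  linear_truth <- truth$hypothesis == "A"
  structure(list(
    detection_rate = rate,
    false_nonlinearity_rate = if (linear_truth) rate else NA_real_,
    beta = if (linear_truth) NA_real_ else 1 - rate,
    ci = as.numeric(ci),
    n_nonconverged = sum(!(reps$converged %in% TRUE)),
    detected = detected, reps = reps, config = config,
    truth = truth
  ), class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat("<power_result>", x$config$n_reps, "reps, truth",
      x$truth$hypothesis, "\n")
  cat(sprintf("  detection rate %.1f%% (95%% CI %.1f-%.1f), %d non-converged\n",
              100 * x$detection_rate, 100 * x$ci[1], 100 * x$ci[2],
              x$n_nonconverged))
  if (!is.na(x$beta))
    cat(sprintf("  type-II error beta = %.1f%%\n", 100 * x$beta))
  invisible(x)
}

#' @method glance power_result
#' @export
glance.power_result <- function(x, ...) {
  tibble::tibble(detection_rate = x$detection_rate,
                 false_nonlinearity_rate = x$false_nonlinearity_rate,
                 beta = x$beta, ci_lo = x$ci[1], ci_hi = x$ci[2],
                 n_reps = x$config$n_reps,
                 n_nonconverged = x$n_nonconverged)
}

#' Can the plotted shape disambiguate false nonlinearity calls?
#'
#' For linear-truth replicates flagged as nonlinear by the comparison,
#' classifies the shape of each flagged replicate's partial effect; a
#' majority of `"A"` verdicts supports reading the accompanying partial
#' effect plots to recognize spurious nonlinearity.
#'
#' @param power A `power_result` from a linear-truth run with partial
#'   effects kept.
#' @return List with `verdict_counts` (table of shape verdicts among
#'   flagged replicates), `n_flagged`, `supportive` (logical; vacuously
#'   `TRUE` when nothing was flagged).
#' @export
shape_readability_check <- function(power) {
  if (!inherits(power, "power_result")) abort("`power` must be a power_result.")
  ok <- power$reps[power$reps$converged %in% TRUE, ]
  if (nrow(ok) < 10) abort("need at least 10 converged replicates.")
  flagged <- ok[power$detected, ]
  if (nrow(flagged) == 0)
    return(list(verdict_counts = table(character()), n_flagged = 0L,
                supportive = TRUE))
  verdicts <- purrr::map_chr(seq_len(nrow(flagged)), function(i) {
    pe <- flagged$partial_effect[[i]]
    if (is.null(pe)) return(NA_character_)
    # the comparison already called "full"; judge the plotted shape alone
    cmp <- flagged$comparison[[i]]
    classify_shape(cmp, pe)$hypothesis
  })
  counts <- table(verdicts)
  list(verdict_counts = counts, n_flagged = nrow(flagged),
       supportive = sum(verdicts %in% "A") > nrow(flagged) / 2)
}
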
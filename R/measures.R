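#' Measurement-derivation settings
#'
#' Bounds and cutpoints used by the measurement-level derivations:
#' plausibility windows for BMI and systolic blood pressure, hypertension and
#' diabetes cutpoints, the education dichotomization cut, the epsilon added
#' after the negate-shift transform for gamma-family outcomes, and the
#' population share per socioeconomic quintile used in weighting.
#'
#' @param bmi_bounds,sbp_bounds Plausibility windows; values outside are set
#'   missing before any averaging.
#' @param sbp_hyper,dbp_hyper Blood-pressure cutpoints (exceeding either mean
#'   flags hypertension).
#' @param hba1c_cut HbA1c percentage at or above which diabetes is flagged.
#' @param education_cut Education score below which low education is flagged.
#' @param income_bounds Score range of the banded equivalised income.
#' @param gamma_shift_epsilon Offset keeping shifted scores strictly positive.
#' @param ses_population_share Population share per SES quintile (0.20).
#' @param ses_quintile_breaks Upper breakpoints of SES-score quintile bands
#'   on the 3--21 score scale (fixed population-referenced stand-ins, not
#'   sample quantiles).
#' @return A `derived_config` list.
#' @export
derived_config <- function(bmi_bounds = c(15, 50),
                           sbp_bounds = c(80, 200),
                           sbp_hyper = 140, dbp_hyper = 90,
                           hba1c_cut = 6.0,
                           education_cut = 3.6,
                           income_bounds = c(1, 7),
                           gamma_shift_epsilon = 1e-5,
                           ses_population_share = 0.20,
                           ses_quintile_breaks = c(8, 11, 14, 17)) {
  stopifnot(bmi_bounds[1] < bmi_bounds[2], sbp_bounds[1] < sbp_bounds[2],
            gamma_shift_epsilon > 0, length(ses_quintile_breaks) == 4,
            !is.unsorted(ses_quintile_breaks))
  structure(as.list(environment()), class = "derived_config")
}

#' z-transform with missing propagation
#'
#' Centers and scales to unit sample (n-1) standard deviation over the
#' non-missing entries; missing entries stay missing.
#'
#' @param x Numeric vector with at least two distinct non-missing values.
#' @return Numeric vector, mean 0 and SD 1 over non-missing entries.
#' @export
#' @examples zscore(c(1, 2, 3))
zscore <- function(x) {
  obs <- x[!is.na(x)]
  if (length(obs) < 2) abort("zscore needs >= 2 non-missing values.")
  s <- sd(obs)
  if (s == 0) abort("zscore is undefined for a constant vector.")
  (x - mean(obs)) / s
}

#' Domain-specific cognitive composite scores
#'
#' Builds the three composites from raw subtests, z-transforming each
#' component over the supplied sample:
#' executive = (z(phonematic) + z(semantic) + z(-(TMT-B - TMT-A)/TMT-A)) / 3;
#' memory = (z(learning) + z(recall) + z(recognition)) / 3;
#' processing speed = -z(TMT-A), so slower times mean lower scores.
#' A missing component makes the composite missing; TMT-A of zero is flagged
#' missing with a warning.
#'
#' @param data Data frame with columns `tmt_a`, `tmt_b`, `fluency_phon`,
#'   `fluency_sem`, `learning`, `recall`, `recognition`.
#' @return `data` with `executive`, `memory` and `processing_speed` added.
#' @export
composite_scores <- function(data) {
  need <- c("tmt_a", "tmt_b", "fluency_phon", "fluency_sem",
            "learning", "recall", "recognition")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(paste0("missing columns: ", paste(miss, collapse = ", ")))
  tmt_a <- data$tmt_a
  bad <- !is.na(tmt_a) & tmt_a == 0
  if (any(bad)) {
    warn(sprintf("%d TMT-A values of zero set missing in composites.", sum(bad)))
    tmt_a[bad] <- NA
  }
  tmt_contrast <- -(data$tmt_b - tmt_a) / tmt_a
  data$executive <- (zscore(data$fluency_phon) + zscore(data$fluency_sem) +
                       zscore(tmt_contrast)) / 3
  data$memory <- (zscore(data$learning) + zscore(data$recall) +
                    zscore(data$recognition)) / 3
  data$processing_speed <- -zscore(tmt_a)
  data
}

#' Adjust hippocampal volume for intracranial volume
#'
#' Removes the head-size component of hippocampal volume via
#' `HCV_adj = HCV_raw - beta * (ICV_raw - mean(ICV))`, where `beta` is the
#' unstandardized coefficient of HCV on ICV from a random-intercept linear
#' fit on the analysis sample (supply a fit from [fit_gamm()] with `icv_raw`
#' as a parametric term, or a numeric `beta` directly).
#'
#' @param hcv_raw,icv_raw Volumes in cubic millimetres.
#' @param fit A `gamm_fit` containing an `icv_raw` coefficient, or a single
#'   numeric `beta`.
#' @return Adjusted volumes; their sample covariance with ICV is
#'   approximately zero by construction.
#' @export
adjust_hcv <- function(hcv_raw, icv_raw, fit) {
  beta <- if (is.numeric(fit) && length(fit) == 1) {
    fit
  } else if (inherits(fit, "gamm_fit")) {
    if (!"icv_raw" %in% names(fit$coefficients))
      abort("`fit` has no `icv_raw` term; the adjustment model must regress HCV on ICV.")
    unname(fit$coefficients[["icv_raw"]])
  } else {
    abort("`fit` must be a gamm_fit with an `icv_raw` term or a numeric beta.")
  }
  hcv_raw - beta * (icv_raw - mean(icv_raw, na.rm = TRUE))
}

#' OECD-modified equivalised household income and its banded score
#'
#' Divides net household income by `1 + 0.5 * (additional members >= 15y) +
#' 0.3 * (members < 15y)`. `income_score()` bands the equivalised income on
#' the 1.0--7.0 scale, with 1.0 below 800 EUR, 7.0 at or above 3000 EUR, and
#' equal-width half-point steps in between.
#'
#' @param net_income Net household income (EUR / month).
#' @param members_ge15 Additional household members aged >= 15 (excluding the
#'   reference person).
#' @param members_lt15 Household members younger than 15.
#' @return Equivalised income (numeric).
#' @export
#' @examples
#' equivalised_income(1800, 1, 1)  # couple with one child: divisor 1.8
equivalised_income <- function(net_income, members_ge15, members_lt15) {
  if (any(members_ge15 < 0, na.rm = TRUE) || any(members_lt15 < 0, na.rm = TRUE))
    abort("household member counts must be non-negative.")
  net_income / (1 + 0.5 * members_ge15 + 0.3 * members_lt15)
}

#' @rdname equivalised_income
#' @param equiv_income Equivalised income as returned by
#'   [equivalised_income()].
#' @export
income_score <- function(equiv_income) {
  # equal-width half-point bands between the printed endpoints:
  # < 800 -> 1.0, >= 3000 -> 7.0
  breaks <- seq(800, 3000, length.out = 12)
  1 + 0.5 * findInterval(equiv_income, breaks)
}

#' Socioeconomic score, quintile and survey weights
#'
#' `ses_score()` sums the education, income and occupation sub-scores (each
#' 1--7, total 3--21). `ses_quintile()` assigns population-referenced
#' quintile bands from fixed breakpoints (a documented stand-in for the
#' published reference table). `ses_weights()` returns
#' `weight = 0.20 / (sample prevalence of the participant's quintile)` so
#' the weighted quintile shares are exactly 20% each; participants with no
#' pre-imputation SES get weight 1. Weights are computed per participant
#' (constant across that participant's waves, from the baseline label).
#'
#' @param education,income,occupation Sub-scores on the 1--7 scale.
#' @return For `ses_score()` a numeric vector.
#' @export
ses_score <- function(education, income, occupation) {
  education + income + occupation
}

#' @rdname ses_score
#' @param score SES scores on the 3--21 scale.
#' @param config A [derived_config()].
#' @export
ses_quintile <- function(score, config = derived_config()) {
  q <- findInterval(score, config$ses_quintile_breaks, left.open = TRUE) + 1L
  q[is.na(score)] <- NA_integer_
  q
}

#' @rdname ses_score
#' @param quintile Integer quintile labels 1--5 (NA = SES unavailable before
#'   imputation).
#' @export
ses_weights <- function(quintile, config = derived_config()) {
  obs <- quintile[!is.na(quintile)]
  if (length(obs)) {
    present <- sort(unique(obs))
    prev <- tabulate(obs, nbins = 5L)[present] / length(obs)
    w_by_q <- setNames(config$ses_population_share / prev, present)
    bad <- setdiff(obs, as.integer(names(w_by_q)[w_by_q > 0]))
    if (length(bad)) abort("quintile label with zero prevalence encountered.")
  } else {
    w_by_q <- numeric()
  }
  out <- rep(1, length(quintile))
  idx <- !is.na(quintile)
  out[idx] <- w_by_q[as.character(quintile[idx])]
  out
}

#' Dichotomize hypertension and diabetes
#'
#' Applies plausibility filtering first (systolic readings outside the
#' configured window set missing; BMI is filtered separately), then averages
#' the available blood-pressure readings and flags hypertension when there is
#' a prior diagnosis, antihypertensive medication, mean systolic > 140 mmHg
#' or mean diastolic > 90 mmHg. Diabetes is flagged on prior diagnosis,
#' antidiabetic medication or HbA1c >= 6%. When no reading survives and no
#' diagnosis/medication flag is positive, the flag is missing.
#'
#' @param data Data frame with `sbp_1..3`, `dbp_1..3`, `hypertension_dx`,
#'   `antihypertensive_med`, `diabetes_dx`, `antidiabetic_med`, `hba1c`.
#' @param config A [derived_config()].
#' @return `data` with logical `hypertension` and `diabetes` columns and
#'   plausibility-filtered `bmi`.
#' @export
dichotomize_clinical <- function(data, config = derived_config()) {
  sbp <- as.matrix(data[paste0("sbp_", 1:3)])
  dbp <- as.matrix(data[paste0("dbp_", 1:3)])
  sbp[sbp > config$sbp_bounds[2] | sbp < config$sbp_bounds[1]] <- NA
  mean_sbp <- rowMeans(sbp, na.rm = TRUE); mean_sbp[is.nan(mean_sbp)] <- NA
  mean_dbp <- rowMeans(dbp, na.rm = TRUE); mean_dbp[is.nan(mean_dbp)] <- NA
  bp_high <- (mean_sbp > config$sbp_hyper) | (mean_dbp > config$dbp_hyper)
  dxmed <- data$hypertension_dx | data$antihypertensive_med
  hyper <- dxmed | bp_high
  # dx/med FALSE with unknown BP leaves the flag unknown
  hyper[is.na(bp_high) & !(dxmed %in% TRUE)] <- NA
  dxmed_d <- data$diabetes_dx | data$antidiabetic_med
  high_a1c <- data$hba1c >= config$hba1c_cut
  diab <- dxmed_d | high_a1c
  diab[is.na(high_a1c) & !(dxmed_d %in% TRUE)] <- NA
  data$hypertension <- hyper
  data$diabetes <- diab
  if ("bmi" %in% names(data)) {
    out_of_range <- !is.na(data$bmi) &
      (data$bmi > config$bmi_bounds[2] | data$bmi < config$bmi_bounds[1])
    data$bmi[out_of_range] <- NA
  }
  data
}

#' Inverse-hyperbolic-sine transform for depressive-symptom scores
#'
#' Monotone variance-stabilizing transform used when the CESD sum score
#' enters as a covariate; maps 0 to 0.
#'
#' @param cesd Non-negative scores.
#' @return `asinh(cesd)`.
#' @export
asinh_cesd <- function(cesd) {
  if (any(cesd < 0, na.rm = TRUE)) abort("CESD scores must be non-negative.")
  asinh(cesd)
}

#' Negate-shift transform for gamma-family modelling
#'
#' Negates scores (so worse performance becomes larger values), subtracts the
#' minimum and adds a small epsilon, yielding a strictly positive,
#' right-skew-compatible variable with reversed order.
#'
#' @param scores Numeric vector.
#' @param epsilon Positive offset (default 1e-5).
#' @return Positive vector with minimum `epsilon`.
#' @export
#' @examples gamma_shift(c(-1, 0, 2))
gamma_shift <- function(scores, epsilon = 1e-5) {
  neg <- -scores
  neg - min(neg, na.rm = TRUE) + epsilon
}

#' Derive all analysis variables on a cohort table
#'
#' Convenience wrapper applying the full measurement chain: plausibility
#' filters and clinical dichotomizations, cognitive composites, equivalised
#' income and its score, SES score/quintile/weights (from baseline labels,
#' constant across waves), the low-education flag, `asinh`-transformed CESD
#' (when present), ICV-adjusted hippocampal volume (via a random-intercept
#' linear fit of HCV on ICV when both volumes are present), and the
#' negate-shift transforms `memory_shift` / `processing_speed_shift`.
#'
#' @param data A cohort tibble (as from [sample_cohort()]).
#' @param config A [derived_config()].
#' @return The augmented tibble.
#' @export
derive_measures <- function(data, config = derived_config()) {
  data <- dichotomize_clinical(data, config)
  data <- composite_scores(data)
  data$equiv_income <- equivalised_income(data$net_income, data$members_ge15,
                                          data$members_lt15)
  data$income_score <- income_score(data$equiv_income)
  data$ses_score <- ses_score(data$education_score, data$income_score,
                              data$occupation_score)
  # baseline SES label carried to all waves, weights constant per participant
  bl <- data[data$wave == "baseline", c("participant_id", "ses_score")]
  bl$ses_quintile <- ses_quintile(bl$ses_score, config)
  bl$weight <- ses_weights(bl$ses_quintile, config)
  data$ses_quintile <- bl$ses_quintile[match(data$participant_id, bl$participant_id)]
  data$ses_score <- bl$ses_score[match(data$participant_id, bl$participant_id)]
  data$weight <- bl$weight[match(data$participant_id, bl$participant_id)]
  data$low_education <- data$education_score < config$education_cut
  if ("cesd" %in% names(data)) data$cesd_asinh <- asinh_cesd(data$cesd)
  if (all(c("hcv_raw", "icv_raw") %in% names(data))) {
    adj_fit <- fit_gamm(data, model_spec(
      outcome = "hcv_raw", family = "gaussian",
      parametric = "icv_raw", smooths = list(),
      random_intercept = TRUE, id = "participant_id"))
    data$hcv_adj <- adjust_hcv(data$hcv_raw, data$icv_raw, adj_fit)
  }
  if ("memory" %in% names(data))
    data$memory_shift <- gamma_shift(data$memory, config$gamma_shift_epsilon)
  if ("processing_speed" %in% names(data))
    data$processing_speed_shift <- gamma_shift(data$processing_speed,
                                               config$gamma_shift_epsilon)
  data
}
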
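#' Configuration for the synthetic cohort simulator
#'
#' Collects the population-level parameters of the simulated longitudinal
#' cohort: two assessment waves roughly 6.5 years apart, partial retention at
#' follow-up, a discretized near-normal social-contact score (LSNS-6, 0--30,
#' higher = more contact, mean around 16--17 with roughly 20% of participants
#' below the conventional isolation cutoff of 12), and participant-level
#' random intercepts shared across waves.
#'
#' @param n_participants Number of baseline participants.
#' @param retention Fraction of baseline participants re-assessed at
#'   follow-up, in (0, 1].
#' @param lsns_mean,lsns_sd Mean and SD of the latent normal behind the
#'   rounded, truncated LSNS score.
#' @param female_fraction Fraction of female participants.
#' @param age_range_baseline Length-2 numeric, uniform age range at baseline
#'   in years.
#' @param wave_gap_years Years between baseline and follow-up.
#' @param random_intercept_sd Named numeric vector of per-outcome random
#'   intercept SDs on the link scale; unnamed outcomes fall back to defaults.
#' @param noise_params Named list of per-outcome family dispersion parameters
#'   (`sd` for gaussian, `phi` for gamma); merged over defaults.
#' @param age_amplitude Amplitude of the quadratic age effect on the link
#'   scale of each outcome (named numeric, merged over defaults). The age
#'   effect is a mild quadratic so that the `s(age)` term of downstream
#'   models has genuinely nonlinear structure to absorb.
#' @param informative_attrition If `TRUE`, dropout probability increases with
#'   baseline age (logistic, +0.5 log-odds per age SD) while keeping the
#'   marginal retention at `retention`; default is dropout completely at
#'   random.
#' @param seed Integer seed; the same configuration and seed reproduce a
#'   byte-identical cohort.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @export
#' @examples
#' cfg <- cohort_config(n_participants = 500, seed = 1)
cohort_config <- function(n_participants,
                          retention = 0.55,
                          lsns_mean = 16.5,
                          lsns_sd = 5.7,
                          female_fraction = 0.53,
                          age_range_baseline = c(40, 80),
                          wave_gap_years = 6.5,
                          random_intercept_sd = NULL,
                          noise_params = NULL,
                          age_amplitude = NULL,
                          informative_attrition = FALSE,
                          seed = 1L) {
  n_participants <- assert_count(n_participants)
  retention <- assert_fraction(retention, open_left = TRUE)
  if (!(lsns_mean > 0 && lsns_mean < 30)) abort("`lsns_mean` must lie in (0, 30).")
  if (!(lsns_sd >= 0)) abort("`lsns_sd` must be non-negative.")
  assert_fraction(female_fraction)
  stopifnot(length(age_range_baseline) == 2L,
            age_range_baseline[1] < age_range_baseline[2],
            wave_gap_years > 0)

  ri_default <- c(y = 0.5, hcv = 150, wmhv = 0.3, gad7 = 0.25, cesd = 0.3,
                  executive = 0.5, memory = 0.5, processing_speed = 0.5)
  ri <- ri_default
  if (!is.null(random_intercept_sd)) {
    if (any(random_intercept_sd < 0)) abort("random intercept SDs must be >= 0.")
    ri[names(random_intercept_sd)] <- random_intercept_sd
  }
  noise_default <- list(y = c(sd = 1), hcv = c(sd = 300), wmhv = c(phi = 0.4),
                        gad7 = c(mu0 = 2.5), cesd = c(mu0 = 8),
                        executive = c(sd = 0.6), memory = c(sd = 0.6),
                        processing_speed = c(sd = 0.6))
  if (!is.null(noise_params)) noise_default[names(noise_params)] <- noise_params
  age_default <- c(y = 0.3, hcv = -120, wmhv = 0.35, gad7 = -0.1, cesd = -0.1,
                   executive = -0.3, memory = -0.35, processing_speed = -0.35)
  if (!is.null(age_amplitude)) age_default[names(age_amplitude)] <- age_amplitude

  structure(list(
    n_participants = n_participants, retention = retention,
    lsns_mean = lsns_mean, lsns_sd = lsns_sd,
    female_fraction = female_fraction,
    age_range_baseline = as.numeric(age_range_baseline),
    wave_gap_years = wave_gap_years,
    random_intercept_sd = ri, noise_params = noise_default,
    age_amplitude = age_default,
    informative_attrition = isTRUE(informative_attrition),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Ground-truth exposure-outcome shape
#'
#' Encodes the three competing hypotheses on the shape of the LSNS-outcome
#' relationship: `"A"` a single linear slope across the whole score range;
#' `"B"` an effect everywhere that is steeper below the isolation cutoff
#' (piecewise linear, continuous at the cutoff); `"C"` an effect confined to
#' scores below the cutoff (flat at and above it).
#'
#' Slopes are per LSNS point on the link scale of the outcome they are
#' attached to. Defaults are on a unit-residual-SD scale (see the methods
#' vignette for the calibration of the hypothesis-B slope).
#'
#' @param hypothesis One of `"A"`, `"B"`, `"C"`.
#' @param cutoff Integer isolation cutoff (scores strictly below are
#'   "isolated"); default 12.
#' @param slope_above Slope for scores at or above the cutoff.
#' @param slope_below Slope for scores below the cutoff.
#' @return An object of class `shape_spec`.
#' @export
#' @examples
#' shape_spec("B")
shape_spec <- function(hypothesis = c("A", "B", "C"),
                       cutoff = 12L,
                       slope_above = NULL,
                       slope_below = NULL) {
  hypothesis <- match.arg(hypothesis)
  cutoff <- assert_count(cutoff)
  defaults <- switch(hypothesis,
    A = list(above = 0.05, below = 0.05),
    B = list(above = 0.05, below = 0.25),
    C = list(above = 0, below = 0.25))
  slope_above <- slope_above %||% defaults$above
  if (hypothesis == "A") {
    slope_below <- slope_below %||% slope_above
    if (!isTRUE(all.equal(slope_below, slope_above)))
      abort("hypothesis A requires slope_below == slope_above.")
  } else {
    slope_below <- slope_below %||% (sign(slope_above + (slope_above == 0)) *
                                       abs(defaults$below))
  }
  if (hypothesis == "B" &&
      !(abs(slope_below) > abs(slope_above) && abs(slope_above) > 0))
    abort("hypothesis B requires |slope_below| > |slope_above| > 0.")
  if (hypothesis == "C" && !(slope_above == 0 && slope_below != 0))
    abort("hypothesis C requires slope_above == 0 and slope_below != 0.")
  structure(list(hypothesis = hypothesis, cutoff = cutoff,
                 slope_above = slope_above, slope_below = slope_below),
            class = "shape_spec")
}

#' Draw discretized LSNS-6 scores
#'
#' Samples from a normal distribution truncated to (-0.5, 30.5) and rounded
#' to integers, so scores cover 0--30 and, at the default mean 16.5 / SD 5.7,
#' about 19--20% fall below the isolation cutoff of 12.
#'
#' @param n Number of draws.
#' @param config A [cohort_config()]; supplies mean and SD.
#' @param seed Optional integer seed (defaults to the config seed).
#' @return Integer vector in 0..30.
#' @export
#' @examples
#' mean(sample_lsns(1e4, cohort_config(10), seed = 1) < 12)
sample_lsns <- function(n, config = cohort_config(n), seed = NULL) {
  n <- assert_count(n)
  if (!is.null(seed)) set.seed(as.integer(seed))
  r_lsns(n, config$lsns_mean, config$lsns_sd)
}

# inverse-CDF draw from the rounded truncated normal
r_lsns <- function(n, mean, sd) {
  if (sd == 0) return(rep.int(as.integer(round(mean)), n))
  lo <- pnorm(-0.5, mean, sd)
  hi <- pnorm(30.5, mean, sd)
  u <- runif(n, lo, hi)
  as.integer(pmin(pmax(round(qnorm(u, mean, sd)), 0L), 30L))
}

#' Ground-truth contribution of LSNS to the linear predictor
#'
#' Evaluates the piecewise-linear latent effect implied by a [shape_spec()]:
#' continuous in the score, anchored at zero at the cutoff.
#'
#' @param lsns Integer scores in 0..30.
#' @param shape A [shape_spec()].
#' @return Numeric vector, link-scale contribution.
#' @export
#' @examples
#' latent_effect(0:30, shape_spec("C"))
latent_effect <- function(lsns, shape) {
  if (!inherits(shape, "shape_spec")) abort("`shape` must be a shape_spec.")
  if (any(lsns < 0 | lsns > 30, na.rm = TRUE)) abort("scores must lie in [0, 30].")
  d <- lsns - shape$cutoff
  switch(shape$hypothesis,
    A = shape$slope_above * d,
    B = ifelse(d < 0, shape$slope_below * d, shape$slope_above * d),
    C = shape$slope_below * pmin(d, 0))
}

# quadratic age effect, centered at 60 and scaled per 20 years; bounded and
# mean-ish zero over the default 40-80 range
age_effect <- function(age, amplitude) {
  z <- (age - 60) / 20
  amplitude * (z^2 - 1 / 3)
}

#' Simulate a two-wave cohort table
#'
#' Generates a long-format cohort (one row per participant-wave) with the
#' structure the shape analysis assumes: discretized LSNS scores, a smooth
#' nonlinear age effect, a gender effect, participant random intercepts
#' shared across waves, family-appropriate outcome noise (gaussian for `y`,
#' `hcv` and cognitive composites; gamma for `wmhv`; Poisson for `gad7` and
#' `cesd`), plus the covariates consumed by the measurement derivations
#' (blood pressure readings, HbA1c, BMI, education/income/occupation,
#' household composition, diagnosis and medication flags, raw cognitive
#' subtests, MRI volumes and QC flags).
#'
#' Outcomes are generated for exactly the names in `shapes`; cognitive
#' subtests are always emitted (with the latent effect propagated into them
#' when the corresponding composite outcome is requested). Questionnaire
#' counts are clipped to the instrument range and the clipped fraction is
#' recorded in the `"clipping"` attribute.
#'
#' @param config A [cohort_config()].
#' @param shapes Named list of [shape_spec()] objects; names among
#'   `"y"`, `"hcv"`, `"wmhv"`, `"gad7"`, `"cesd"`, `"executive"`,
#'   `"memory"`, `"processing_speed"`.
#' @param seed Optional seed overriding `config$seed`.
#' @return A tibble with one row per participant-wave.
#' @export
#' @examples
#' tab <- sample_cohort(cohort_config(200, seed = 7), list(y = shape_spec("A")))
sample_cohort <- function(config, shapes, seed = NULL) {
  if (!inherits(config, "cohort_config")) abort("`config` must be a cohort_config.")
  known <- c("y", "hcv", "wmhv", "gad7", "cesd",
             "executive", "memory", "processing_speed")
  if (length(shapes) == 0 || is.null(names(shapes)) || any(names(shapes) == ""))
    abort("`shapes` must be a named list of shape_spec objects.")
  bad <- setdiff(names(shapes), known)
  if (length(bad)) abort(paste0("unknown outcome(s) in `shapes`: ",
                                paste(bad, collapse = ", ")))
  if (!all(vapply(shapes, inherits, TRUE, "shape_spec")))
    abort("every element of `shapes` must be a shape_spec.")
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))

  n <- config$n_participants
  id <- seq_len(n)
  gender <- ifelse(runif(n) < config$female_fraction, "female", "male")
  age_bl <- runif(n, config$age_range_baseline[1], config$age_range_baseline[2])
  lsns_bl <- r_lsns(n, config$lsns_mean, config$lsns_sd)
  # follow-up score correlated with baseline (rho = 0.7 on the latent scale)
  rho <- 0.7
  lat_bl <- lsns_bl + runif(n, -0.5, 0.5)
  lat_fu <- config$lsns_mean + rho * (lat_bl - config$lsns_mean) +
    sqrt(1 - rho^2) * config$lsns_sd * rnorm(n)
  lsns_fu <- as.integer(pmin(pmax(round(lat_fu), 0L), 30L))

  # retention: MCAR dropout by default, optionally informative in age
  if (config$retention >= 1) {
    keep <- rep(TRUE, n)
  } else if (config$informative_attrition) {
    za <- as.numeric(scale(age_bl))
    a0 <- uniroot(function(a) mean(plogis(a + 0.5 * za)) - config$retention,
                  c(-20, 20))$root
    keep <- runif(n) < plogis(a0 + 0.5 * za)
  } else {
    keep <- runif(n) < config$retention
  }

  # time-constant socioeconomic block: Gaussian copula, rho = 0.5
  ch <- chol(matrix(c(1, .5, .5, .5, 1, .5, .5, .5, 1), 3))
  zz <- matrix(rnorm(3 * n), n) %*% ch
  u <- pnorm(zz)
  edu_probs <- c(.02, .05, .10, .18, .25, .22, .18)  # <10% below tertiary cut
  education <- findInterval(u[, 1], cumsum(edu_probs)) + 1L
  education <- pmin(education, 7L)
  net_income <- round(exp(log(2200) + 0.55 * zz[, 2]))
  occupation <- pmin(findInterval(u[, 3], cumsum(edu_probs)) + 1L, 7L)
  members_ge15 <- rbinom(n, 2, 0.45)
  members_lt15 <- rbinom(n, 2, 0.20)

  # clinical covariates
  hba1c <- round(rnorm(n, 5.5, 0.55), 2)
  bmi <- round(rnorm(n, 27, 4), 1)
  hypertension_dx <- runif(n) < plogis(-1.2 + 0.05 * (age_bl - 60))
  antihypertensive_med <- hypertension_dx & runif(n) < 0.7
  diabetes_dx <- runif(n) < plogis(-2.3 + 0.04 * (age_bl - 60))
  antidiabetic_med <- diabetes_dx & runif(n) < 0.8
  sbp_base <- rnorm(n, 128 + 0.4 * (age_bl - 60), 14)
  dbp_base <- rnorm(n, 80 + 0.1 * (age_bl - 60), 9)
  married <- runif(n) < 0.62
  living_alone <- !married & runif(n) < 0.55
  non_working <- runif(n) < plogis(-3 + 0.18 * (age_bl - 60))

  ri <- lapply(config$random_intercept_sd, function(s) rnorm(n, 0, s))
  clip_log <- c()

  make_wave <- function(wave, idx) {
    m <- length(idx)
    age <- age_bl[idx] + if (wave == "followup") config$wave_gap_years else 0
    lsns <- if (wave == "baseline") lsns_bl[idx] else lsns_fu[idx]
    gend <- gender[idx]
    g_num <- as.numeric(gend == "male")
    bmi_w <- bmi[idx] + if (identical(wave, "followup"))
      round(rnorm(m, 0.3, 0.8), 1) else 0
    out <- tibble::tibble(
      participant_id = id[idx], wave = wave, age = age, gender = gend,
      lsns = lsns,
      education_score = education[idx], occupation_score = occupation[idx],
      net_income = net_income[idx], members_ge15 = members_ge15[idx],
      members_lt15 = members_lt15[idx],
      bmi = bmi_w,
      sbp_1 = round(sbp_base[idx] + rnorm(m, 0, 6)),
      sbp_2 = round(sbp_base[idx] + rnorm(m, 0, 6)),
      sbp_3 = round(sbp_base[idx] + rnorm(m, 0, 6)),
      dbp_1 = round(dbp_base[idx] + rnorm(m, 0, 5)),
      dbp_2 = round(dbp_base[idx] + rnorm(m, 0, 5)),
      dbp_3 = round(dbp_base[idx] + rnorm(m, 0, 5)),
      hba1c = hba1c[idx],
      hypertension_dx = hypertension_dx[idx],
      antihypertensive_med = antihypertensive_med[idx],
      diabetes_dx = diabetes_dx[idx],
      antidiabetic_med = antidiabetic_med[idx],
      married = married[idx], living_alone = living_alone[idx],
      non_working = non_working[idx],
      mri_qc_ok = runif(m) < 0.98,
      flair_qc_ok = runif(m) < 0.97,
      ventricular_enlargement = runif(m) < 0.03,
      weight = 1
    )
    eta_for <- function(outcome) {
      le <- if (outcome %in% names(shapes))
        latent_effect(lsns, shapes[[outcome]]) else 0
      gender_eff <- c(y = 0.1, hcv = -120, wmhv = 0.1, gad7 = -0.25,
                      cesd = -0.2, executive = 0.05, memory = 0.25,
                      processing_speed = 0)[outcome]
      age_effect(age, config$age_amplitude[[outcome]]) +
        gender_eff * g_num + le + ri[[outcome]][idx]
    }
    np <- config$noise_params
    if ("y" %in% names(shapes))
      out$y <- eta_for("y") + rnorm(m, 0, np$y[["sd"]])
    if ("hcv" %in% names(shapes)) {
      out$icv_raw <- rnorm(m, 1.45e6, 1.2e5)
      out$hcv_raw <- 3500 + 0.004 * (out$icv_raw - 1.45e6) + eta_for("hcv") +
        rnorm(m, 0, np$hcv[["sd"]])
    }
    if ("wmhv" %in% names(shapes)) {
      if (!"icv_raw" %in% names(out)) out$icv_raw <- rnorm(m, 1.45e6, 1.2e5)
      mu <- exp(log(2500) + eta_for("wmhv"))
      out$wmhv <- rgamma(m, shape = 1 / np$wmhv[["phi"]],
                         scale = mu * np$wmhv[["phi"]])
    }
    for (q in c("gad7", "cesd")) {
      if (q %in% names(shapes)) {
        mu <- exp(log(np[[q]][["mu0"]]) + eta_for(q))
        raw <- rpois(m, mu)
        upper <- if (q == "gad7") 21L else 60L
        clip_log[[paste0(q, "_", wave)]] <<- mean(raw > upper)
        out[[q]] <- pmin(raw, upper)
      }
    }
    # raw cognitive subtests; latent composite effects propagate into them
    e_lat <- if ("executive" %in% names(shapes)) eta_for("executive") else
      age_effect(age, config$age_amplitude[["executive"]]) + ri$executive[idx]
    m_lat <- if ("memory" %in% names(shapes)) eta_for("memory") else
      age_effect(age, config$age_amplitude[["memory"]]) + ri$memory[idx]
    p_lat <- if ("processing_speed" %in% names(shapes)) eta_for("processing_speed") else
      age_effect(age, config$age_amplitude[["processing_speed"]]) + ri$processing_speed[idx]
    np_e <- np$executive[["sd"]]; np_m <- np$memory[["sd"]]; np_p <- np$processing_speed[["sd"]]
    out$tmt_a <- exp(log(35) - 0.25 * (p_lat + rnorm(m, 0, np_p)))
    out$fluency_phon <- pmax(round(24 + 5 * (e_lat + rnorm(m, 0, np_e))), 0)
    out$fluency_sem <- pmax(round(22 + 5 * (e_lat + rnorm(m, 0, np_e))), 0)
    ratio <- pmax(1.1 - 0.35 * (e_lat + rnorm(m, 0, np_e)), 0.05)
    out$tmt_b <- out$tmt_a * (1 + ratio)
    out$learning <- pmin(pmax(round(18 + 4 * (m_lat + rnorm(m, 0, np_m))), 0L), 30L)
    out$recall <- pmin(pmax(round(6 + 1.8 * (m_lat + rnorm(m, 0, np_m))), 0L), 10L)
    out$recognition <- pmin(pmax(round(17 + 1.6 * (m_lat + rnorm(m, 0, np_m))), 0L), 20L)
    out
  }

  tab <- dplyr::bind_rows(make_wave("baseline", seq_len(n)),
                          make_wave("followup", which(keep)))
  attr(tab, "clipping") <- clip_log
  attr(tab, "seed") <- if (is.null(seed)) config$seed else as.integer(seed)
  tab
}

#' Set entries missing completely at random or at random given covariates
#'
#' Introduces missingness into selected columns so the chained-equation
#' imputation has realistic work to do. `"MCAR"` removes each entry with the
#' requested probability. `"MAR"` conditions the removal probability on age
#' and socioeconomic position through a logistic model (+0.5 log-odds per
#' age SD, -0.5 per SES SD, intercept solved so the marginal rate matches the
#' request). The exposure, id and wave columns are never removed.
#'
#' @param table A cohort tibble.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param rates Named numeric vector, column -> missingness fraction in [0, 1).
#' @param seed Optional integer seed.
#' @param mar_coef Log-odds coefficients per SD of age and SES for MAR.
#' @return The table with NAs injected.
#' @export
inject_missingness <- function(table, mechanism = c("MCAR", "MAR"), rates,
                               seed = NULL, mar_coef = c(age = 0.5, ses = -0.5)) {
  mechanism <- match.arg(mechanism)
  if (any(rates < 0) || any(rates >= 1)) abort("rates must lie in [0, 1).")
  protected <- c("participant_id", "wave", "lsns")
  if (any(names(rates) %in% protected))
    abort("exposure, id and wave columns cannot be made missing.")
  missing_cols <- setdiff(names(rates), names(table))
  if (length(missing_cols))
    abort(paste0("columns not in table: ", paste(missing_cols, collapse = ", ")))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(table)
  if (mechanism == "MAR") {
    za <- as.numeric(scale(table$age))
    ses_proxy <- if ("ses_score" %in% names(table)) table$ses_score else
      table$education_score
    zs <- as.numeric(scale(ses_proxy))
    zs[is.na(zs)] <- 0
    lin <- mar_coef[["age"]] * za + mar_coef[["ses"]] * zs
  }
  for (col in names(rates)) {
    r <- rates[[col]]
    if (r == 0) next
    p <- if (mechanism == "MCAR") rep(r, n) else {
      a0 <- uniroot(function(a) mean(plogis(a + lin)) - r, c(-25, 25))$root
      plogis(a0 + lin)
    }
    table[[col]][runif(n) < p] <- NA
  }
  table
}
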
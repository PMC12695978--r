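test_that("z-transform normalizes and propagates missingness", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  x <- c(rnorm(50), NA)
  z <- zscore(x)
  expect_true(is.na(z[51]))
  expect_lt(abs(mean(z, na.rm = TRUE)), 1e-12)
  expect_lt(abs(sd(z, na.rm = TRUE) - 1), 1e-12)
  expect_error(zscore(rep(2, 5)), "constant")
  expect_error(zscore(c(1, NA)), "non-missing")
})

test_that("cognitive composites match the hand-computed oracle", {
  d <- data.frame(
    tmt_a = c(30, 40, 50), tmt_b = c(60, 100, 150),
    fluency_phon = c(20, 25, 30), fluency_sem = c(18, 22, 26),
    learning = c(15, 20, 25), recall = c(4, 6, 8),
    recognition = c(15, 17, 19))
  out <- composite_scores(d)
  # arithmetic oracle for the executive composite, row by row
  zz <- function(x) (x - mean(x)) / sd(x)
  contrast <- -(d$tmt_b - d$tmt_a) / d$tmt_a
  exec_oracle <- (zz(d$fluency_phon) + zz(d$fluency_sem) + zz(contrast)) / 3
  expect_equal(out$executive, exec_oracle)
  expect_equal(out$memory,
               (zz(d$learning) + zz(d$recall) + zz(d$recognition)) / 3)
  expect_equal(out$processing_speed, -zz(d$tmt_a))
  # slower TMT-A strictly lowers processing speed
  expect_true(all(diff(out$processing_speed) < 0))

  # missing component propagates; zero TMT-A is flagged missing
  d2 <- d; d2$recall[2] <- NA
  expect_true(is.na(composite_scores(d2)$memory[2]))
  d3 <- rbind(d, d[1, ]); d3$tmt_a[4] <- 0
  expect_warning(out3 <- composite_scores(d3), "TMT-A")
  expect_true(is.na(out3$executive[4]))
})

test_that("ICV adjustment removes the head-size component of HCV", {
  set.seed(21)
  # centering identities
  icv <- rnorm(100, 1.45e6, 1e5)
  hcv <- rnorm(100, 3500, 300)
  expect_equal(adjust_hcv(hcv, rep(mean(icv), 100), 0.004), hcv)
  expect_equal(adjust_hcv(hcv, icv, 0), hcv)

  # simulation with known coefficient, random-intercept fit recovers it
  n <- 600
  id <- rep(1:300, each = 2)
  icv2 <- rnorm(300, 1.45e6, 1.2e5)[id]
  hcv2 <- 3500 + 0.004 * (icv2 - 1.45e6) + rnorm(300, 0, 200)[id] +
    rnorm(n, 0, 150)
  d <- data.frame(participant_id = id, icv_raw = icv2, hcv_raw = hcv2)
  fit <- fit_gamm(d, model_spec("hcv_raw", parametric = "icv_raw"))
  beta <- fit$coefficients[["icv_raw"]]
  se <- sqrt(fit$covariance["icv_raw", "icv_raw"])
  expect_lt(abs(beta - 0.004), 3 * se)
  adj <- adjust_hcv(hcv2, icv2, fit)
  expect_lt(abs(cor(adj, icv2)), 0.05)
  bad <- fit_gamm(d, model_spec("hcv_raw", parametric = character()))
  expect_error(adjust_hcv(hcv2, icv2, bad), "icv_raw")
})

test_that("equivalised income follows the OECD-modified scale and bands", {
  expect_equal(equivalised_income(1600, 0, 0), 1600)
  expect_equal(equivalised_income(1800, 1, 1), 1000)
  expect_error(equivalised_income(1000, -1, 0), "non-negative")
  expect_equal(income_score(c(799, 3000, 5000)), c(1, 7, 7))
  expect_equal(income_score(800), 1.5)
  # monotone non-decreasing half-point bands
  sc <- income_score(seq(500, 3500, by = 50))
  expect_true(all(diff(sc) >= 0))
  expect_true(all(sc %in% seq(1, 7, by = 0.5)))
})

test_that("SES weights rebalance quintiles to 20% population shares", {
  expect_equal(ses_weights(rep(1:5, each = 20)), rep(1, 100))
  q <- c(rep(1, 10), rep(2, 30), rep(3, 20), rep(4, 20), rep(5, 20))
  w <- ses_weights(q)
  expect_equal(w[q == 1][1], 2.0)  # 10% prevalence -> weight 2
  # weighted shares exactly 20% each
  shares <- tapply(w, q, sum) / sum(w)
  expect_equal(as.numeric(shares), rep(0.2, 5))
  # missing pre-imputation SES gets weight 1
  expect_equal(ses_weights(c(q, NA))[101], 1)
})

test_that("clinical dichotomizations apply plausibility filters first", {
  d <- data.frame(
    sbp_1 = c(141, 210, 138, NA), sbp_2 = c(141, NA, 139, NA),
    sbp_3 = c(141, NA, 140, NA),
    dbp_1 = c(80, 80, 80, NA), dbp_2 = c(80, 80, 80, NA),
    dbp_3 = c(80, 80, 80, NA),
    hypertension_dx = c(FALSE, FALSE, FALSE, FALSE),
    antihypertensive_med = c(FALSE, FALSE, FALSE, FALSE),
    diabetes_dx = c(FALSE, FALSE, FALSE, TRUE),
    antidiabetic_med = c(FALSE, FALSE, FALSE, FALSE),
    hba1c = c(6.0, 5.5, NA, 5.0),
    bmi = c(27, 55, 14, 30))
  out <- dichotomize_clinical(d)
  expect_true(out$hypertension[1])          # mean SBP 141 > 140
  expect_true(is.na(out$hypertension[2]))   # sole reading 210 implausible
  expect_false(out$hypertension[3])         # mean 139 and DBP 80
  expect_true(out$diabetes[1])              # HbA1c at the 6.0 boundary
  expect_false(out$diabetes[2])
  expect_true(is.na(out$diabetes[3]))       # no HbA1c, no dx/med
  expect_true(out$diabetes[4])              # diagnosis dominates
  expect_equal(is.na(out$bmi), c(FALSE, TRUE, TRUE, FALSE))
  # dbp above 90 alone flags hypertension
  d$dbp_1 <- d$dbp_2 <- d$dbp_3 <- 95
  expect_true(dichotomize_clinical(d)$hypertension[3])
})

test_that("transforms are monotone and hit their anchor points", {
  expect_equal(asinh_cesd(0), 0)
  expect_equal(asinh_cesd(1), log(1 + sqrt(2)))
  expect_true(all(diff(asinh_cesd(0:60)) > 0))
  expect_error(asinh_cesd(-1), "non-negative")

  expect_equal(gamma_shift(c(-1, 0, 2)), c(3.00001, 2.00001, 0.00001))
  expect_equal(gamma_shift(rep(4, 3)), rep(1e-5, 3))
  x <- rnorm(50)
  expect_equal(rank(gamma_shift(x)), rank(-x))
  expect_equal(min(gamma_shift(x)), 1e-5)
})

test_that("measurement derivations are pure functions of their inputs", {
  tab <- sample_cohort(cohort_config(300, seed = 31),
                       list(hcv = shape_spec("A", slope_above = 10),
                            cesd = shape_spec("A", slope_above = -0.02)))
  d1 <- derive_measures(tab)
  d2 <- derive_measures(tab)
  expect_identical(d1, d2)
  # weights constant across waves per participant
  w <- tapply(d1$weight, d1$participant_id, function(v) length(unique(v)))
  expect_true(all(w == 1))
  expect_true(all(c("hcv_adj", "executive", "memory_shift", "cesd_asinh",
                    "ses_quintile", "hypertension") %in% names(d1)))
})
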
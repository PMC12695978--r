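test_that("LSNS sampler matches the rounded truncated normal and its isolation rate", {
  cfg <- cohort_config(10)
  s <- sample_lsns(1e5, cfg, seed = 1)
  expect_true(all(s >= 0 & s <= 30))
  expect_true(all(s == floor(s)))
  frac_below <- mean(s < 12)
  expect_gte(frac_below, 0.18)
  expect_lte(frac_below, 0.22)
  # symmetry up to discretization
  expect_lte(abs(mean(s) - median(s)), 0.5)

  # oracle: numerically integrate the discretized density
  lo <- pnorm(-0.5, 16.5, 5.7); hi <- pnorm(30.5, 16.5, 5.7)
  probs <- vapply(0:30, function(k)
    (pnorm(k + 0.5, 16.5, 5.7) - pnorm(k - 0.5, 16.5, 5.7)) / (hi - lo),
    numeric(1))
  oracle_mean <- sum((0:30) * probs)
  s_big <- sample_lsns(1e6, cfg, seed = 2)
  expect_lt(abs(mean(s_big) - oracle_mean), 0.1)

  # degenerate spread collapses to the rounded mean
  cfg0 <- cohort_config(10, lsns_sd = 0)
  expect_true(all(sample_lsns(50, cfg0, seed = 1) == round(16.5)))

  expect_error(sample_lsns(0, cfg), "positive integer")
})

test_that("latent effects follow the three hypothesized shapes", {
  # threshold-only: flat at and above the cutoff
  expect_equal(latent_effect(12:30, shape_spec("C")), rep(0, 19))
  # linear through the cutoff
  expect_equal(latent_effect(c(10, 11, 12),
                             shape_spec("A", slope_above = 0.5)),
               c(-1.0, -0.5, 0.0))
  # piecewise slope ratio via finite differences
  sh <- shape_spec("B", slope_above = 0.1, slope_below = 0.2)
  eff <- latent_effect(0:30, sh)
  d <- diff(eff)
  expect_equal(unique(round(d[1:11], 12)), 0.2)
  expect_equal(unique(round(d[13:30], 12)), 0.1)
  expect_equal(d[1] / d[20], 2)
  # continuity across the cutoff
  expect_lt(abs(eff[14] - eff[13] - sh$slope_above), 1e-12)

  expect_error(shape_spec("B", slope_above = 0.2, slope_below = 0.1),
               "slope_below")
  expect_error(shape_spec("C", slope_above = 0.1), "slope_above == 0")
  expect_error(latent_effect(31, shape_spec("A")), "0, 30")
})

test_that("cohort generator reproduces the configured population structure", {
  cfg <- cohort_config(1e4, retention = 1, seed = 5)
  tab <- sample_cohort(cfg, list(y = shape_spec("A")))
  # full retention: exactly two waves each
  expect_true(all(table(tab$participant_id) == 2))
  # female share within one percentage point at n = 1e4
  fem <- mean(tab$gender[tab$wave == "baseline"] == "female")
  expect_lt(abs(fem - 0.53), 0.01)
  # follow-up ages shifted by the wave gap
  bl <- tab[tab$wave == "baseline", ]
  fu <- tab[tab$wave == "followup", ]
  expect_equal(fu$age - bl$age[match(fu$participant_id, bl$participant_id)],
               rep(6.5, nrow(fu)))

  # retention fraction honoured approximately
  cfg2 <- cohort_config(5000, retention = 0.55, seed = 6)
  tab2 <- sample_cohort(cfg2, list(y = shape_spec("A")))
  ret <- sum(tab2$wave == "followup") / 5000
  expect_lt(abs(ret - 0.55), 0.03)

  # determinism: same seed, byte-identical table
  expect_identical(sample_cohort(cfg2, list(y = shape_spec("A"))),
                   sample_cohort(cfg2, list(y = shape_spec("A"))))

  expect_error(sample_cohort(cfg2, list(nope = shape_spec("A"))), "unknown")
})

test_that("null-effect outcomes match their configured family moments", {
  cfg <- cohort_config(
    8000, retention = 1, seed = 9,
    random_intercept_sd = c(y = 0, wmhv = 0, gad7 = 0),
    age_amplitude = c(y = 0, wmhv = 0, gad7 = 0))
  shapes <- list(y = shape_spec("A", slope_above = 0),
                 wmhv = shape_spec("A", slope_above = 0),
                 gad7 = shape_spec("A", slope_above = 0))
  tab <- sample_cohort(cfg, shapes)
  f <- tab[tab$gender == "female", ]
  n <- nrow(f)
  # gaussian: unit residual SD around zero (gender effect excluded)
  expect_lt(abs(mean(f$y)), 4 / sqrt(n))
  expect_lt(abs(sd(f$y) - 1), 0.03)
  # gamma: mean 2500 and squared coefficient of variation phi = 0.4
  expect_lt(abs(mean(f$wmhv) - 2500) / 2500, 0.03)
  expect_lt(abs(var(f$wmhv) / mean(f$wmhv)^2 - 0.4), 0.03)
  # poisson around mu0 exp(gender effect 0): mean approx variance
  expect_lt(abs(mean(f$gad7) - 2.5), 0.1)
  expect_lt(abs(var(f$gad7) / mean(f$gad7) - 1), 0.1)
  # instrument bounds and positivity
  expect_true(all(tab$gad7 >= 0 & tab$gad7 <= 21 & tab$gad7 == floor(tab$gad7)))
  expect_true(all(tab$wmhv > 0))
  clip <- attr(tab, "clipping")
  expect_true(all(unlist(clip) < 0.01))
})

test_that("a linear ground truth is recovered by ordinary least squares", {
  cfg <- cohort_config(5000, seed = 11)
  tab <- sample_cohort(cfg, list(y = shape_spec("A", slope_above = 0.05)))
  bl <- tab[tab$wave == "baseline", ]
  fit <- lm(y ~ lsns + gender, data = bl)
  est <- coef(summary(fit))["lsns", ]
  expect_lt(abs(est["Estimate"] - 0.05), 3 * est["Std. Error"])
})

test_that("missingness injection honours mechanism and never touches the exposure", {
  cfg <- cohort_config(5e4, retention = 1, seed = 13)
  tab <- sample_cohort(cfg, list(y = shape_spec("A")))

  expect_identical(inject_missingness(tab, "MCAR", c(bmi = 0), seed = 1), tab)

  out <- inject_missingness(tab, "MCAR", c(bmi = 0.1), seed = 2)
  r <- mean(is.na(out$bmi))
  expect_gte(r, 0.095); expect_lte(r, 0.105)
  expect_false(anyNA(out$lsns))

  mar <- inject_missingness(tab, "MAR", c(y = 0.2), seed = 3)
  tert <- cut(mar$age, quantile(mar$age, c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE)
  rates <- tapply(is.na(mar$y), tert, mean)
  expect_true(all(diff(rates) > 0))
  expect_lt(abs(mean(is.na(mar$y)) - 0.2), 0.01)

  expect_error(inject_missingness(tab, "MCAR", c(bmi = 1)), "rates")
  expect_error(inject_missingness(tab, "MCAR", c(lsns = 0.1)), "exposure")
})
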
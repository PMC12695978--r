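test_that("smooth test is scale-equivariant and powerful against strong effects", {
  d <- sim_frame(800, seed = 81,
                 lsns_effect = function(x) 0.2 * (x - 12), noise_sd = 0.5)
  f <- fit_gamm(d, tier1_full())
  expect_lt(f$smooth_pvalues[["s(lsns)"]], 1e-6)
  # rescaling a gaussian outcome leaves the p-value unchanged
  d2 <- d; d2$y <- 3.7 * d$y
  f2 <- fit_gamm(d2, tier1_full())
  expect_equal(f$smooth_pvalues[["s(lsns)"]],
               f2$smooth_pvalues[["s(lsns)"]], tolerance = 1e-6)
})

test_that("one-sided linear test points in the requested direction", {
  d <- sim_frame(800, seed = 82,
                 lsns_effect = function(x) 0.05 * (x - 12))
  f <- fit_gamm(d, tier1_base())
  expect_lt(linear_pvalue(f, "lsns", "positive"), 0.01)
  expect_gt(linear_pvalue(f, "lsns", "negative"), 0.9)
})

test_that("model comparison treats identical fits as equivalent", {
  d <- sim_frame(400, seed = 83)
  b <- fit_gamm(d, tier1_base())
  cmp <- compare_models(b, b)
  expect_gt(cmp$p, 0.99)
  expect_equal(cmp$delta_bic, 0)
  expect_equal(cmp$preferred, "base")
  # differing row sets are a contract violation
  d2 <- d[-1, ]
  b2 <- fit_gamm(d2, tier1_base())
  expect_error(compare_models(b, b2), "same rows")
})

test_that("a strong piecewise truth is detected, a linear truth mostly is not", {
  prefer_full <- 0
  for (s in 1:20) {
    d <- sim_frame(1500, seed = 830 + s,
                   lsns_effect = function(x) latent_effect(x, shape_spec("B",
                     slope_above = 0.05, slope_below = 0.3)))
    full <- fit_gamm(d, tier1_full())
    base <- fit_gamm(d, tier1_base())
    if (compare_models(full, base)$preferred == "full")
      prefer_full <- prefer_full + 1
  }
  expect_gte(prefer_full, 16)  # >= 80% detection of real nonlinearity

  prefer_full_lin <- 0
  for (s in 1:20) {
    d <- sim_frame(1500, seed = 860 + s,
                   lsns_effect = function(x) 0.05 * (x - 12))
    full <- fit_gamm(d, tier1_full())
    base <- fit_gamm(d, tier1_base())
    if (compare_models(full, base)$preferred == "full")
      prefer_full_lin <- prefer_full_lin + 1
  }
  expect_lte(prefer_full_lin / 20, 0.2)
})

test_that("BH correction within the cognitive family matches the hand-worked example", {
  p <- c(hcv = 0.01, wmhv = 0.02, executive = 0.03, memory = 0.04,
         processing_speed = 0.05, gad7 = 0.04, cesd = 0.9)
  q <- fdr_family(p)
  # BH by hand: q_i = min over j >= i of p_(j) * 5 / j, all equal 0.05 here
  expect_equal(unname(q[1:5]), rep(0.05, 5))
  # non-family outcomes pass through uncorrected
  expect_equal(q[["gad7"]], 0.04)
  expect_equal(q[["cesd"]], 0.9)
  # equal p-values map to themselves
  pe <- setNames(rep(0.2, 5), names(p)[1:5])
  expect_equal(unname(fdr_family(pe)), rep(0.2, 5))
  # monotonicity: q ordering never reverses p ordering
  set.seed(84)
  pr <- setNames(runif(5), names(p)[1:5])
  qr <- fdr_family(pr)
  expect_true(all(diff(qr[order(pr)]) >= -1e-12))
  expect_error(fdr_family(c(hcv = 1.2)), "0, 1")
})

test_that("shape classification follows the A/B/C decision rule", {
  # base-preferred comparisons always yield A, regardless of wiggle
  d <- sim_frame(800, seed = 85, lsns_effect = function(x) 0.05 * (x - 12))
  f <- fit_gamm(d, tier1_full())
  pe <- partial_effect(f, "lsns", grid = 0:30)
  forced_base <- tibble::tibble(p = 1, delta_bic = -5, df = 1,
                                preferred = "base")
  expect_equal(classify_shape(forced_base, pe)$hypothesis, "A")

  # simulated truths: A mostly classified A
  verdict_A <- 0
  for (s in 1:15) {
    d <- sim_frame(2000, seed = 850 + s,
                   lsns_effect = function(x) 0.05 * (x - 12))
    full <- fit_gamm(d, tier1_full())
    base <- fit_gamm(d, tier1_base())
    v <- classify_shape(compare_models(full, base),
                        partial_effect(full, "lsns", grid = 0:30))
    if (v$hypothesis == "A") verdict_A <- verdict_A + 1
  }
  expect_gte(verdict_A, 12)  # >= 80%

  # threshold-only truth classified C in the majority of seeds
  verdict_C <- 0
  for (s in 1:10) {
    d <- sim_frame(4000, seed = 880 + s,
                   lsns_effect = function(x)
                     latent_effect(x, shape_spec("C", slope_below = 0.3)),
                   noise_sd = 0.8)
    full <- fit_gamm(d, tier1_full())
    base <- fit_gamm(d, tier1_base())
    v <- classify_shape(compare_models(full, base),
                        partial_effect(full, "lsns", grid = 0:30))
    if (v$hypothesis == "C") verdict_C <- verdict_C + 1
  }
  expect_gte(verdict_C, 6)
})

test_that("outcome table pins families, links and test-family membership", {
  os <- outcome_specs()
  expect_equal(nrow(os), 7)
  expect_equal(sum(os$cognitive_family), 5)
  expect_equal(os$family[os$outcome == "gad7"], "poisson")
  expect_equal(os$link[os$outcome == "wmhv"], "log")
  expect_equal(os$link[os$outcome == "processing_speed"], "identity")
  expect_equal(os$family[os$outcome == "hcv"], "gaussian")
  # WMHV additionally controls for head size and ventricular enlargement
  expect_true(all(c("icv_raw", "ventricular_enlargement") %in%
                    os$tier2[os$outcome == "wmhv"][[1]]))
})
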
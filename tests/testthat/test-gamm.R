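test_that("without penalties the fit reduces to ordinary least squares", {
  set.seed(51)
  n <- 200
  d <- data.frame(y = rnorm(n), x1 = rnorm(n), x2 = rnorm(n),
                  participant_id = 1:n)
  f <- fit_gamm(d, model_spec("y", parametric = c("x1", "x2"),
                              random_intercept = FALSE))
  expect_lt(max(abs(f$coefficients - coef(lm(y ~ x1 + x2, d)))), 1e-8)
  expect_equal(unname(f$edf_by_term), c(1, 1, 1))
  expect_equal(f$edf_total, 3)
  # gaussian BIC equals the closed-form expression on the unpenalized fit
  rss <- sum(residuals(lm(y ~ x1 + x2, d))^2)
  bic_closed <- n * log(rss / n) + n * (1 + log(2 * pi)) + log(n) * 3
  expect_equal(f$bic, bic_closed, tolerance = 1e-10)
})

test_that("fixed-lambda gaussian fits equal the generalized ridge closed form", {
  set.seed(52)
  n <- 100
  d <- data.frame(x = runif(n), participant_id = 1:n)
  d$y <- sin(2 * pi * d$x) + rnorm(n, 0, 0.3)
  for (lam in c(0.01, 1, 100)) {
    f <- fit_gamm(d, model_spec("y", smooths = list(smooth_spec("x", k = 8)),
                                random_intercept = FALSE),
                  lambda = c("s(x)" = lam))
    bs <- build_basis(d$x, smooth_spec("x", k = 8))
    X <- cbind(1, bs$design)
    S <- matrix(0, 8, 8); S[-1, -1] <- lam * bs$penalty
    beta <- solve(crossprod(X) + S, crossprod(X, d$y))
    expect_lt(max(abs(f$coefficients - beta)), 1e-8)
    # edf from the same closed form
    edf <- sum(diag(solve(crossprod(X) + S, crossprod(X))))
    expect_equal(f$edf_total, edf, tolerance = 1e-8)
  }
})

test_that("penalty limits collapse a smooth to linear or release it to k - 1", {
  set.seed(53)
  n <- 300
  d <- data.frame(x = runif(n, 0, 10), participant_id = 1:n)
  d$y <- sin(d$x) + rnorm(n, 0, 0.2)
  sp <- model_spec("y", smooths = list(smooth_spec("x", k = 10)),
                   random_intercept = FALSE)
  f_inf <- fit_gamm(d, sp, lambda = c("s(x)" = 1e12))
  expect_lt(abs(f_inf$edf_by_term[["s(x)"]] - 1), 0.01)
  pe <- partial_effect(f_inf, "x", grid = seq(0, 10, by = 0.5))
  lin <- lm(estimate ~ grid, data = pe)
  expect_gt(summary(lin)$r.squared, 0.9999)

  f_0 <- fit_gamm(d, sp, lambda = c("s(x)" = 1e-12))
  expect_lt(abs(f_0$edf_by_term[["s(x)"]] - 9), 0.01)
  ck <- check_oversmoothing(f_0)
  expect_true(ck$flag[ck$term == "s(x)"])
  expect_false(check_oversmoothing(f_inf)$flag)
})

test_that("selected-lambda smooths track an established GAM implementation", {
  set.seed(54)
  n <- 500
  x <- runif(n, 0, 10)
  f_true <- 0.5 * sin(x)
  cases <- list(
    list(family = "gaussian", link = "identity",
         y = f_true + rnorm(n, 0, 0.3), mfam = gaussian()),
    list(family = "poisson", link = "log",
         y = rpois(n, exp(1 + f_true)), mfam = poisson()),
    list(family = "gamma", link = "log",
         y = rgamma(n, shape = 5, scale = exp(0.5 + f_true) / 5),
         mfam = Gamma(link = "log")))
  for (cs in cases) {
    d <- data.frame(y = cs$y, x = x, participant_id = 1:n)
    f <- fit_gamm(d, model_spec("y", family = cs$family, link = cs$link,
                                smooths = list(smooth_spec("x", k = 10)),
                                random_intercept = FALSE))
    g <- mgcv::gam(y ~ s(x, bs = "ps", k = 10), family = cs$mfam, data = d,
                   method = "GCV.Cp")
    grid <- seq(0.2, 9.8, length.out = 50)
    pe <- partial_effect(f, "x", grid = grid)
    pm <- stats::predict(g, newdata = data.frame(x = grid), type = "terms")[, 1]
    expect_gt(cor(pe$estimate, pm), 0.99)
    expect_lt(abs(f$edf_by_term[["s(x)"]] - sum(g$edf[-1])) /
                max(sum(g$edf[-1]), 1), 0.15)
  }
})

test_that("integer observation weights act like row replication at fixed lambda", {
  set.seed(55)
  n <- 60
  d <- data.frame(x = runif(n, 0, 5), w = sample(1:3, n, replace = TRUE),
                  participant_id = 1:n)
  d$y <- cos(d$x) + rnorm(n, 0, 0.2)
  lam <- c("s(x)" = 2)
  fw <- fit_gamm(d, model_spec("y", smooths = list(smooth_spec("x", k = 6)),
                               random_intercept = FALSE, weights = "w"),
                 lambda = lam)
  drep <- d[rep(seq_len(n), d$w), ]
  fr <- fit_gamm(drep, model_spec("y", smooths = list(smooth_spec("x", k = 6)),
                                  random_intercept = FALSE),
                 lambda = lam)
  expect_lt(max(abs(fw$coefficients - fr$coefficients)), 1e-8)
})

test_that("the random-intercept ridge block interpolates between pooling extremes", {
  set.seed(56)
  q <- 40
  id <- rep(seq_len(q), each = 2)
  b <- rnorm(q, 0, 1)
  d <- data.frame(participant_id = id, y = 2 + b[id] + rnorm(2 * q, 0, 0.3))
  sp <- model_spec("y", parametric = character(), random_intercept = TRUE)
  # lambda -> infinity: predictions collapse to the no-random-effect fit
  f_inf <- fit_gamm(d, sp, lambda = c("(random)" = 1e10))
  expect_lt(max(abs(f_inf$fitted - mean(d$y))), 1e-4)
  expect_lt(f_inf$edf_by_term[["(random)"]], 0.01)
  # lambda -> 0: per-participant means are interpolated (balanced gaussian)
  f_0 <- fit_gamm(d, sp, lambda = c("(random)" = 1e-10))
  pm <- tapply(d$y, d$participant_id, mean)
  expect_lt(max(abs(f_0$fitted - pm[id])), 1e-6)
  # selected lambda approximates the variance-ratio shrinkage (BLUP)
  f_sel <- fit_gamm(d, sp)
  expect_gt(f_sel$edf_by_term[["(random)"]], 5)
  expect_lt(f_sel$edf_by_term[["(random)"]], q)
})

test_that("nesting inequalities hold for deviance and degrees of freedom", {
  for (s in 1:5) {
    d <- sim_frame(600, seed = 560 + s,
                   lsns_effect = function(x) 0.05 * (x - 12))
    full <- fit_gamm(d, tier1_full())
    base <- fit_gamm(d, tier1_base())
    expect_lte(full$deviance, base$deviance + 1e-8)
    expect_gte(full$edf_total, base$edf_total - 0.2)
  }
})

test_that("the fitted exposure effect recovers a linear ground truth", {
  hits <- 0
  n_seeds <- 25
  for (s in seq_len(n_seeds)) {
    d <- sim_frame(3000, seed = 600 + s,
                   lsns_effect = function(x) 0.05 * (x - 12))
    f <- fit_gamm(d, tier1_full())
    pe <- partial_effect(f, "lsns", grid = 2:28)
    truth <- 0.05 * (2:28 - 12)
    truth <- truth - mean(0.05 * (d$lsns - 12))  # same centering as the fit
    rmse <- sqrt(mean((pe$estimate - truth)^2))
    if (rmse < 0.2 * diff(range(truth))) hits <- hits + 1
  }
  expect_gte(hits, 21)  # at least ~85% of seeds
})

test_that("weighted fits and diagnostics expose the documented contracts", {
  d <- sim_frame(500, seed = 71)
  f <- fit_gamm(d, tier1_full())
  # tidy/glance surfaces
  td <- tidy(f)
  expect_true(all(c("(Intercept)", "s(age)", "s(lsns)") %in% td$term))
  gl <- glance(f)
  expect_true(gl$converged)
  expect_equal(gl$n_obs, 500)
  # concurvity of independent covariates is near zero, bounded in [0, 1]
  cv <- concurvity(f)
  expect_true(all(cv >= 0 & cv <= 1))
  expect_lt(max(cv), 0.1)
  # duplicated covariate smoothed twice: concurvity near one
  d$lsns2 <- d$lsns + runif(500, -1e-4, 1e-4)
  f2 <- fit_gamm(d, model_spec("y", smooths = list(smooth_spec("lsns"),
                                                   smooth_spec("lsns2")),
                               random_intercept = FALSE))
  expect_gt(max(concurvity(f2)), 0.95)
  # VIFs: orthogonal-ish columns near 1; duplicates explode
  set.seed(72)
  X <- cbind(a = rnorm(200), b = rnorm(200))
  expect_true(all(abs(vif_terms(X) - 1) < 0.1))
  X2 <- cbind(X, a2 = X[, "a"])
  expect_true(any(!is.finite(vif_terms(X2)) | vif_terms(X2) > 1e6))
  r <- cor(X[, 1], X[, 2])
  expect_equal(unname(vif_terms(X)[1]), 1 / (1 - r^2), tolerance = 1e-8)
})

test_that("gamma outcomes demand positivity and log links overflow safely", {
  d <- sim_frame(300, seed = 73)
  d$g <- -abs(d$y)
  expect_error(fit_gamm(d, model_spec("g", family = "gamma",
                                      smooths = list(smooth_spec("age")),
                                      random_intercept = FALSE)),
               "strictly positive")
  d$g2 <- gamma_shift(d$y)
  f <- fit_gamm(d, model_spec("g2", family = "gamma", link = "log",
                              smooths = list(smooth_spec("age")),
                              random_intercept = FALSE))
  expect_true(f$converged)
  expect_true(all(f$fitted > 0))
})
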
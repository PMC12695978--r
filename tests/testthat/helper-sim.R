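# small simulated frames used across tests

sim_frame <- function(n, seed, lsns_effect = function(s) 0 * s,
                      noise_sd = 1) {
  set.seed(seed)
  d <- data.frame(
    age = runif(n, 40, 80),
    lsns = sample_lsns(n, cohort_config(n), seed = seed + 1),
    gender = sample(c("female", "male"), n, replace = TRUE),
    participant_id = seq_len(n)
  )
  d$y <- 0.3 * ((d$age - 60) / 20)^2 + 0.1 * (d$gender == "male") +
    lsns_effect(d$lsns) + rnorm(n, 0, noise_sd)
  d
}

tier1_full <- function(k = 10, random_intercept = FALSE) {
  model_spec("y", parametric = "gender",
             smooths = list(smooth_spec("age", k = k),
                            smooth_spec("lsns", k = k)),
             random_intercept = random_intercept)
}

tier1_base <- function(k = 10, random_intercept = FALSE) {
  model_spec("y", parametric = c("gender", "lsns"),
             smooths = list(smooth_spec("age", k = k)),
             random_intercept = random_intercept)
}
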
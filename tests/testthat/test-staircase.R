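test_that("the dilution ladder has the protocol geometry", {
  lad <- build_ladder(3.2, 0.00032, 1 / 6)
  expect_equal(lad$n_rungs, 25L)
  expect_equal(lad$conc[1], 3.2)
  expect_equal(lad$conc[25], 0.00032)
  # consecutive-rung ratio is the 1.468-fold dilution
  expect_equal(round(lad$conc[1] / lad$conc[2], 3), 1.468)
  # the protocol's start concentrations are rungs 5 and 12
  expect_equal(lad$conc[5], 0.689, tolerance = 0.005)
  expect_equal(lad$conc[12], 0.047, tolerance = 0.005)
  expect_error(build_ladder(3.2, 0.001, 1 / 6), "ladder mismatch")
})

test_that("detection follows the configured psychometric model", {
  cfg_step <- staircase_config(psychometric = "step")
  expect_true(detect_trial(1.0, log10(0.5), cfg_step))
  expect_false(detect_trial(0.25, log10(0.5), cfg_step))
  expect_true(detect_trial(0.5, log10(0.5), cfg_step))  # boundary detects

  cfg_probit <- staircase_config(psychometric = "probit", sigma_p = 0.15,
                                 guess_rate = 0)
  set.seed(1)
  hits <- replicate(10000, detect_trial(0.5, log10(0.5), cfg_probit))
  expect_equal(mean(hits), 0.5, tolerance = 0.04)
  expect_error(staircase_config(psychometric = "probit", sigma_p = 0),
               "sigma_p")
})

test_that("the staircase straddles the threshold and starts per the pre-test", {
  lad <- build_ladder()
  # threshold strictly between rungs 11 and 12: estimate is the geometric
  # mean of the straddling rungs
  th <- mean(lad$log10_conc[11:12]) + 0.02
  run <- run_staircase(th, lad)
  expect_true(run$converged)
  expect_equal(run$threshold_estimate, 10^mean(lad$log10_conc[11:12]))
  expect_length(run$reversals, 5L)
  # taster pre-test: first trial at 0.047 mM
  expect_equal(run$trials$concentration_mM[1], lad$conc[12])

  # non-taster start at 0.689 mM
  run2 <- run_staircase(log10(0.5), lad)
  expect_equal(run2$trials$concentration_mM[1], lad$conc[5])

  # estimate error bounded by half a rung for thresholds inside the ladder
  set.seed(5)
  ths <- runif(200, -2.5, 0.3)
  errs <- vapply(ths, function(t)
    abs(log10(run_staircase(t, lad)$threshold_estimate) - t), numeric(1))
  expect_true(all(errs <= 1 / 12 + 1e-9))
})

test_that("a threshold above the top rung pins the staircase without converging", {
  lad <- build_ladder()
  run <- run_staircase(log10(10), lad)
  expect_false(run$converged)
  expect_identical(run$pinned, "top")
  expect_true(is.na(run$threshold_estimate))
  # cohort-level measurement censors the run at the top concentration
  pr <- data.frame(subject_id = "S1", theta_log10 = log10(10))
  pr$day_offsets <- matrix(0, 1, 1)
  m <- measure_thresholds(pr, lad)
  expect_equal(unname(m$estimate[1, 1]), lad$conc[1])
  expect_false(m$converged[1, 1])
  m2 <- measure_thresholds(pr, lad, censor = "drop")
  expect_true(is.na(m2$estimate[1, 1]))
})

test_that("the lean cohort staircase matches the trial-logging implementation", {
  lad <- build_ladder()
  cfg <- staircase_config()
  set.seed(9)
  ths <- runif(100, -3.0, 0.6)
  for (t in ths) {
    ref <- run_staircase(t, lad, cfg)
    pr <- data.frame(subject_id = "S1", theta_log10 = t)
    pr$day_offsets <- matrix(0, 1, 1)
    fast <- measure_thresholds(pr, lad, cfg, censor = "drop")
    expect_equal(unname(fast$estimate[1, 1]), ref$threshold_estimate)
    expect_equal(unname(fast$converged[1, 1]), ref$converged)
  }
})

test_that("staircase estimates are unbiased at the population level", {
  lad <- build_ladder()
  set.seed(41)
  n <- 4000
  pr <- data.frame(subject_id = sprintf("S%04d", 1:n),
                   theta_log10 = runif(n, -2.5, -0.3))
  pr$day_offsets <- matrix(0, n, 1)
  m <- measure_thresholds(pr, lad)
  bias <- mean(log10(m$estimate[, 1])) - mean(pr$theta_log10)
  expect_lt(abs(bias), 0.02)
})

test_that("duplicate staircases reproduce the day-to-day variability scale", {
  cfg <- cohort_config(n_subjects = 10000, n_null_snps = 0, n_ld_partners = 0,
                       seed = 43)
  cov <- simulate_covariates(cfg)
  pan <- simulate_genotypes(cfg, cov)
  pr <- assign_latent_thresholds(pan, cov, cfg)
  pr <- sample_day_effects(pr, 2, cfg)
  m <- measure_thresholds(pr)
  v <- variability_stats(m$estimate)
  expect_equal(v$d_mean, 0.32, tolerance = 0.01 / 0.32)
})

test_that("gLMS ratings follow the hinge model and stay on the scale", {
  n <- 400
  pr <- data.frame(subject_id = sprintf("S%03d", 1:n),
                   theta_log10 = rep(log10(0.32), n),
                   glms_baseline = rep(10, n),
                   glms_slope = rep(20, n),
                   glms_noise_sd = rep(0, n))
  # noiseless: exactly one decade above threshold scores baseline + slope
  s <- simulate_glms_session(pr, day_offset = 0)
  expect_equal(unname(s$ratings[, "3.200"]), rep(30, n))
  expect_equal(unname(s$ratings[, "water"]), rep(10, n))
  # noiseless ratings are non-decreasing in concentration
  expect_true(all(apply(s$ratings, 1, function(r) all(diff(r) >= 0))))

  # a subject far above the top concentration rates everything like water
  pr2 <- pr
  pr2$theta_log10 <- rep(2, n)
  pr2$glms_noise_sd <- rep(5, n)
  set.seed(3)
  s2 <- simulate_glms_session(pr2)
  expect_equal(unname(colMeans(s2$ratings)), rep(mean(s2$ratings[, "water"]), 6),
               tolerance = 0.05)

  # clipping contract under extreme noise
  pr3 <- pr
  pr3$glms_noise_sd <- rep(500, n)
  set.seed(4)
  s3 <- simulate_glms_session(pr3)
  expect_true(all(s3$ratings >= 0 & s3$ratings <= 100))
})
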
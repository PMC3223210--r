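test_that("covariates respect the configured ranges and distributions", {
  cov <- simulate_covariates(cohort_config(n_subjects = 225, seed = 1))
  expect_equal(nrow(cov), 225)
  expect_true(all(cov$age >= 18 & cov$age <= 47))
  expect_true(all(cov$bmi >= 16.6 & cov$bmi <= 46.1))
  expect_true(all(cov$sex %in% c(0L, 1L)))
  expect_equal(rowSums(cov$admixture), rep(1, 225))

  big <- simulate_covariates(cohort_config(n_subjects = 100000, seed = 2))
  expect_equal(mean(big$age), 32.5, tolerance = 0.1 / 32.5)

  empty <- simulate_covariates(cohort_config(n_subjects = 0, seed = 1))
  expect_equal(nrow(empty), 0)
})

test_that("covariate simulation is reproducible under a fixed seed", {
  a <- simulate_covariates(cohort_config(n_subjects = 50, seed = 7))
  b <- simulate_covariates(cohort_config(n_subjects = 50, seed = 7))
  expect_identical(a, b)
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(n_subjects = -1), "n_subjects")
  expect_error(cohort_config(fst = 1), "fst")
  expect_error(cohort_config(causal_allele_freq = 1.2), "causal_allele_freq")
  expect_error(cohort_config(class_means_mM = c(0.1, 0.2, 0.3)), "decrease")
  expect_error(cohort_config(class_means_mM = c(0.37, 0.37, 0.37)), "decrease")
  expect_error(cohort_config(target_causal_r2 = 0.8, age_effect_r2 = 0.3),
               "< 1")
})

test_that("causal SNP frequency matches the configured value at large n", {
  cfg <- cohort_config(n_subjects = 100000, n_null_snps = 0,
                       n_ld_partners = 1, ld_copy_prob = 1, seed = 11)
  cov <- simulate_covariates(cfg)
  pan <- simulate_genotypes(cfg, cov)
  expect_equal(mean(pan$dosage[, 1]) / 2, 0.46, tolerance = 0.01)
  # perfect LD partner copies the causal dosage exactly
  expect_identical(pan$dosage[, 2], pan$dosage[, 1])
})

test_that("unstructured panels are consistent with Hardy-Weinberg equilibrium", {
  cfg <- cohort_config(n_subjects = 2000, n_null_snps = 300, n_ld_partners = 0,
                       fst = 0, n_populations = 1, seed = 13)
  cov <- simulate_covariates(cfg)
  pan <- simulate_genotypes(cfg, cov)
  hwe_p <- apply(pan$dosage, 2, function(d)
    hwe_test(c(sum(d == 0), sum(d == 1), sum(d == 2))))
  expect_gte(mean(hwe_p > 0.001), 0.99)
})

test_that("latent thresholds hit the class means and the calibrated r2", {
  cfg <- cohort_config(n_subjects = 100000, n_null_snps = 0,
                       n_ld_partners = 0, seed = 17)
  cov <- simulate_covariates(cfg)
  pan <- simulate_genotypes(cfg, cov)
  pr <- assign_latent_thresholds(pan, cov, cfg)

  # genotype-class geometric means recover the configured concentrations
  cls <- 10^tapply(pr$theta_log10, pr$dosage, mean)
  expect_equal(as.numeric(cls), c(0.37, 0.113, 0.047), tolerance = 0.01)

  # measured calibration: log-average of duplicate day-noisy measurements
  # attains the target additive r2
  pr <- sample_day_effects(pr, 2, cfg)
  measured <- pr$theta_log10 + rowMeans(pr$day_offsets)
  r2_meas <- summary(stats::lm(measured ~ pr$dosage))$r.squared
  expect_equal(r2_meas, 0.49, tolerance = 0.02 / 0.49)

  # age share of the phenotype variance
  r2_age <- summary(stats::lm(measured ~ cov$age))$r.squared
  expect_equal(r2_age, 0.038, tolerance = 0.3)
})

test_that("latent calibration places the target r2 on the noiseless threshold", {
  cfg <- cohort_config(n_subjects = 100000, n_null_snps = 0, n_ld_partners = 0,
                       calibration = "latent", seed = 19)
  cov <- simulate_covariates(cfg)
  pan <- simulate_genotypes(cfg, cov)
  pr <- assign_latent_thresholds(pan, cov, cfg)
  r2 <- summary(stats::lm(pr$theta_log10 ~ pr$dosage))$r.squared
  expect_equal(r2, 0.49, tolerance = 0.02 / 0.49)
})

test_that("an infeasible variance budget raises a calibration error", {
  expect_error(variance_budget(cohort_config(target_causal_r2 = 0.95,
                                             age_effect_r2 = 0.04)),
               "infeasible")
})

test_that("day effects have the configured scale and are independent", {
  cfg <- cohort_config(n_subjects = 100000, n_null_snps = 0,
                       n_ld_partners = 0, seed = 23)
  cov <- simulate_covariates(cfg)
  pan <- simulate_genotypes(cfg, cov)
  pr <- assign_latent_thresholds(pan, cov, cfg)
  pr <- sample_day_effects(pr, 2, cfg)
  d <- abs(pr$day_offsets[, 1] - pr$day_offsets[, 2])
  # E|N(0, 2 sigma^2)| = 2 sigma / sqrt(pi) = 0.32 at sigma = 0.2836
  expect_equal(mean(d), 0.32, tolerance = 0.005 / 0.32)
  expect_lt(abs(cor(pr$day_offsets[, 1], pr$day_offsets[, 2])), 0.02)

  cfg0 <- cohort_config(n_subjects = 100, n_null_snps = 0, n_ld_partners = 0,
                        sigma_day = 0, seed = 23)
  pr0 <- sample_day_effects(pr[1:100, ], 2, cfg0)
  expect_true(all(pr0$day_offsets == 0))
  expect_error(sample_day_effects(pr, 0, cfg), "n_sessions")
})

test_that("ancestry PC1 tracks admixture in a structured cohort", {
  cfg <- cohort_config(n_subjects = 200, n_null_snps = 500, n_ld_partners = 0,
                       fst = 0.1, n_populations = 2, seed = 29)
  cov <- simulate_covariates(cfg)
  pan <- simulate_genotypes(cfg, cov)
  pcs <- compute_ancestry_pcs(pan, 2)
  expect_gt(abs(cor(pcs[, 1], cov$admixture[, 1])), 0.9)
})

test_that("whole-cohort simulation is bit-reproducible under a fixed seed", {
  a <- small_cohort(31, n = 40, n_null = 30)
  b <- small_cohort(31, n = 40, n_null = 30)
  expect_identical(a$thresholds, b$thresholds)
  expect_identical(a$panel$dosage, b$panel$dosage)
  expect_identical(a$covariates, b$covariates)
})
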
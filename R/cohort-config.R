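#' Configuration for a synthetic taste-phenotyping cohort
#'
#' Collects every parameter of the synthetic cohort generator: panel size, the
#' causal bitter-receptor SNP (allele frequency and per-genotype-class detection
#' threshold means), the variance budget of the latent log10 threshold
#' (heritable share, age share, day-to-day noise), and the structure of the
#' surrounding SNP panel (null SNPs, LD partners of the causal SNP, number of
#' ancestral populations and their divergence).
#'
#' The defaults encode the benchmark trait: a biallelic SNP at allele frequency
#' 0.46 whose three genotype classes have geometric-mean detection thresholds of
#' 0.37, 0.113 and 0.047 mM (0, 1, 2 copies of the sensitive allele), an
#' additive dosage regression explaining 49% of latent threshold variance, an
#' age effect explaining 3.8%, and day-to-day threshold noise with standard
#' deviation 0.2836 log10 units (so the expected absolute difference between
#' two sessions is 0.32 log10 units under the Gaussian day-effect model).
#'
#' @param n_subjects number of subjects.
#' @param causal_allele_freq frequency of the sensitive (threshold-lowering)
#'   allele of the causal SNP.
#' @param class_means_mM geometric-mean detection thresholds (mM) for genotype
#'   classes with 0, 1 and 2 copies of the sensitive allele; must be strictly
#'   positive and strictly decreasing.
#' @param target_causal_r2 fraction of phenotype variance explained by the
#'   additive (linear-in-dosage) regression on the causal SNP. Under the
#'   default `calibration = "measured"` this is the variance of the observed
#'   phenotype (the log-average of `n_measurement_repeats` threshold
#'   measurements, whose day-to-day noise contributes
#'   `sigma_day^2 / n_measurement_repeats`); under `"latent"` it is the
#'   variance of the noiseless latent threshold.
#' @param age_effect_r2 fraction of (the same) phenotype variance explained by
#'   age.
#' @param calibration `"measured"` (default) or `"latent"`; see above.
#' @param n_measurement_repeats threshold measurements per subject assumed by
#'   the measured calibration (the benchmark design uses duplicates).
#' @param sigma_day standard deviation (log10 units) of the per-session
#'   day-effect added to each subject's latent threshold.
#' @param age_range,age_mean sampling range for age (uniform) and the centring
#'   constant used for the age effect.
#' @param bmi_mean,bmi_sd,bmi_range BMI normal parameters and truncation range.
#' @param n_null_snps number of unlinked background SNPs.
#' @param n_ld_partners number of SNPs in LD with the causal SNP.
#' @param ld_copy_prob per-haplotype probability that an LD partner copies the
#'   causal allele (r between partner and causal dosage is approximately this).
#' @param fst Balding-Nichols divergence of the simulated populations.
#' @param n_populations number of ancestral populations mixed per subject
#'   (admixture proportions are uniform Dirichlet).
#' @param glms_baseline_mean,glms_baseline_sd gLMS rating of water (scale units),
#'   per-subject, truncated at zero.
#' @param glms_slope_mean,glms_slope_sd gLMS units gained per decade of
#'   concentration above threshold, per-subject, truncated at zero.
#' @param glms_exponent exponent of the supra-threshold intensity response
#'   (see [simulate_glms_session()]); 1 = linear hinge.
#' @param glms_noise_sd trial-to-trial gLMS rating noise (scale units).
#' @param missing_rate per-SNP probability that a genotype call is missing
#'   (0 disables missingness).
#' @param seed integer seed; if non-NULL, generator functions seed the global
#'   RNG with it so the cohort is reproducible.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @examples
#' cfg <- cohort_config(n_subjects = 50, seed = 1)
#' cfg$class_means_mM
#' @export
cohort_config <- function(n_subjects = 225,
                          causal_allele_freq = 0.46,
                          class_means_mM = c(0.37, 0.113, 0.047),
                          target_causal_r2 = 0.49,
                          age_effect_r2 = 0.038,
                          calibration = c("measured", "latent"),
                          n_measurement_repeats = 2,
                          sigma_day = 0.2836,
                          age_range = c(18, 47),
                          age_mean = mean(age_range),
                          bmi_mean = 25.5, bmi_sd = 4.5,
                          bmi_range = c(16.6, 46.1),
                          n_null_snps = 4997,
                          n_ld_partners = 2,
                          ld_copy_prob = 0.9,
                          fst = 0.1,
                          n_populations = 2,
                          glms_baseline_mean = 5, glms_baseline_sd = 2,
                          glms_slope_mean = 20, glms_slope_sd = 3,
                          glms_exponent = 1.5,
                          glms_noise_sd = 12,
                          missing_rate = 0,
                          seed = NULL) {
  cfg <- list(
    n_subjects = n_subjects, causal_allele_freq = causal_allele_freq,
    class_means_mM = class_means_mM, target_causal_r2 = target_causal_r2,
    age_effect_r2 = age_effect_r2,
    calibration = match.arg(calibration),
    n_measurement_repeats = n_measurement_repeats,
    sigma_day = sigma_day,
    age_range = age_range, age_mean = age_mean,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd, bmi_range = bmi_range,
    n_null_snps = n_null_snps, n_ld_partners = n_ld_partners,
    ld_copy_prob = ld_copy_prob, fst = fst, n_populations = n_populations,
    glms_baseline_mean = glms_baseline_mean, glms_baseline_sd = glms_baseline_sd,
    glms_slope_mean = glms_slope_mean, glms_slope_sd = glms_slope_sd,
    glms_exponent = glms_exponent,
    glms_noise_sd = glms_noise_sd,
    missing_rate = missing_rate, seed = seed
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (length(cfg$n_subjects) != 1L || is.na(cfg$n_subjects) || cfg$n_subjects < 0)
    stop("invalid cohort config: n_subjects must be a non-negative integer", call. = FALSE)
  fracs <- c(causal_allele_freq = cfg$causal_allele_freq,
             target_causal_r2 = cfg$target_causal_r2,
             age_effect_r2 = cfg$age_effect_r2,
             ld_copy_prob = cfg$ld_copy_prob,
             missing_rate = cfg$missing_rate)
  bad <- fracs < 0 | fracs > 1 | is.na(fracs)
  if (any(bad))
    stop("invalid cohort config: ", paste(names(fracs)[bad], collapse = ", "),
         " must lie in [0, 1]", call. = FALSE)
  if (cfg$fst < 0 || cfg$fst >= 1)
    stop("invalid cohort config: fst must lie in [0, 1)", call. = FALSE)
  if (length(cfg$class_means_mM) != 3L || any(cfg$class_means_mM <= 0))
    stop("invalid cohort config: class_means_mM must be three positive concentrations",
         call. = FALSE)
  if (any(diff(cfg$class_means_mM) >= 0))
    stop("invalid cohort config: class_means_mM must decrease with allele count",
         call. = FALSE)
  if (cfg$target_causal_r2 + cfg$age_effect_r2 >= 1)
    stop("invalid cohort config: target_causal_r2 + age_effect_r2 must be < 1",
         call. = FALSE)
  if (cfg$sigma_day < 0)
    stop("invalid cohort config: sigma_day must be non-negative", call. = FALSE)
  if (cfg$n_populations < 1)
    stop("invalid cohort config: n_populations must be >= 1", call. = FALSE)
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  subjects: %d   causal allele freq: %.2f\n",
              x$n_subjects, x$causal_allele_freq))
  cat(sprintf("  class threshold means (mM): %s\n",
              paste(format(x$class_means_mM), collapse = " / ")))
  cat(sprintf("  variance budget: causal r2 %.3f, age r2 %.3f, sigma_day %.4f log10\n",
              x$target_causal_r2, x$age_effect_r2, x$sigma_day))
  cat(sprintf("  panel: %d null SNPs, %d LD partners (copy prob %.2f), %d pops (Fst %.2f)\n",
              x$n_null_snps, x$n_ld_partners, x$ld_copy_prob,
              x$n_populations, x$fst))
  invisible(x)
}

#' Variance budget of the latent threshold model
#'
#' Solves the closed-form budget that calibrates the latent log10 threshold so
#' the additive dosage regression of the causal SNP explains
#' `target_causal_r2` of phenotype variance and age explains `age_effect_r2`.
#' With genotype-class means m_d (log10 mM) and Hardy-Weinberg class
#' probabilities at allele frequency p, the additive genetic variance is
#' V_A = Cov(m_D, D)^2 / Var(D), fixed by the printed class means and allele
#' frequency. The reference phenotype variance is V_P = V_A / r2_causal. Under
#' the default measured calibration V_P is the variance of the log-averaged
#' repeat measurements, so the latent total is
#' V_T = V_P - sigma_day^2 / n_measurement_repeats; under the latent
#' calibration V_T = V_P. The age variance is V_age = r2_age * V_P and the
#' residual variance V_e = V_T - Var(m_D) - V_age. Var(m_D) >= V_A (dominance
#' deviation), so the budget is infeasible when the class-mean variance, age
#' share and measurement noise together exceed V_P.
#'
#' @param config a [cohort_config()].
#' @return list with components `class_means_log10`, `v_additive`,
#'   `v_genetic` (class-mean variance), `v_age`, `v_resid`, `v_total`
#'   (latent), `v_phenotype` (reference phenotype variance),
#'   `beta_age` (log10 units per year) and `beta_additive` (log10 units per
#'   allele copy).
#' @export
variance_budget <- function(config) {
  p <- config$causal_allele_freq
  m <- log10(config$class_means_mM)
  w <- c((1 - p)^2, 2 * p * (1 - p), p^2)      # HWE class probabilities for D = 0,1,2
  d <- 0:2
  mu_g <- sum(w * m)
  v_g <- sum(w * (m - mu_g)^2)
  mu_d <- sum(w * d)
  v_d <- sum(w * (d - mu_d)^2)
  cov_gd <- sum(w * (m - mu_g) * (d - mu_d))
  beta_add <- cov_gd / v_d
  v_a <- cov_gd^2 / v_d
  if (v_a <= 0)
    stop("variance budget: causal SNP has no additive effect", call. = FALSE)
  v_p <- v_a / config$target_causal_r2
  meas_var <- if (identical(config$calibration, "latent")) 0 else
    config$sigma_day^2 / config$n_measurement_repeats
  v_t <- v_p - meas_var
  v_age <- config$age_effect_r2 * v_p
  v_e <- v_t - v_g - v_age
  if (v_e < 0)
    stop("variance budget infeasible: class-mean variance (", signif(v_g, 4),
         ") plus age and measurement-noise shares exceed the phenotype variance (",
         signif(v_p, 4), ") implied by target_causal_r2", call. = FALSE)
  v_age_pop <- diff(config$age_range)^2 / 12   # variance of uniform age
  beta_age <- if (v_age > 0) sqrt(v_age / v_age_pop) else 0
  list(class_means_log10 = m, v_additive = v_a, v_genetic = v_g,
       v_age = v_age, v_resid = v_e, v_total = v_t, v_phenotype = v_p,
       beta_age = beta_age, beta_additive = beta_add)
}
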
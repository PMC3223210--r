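#' Simulate subject covariates
#'
#' Draws age, sex, BMI and per-subject admixture proportions for a synthetic
#' cohort. Ages are uniform on the configured range, sex is Bernoulli(0.5)
#' coded 0/1, BMI is normal truncated to the configured range, and admixture
#' proportions across the configured ancestral populations are uniform
#' Dirichlet (exponential draws renormalised to sum to one).
#'
#' @param config a [cohort_config()].
#' @return data.frame with columns `subject_id`, `age`, `sex`, `bmi` and an
#'   `admixture` matrix column (subjects x populations, rows summing to 1).
#' @examples
#' cov <- simulate_covariates(cohort_config(n_subjects = 10, seed = 1))
#' range(cov$age)
#' @export
simulate_covariates <- function(config) {
  config <- validate_cohort_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- as.integer(config$n_subjects)
  if (n == 0L) {
    out <- data.frame(subject_id = character(0), age = numeric(0),
                      sex = integer(0), bmi = numeric(0))
    out$admixture <- matrix(numeric(0), 0, config$n_populations)
    return(out)
  }
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- stats::rbinom(n, 1L, 0.5)
  # truncated normal by resampling; range is ~2 sd either side so this is cheap
  bmi <- stats::rnorm(n, config$bmi_mean, config$bmi_sd)
  out_of_range <- function(x) x < config$bmi_range[1] | x > config$bmi_range[2]
  while (any(bad <- out_of_range(bmi)))
    bmi[bad] <- stats::rnorm(sum(bad), config$bmi_mean, config$bmi_sd)
  k <- config$n_populations
  adm <- matrix(stats::rexp(n * k), n, k)
  adm <- adm / rowSums(adm)
  out <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                    age = age, sex = sex, bmi = bmi)
  out$admixture <- adm
  out
}

#' Simulate a SNP panel with one causal locus, LD partners and structure
#'
#' Generates genotype dosages under the Balding-Nichols model: each SNP has an
#' ancestral frequency, per-population frequencies are Beta-distributed around
#' it with divergence `fst`, and each subject's allele frequency is the
#' admixture-weighted average of the population frequencies. The causal SNP's
#' frequency is fixed at `causal_allele_freq` in every population (so its
#' observed MAF matches the configured value and carries no stratification
#' confound); LD partners copy each causal haplotype with probability
#' `ld_copy_prob` and otherwise draw an independent allele at the same
#' frequency.
#'
#' @param config a [cohort_config()].
#' @param covariates covariate table from [simulate_covariates()] (supplies the
#'   admixture proportions).
#' @return an object of class `snp_panel`: list with `snp_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `dosage` (subjects x SNPs integer matrix, NA = missing),
#'   `is_causal`, `is_ld_partner`, and `pop_freq` (populations x SNPs).
#' @export
simulate_genotypes <- function(config, covariates) {
  config <- validate_cohort_config(config)
  if (is.null(covariates$admixture))
    stop("covariates must carry admixture proportions", call. = FALSE)
  n <- nrow(covariates)
  adm <- covariates$admixture
  npop <- ncol(adm)
  n_null <- as.integer(config$n_null_snps)
  n_ld <- as.integer(config$n_ld_partners)
  m <- 1L + n_ld + n_null
  fst <- config$fst

  # ancestral frequencies for null SNPs; causal/LD partners pinned to config
  p_anc <- c(config$causal_allele_freq, rep(config$causal_allele_freq, n_ld),
             stats::runif(n_null, 0.05, 0.95))
  pop_freq <- matrix(NA_real_, npop, m)
  pop_freq[, seq_len(1L + n_ld)] <- config$causal_allele_freq
  if (n_null > 0) {
    idx <- (2L + n_ld):m
    if (fst > 0) {
      a <- p_anc[idx] * (1 - fst) / fst
      b <- (1 - p_anc[idx]) * (1 - fst) / fst
      for (k in seq_len(npop))
        pop_freq[k, idx] <- stats::rbeta(n_null, a, b)
    } else {
      pop_freq[, idx] <- matrix(p_anc[idx], npop, n_null, byrow = TRUE)
    }
  }

  # subject-specific frequencies via admixture, one haplotype pair per SNP
  subj_freq <- adm %*% pop_freq                 # n x m
  # causal SNP as explicit haplotypes so LD partners can copy them
  hap1 <- stats::rbinom(n, 1L, config$causal_allele_freq)
  hap2 <- stats::rbinom(n, 1L, config$causal_allele_freq)
  dosage <- matrix(NA_integer_, n, m)
  dosage[, 1L] <- hap1 + hap2
  if (n_ld > 0) {
    for (j in seq_len(n_ld)) {
      keep1 <- stats::rbinom(n, 1L, config$ld_copy_prob) == 1L
      keep2 <- stats::rbinom(n, 1L, config$ld_copy_prob) == 1L
      h1 <- ifelse(keep1, hap1, stats::rbinom(n, 1L, config$causal_allele_freq))
      h2 <- ifelse(keep2, hap2, stats::rbinom(n, 1L, config$causal_allele_freq))
      dosage[, 1L + j] <- h1 + h2
    }
  }
  if (n_null > 0) {
    idx <- (2L + n_ld):m
    dosage[, idx] <- stats::rbinom(n * n_null, 2L, as.vector(subj_freq[, idx]))
  }

  if (config$missing_rate > 0 && n > 0) {
    miss <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
    dosage[miss] <- NA_integer_
  }

  # causal locus and LD partners clustered on chr7; null SNPs tiled over 1..22
  chrom <- character(m)
  pos <- integer(m)
  chrom[seq_len(1L + n_ld)] <- "7"
  pos[seq_len(1L + n_ld)] <- 141672345L + 1000L * (seq_len(1L + n_ld) - 1L)
  if (n_null > 0) {
    idx <- (2L + n_ld):m
    chr_null <- rep_len(as.character(c(1:6, 8:22)), n_null)
    chrom[idx] <- chr_null
    pos_null <- integer(n_null)
    for (cc in unique(chr_null))
      pos_null[chr_null == cc] <- seq_len(sum(chr_null == cc)) * 50000L
    pos[idx] <- pos_null
  }
  snp_id <- c("snp_causal",
              if (n_ld > 0) sprintf("snp_ld%02d", seq_len(n_ld)),
              if (n_null > 0) sprintf("snp_null%05d", seq_len(n_null)))
  panel <- list(snp_id = snp_id, chrom = chrom, pos = pos,
                ref = rep("C", m), alt = rep("T", m),
                dosage = dosage,
                is_causal = seq_len(m) == 1L,
                is_ld_partner = seq_len(m) %in% (1L + seq_len(n_ld)),
                pop_freq = pop_freq)
  class(panel) <- "snp_panel"
  panel
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("SNP panel: %d subjects x %d SNPs (%d causal, %d LD partners)\n",
              nrow(x$dosage), length(x$snp_id), sum(x$is_causal),
              sum(x$is_ld_partner)))
  invisible(x)
}

#' Assign latent detection thresholds
#'
#' Builds each subject's true log10 detection threshold as
#' `class mean (log10 mM) + age effect + residual`, with the age slope and
#' residual variance calibrated by the closed-form [variance_budget()] so the
#' additive regression of threshold on causal dosage explains
#' `target_causal_r2` of total variance and age explains `age_effect_r2`.
#' Per-subject gLMS response parameters (baseline, slope, rating noise) are
#' drawn at the same time.
#'
#' @param panel a `snp_panel` containing the causal SNP.
#' @param covariates covariate table (ages used for the age effect).
#' @param config a [cohort_config()].
#' @return data.frame of latent taste profiles: `subject_id`, `theta_log10`
#'   (true threshold, log10 mM), `glms_baseline`, `glms_slope`,
#'   `glms_noise_sd`, plus the causal `dosage` used.
#' @export
assign_latent_thresholds <- function(panel, covariates, config) {
  config <- validate_cohort_config(config)
  if (!any(panel$is_causal)) stop("panel has no causal SNP", call. = FALSE)
  budget <- variance_budget(config)
  dos <- panel$dosage[, which(panel$is_causal)[1]]
  if (anyNA(dos))
    stop("causal SNP has missing dosages; latent assignment requires complete calls",
         call. = FALSE)
  n <- nrow(covariates)
  theta <- budget$class_means_log10[dos + 1L] +
    budget$beta_age * (covariates$age - config$age_mean) +
    stats::rnorm(n, 0, sqrt(budget$v_resid))
  trunc0 <- function(x) { x[x < 0] <- 0; x }
  data.frame(
    subject_id = covariates$subject_id,
    theta_log10 = theta,
    dosage = dos,
    glms_baseline = trunc0(stats::rnorm(n, config$glms_baseline_mean,
                                        config$glms_baseline_sd)),
    glms_slope = trunc0(stats::rnorm(n, config$glms_slope_mean,
                                     config$glms_slope_sd)),
    glms_noise_sd = rep(config$glms_noise_sd, n)
  )
}

#' Sample session-to-session day effects
#'
#' Adds i.i.d. Gaussian day offsets (mean zero, sd `sigma_day`) to each
#' subject's latent threshold, one per phenotyping session. The threshold in
#' force on session j is `theta_log10 + day_offsets[, j]`.
#'
#' @param profiles latent profiles from [assign_latent_thresholds()].
#' @param n_sessions number of sessions (>= 1).
#' @param config a [cohort_config()].
#' @return `profiles` with a matrix column `day_offsets` (subjects x sessions).
#' @export
sample_day_effects <- function(profiles, n_sessions, config) {
  config <- validate_cohort_config(config)
  if (n_sessions < 1) stop("n_sessions must be >= 1", call. = FALSE)
  n <- nrow(profiles)
  off <- matrix(stats::rnorm(n * n_sessions, 0, config$sigma_day), n, n_sessions)
  profiles$day_offsets <- off
  profiles
}

#' Simulate a complete phenotyped cohort
#'
#' Convenience wrapper running the whole generator: covariates, SNP panel,
#' latent thresholds, day effects, duplicate staircase threshold measurements
#' and (optionally) triplicate gLMS intensity sessions.
#'
#' @param config a [cohort_config()].
#' @param n_staircase_sessions staircase repeats per subject (default 2).
#' @param n_glms_sessions gLMS repeats per subject (default 3); 0 skips gLMS.
#' @param ladder concentration ladder, default [build_ladder()] defaults.
#' @param staircase a [staircase_config()].
#' @return object of class `taste_cohort`: list with `config`, `covariates`,
#'   `panel`, `profiles`, `thresholds` (subjects x sessions, mM, NA where the
#'   staircase did not converge), `converged`, and `glms` (list of session
#'   rating matrices) with `glms_concentrations`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_subjects = 20, n_null_snps = 10, seed = 1),
#'                        n_glms_sessions = 0)
#' coh$thresholds[1:3, ]
#' @export
simulate_cohort <- function(config = cohort_config(),
                            n_staircase_sessions = 2,
                            n_glms_sessions = 3,
                            ladder = build_ladder(),
                            staircase = staircase_config()) {
  config <- validate_cohort_config(config)
  covariates <- simulate_covariates(config)   # seeds the RNG if config$seed set
  panel <- simulate_genotypes(config, covariates)
  profiles <- assign_latent_thresholds(panel, covariates, config)
  profiles <- sample_day_effects(profiles, n_staircase_sessions, config)
  meas <- measure_thresholds(profiles, ladder, staircase)
  glms <- NULL
  if (n_glms_sessions > 0)
    glms <- simulate_glms_sessions(profiles, n_sessions = n_glms_sessions,
                                   config = config)
  out <- list(config = config, covariates = covariates, panel = panel,
              profiles = profiles, thresholds = meas$estimate,
              converged = meas$converged,
              glms = glms$ratings, glms_concentrations = glms$concentrations)
  class(out) <- "taste_cohort"
  out
}

#' @export
print.taste_cohort <- function(x, ...) {
  cat(sprintf("Synthetic taste cohort: %d subjects, %d SNPs, %d staircase sessions%s\n",
              nrow(x$covariates), length(x$panel$snp_id), ncol(x$thresholds),
              if (is.null(x$glms)) "" else sprintf(", %d gLMS sessions", length(x$glms))))
  conv <- mean(apply(x$converged, 1, all))
  cat(sprintf("  staircase convergence (all sessions): %.1f%% of subjects\n", 100 * conv))
  invisible(x)
}
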
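# Small builders shared across test files.

# A lean cohort: no LD partners, few null SNPs, duplicate staircases, no gLMS.
small_cohort <- function(seed, n = 120, n_null = 250, ...) {
  simulate_cohort(
    cohort_config(n_subjects = n, n_null_snps = n_null, n_ld_partners = 0,
                  seed = seed, ...),
    n_glms_sessions = 0)
}

# Wrap a bare dosage matrix as a snp_panel.
make_panel <- function(dosage, chrom = NULL, pos = NULL) {
  m <- ncol(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("S%04d", seq_len(nrow(dosage)))
  structure(list(
    snp_id = sprintf("snp%05d", seq_len(m)),
    chrom = if (is.null(chrom)) rep("1", m) else chrom,
    pos = if (is.null(pos)) seq_len(m) * 1000L else pos,
    ref = rep("C", m), alt = rep("T", m),
    dosage = dosage,
    is_causal = c(TRUE, rep(FALSE, m - 1L)),
    is_ld_partner = rep(FALSE, m),
    pop_freq = NULL), class = "snp_panel")
}

# Covariate table with no real structure, for engine-level tests.
null_covariates <- function(n) {
  data.frame(subject_id = sprintf("S%04d", seq_len(n)),
             age = runif(n, 18, 47),
             sex = rbinom(n, 1, 0.5),
             bmi = rnorm(n, 25.5, 4.5))
}

light_gwas_config <- function(...) gwas_config(n_pcs = 2, ...)
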
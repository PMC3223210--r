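experiment_report <- function(name, conditions, seed = NULL, config = NULL) {
  out <- list(name = name, conditions = conditions, seed = seed,
              config = config)
  class(out) <- "experiment_report"
  out
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Experiment report: %s\n", x$name))
  print(x$conditions, row.names = FALSE, digits = 4)
  invisible(x)
}

causal_row <- function(scan) {
  scan$results[scan$panel_flags$is_causal, , drop = FALSE]
}

min_valid_p <- function(scan) {
  p <- scan$results$p_gc
  min(p, na.rm = TRUE)
}

#' Compare phenotype representations in full GWAS runs
#'
#' Runs the complete association scan once per threshold representation
#' (linear model for the continuous ones, stacked repeats with genomic
#' control, logistic for the binary taster phenotype) on the same cohort, and
#' reports the causal-SNP p-value before and after genomic control, the
#' causal r2 and the inflation factor for each.
#'
#' @param cohort a `taste_cohort` with duplicate staircase measurements.
#' @param representations character vector of representation kinds.
#' @param cutoff_mM taster cutoff for the binary representation.
#' @param config a [gwas_config()].
#' @return an `experiment_report`; `conditions` has one row per
#'   representation with `p_causal_raw`, `p_causal_gc`, `p_min`, `lambda`,
#'   `r2_causal`.
#' @export
compare_representations <- function(cohort,
                                    representations = c("log_then_average",
                                                        "log_of_average",
                                                        "average_raw",
                                                        "stacked_repeats",
                                                        "binary_taster"),
                                    cutoff_mM = 0.2,
                                    config = gwas_config()) {
  rows <- lapply(representations, function(kind) {
    ph <- make_threshold_representation(cohort$thresholds, kind,
                                        cutoff_mM = cutoff_mM)
    scan <- gwas(ph, cohort$panel, cohort$covariates, config = config)
    cr <- causal_row(scan)
    data.frame(representation = kind, model = scan$model,
               p_causal_raw = cr$p_raw, p_causal_gc = cr$p_gc,
               p_min = min_valid_p(scan), lambda = scan$lambda,
               r2_causal = cr$r2_snp, stringsAsFactors = FALSE)
  })
  experiment_report("phenotype representation comparison",
                    do.call(rbind, rows),
                    seed = cohort$config$seed, config = config)
}

#' Single measurements on a full panel vs duplicates on half panels
#'
#' Condition A runs the GWAS on every subject using only the first threshold
#' measurement. Condition B draws random half panels (floor(n/2) + 1
#' subjects, without replacement, independent across draws), runs the GWAS on
#' the log-averaged duplicates in each, and averages -log10 of the minimum
#' p-value across draws.
#'
#' @param cohort a `taste_cohort` with at least two staircase repeats.
#' @param n_draws number of random half-panel draws (the benchmark uses 1000).
#' @param config a [gwas_config()].
#' @return an `experiment_report` with one row per condition and the mean
#'   -log10 minimum p.
#' @export
subpanel_experiment <- function(cohort, n_draws = 1000,
                                config = gwas_config()) {
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  if (ncol(cohort$thresholds) < 2)
    stop("subpanel experiment needs duplicate measurements", call. = FALSE)
  n <- nrow(cohort$covariates)
  half <- as.integer(floor(n / 2) + 1L)

  ph_first <- make_threshold_representation(
    cohort$thresholds[, 1, drop = FALSE], "log_then_average")
  scan_a <- gwas(ph_first, cohort$panel, cohort$covariates, config = config)

  neglog_b <- numeric(n_draws)
  for (d in seq_len(n_draws)) {
    pick <- sort(sample.int(n, half))
    sub_cov <- cohort$covariates[pick, , drop = FALSE]
    sub_panel <- cohort$panel
    sub_panel$dosage <- cohort$panel$dosage[pick, , drop = FALSE]
    ph <- make_threshold_representation(
      cohort$thresholds[pick, , drop = FALSE], "log_then_average",
      subject_id = cohort$covariates$subject_id[pick])
    scan_b <- gwas(ph, sub_panel, sub_cov, config = config)
    neglog_b[d] <- -log10(min_valid_p(scan_b))
  }
  conditions <- data.frame(
    condition = c("full_panel_single_measurement", "half_panel_duplicates"),
    n_subjects = c(n, half),
    n_draws = c(1L, n_draws),
    mean_neglog10_pmin = c(-log10(min_valid_p(scan_a)), mean(neglog_b)),
    stringsAsFactors = FALSE)
  experiment_report("full panel single measurement vs half panel duplicates",
                    conditions, seed = cohort$config$seed, config = config)
}

#' Scan the taster/non-taster cutoff for the logistic GWAS
#'
#' Re-runs the binary-phenotype logistic GWAS over a grid of classification
#' cutoffs (default 0.1 to 0.3 mM in 0.025 mM steps) and reports the
#' causal-SNP p at each cutoff; cutoffs that leave a single outcome class are
#' flagged and skipped.
#'
#' @param cohort a `taste_cohort`.
#' @param lo,hi,step cutoff grid in mM.
#' @param config a [gwas_config()].
#' @return an `experiment_report`; one row per cutoff.
#' @export
cutoff_scan <- function(cohort, lo = 0.1, hi = 0.3, step = 0.025,
                        config = gwas_config()) {
  if (!(lo < hi && step > 0)) stop("need lo < hi and step > 0", call. = FALSE)
  grid <- seq(lo, hi, by = step)
  rows <- lapply(grid, function(cut) {
    ph <- make_threshold_representation(cohort$thresholds, "binary_taster",
                                        cutoff_mM = cut)
    if (length(unique(ph$values)) < 2)
      return(data.frame(cutoff_mM = cut, p_causal = NA_real_,
                        p_min = NA_real_, skipped = TRUE))
    scan <- gwas(ph, cohort$panel, cohort$covariates, model = "logistic",
                 config = config)
    data.frame(cutoff_mM = cut, p_causal = causal_row(scan)$p_gc,
               p_min = min_valid_p(scan), skipped = FALSE)
  })
  experiment_report("taster cutoff scan (logistic GWAS)",
                    do.call(rbind, rows),
                    seed = cohort$config$seed, config = config)
}

#' Conditional re-analysis on the top SNP
#'
#' Corrects each subject's phenotype for their dosage at a chosen top SNP
#' (linear, additive) and re-runs the GWAS on the corrected phenotype,
#' reporting every SNP's p-value before and after conditioning. Signals that
#' merely tag the top SNP through LD collapse; independent signals survive.
#'
#' @param cohort a `taste_cohort`.
#' @param top_snp SNP id to condition on (default: the causal SNP).
#' @param phenotype optional [phenotype_vector()]; default log-averaged
#'   duplicate thresholds.
#' @param config a [gwas_config()].
#' @return an `experiment_report`; `conditions` has one row per QC-passing
#'   SNP with `p_before` and `p_after`.
#' @export
conditional_gwas <- function(cohort, top_snp = NULL, phenotype = NULL,
                             config = gwas_config()) {
  panel <- cohort$panel
  if (is.null(top_snp)) top_snp <- panel$snp_id[panel$is_causal][1]
  j <- match(top_snp, panel$snp_id)
  if (is.na(j)) stop("top SNP '", top_snp, "' not in panel", call. = FALSE)
  g <- panel$dosage[, j]
  if (stats::var(g, na.rm = TRUE) == 0)
    stop("cannot condition on a monomorphic SNP", call. = FALSE)
  if (is.null(phenotype))
    phenotype <- make_threshold_representation(cohort$thresholds,
                                               "log_then_average")
  before <- gwas(phenotype, panel, cohort$covariates, config = config)

  idx <- match(phenotype$subject_id, cohort$covariates$subject_id)
  gg <- g[idx]
  fit <- stats::lm.fit(cbind(1, gg), phenotype$values)
  cond_ph <- phenotype_vector(fit$residuals, phenotype$subject_id,
                              paste0(phenotype$representation, "|cond"))
  after <- gwas(cond_ph, panel, cohort$covariates, config = config)

  key <- data.frame(snp_id = before$results$snp_id,
                    is_causal = before$panel_flags$is_causal,
                    is_ld_partner = before$panel_flags$is_ld_partner,
                    p_before = before$results$p_gc, stringsAsFactors = FALSE)
  key$p_after <- after$results$p_gc[match(key$snp_id, after$results$snp_id)]
  experiment_report(sprintf("conditional GWAS on %s", top_snp), key,
                    seed = cohort$config$seed, config = config)
}

#' Region-wise Bonferroni correction
#'
#' @param min_p smallest p-value observed in the region, in (0, 1].
#' @param n_snps number of quality-controlled SNPs in the region.
#' @return the Bonferroni-corrected p-value, capped at 1.
#' @examples
#' region_bonferroni(2.8e-4, 10165)   # 1
#' @export
region_bonferroni <- function(min_p, n_snps) {
  if (any(min_p <= 0 | min_p > 1)) stop("min_p must lie in (0, 1]", call. = FALSE)
  if (any(n_snps < 1)) stop("n_snps must be >= 1", call. = FALSE)
  pmin(1, min_p * n_snps)
}

#' Univariate demographic associations with the phenotype
#'
#' One simple linear regression of the phenotype on each covariate (age, BMI,
#' sex and the first two ancestry PCs), reporting slope, r2 and the two-sided
#' p-value - the per-plot regressions of an exploratory demographics figure.
#'
#' @param phenotype a continuous [phenotype_vector()].
#' @param covariates covariate table.
#' @param pcs optional subjects x >=2 PC matrix (from
#'   [compute_ancestry_pcs()]); adds PC1/PC2 rows.
#' @return data.frame with `covariate`, `slope`, `r2`, `p`, `flag`.
#' @export
demographic_associations <- function(phenotype, covariates, pcs = NULL) {
  idx <- match(phenotype$subject_id, covariates$subject_id)
  vars <- list(age = covariates$age[idx], bmi = covariates$bmi[idx],
               sex = as.numeric(covariates$sex[idx]))
  if (!is.null(pcs)) {
    vars$PC1 <- pcs[idx, 1]
    if (ncol(pcs) >= 2) vars$PC2 <- pcs[idx, 2]
  }
  y <- phenotype$values
  rows <- lapply(names(vars), function(v) {
    x <- vars[[v]]
    if (stats::var(x) == 0)
      return(data.frame(covariate = v, slope = NA_real_, r2 = NA_real_,
                        p = NA_real_, flag = "constant"))
    r <- stats::cor(y, x)
    n <- length(y)
    slope <- r * stats::sd(y) / stats::sd(x)
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    data.frame(covariate = v, slope = slope, r2 = r^2,
               p = 2 * stats::pt(-abs(tt), n - 2), flag = NA_character_)
  })
  do.call(rbind, rows)
}
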
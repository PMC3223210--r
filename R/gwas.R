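#' GWAS engine configuration
#'
#' QC thresholds, covariate choices and correction switches for the
#' allele-dosage association scan. Defaults follow common chip-QC practice:
#' minor allele frequency above 5%, call rate above 95%, Hardy-Weinberg exact
#' departure p above 1e-5, age/sex/BMI plus the first 10 ancestry principal
#' components as covariates, genome-wide significance at 5e-8, and genomic
#' control applied to the final p-values.
#'
#' @param covariates character vector of covariate columns used from the
#'   covariate table.
#' @param n_pcs number of ancestry principal components included.
#' @param maf_min,call_rate_min,hwe_p_min QC thresholds (SNPs must exceed
#'   them strictly).
#' @param significance_alpha genome-wide significance threshold.
#' @param apply_genomic_control logical; divide test chi-squares by the
#'   inflation factor lambda when lambda > 1.
#' @return object of class `gwas_config`.
#' @export
gwas_config <- function(covariates = c("age", "sex", "bmi"),
                        n_pcs = 10,
                        maf_min = 0.05,
                        call_rate_min = 0.95,
                        hwe_p_min = 1e-5,
                        significance_alpha = 5e-8,
                        apply_genomic_control = TRUE) {
  for (v in c(maf_min, call_rate_min, hwe_p_min, significance_alpha))
    if (v <= 0 || v >= 1)
      stop("invalid GWAS config: thresholds must lie in (0, 1)", call. = FALSE)
  out <- list(covariates = covariates, n_pcs = n_pcs, maf_min = maf_min,
              call_rate_min = call_rate_min, hwe_p_min = hwe_p_min,
              significance_alpha = significance_alpha,
              apply_genomic_control = apply_genomic_control)
  class(out) <- "gwas_config"
  out
}

#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom chi-square goodness-of-fit of the observed genotype
#' counts against Hardy-Weinberg expectations at the sample allele frequency.
#' Monomorphic SNPs return p = 1 by convention.
#'
#' @param counts integer vector `(n_AA, n_Aa, n_aa)` of genotype counts.
#' @return the HWE p-value.
#' @examples
#' hwe_test(c(25, 50, 25))   # exact HWE proportions: p = 1
#' @export
hwe_test <- function(counts) {
  if (length(counts) != 3L || any(counts < 0) || sum(counts) == 0)
    stop("counts must be three non-negative genotype counts with total > 0",
         call. = FALSE)
  n <- sum(counts)
  p <- (2 * counts[3] + counts[2]) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expect <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi2 <- sum((counts - expect)^2 / expect)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

snp_maf <- function(dos) {
  p <- mean(dos, na.rm = TRUE) / 2
  min(p, 1 - p)
}

#' QC-filter a SNP panel
#'
#' Retains SNPs whose minor allele frequency, call rate and Hardy-Weinberg
#' p-value all exceed the configured thresholds, and reports each exclusion
#' with its (first failing) reason.
#'
#' @param panel a `snp_panel`.
#' @param config a [gwas_config()].
#' @return list with `panel` (filtered) and `exclusions` (data.frame of
#'   `snp_id`, `reason`).
#' @export
qc_filter_snps <- function(panel, config = gwas_config()) {
  dos <- panel$dosage
  m <- ncol(dos)
  call_rate <- colMeans(!is.na(dos))
  maf <- apply(dos, 2, snp_maf)
  hwe_p <- vapply(seq_len(m), function(j) {
    d <- dos[, j]; d <- d[!is.na(d)]
    hwe_test(c(sum(d == 0L), sum(d == 1L), sum(d == 2L)))
  }, numeric(1))
  reason <- rep(NA_character_, m)
  reason[hwe_p <= config$hwe_p_min] <- "hwe"
  reason[maf <= config$maf_min] <- "maf"
  reason[call_rate <= config$call_rate_min] <- "call_rate"
  keep <- is.na(reason)
  list(panel = subset_panel(panel, keep),
       exclusions = data.frame(snp_id = panel$snp_id[!keep],
                               reason = reason[!keep]))
}

subset_panel <- function(panel, keep) {
  out <- panel
  for (f in c("snp_id", "chrom", "pos", "ref", "alt", "is_causal", "is_ld_partner"))
    out[[f]] <- panel[[f]][keep]
  out$dosage <- panel$dosage[, keep, drop = FALSE]
  if (!is.null(panel$pop_freq)) out$pop_freq <- panel$pop_freq[, keep, drop = FALSE]
  out
}

#' Ancestry principal components
#'
#' PCA of the standardised dosage matrix: each SNP is centred by twice its
#' sample allele frequency and scaled by the binomial standard deviation
#' sqrt(2 p (1 - p)); missing dosages are set to the SNP mean; monomorphic
#' SNPs are dropped. The top-k left singular vectors (orthonormal) are the
#' subject coordinates.
#'
#' @param panel a `snp_panel` (typically after QC).
#' @param k number of components.
#' @return subjects x k matrix with columns `PC1..PCk`.
#' @export
compute_ancestry_pcs <- function(panel, k = 10) {
  dos <- panel$dosage
  p_hat <- colMeans(dos, na.rm = TRUE) / 2
  poly <- p_hat > 0 & p_hat < 1 & !is.na(p_hat)
  if (sum(poly) < 2)
    stop("need at least 2 polymorphic SNPs for ancestry PCA", call. = FALSE)
  x <- dos[, poly, drop = FALSE]
  p <- p_hat[poly]
  x <- sweep(x, 2, 2 * p)
  x[is.na(x)] <- 0                      # mean imputation after centring
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  n <- nrow(x)
  # left singular vectors via the small n x n Gram matrix
  g <- tcrossprod(x)
  e <- eigen(g, symmetric = TRUE)
  rank <- sum(e$values > max(e$values) * 1e-9)
  if (k > rank)
    stop("requested ", k, " PCs but the dosage matrix has rank ", rank,
         call. = FALSE)
  u <- e$vectors[, seq_len(k), drop = FALSE]
  colnames(u) <- paste0("PC", seq_len(k))
  rownames(u) <- rownames(dos)
  u
}

build_design <- function(covariates, pcs, config, obs_idx) {
  cols <- intersect(config$covariates, names(covariates))
  x <- as.matrix(covariates[cols])
  if (!is.null(pcs) && config$n_pcs > 0)
    x <- cbind(x, pcs[, seq_len(min(config$n_pcs, ncol(pcs))), drop = FALSE])
  x[obs_idx, , drop = FALSE]
}

drop_aliased <- function(x) {
  qrx <- qr(cbind(1, x))
  if (qrx$rank < ncol(x) + 1L) {
    keep <- sort(qrx$pivot[seq_len(qrx$rank)])
    keep <- setdiff(keep, 1L) - 1L
    warning("dropping collinear covariate column(s): ",
            paste(colnames(x)[setdiff(seq_len(ncol(x)), keep)], collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  x
}

#' Residualise a phenotype on covariates
#'
#' Least-squares regression of a continuous phenotype on an intercept plus the
#' covariate design (age, sex, BMI, ancestry PCs); returns the residuals,
#' which are orthogonal to every retained covariate. Collinear covariate
#' columns are dropped with a warning. Binary phenotypes are refused - the
#' logistic path adjusts for covariates inside the model instead.
#'
#' @param pheno a [phenotype_vector()].
#' @param design numeric matrix of covariates, one row per observation.
#' @return a [phenotype_vector()] of residuals.
#' @export
residualize_phenotype <- function(pheno, design) {
  if (pheno$representation == "binary_taster" ||
      all(pheno$values %in% c(0, 1)))
    stop("refusing to residualise a binary phenotype; use the logistic path",
         call. = FALSE)
  design <- drop_aliased(as.matrix(design))
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, design), pheno$values)
  phenotype_vector(fit$residuals, pheno$subject_id,
                   paste0(pheno$representation, "|resid"))
}

# Vectorised per-SNP simple OLS of y on dosage with intercept.
# Returns a data.frame of beta, se, stat, p, r2 with monomorphic flags.
linear_scan <- function(y, dosage) {
  n_obs <- length(y)
  m <- ncol(dosage)
  beta <- se <- stat <- p <- r2 <- rep(NA_real_, m)
  flag <- rep(NA_character_, m)
  has_na <- colSums(is.na(dosage)) > 0L
  scan_one <- function(yv, g) {
    n <- length(yv)
    vg <- stats::var(g)
    if (n < 3 || is.na(vg) || vg == 0) return(NULL)
    r <- stats::cor(yv, g)
    b <- r * stats::sd(yv) / stats::sd(g)
    s <- sqrt(max(stats::var(yv) * (1 - r^2), 0) / vg / (n - 2))
    tt <- if (s > 0) b / s else sign(b) * Inf
    c(b, s, tt, 2 * stats::pt(-abs(tt), n - 2), r^2)
  }
  # complete-dosage columns in one vectorised pass
  cc <- which(!has_na)
  if (length(cc)) {
    g <- dosage[, cc, drop = FALSE]
    gm <- colMeans(g)
    gc_ <- sweep(g, 2, gm)
    ssg <- colSums(gc_^2)
    yc <- y - mean(y)
    ssy <- sum(yc^2)
    sxy <- as.vector(crossprod(gc_, yc))
    ok <- ssg > 0
    b <- sxy / ssg
    rr2 <- ifelse(ok & ssy > 0, sxy^2 / (ssg * ssy), NA_real_)
    s <- sqrt(pmax(ssy * (1 - rr2), 0) / ssg / (n_obs - 2))
    tt <- ifelse(s > 0, b / s, sign(b) * Inf)
    beta[cc] <- ifelse(ok, b, NA_real_)
    stat[cc] <- ifelse(ok, tt, NA_real_)
    se[cc] <- ifelse(ok, s, NA_real_)
    p[cc] <- ifelse(ok, 2 * stats::pt(-abs(tt), n_obs - 2), NA_real_)
    r2[cc] <- rr2
    flag[cc][!ok] <- "monomorphic"
  }
  for (j in which(has_na)) {
    g <- dosage[, j]
    use <- !is.na(g)
    res <- scan_one(y[use], g[use])
    if (is.null(res)) { flag[j] <- "monomorphic"; next }
    beta[j] <- res[1]; se[j] <- res[2]; stat[j] <- res[3]
    p[j] <- res[4]; r2[j] <- res[5]
  }
  data.frame(beta = beta, se = se, stat = stat, p_raw = p, r2_snp = r2,
             flag = flag, stringsAsFactors = FALSE)
}

# Per-SNP logistic fit (IRLS via glm.fit) of y on dosage + covariates.
logistic_scan <- function(y, dosage, design) {
  m <- ncol(dosage)
  beta <- se <- stat <- p <- rep(NA_real_, m)
  flag <- rep(NA_character_, m)
  base <- cbind(`(Intercept)` = 1, design)
  for (j in seq_len(m)) {
    g <- dosage[, j]
    use <- !is.na(g)
    if (stats::var(g[use]) == 0) { flag[j] <- "monomorphic"; next }
    x <- cbind(dosage = g[use], base[use, , drop = FALSE])
    fit <- suppressWarnings(
      stats::glm.fit(x, y[use], family = stats::binomial()))
    eta <- fit$linear.predictors
    sep <- !fit$converged || max(abs(eta)) > 25
    if (sep) { flag[j] <- "separation"; next }
    # Wald from the IRLS working weights
    w <- fit$weights
    xtwx <- crossprod(x * sqrt(w))
    cov_b <- tryCatch(solve(xtwx), error = function(e) NULL)
    if (is.null(cov_b)) { flag[j] <- "separation"; next }
    beta[j] <- fit$coefficients["dosage"]
    se[j] <- sqrt(cov_b["dosage", "dosage"])
    stat[j] <- beta[j] / se[j]
    p[j] <- 2 * stats::pnorm(-abs(stat[j]))
  }
  data.frame(beta = beta, se = se, stat = stat, p_raw = p,
             r2_snp = NA_real_, flag = flag, stringsAsFactors = FALSE)
}

#' Genomic control
#'
#' Converts two-sided p-values to 1-df chi-squares, estimates the inflation
#' factor lambda as the median chi-square divided by 0.4549 (the median of a
#' central 1-df chi-square), and, when lambda exceeds 1, divides every
#' chi-square by lambda and recomputes the p-values. Applying the correction
#' twice equals applying it once.
#'
#' @param p vector of two-sided p-values (NA allowed for flagged SNPs).
#' @return list with `lambda`, `chi2` (corrected), `p` (corrected).
#' @export
genomic_control <- function(p) {
  if (all(is.na(p))) stop("genomic control needs at least one valid p-value",
                          call. = FALSE)
  chi2 <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chi2, na.rm = TRUE) / stats::qchisq(0.5, df = 1)
  if (lambda > 1) {
    chi2 <- chi2 / lambda
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  list(lambda = lambda, chi2 = chi2, p = p)
}

#' QQ-plot coordinates
#'
#' Expected versus observed -log10 p-value quantiles under the uniform null:
#' expected -log10((i - 0.5)/m) for rank i of m, both columns sorted
#' ascending.
#'
#' @param p p-values in (0, 1]; NAs dropped.
#' @return data.frame with columns `expected` and `observed`.
#' @export
qq_data <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) stop("no p-values supplied", call. = FALSE)
  m <- length(p)
  data.frame(expected = sort(-log10((seq_len(m) - 0.5) / m)),
             observed = sort(-log10(p)))
}

#' Allele-dosage association scan
#'
#' The central model fit: QC-filters the panel, computes ancestry principal
#' components, then tests every SNP for association with the phenotype under
#' an additive dosage model. Continuous phenotypes are first residualised on
#' the covariates (age, sex, BMI, top PCs) and each SNP is fit by simple
#' least squares of the residual on dosage (two-sided t-test). Binary
#' phenotypes are fit per SNP by logistic regression of outcome on dosage plus
#' the same covariates (Wald test). Genomic control is applied to the
#' resulting p-values when configured.
#'
#' @param phenotype a [phenotype_vector()]. Duplicated subject ids (the
#'   stacked-repeats representation) are allowed; dosage and covariate rows
#'   are duplicated accordingly.
#' @param panel a `snp_panel`.
#' @param covariates covariate table from [simulate_covariates()] (or any
#'   data.frame with `subject_id` and the configured covariate columns).
#' @param model `"linear"` or `"logistic"`; the default picks logistic for a
#'   binary taster phenotype and linear otherwise.
#' @param config a [gwas_config()].
#' @return object of class `gwas_scan`; see [summary.gwas_scan()]. The
#'   `results` component holds one row per QC-passing SNP with `beta`, `se`,
#'   `stat`, `chi2`, `p_raw`, `p_gc`, `r2_snp` and `flag`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_subjects = 60, n_null_snps = 30, seed = 2),
#'                        n_glms_sessions = 0)
#' ph <- make_threshold_representation(coh$thresholds, "log_then_average")
#' scan <- gwas(ph, coh$panel, coh$covariates, config = gwas_config(n_pcs = 2))
#' summary(scan)
#' @export
gwas <- function(phenotype, panel, covariates,
                 model = c("auto", "linear", "logistic"),
                 config = gwas_config()) {
  model <- match.arg(model)
  binary <- phenotype$representation == "binary_taster" ||
    all(phenotype$values %in% c(0, 1))
  if (model == "auto") model <- if (binary) "logistic" else "linear"
  if (model == "logistic" && length(unique(phenotype$values)) < 2)
    stop("logistic GWAS needs both outcome classes present", call. = FALSE)

  qc <- qc_filter_snps(panel, config)
  fpanel <- qc$panel
  if (length(fpanel$snp_id) == 0)
    stop("no SNPs passed QC", call. = FALSE)
  pcs <- NULL
  if (config$n_pcs > 0)
    pcs <- compute_ancestry_pcs(fpanel,
                                k = min(config$n_pcs,
                                        nrow(covariates) - 1L,
                                        length(fpanel$snp_id)))
  obs_idx <- match(phenotype$subject_id, covariates$subject_id)
  if (anyNA(obs_idx))
    stop("phenotype subjects missing from the covariate table", call. = FALSE)
  design <- build_design(covariates, pcs, config, obs_idx)
  dosage <- fpanel$dosage[obs_idx, , drop = FALSE]

  if (model == "linear") {
    resid <- residualize_phenotype(phenotype, design)
    res <- linear_scan(resid$values, dosage)
  } else {
    res <- logistic_scan(phenotype$values, dosage, design)
  }

  res$chi2 <- stats::qchisq(res$p_raw, df = 1, lower.tail = FALSE)
  lambda <- NA_real_
  res$p_gc <- res$p_raw
  if (config$apply_genomic_control && any(!is.na(res$p_raw))) {
    gc_out <- genomic_control(res$p_raw)
    lambda <- gc_out$lambda
    res$p_gc <- gc_out$p
    res$chi2 <- gc_out$chi2
  }
  results <- cbind(data.frame(snp_id = fpanel$snp_id, chrom = fpanel$chrom,
                              pos = fpanel$pos, stringsAsFactors = FALSE),
                   res)
  out <- list(results = results, model = model, lambda = lambda,
              n = length(unique(phenotype$subject_id)),
              n_obs = length(phenotype$values),
              representation = phenotype$representation,
              exclusions = qc$exclusions, pcs = pcs, config = config,
              panel_flags = list(is_causal = fpanel$is_causal,
                                 is_ld_partner = fpanel$is_ld_partner))
  class(out) <- "gwas_scan"
  out
}
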
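test_that("the Hardy-Weinberg chi-square test matches hand-computed cases", {
  expect_equal(hwe_test(c(25, 50, 25)), 1)                 # exact HWE
  expect_equal(hwe_test(c(50, 0, 50)),                     # chi2 = 100
               pchisq(100, 1, lower.tail = FALSE))
  expect_lt(hwe_test(c(50, 0, 50)), 1e-22)
  expect_equal(hwe_test(c(100, 0, 0)), 1)                  # monomorphic
  expect_error(hwe_test(c(0, 0, 0)), "total")
})

test_that("QC excludes SNPs by MAF, call rate and HWE with named reasons", {
  set.seed(12)
  n <- 200
  good <- replicate(5, rbinom(n, 2, 0.3))
  low_maf <- rbinom(n, 2, 0.04)
  low_call <- rbinom(n, 2, 0.3); low_call[sample(n, 21)] <- NA
  bad_hwe <- sample(rep(c(0L, 2L), each = n / 2))          # no heterozygotes
  panel <- make_panel(cbind(good, low_maf, low_call, bad_hwe))
  qc <- qc_filter_snps(panel, gwas_config())
  expect_equal(length(qc$panel$snp_id), 5L)
  expect_setequal(qc$exclusions$reason, c("maf", "call_rate", "hwe"))

  all_good <- make_panel(good)
  qc2 <- qc_filter_snps(all_good, gwas_config())
  expect_identical(qc2$panel$dosage, all_good$dosage)
  expect_equal(nrow(qc2$exclusions), 0L)
})

test_that("ancestry PCs are orthonormal and ignore monomorphic SNPs", {
  set.seed(14)
  dos <- cbind(replicate(40, rbinom(100, 2, runif(1, 0.2, 0.8))),
               rep(0L, 100))                               # monomorphic
  pcs <- compute_ancestry_pcs(make_panel(dos), 5)
  gram <- crossprod(pcs)
  expect_equal(unname(gram), diag(5), tolerance = 1e-8)
  expect_error(compute_ancestry_pcs(make_panel(dos), 150), "rank")
})

test_that("residualisation leaves residuals orthogonal to the design", {
  set.seed(16)
  n <- 150
  design <- cbind(age = runif(n, 18, 47), sex = rbinom(n, 1, 0.5))
  ph <- phenotype_vector(rnorm(n), sprintf("S%03d", 1:n), "log_then_average")
  res <- residualize_phenotype(ph, design)
  expect_lt(abs(sum(res$values * design[, "age"])), 1e-8)
  expect_lt(abs(sum(res$values)), 1e-8)
  # an already-orthogonal phenotype passes through unchanged
  res2 <- residualize_phenotype(res, design)
  expect_equal(res2$values, res$values, tolerance = 1e-10)
  # duplicated covariate columns are dropped with a warning, fit proceeds
  expect_warning(res3 <- residualize_phenotype(ph, cbind(design,
                                                         age2 = design[, 1])),
                 "collinear")
  expect_equal(res3$values, res$values)
  # binary phenotypes are refused
  bin <- phenotype_vector(rbinom(n, 1, 0.5), ph$subject_id, "binary_taster")
  expect_error(residualize_phenotype(bin, design), "logistic")
})

test_that("the linear scan recovers a perfect fit and flags monomorphic SNPs", {
  dos <- cbind(c(0, 0, 1, 1, 2, 2), rep(1, 6))
  res <- propbench:::linear_scan(c(0, 0, 1, 1, 2, 2), dos)
  expect_equal(res$beta[1], 1)
  expect_equal(res$r2_snp[1], 1)
  expect_equal(res$flag[2], "monomorphic")
  expect_true(is.na(res$p_raw[2]))
})

test_that("null p-values are uniform and lambda is near 1", {
  set.seed(18)
  n <- 150
  dos <- matrix(rbinom(n * 10000, 2, 0.4), n, 10000)
  y <- rnorm(n)
  res <- propbench:::linear_scan(y, dos)
  expect_equal(mean(res$p_raw < 0.05), 0.05, tolerance = 0.01 / 0.05)
  expect_gt(ks.test(res$p_raw, "punif")$p.value, 0.001)
  gc_out <- genomic_control(res$p_raw)
  expect_equal(gc_out$lambda, 1, tolerance = 0.05)
})

test_that("genomic control uses the median chi-square and is idempotent", {
  # all chi2 equal to twice the null median: lambda exactly 2
  chi2 <- rep(qchisq(0.5, 1) * 2, 50)
  p <- pchisq(chi2, 1, lower.tail = FALSE)
  gc1 <- genomic_control(p)
  expect_equal(gc1$lambda, 2)
  expect_equal(gc1$chi2, rep(qchisq(0.5, 1), 50))
  # a second application changes nothing
  gc2 <- genomic_control(gc1$p)
  expect_equal(gc2$lambda, 1)
  expect_equal(gc2$p, gc1$p)
  # deflation (lambda < 1) passes p through untouched
  small <- pchisq(rep(0.2, 20), 1, lower.tail = FALSE)
  expect_equal(genomic_control(small)$p, small)
})

test_that("QQ coordinates are the documented quantile pairs", {
  expect_equal(qq_data(0.5)$expected, -log10(0.5))
  qq <- qq_data(runif(500))
  expect_true(all(diff(qq$expected) >= 0))
  expect_true(all(diff(qq$observed) >= 0))
  spiked <- qq_data(c(runif(500), 1e-30))
  expect_gt(max(spiked$observed), max(spiked$expected))
})

test_that("logistic scan is calibrated under the null and flags separation", {
  set.seed(20)
  n <- 300
  dos <- matrix(rbinom(n * 400, 2, 0.4), n, 400)
  y <- rbinom(n, 1, 0.5)
  design <- cbind(age = runif(n, 18, 47))
  res <- propbench:::logistic_scan(y, dos, design)
  expect_gt(ks.test(res$p_raw, "punif")$p.value, 0.001)

  # a perfectly separating SNP is flagged, not reported
  g_sep <- ifelse(y == 1, 2L, 0L)
  res_sep <- propbench:::logistic_scan(y, cbind(g_sep), design)
  expect_equal(res_sep$flag[1], "separation")
  expect_true(is.na(res_sep$p_raw[1]))
})

test_that("the full scan finds the causal SNP and estimates its r2", {
  r2s <- vapply(1:8, function(s) {
    coh <- small_cohort(100 + s, n = 225, n_null = 1000)
    ph <- make_threshold_representation(coh$thresholds, "log_then_average")
    scan <- gwas(ph, coh$panel, coh$covariates)
    expect_lt(scan$results$p_gc[scan$panel_flags$is_causal], 5e-8)
    scan$results$r2_snp[scan$panel_flags$is_causal]
  }, numeric(1))
  # engine r2 at the causal SNP is the target minus the finite-sample
  # covariate-projection loss (13 regressors at n = 225)
  expect_equal(mean(r2s), 0.49, tolerance = 0.1)
  expect_error(gwas(phenotype_vector(rep(1, 10), sprintf("S%04d", 1:10),
                                     "binary_taster"),
                    NULL, NULL, model = "logistic"), "both outcome classes")
})
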
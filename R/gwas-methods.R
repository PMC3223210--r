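#' @export
print.gwas_scan <- function(x, ...) {
  valid <- !is.na(x$results$p_gc)
  cat(sprintf("Allele-dosage GWAS (%s model) on '%s'\n",
              x$model, x$representation))
  cat(sprintf("  %d subjects (%d observations), %d SNPs tested, %d excluded by QC\n",
              x$n, x$n_obs, nrow(x$results), nrow(x$exclusions)))
  if (!is.na(x$lambda))
    cat(sprintf("  genomic-control lambda = %.3f%s\n", x$lambda,
                if (x$lambda > 1) " (correction applied)" else ""))
  if (any(valid)) {
    top <- x$results[which.min(x$results$p_gc), ]
    cat(sprintf("  top SNP: %s (chr%s:%d)  p = %.3g  beta = %.3g\n",
                top$snp_id, top$chrom, top$pos, top$p_gc, top$beta))
  }
  invisible(x)
}

#' Summarise a GWAS scan
#'
#' @param object a `gwas_scan`.
#' @param alpha significance threshold (defaults to the scan's configured
#'   genome-wide level).
#' @param ... unused.
#' @return list with the top hits table (`hits`, all SNPs with corrected p
#'   below `alpha`, ordered by p), `lambda`, `n_significant` and `top`.
#' @export
summary.gwas_scan <- function(object, alpha = object$config$significance_alpha,
                              ...) {
  res <- object$results
  ok <- !is.na(res$p_gc)
  hits <- res[ok & res$p_gc < alpha, , drop = FALSE]
  hits <- hits[order(hits$p_gc), , drop = FALSE]
  out <- list(hits = hits, lambda = object$lambda,
              n_significant = nrow(hits),
              top = if (any(ok)) res[which.min(res$p_gc), ] else NULL,
              alpha = alpha, model = object$model,
              representation = object$representation)
  class(out) <- "summary.gwas_scan"
  out
}

#' @export
print.summary.gwas_scan <- function(x, ...) {
  cat(sprintf("GWAS summary (%s model, '%s'): %d SNP(s) with p < %g\n",
              x$model, x$representation, x$n_significant, x$alpha))
  if (!is.null(x$top))
    cat(sprintf("  minimum p = %.3g at %s\n", x$top$p_gc, x$top$snp_id))
  if (!is.na(x$lambda)) cat(sprintf("  lambda_GC = %.3f\n", x$lambda))
  if (x$n_significant > 0) {
    cat("\n")
    print(utils::head(x$hits[c("snp_id", "chrom", "pos", "beta", "p_raw", "p_gc",
                               "r2_snp")], 10), row.names = FALSE)
  }
  invisible(x)
}

#' Manhattan and QQ plots for a GWAS scan
#'
#' @param x a `gwas_scan`.
#' @param type `"manhattan"` or `"qq"`.
#' @param ... passed to the underlying plot call.
#' @return invisibly, the plotted coordinates.
#' @export
plot.gwas_scan <- function(x, type = c("manhattan", "qq"), ...) {
  type <- match.arg(type)
  res <- x$results[!is.na(x$results$p_gc), ]
  if (type == "qq") {
    qq <- qq_data(res$p_gc)
    graphics::plot(qq$expected, qq$observed,
                   xlab = expression(Expected ~ -log[10](p)),
                   ylab = expression(Observed ~ -log[10](p)), ...)
    graphics::abline(0, 1, lty = 2)
    return(invisible(qq))
  }
  chrom <- suppressWarnings(as.integer(res$chrom))
  chrom[is.na(chrom)] <- max(chrom, na.rm = TRUE) + 1L
  ord <- order(chrom, res$pos)
  res <- res[ord, ]
  xpos <- seq_len(nrow(res))
  graphics::plot(xpos, -log10(res$p_gc), col = 1 + chrom[ord] %% 2, pch = 20,
                 xlab = "SNP (genome order)", ylab = expression(-log[10](p)), ...)
  graphics::abline(h = -log10(x$config$significance_alpha), lty = 2)
  invisible(data.frame(x = xpos, neglog10p = -log10(res$p_gc)))
}

#' Residuals of the covariate-corrected phenotype
#'
#' For the linear model, `gwas()` tests the covariate-residualised phenotype;
#' this helper re-derives those residuals for a fitted scan's inputs.
#'
#' @param object a `gwas_scan`.
#' @param phenotype,covariates the phenotype vector and covariate table the
#'   scan was fitted to.
#' @param ... unused.
#' @return numeric residual vector.
#' @export
residuals.gwas_scan <- function(object, phenotype, covariates, ...) {
  if (object$model != "linear")
    stop("residuals are defined for the linear path only", call. = FALSE)
  obs_idx <- match(phenotype$subject_id, covariates$subject_id)
  design <- build_design(covariates, object$pcs, object$config, obs_idx)
  residualize_phenotype(phenotype, design)$values
}
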
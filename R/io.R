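#' Write a SNP panel as minimal VCF 4.2
#'
#' One sample column per subject, GT field only, missing dosage written as
#' `./.`. Dosage d is encoded as d copies of the ALT allele (0 -> `0/0`,
#' 1 -> `0/1`, 2 -> `1/1`).
#'
#' @param panel a `snp_panel`.
#' @param path output file.
#' @param sample_ids sample column names (default `S0001..`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path, sample_ids = NULL) {
  n <- nrow(panel$dosage)
  if (is.null(sample_ids))
    sample_ids <- rownames(panel$dosage)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n))
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_ids), collapse = "\t"))
  m <- length(panel$snp_id)
  body <- vapply(seq_len(m), function(j) {
    d <- panel$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    paste(c(panel$chrom[j], panel$pos[j], panel$snp_id[j], panel$ref[j],
            panel$alt[j], ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a minimal GT-only VCF back into a SNP panel
#'
#' Parses the dialect written by [write_vcf()] (VCF 4.2, GT field first,
#' diploid genotypes, `./.` for missing). Malformed records raise an error
#' naming the offending line.
#'
#' @param path VCF file.
#' @return a `snp_panel` (without causal/LD annotation or population
#'   frequencies, which are simulation-side truth).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop("VCF parse error: missing #CHROM header line",
                              call. = FALSE)
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L)
    stop("VCF parse error: header has no sample columns", call. = FALSE)
  samples <- cols[-(1:9)]
  body_idx <- seq((hdr + 1L), length(lines))
  body_idx <- body_idx[nzchar(lines[body_idx])]
  m <- length(body_idx)
  snp_id <- chrom <- ref <- alt <- character(m)
  pos <- integer(m)
  dosage <- matrix(NA_integer_, length(samples), m)
  for (i in seq_len(m)) {
    ln <- body_idx[i]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L + length(samples))
      stop("VCF parse error at line ", ln, ": expected ",
           9L + length(samples), " fields, found ", length(f), call. = FALSE)
    chrom[i] <- f[1]
    pos[i] <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos[i]))
      stop("VCF parse error at line ", ln, ": bad POS '", f[2], "'",
           call. = FALSE)
    snp_id[i] <- f[3]; ref[i] <- f[4]; alt[i] <- f[5]
    gt <- sub(":.*", "", f[-(1:9)])
    d <- rep(NA_integer_, length(gt))
    known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
               "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
    hit <- gt %in% c(names(known), "./.", ".|.")
    if (!all(hit))
      stop("VCF parse error at line ", ln, ": unrecognised genotype '",
           gt[!hit][1], "'", call. = FALSE)
    d[gt %in% names(known)] <- known[gt[gt %in% names(known)]]
    dosage[, i] <- d
  }
  rownames(dosage) <- samples
  panel <- list(snp_id = snp_id, chrom = chrom, pos = pos, ref = ref,
                alt = alt, dosage = dosage,
                is_causal = rep(FALSE, m), is_ld_partner = rep(FALSE, m),
                pop_freq = NULL)
  class(panel) <- "snp_panel"
  panel
}

#' Write association results in the semicolon dialect
#'
#' One SNP per row with exactly four semicolon-separated fields:
#' `snp_id;chromosome;position;p`, using the genomic-control-corrected p when
#' correction was applied. SNPs with a flag (monomorphic, separation) carry no
#' p-value and are omitted; the omission count is reported via a message.
#'
#' @param scan a `gwas_scan` (or its `results` data.frame).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results_semicolon <- function(scan, path) {
  res <- if (inherits(scan, "gwas_scan")) scan$results else scan
  if (nrow(res) == 0) stop("no results to write", call. = FALSE)
  keep <- !is.na(res$p_gc)
  if (any(!keep))
    message(sum(!keep), " flagged SNP(s) without p-value omitted")
  res <- res[keep, ]
  writeLines(sprintf("%s;%s;%d;%s", res$snp_id, res$chrom, res$pos,
                     formatC(res$p_gc, format = "e", digits = 5)), path)
  invisible(path)
}

#' Read the semicolon results dialect
#'
#' @param path file written by [write_results_semicolon()].
#' @return data.frame with `snp_id`, `chrom`, `pos`, `p`.
#' @export
read_results_semicolon <- function(path) {
  out <- utils::read.table(path, sep = ";", col.names = c("snp_id", "chrom",
                                                          "pos", "p"),
                           colClasses = c("character", "character", "integer",
                                          "numeric"))
  out
}

#' Write a phenotype vector as TSV
#'
#' Two-column tab-separated table keyed by subject id; the representation tag
#' is carried in the value column's header.
#'
#' @param pheno a [phenotype_vector()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phenotype_tsv <- function(pheno, path) {
  df <- data.frame(subject_id = pheno$subject_id, value = pheno$values)
  names(df)[2] <- pheno$representation
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype TSV written by [write_phenotype_tsv()]
#'
#' @param path input file.
#' @return a [phenotype_vector()] (representation from the header).
#' @export
read_phenotype_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  phenotype_vector(df[[2]], df[[1]], names(df)[2])
}

#' Run the full benchmark pipeline
#'
#' Simulates a cohort, builds the log-averaged threshold phenotype, runs the
#' GWAS, and writes genotypes (VCF), covariates, phenotype, the full
#' association table (TSV) and the semicolon p-value dialect to an output
#' directory. Every stage draws from the RNG state seeded by the cohort
#' config, so the same config yields byte-identical outputs.
#'
#' @param config a [cohort_config()] (its `seed` drives all randomness).
#' @param out_dir output directory, created if absent.
#' @param gwas_cfg a [gwas_config()].
#' @return invisibly, a list with the `taste_cohort`, the `gwas_scan`, and
#'   the written file paths.
#' @export
run_pipeline <- function(config = cohort_config(seed = 1),
                         out_dir = tempfile("propbench_run_"),
                         gwas_cfg = gwas_config()) {
  config <- validate_cohort_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cohort <- simulate_cohort(config)
  ph <- make_threshold_representation(cohort$thresholds, "log_then_average")
  scan <- gwas(ph, cohort$panel, cohort$covariates, config = gwas_cfg)

  paths <- list(
    vcf = file.path(out_dir, "genotypes.vcf"),
    covariates = file.path(out_dir, "covariates.tsv"),
    phenotype = file.path(out_dir, "phenotype.tsv"),
    results = file.path(out_dir, "association.tsv"),
    results_semicolon = file.path(out_dir, "association_semicolon.csv"),
    config = file.path(out_dir, "config.json"))
  write_vcf(cohort$panel, paths$vcf,
            sample_ids = cohort$covariates$subject_id)
  cov_out <- cohort$covariates
  cov_out$admixture <- NULL
  utils::write.table(cov_out, paths$covariates, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_phenotype_tsv(ph, paths$phenotype)
  utils::write.table(scan$results, paths$results, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  suppressMessages(write_results_semicolon(scan, paths$results_semicolon))
  cfg_json <- config
  cfg_json$class_means_mM <- as.list(cfg_json$class_means_mM)
  jsonlite::write_json(unclass(cfg_json), paths$config, auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(list(cohort = cohort, scan = scan, paths = paths))
}
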
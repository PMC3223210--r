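#' Phenotype vectors
#'
#' A phenotype vector pairs per-observation values with subject ids and a tag
#' naming the representation. All representations map one observation to one
#' subject except `stacked_repeats`, which deliberately duplicates each
#' subject (both log-transformed threshold repeats entered as if independent).
#'
#' @param values numeric observations.
#' @param subject_id subject id per observation.
#' @param representation representation tag.
#' @param cutoff_mM taster cutoff (binary representation only).
#' @return object of class `phenotype_vector`.
#' @export
phenotype_vector <- function(values, subject_id, representation,
                             cutoff_mM = NULL) {
  stopifnot(length(values) == length(subject_id))
  out <- list(values = as.numeric(values), subject_id = as.character(subject_id),
              representation = representation, cutoff_mM = cutoff_mM)
  class(out) <- "phenotype_vector"
  out
}

#' @export
print.phenotype_vector <- function(x, ...) {
  cat(sprintf("Phenotype vector [%s]: %d observations, %d subjects\n",
              x$representation, length(x$values), length(unique(x$subject_id))))
  invisible(x)
}

#' Build a threshold phenotype representation
#'
#' Converts per-subject repeated threshold measurements (mM) into one of the
#' representations compared in the benchmark:
#' \describe{
#'   \item{log_then_average}{mean of the log10-transformed repeats (the
#'     reference representation).}
#'   \item{average_raw}{mean of the untransformed thresholds.}
#'   \item{log_of_average}{log10 of the raw mean.}
#'   \item{stacked_repeats}{each log10 repeat entered as its own observation,
#'     subjects duplicated.}
#'   \item{binary_taster}{1 if the geometric mean threshold is strictly below
#'     `cutoff_mM` (more sensitive = taster), else 0; ties at the cutoff are
#'     non-tasters.}
#' }
#'
#' @param thresholds subjects x repeats matrix of thresholds (mM); rows with
#'   any NA (e.g. non-converged staircases) are dropped.
#' @param kind representation name (see above).
#' @param subject_id subject ids (default rownames of `thresholds`).
#' @param cutoff_mM taster cutoff, required for `binary_taster` (default 0.2).
#' @return a [phenotype_vector()].
#' @examples
#' th <- matrix(c(0.1, 1), 1, 2, dimnames = list("S1", NULL))
#' make_threshold_representation(th, "log_then_average")$values  # -0.5
#' @export
make_threshold_representation <- function(thresholds,
                                          kind = c("log_then_average",
                                                   "average_raw",
                                                   "log_of_average",
                                                   "stacked_repeats",
                                                   "binary_taster"),
                                          subject_id = rownames(thresholds),
                                          cutoff_mM = 0.2) {
  kind <- match.arg(kind)
  thresholds <- as.matrix(thresholds)
  if (is.null(subject_id)) subject_id <- sprintf("S%04d", seq_len(nrow(thresholds)))
  keep <- stats::complete.cases(thresholds)
  thresholds <- thresholds[keep, , drop = FALSE]
  subject_id <- subject_id[keep]
  if (any(thresholds <= 0))
    stop("thresholds must be strictly positive concentrations", call. = FALSE)
  if (ncol(thresholds) < 2 &&
      kind %in% c("log_then_average", "average_raw", "log_of_average",
                  "stacked_repeats"))
    warning("representation '", kind, "' built from a single repeat")
  lg <- log10(thresholds)
  switch(kind,
    log_then_average = phenotype_vector(rowMeans(lg), subject_id, kind),
    average_raw = phenotype_vector(rowMeans(thresholds), subject_id, kind),
    log_of_average = phenotype_vector(log10(rowMeans(thresholds)), subject_id, kind),
    stacked_repeats = phenotype_vector(as.vector(lg),
                                       rep(subject_id, times = ncol(lg)),
                                       kind),
    binary_taster = phenotype_vector(
      as.numeric(10^rowMeans(lg) < cutoff_mM), subject_id, kind,
      cutoff_mM = cutoff_mM)
  )
}

#' Per-concentration mean gLMS ratings
#'
#' Averages each subject's intensity ratings across repeated gLMS sessions,
#' separately for every tested sample (water included), without any transform
#' (the gLMS scale is already quasi-logarithmic).
#'
#' @param sessions list of subjects x samples rating matrices with identical
#'   dimnames (one element per session).
#' @return named list of [phenotype_vector()]s, one per sample column.
#' @export
glms_mean_ratings <- function(sessions) {
  if (length(sessions) < 1) stop("no gLMS sessions supplied", call. = FALSE)
  dn <- dimnames(sessions[[1]])
  for (s in sessions)
    if (!identical(dimnames(s), dn))
      stop("gLMS sessions disagree in subjects or concentrations", call. = FALSE)
  if (anyNA(sessions[[1]]) || any(vapply(sessions, anyNA, logical(1)))) {
    bad <- unique(unlist(lapply(sessions, function(s) dn[[1]][apply(is.na(s), 1, any)])))
    stop("missing gLMS ratings for subject(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  avg <- Reduce(`+`, sessions) / length(sessions)
  out <- lapply(colnames(avg), function(cc)
    phenotype_vector(avg[, cc], rownames(avg), paste0("glms_mean(", cc, ")")))
  names(out) <- colnames(avg)
  out
}

#' Area-under-the-curve gLMS phenotype
#'
#' Sums each subject's six per-concentration mean ratings (five concentrations
#' plus water) into a single area-under-the-intensity-curve phenotype.
#'
#' @param per_conc_means list of 6 [phenotype_vector()]s from
#'   [glms_mean_ratings()].
#' @return a [phenotype_vector()] tagged `glms_auc`.
#' @export
auc_phenotype <- function(per_conc_means) {
  if (length(per_conc_means) != 6L)
    stop("AUC phenotype needs exactly 6 per-concentration means (water + 5)",
         call. = FALSE)
  ids <- per_conc_means[[1]]$subject_id
  vals <- rowSums(vapply(per_conc_means, function(p) {
    if (!identical(p$subject_id, ids))
      stop("per-concentration vectors disagree in subjects", call. = FALSE)
    p$values
  }, numeric(length(ids))))
  phenotype_vector(vals, ids, "glms_auc")
}

#' Test-retest variability of threshold measurements
#'
#' Computes the per-subject absolute log10 difference between the two repeat
#' thresholds, d = |log10 t1 - log10 t2|, its mean, and the fraction of
#' subjects exceeding any cutoff.
#'
#' @param thresholds subjects x 2 matrix of repeat thresholds (mM); incomplete
#'   rows dropped.
#' @return object of class `variability_stats`: list with `d_values`,
#'   `d_mean`, `n`, and function `frac_exceeding(x)`.
#' @export
variability_stats <- function(thresholds) {
  thresholds <- as.matrix(thresholds)
  if (ncol(thresholds) < 2)
    stop("variability needs two repeat measurements per subject", call. = FALSE)
  thresholds <- thresholds[stats::complete.cases(thresholds), 1:2, drop = FALSE]
  if (any(thresholds <= 0)) stop("thresholds must be positive", call. = FALSE)
  d <- abs(log10(thresholds[, 1]) - log10(thresholds[, 2]))
  out <- list(d_values = d, d_mean = mean(d), n = length(d),
              frac_exceeding = function(x) mean(d > x))
  class(out) <- "variability_stats"
  out
}

#' @export
print.variability_stats <- function(x, ...) {
  cat(sprintf("Test-retest variability (n = %d): mean |d| = %.3f log10 units, %.1f%% > 0.62\n",
              x$n, x$d_mean, 100 * x$frac_exceeding(0.62)))
  invisible(x)
}

#' Share of phenotype variance due to measurement error
#'
#' Estimates the per-measurement error variance on the log10 scale as
#' Var(l1 - l2)/2 from duplicate measurements, then reports the share of the
#' log-averaged phenotype's variance attributable to measurement error
#' (error variance halved again, because averaging two repeats halves it).
#'
#' @param thresholds subjects x 2 matrix of repeat thresholds (mM).
#' @return list with `error_variance` (per single measurement),
#'   `phenotype_variance` (of the log-averaged phenotype) and `share`.
#' @export
measurement_error_share <- function(thresholds) {
  thresholds <- as.matrix(thresholds)
  thresholds <- thresholds[stats::complete.cases(thresholds), 1:2, drop = FALSE]
  if (nrow(thresholds) < 2)
    stop("need at least two subjects with duplicate measurements", call. = FALSE)
  if (any(thresholds <= 0)) stop("thresholds must be positive", call. = FALSE)
  l1 <- log10(thresholds[, 1]); l2 <- log10(thresholds[, 2])
  err_var <- stats::var(l1 - l2) / 2
  pheno_var <- stats::var((l1 + l2) / 2)
  if (pheno_var == 0)
    stop("phenotype variance is zero; error share undefined", call. = FALSE)
  list(error_variance = err_var, phenotype_variance = pheno_var,
       share = (err_var / 2) / pheno_var)
}
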
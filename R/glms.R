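#' Simulate one gLMS intensity-rating session
#'
#' Each subject rates five bitterant concentrations plus a water control on the
#' 0-100 generalized labeled magnitude scale, presented in a random order. The
#' response model is a hinge on the log-concentration axis: ratings sit at the
#' subject's baseline (their rating of water) until the concentration exceeds
#' that day's threshold, then rise with decades above threshold as
#' `slope * (log10 c - theta_day)^exponent`; trial noise is Gaussian and
#' ratings are clipped to the scale. Water contributes no concentration term.
#' The default exponent 1.5 makes the response mildly convex: barely
#' supra-threshold samples are rated barely above water (matching how
#' insensitive subjects rate near-threshold bitterant like water), while a
#' sample exactly one decade above threshold scores `baseline + slope`
#' whatever the exponent; `exponent = 1` recovers the linear hinge.
#'
#' @param profiles latent profiles (need `theta_log10`, `glms_baseline`,
#'   `glms_slope`, `glms_noise_sd`).
#' @param concentrations tested concentrations in mM (water is always added).
#' @param day_offset per-subject day offset for this session (log10 units);
#'   default 0.
#' @param exponent exponent of the supra-threshold response.
#' @return list with `ratings` (subjects x 6 matrix, columns `water` then the
#'   concentrations) and `order` (subjects x 6 presentation permutation).
#' @export
simulate_glms_session <- function(profiles,
                                  concentrations = c(0.032, 0.1, 0.32, 1, 3.2),
                                  day_offset = 0, exponent = 1.5) {
  n <- nrow(profiles)
  conc <- sort(concentrations)
  theta_day <- profiles$theta_log10 + day_offset
  m <- length(conc) + 1L
  ratings <- matrix(NA_real_, n, m,
                    dimnames = list(profiles$subject_id,
                                    c("water", format(conc, trim = TRUE))))
  ratings[, 1L] <- profiles$glms_baseline
  for (j in seq_along(conc)) {
    above <- pmax(0, log10(conc[j]) - theta_day)
    ratings[, j + 1L] <- profiles$glms_baseline +
      profiles$glms_slope * above^exponent
  }
  ratings <- ratings + matrix(stats::rnorm(n * m, 0, profiles$glms_noise_sd),
                              n, m)
  ratings[ratings < 0] <- 0
  ratings[ratings > 100] <- 100
  ord <- t(vapply(seq_len(n), function(i) sample.int(m), integer(m)))
  list(ratings = ratings, order = ord)
}

#' Simulate repeated gLMS sessions for a cohort
#'
#' Draws a fresh day offset per subject and session (sd `sigma_day` from the
#' cohort config) and runs [simulate_glms_session()] for each.
#'
#' @param profiles latent profiles.
#' @param n_sessions number of sessions (default 3).
#' @param config a [cohort_config()] (supplies `sigma_day`).
#' @param concentrations tested concentrations in mM.
#' @return list with `ratings` (list of subjects x 6 matrices, one per
#'   session) and `concentrations` (numeric, NA for water, matching columns).
#' @export
simulate_glms_sessions <- function(profiles, n_sessions = 3,
                                   config = cohort_config(),
                                   concentrations = c(0.032, 0.1, 0.32, 1, 3.2)) {
  if (n_sessions < 1) stop("n_sessions must be >= 1", call. = FALSE)
  n <- nrow(profiles)
  sessions <- vector("list", n_sessions)
  exponent <- if (is.null(config$glms_exponent)) 1.5 else config$glms_exponent
  for (s in seq_len(n_sessions)) {
    off <- stats::rnorm(n, 0, config$sigma_day)
    sessions[[s]] <- simulate_glms_session(profiles, concentrations, off,
                                           exponent = exponent)$ratings
  }
  list(ratings = sessions,
       concentrations = c(NA_real_, sort(concentrations)))
}
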
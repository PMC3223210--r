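#' Build the staircase concentration ladder
#'
#' A geometric dilution series from `top` down to `bottom` in steps of `step`
#' log10 units (the default 1/6-log10 step is a 1.468-fold dilution). The span
#' must be an integer number of steps.
#'
#' @param top highest concentration (mM).
#' @param bottom lowest concentration (mM).
#' @param step rung spacing in log10 units.
#' @return object of class `ladder`: list with `conc` (descending mM),
#'   `log10_conc`, `step`, `n_rungs`.
#' @examples
#' lad <- build_ladder()
#' lad$n_rungs                      # 25
#' lad$conc[1] / lad$conc[2]        # 1.468
#' @export
build_ladder <- function(top = 3.2, bottom = 0.00032, step = 1 / 6) {
  if (!(top > bottom && bottom > 0)) stop("need top > bottom > 0", call. = FALSE)
  span <- log10(top / bottom) / step
  if (abs(span - round(span)) > 1e-9)
    stop("ladder mismatch: log10(top/bottom) is not an integer multiple of step",
         call. = FALSE)
  n <- as.integer(round(span)) + 1L
  logc <- log10(top) - (seq_len(n) - 1) * step
  out <- list(conc = 10^logc, log10_conc = logc, step = step, n_rungs = n)
  class(out) <- "ladder"
  out
}

#' @export
print.ladder <- function(x, ...) {
  cat(sprintf("Concentration ladder: %d rungs, %.2f mM down to %.3g mM (%.3f-fold steps)\n",
              x$n_rungs, x$conc[1], x$conc[x$n_rungs], 10^x$step))
  invisible(x)
}

#' Configuration of the adaptive staircase protocol
#'
#' Transformed up-down threshold procedure: the concentration moves down one
#' rung after `n_down` consecutive detections and up one rung after any miss;
#' the run stops after `n_reversals` direction changes and the threshold
#' estimate averages the last `n_last_reversals` reversal concentrations
#' (geometric mean by default, since the ladder is logarithmic). The starting
#' rung is chosen by a noiseless pre-test of the true threshold against
#' `pretest_cutoff` (taster start low, non-taster start high).
#'
#' @param n_down consecutive detections required to step down (default 4).
#' @param n_up misses required to step up (fixed at 1 in this protocol).
#' @param n_reversals reversals at which the run stops (default 5).
#' @param n_last_reversals reversals averaged into the estimate (default 4).
#' @param start_taster,start_nontaster starting concentrations (mM); must lie
#'   on the ladder.
#' @param pretest_cutoff taster/non-taster pre-test cutoff (mM).
#' @param max_trials trial budget before the run is declared non-converged.
#' @param estimate_mean `"geometric"` (mean of log10 reversal concentrations)
#'   or `"arithmetic"` (mean of raw concentrations).
#' @param psychometric `"step"` (deterministic: detect iff concentration at or
#'   above the day threshold) or `"probit"` (graded detection probability
#'   `guess_rate + (1-guess_rate) * pnorm((log10(c) - theta)/sigma_p)`).
#' @param sigma_p probit psychometric slope, log10 units (> 0).
#' @param guess_rate probit lower asymptote.
#' @return object of class `staircase_config`.
#' @export
staircase_config <- function(n_down = 4, n_up = 1,
                             n_reversals = 5, n_last_reversals = 4,
                             start_taster = 0.047, start_nontaster = 0.689,
                             pretest_cutoff = 0.2,
                             max_trials = 60,
                             estimate_mean = c("geometric", "arithmetic"),
                             psychometric = c("step", "probit"),
                             sigma_p = 0.15, guess_rate = 0) {
  psychometric <- match.arg(psychometric)
  if (psychometric == "probit" && sigma_p <= 0)
    stop("invalid staircase config: sigma_p must be > 0 for the probit model",
         call. = FALSE)
  if (n_last_reversals > n_reversals)
    stop("invalid staircase config: n_last_reversals exceeds n_reversals",
         call. = FALSE)
  out <- list(n_down = n_down, n_up = n_up, n_reversals = n_reversals,
              n_last_reversals = n_last_reversals,
              start_taster = start_taster, start_nontaster = start_nontaster,
              pretest_cutoff = pretest_cutoff, max_trials = max_trials,
              estimate_mean = match.arg(estimate_mean),
              psychometric = psychometric, sigma_p = sigma_p,
              guess_rate = guess_rate)
  class(out) <- "staircase_config"
  out
}

#' Single detection trial
#'
#' @param c_mM presented concentration (mM, > 0).
#' @param theta_day the subject's threshold in force that day (log10 mM).
#' @param config a [staircase_config()] giving the psychometric model.
#' @return logical: was the sample distinguished from water?
#' @export
detect_trial <- function(c_mM, theta_day, config = staircase_config()) {
  if (any(c_mM <= 0)) stop("concentration must be positive", call. = FALSE)
  lc <- log10(c_mM)
  if (config$psychometric == "step") {
    lc >= theta_day
  } else {
    p <- config$guess_rate +
      (1 - config$guess_rate) * stats::pnorm((lc - theta_day) / config$sigma_p)
    stats::runif(length(lc)) < p
  }
}

# Printed protocol concentrations are rounded rung values (0.047 for
# 0.046970, 0.689 for 0.689419), so snap within 0.005 log10 units.
ladder_rung <- function(ladder, conc) {
  k <- which.min(abs(ladder$log10_conc - log10(conc)))
  if (abs(ladder$log10_conc[k] - log10(conc)) > 0.005)
    stop("start concentration ", conc, " mM does not lie on the ladder",
         call. = FALSE)
  k
}

#' Run one adaptive staircase session
#'
#' Simulates the transformed up-down procedure on the ladder for one subject
#' and one session. Direction changes are logged as reversals at the
#' concentration where the trajectory turned; moves clamped at the ladder ends
#' count as neither moves nor reversals. With the deterministic step
#' psychometric the trajectory converges to oscillating between the two rungs
#' straddling the day threshold, so the geometric-mean estimate is their
#' log-midpoint (absolute log10 error at most half a rung).
#'
#' @param theta_day threshold in force this session (log10 mM).
#' @param ladder a [build_ladder()].
#' @param config a [staircase_config()].
#' @param theta_true true (session-free) threshold used for the pre-test;
#'   defaults to `theta_day`.
#' @return object of class `staircase_run`: list with `trials` (data.frame of
#'   concentration and response), `reversals` (concentrations, mM),
#'   `threshold_estimate` (mM, NA if not converged), `converged`.
#' @examples
#' run <- run_staircase(log10(0.08), build_ladder())
#' run$threshold_estimate
#' @export
run_staircase <- function(theta_day, ladder = build_ladder(),
                          config = staircase_config(),
                          theta_true = theta_day) {
  start <- if (theta_true < log10(config$pretest_cutoff))
    config$start_taster else config$start_nontaster
  k <- ladder_rung(ladder, start)
  logc <- ladder$log10_conc
  n_rungs <- ladder$n_rungs
  step_model <- config$psychometric == "step"

  trial_conc <- numeric(config$max_trials)
  trial_resp <- logical(config$max_trials)
  reversals <- numeric(config$n_reversals)
  n_rev <- 0L
  n_det <- 0L
  last_dir <- 0L       # -1 up, +1 down, 0 before first actual move
  t <- 0L
  while (t < config$max_trials && n_rev < config$n_reversals) {
    t <- t + 1L
    detected <- if (step_model) logc[k] >= theta_day else
      stats::runif(1) < config$guess_rate +
        (1 - config$guess_rate) * stats::pnorm((logc[k] - theta_day) / config$sigma_p)
    trial_conc[t] <- ladder$conc[k]
    trial_resp[t] <- detected
    if (detected) {
      n_det <- n_det + 1L
      if (n_det == config$n_down) {           # step down (toward lower conc)
        n_det <- 0L
        if (k < n_rungs) {
          if (last_dir == -1L) { n_rev <- n_rev + 1L; reversals[n_rev] <- ladder$conc[k] }
          last_dir <- 1L
          k <- k + 1L
        }                                      # clamped at bottom: no move, no reversal
      }
    } else {
      n_det <- 0L
      if (k > 1L) {                            # step up (toward higher conc)
        if (last_dir == 1L) { n_rev <- n_rev + 1L; reversals[n_rev] <- ladder$conc[k] }
        last_dir <- -1L
        k <- k - 1L
      }                                        # clamped at top: pinned
    }
  }
  converged <- n_rev == config$n_reversals
  estimate <- NA_real_
  if (converged) {
    last <- reversals[(n_rev - config$n_last_reversals + 1L):n_rev]
    estimate <- if (config$estimate_mean == "geometric")
      10^mean(log10(last)) else mean(last)
  }
  pinned <- if (converged) NA_character_
    else if (k == 1L) "top" else if (k == n_rungs) "bottom" else NA_character_
  out <- list(trials = data.frame(concentration_mM = trial_conc[seq_len(t)],
                                  detected = trial_resp[seq_len(t)]),
              reversals = reversals[seq_len(n_rev)],
              threshold_estimate = estimate,
              converged = converged,
              pinned = pinned)
  class(out) <- "staircase_run"
  out
}

#' @export
print.staircase_run <- function(x, ...) {
  cat(sprintf("Staircase run: %d trials, %d reversals, %s\n",
              nrow(x$trials), length(x$reversals),
              if (x$converged)
                sprintf("threshold estimate %.4g mM", x$threshold_estimate)
              else "did not converge"))
  invisible(x)
}

#' Measure staircase thresholds for a whole cohort
#'
#' Runs one staircase per subject per session using the day-specific threshold
#' `theta_log10 + day_offsets[, j]`. A lean internal loop equivalent to
#' [run_staircase()] (same protocol, reversal and clamping rules) is used for
#' the deterministic step psychometric so large cohorts stay fast.
#'
#' Runs pinned at a ladder end (a day threshold outside the tested range)
#' never reach the reversal criterion; as in laboratory practice, where every
#' panelist receives a threshold and out-of-range subjects are recorded at the
#' boundary concentration, such runs are censored at the nearest ladder end by
#' default (`censor = "bounds"`). `censor = "drop"` leaves them as NA instead.
#' Runs that merely exhaust the trial budget mid-ladder are always NA.
#'
#' @param profiles latent profiles with `day_offsets` (see
#'   [sample_day_effects()]).
#' @param ladder a [build_ladder()].
#' @param config a [staircase_config()].
#' @param censor `"bounds"` (default) or `"drop"`; see above.
#' @return list of two subjects x sessions matrices: `estimate` (mM, NA where
#'   unmeasurable) and `converged` (FALSE for censored or dropped runs).
#' @export
measure_thresholds <- function(profiles, ladder = build_ladder(),
                               config = staircase_config(),
                               censor = c("bounds", "drop")) {
  censor <- match.arg(censor)
  off <- profiles$day_offsets
  if (is.null(off)) stop("profiles carry no day_offsets; call sample_day_effects()",
                         call. = FALSE)
  n <- nrow(profiles)
  s <- ncol(off)
  est <- matrix(NA_real_, n, s)
  conv <- matrix(FALSE, n, s)
  k_taster <- ladder_rung(ladder, config$start_taster)
  k_nontaster <- ladder_rung(ladder, config$start_nontaster)
  cut_log <- log10(config$pretest_cutoff)
  for (i in seq_len(n)) {
    k0 <- if (profiles$theta_log10[i] < cut_log) k_taster else k_nontaster
    for (j in seq_len(s)) {
      e <- staircase_core(profiles$theta_log10[i] + off[i, j], k0, ladder, config)
      conv[i, j] <- e[2] == 0
      est[i, j] <- if (e[2] == 0) e[1]
        else if (censor == "bounds" && e[2] == 1) ladder$conc[1]
        else if (censor == "bounds" && e[2] == 2) ladder$conc[ladder$n_rungs]
        else NA_real_
    }
  }
  rownames(est) <- rownames(conv) <- profiles$subject_id
  list(estimate = est, converged = conv)
}

# Lean staircase identical in protocol to run_staircase but without trial
# logging. Returns c(estimate_mM, status): status 0 = converged,
# 1 = pinned at top, 2 = pinned at bottom, 3 = trial budget exhausted.
staircase_core <- function(theta_day, k, ladder, config) {
  logc <- ladder$log10_conc
  n_rungs <- ladder$n_rungs
  step_model <- config$psychometric == "step"
  n_down <- config$n_down
  max_trials <- config$max_trials
  need_rev <- config$n_reversals
  reversals <- numeric(need_rev)
  n_rev <- 0L; n_det <- 0L; last_dir <- 0L; t <- 0L
  while (t < max_trials && n_rev < need_rev) {
    t <- t + 1L
    detected <- if (step_model) logc[k] >= theta_day else
      stats::runif(1) < config$guess_rate +
        (1 - config$guess_rate) * stats::pnorm((logc[k] - theta_day) / config$sigma_p)
    if (detected) {
      n_det <- n_det + 1L
      if (n_det == n_down) {
        n_det <- 0L
        if (k < n_rungs) {
          if (last_dir == -1L) { n_rev <- n_rev + 1L; reversals[n_rev] <- logc[k] }
          last_dir <- 1L; k <- k + 1L
        }
      }
    } else {
      n_det <- 0L
      if (k > 1L) {
        if (last_dir == 1L) { n_rev <- n_rev + 1L; reversals[n_rev] <- logc[k] }
        last_dir <- -1L; k <- k - 1L
      }
    }
  }
  if (n_rev < need_rev) {
    status <- if (k == 1L) 1 else if (k == n_rungs) 2 else 3
    return(c(NA_real_, status))
  }
  last <- reversals[(n_rev - config$n_last_reversals + 1L):n_rev]
  est <- if (config$estimate_mean == "geometric") 10^mean(last) else mean(10^last)
  c(est, 0)
}
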
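#' Analytic power to detect a variance-explaining SNP
#'
#' Standard power approximation for a quantitative-trait association test at
#' significance level alpha: with a SNP explaining a fraction r2 of phenotypic
#' variance in s subjects, the test statistic is approximately normal with
#' noncentrality sqrt(s * r2 / (1 - r2)), giving
#' `power = Phi(sqrt(s * r2 / (1 - r2)) - z_crit)` where z_crit is the
#' (1 - alpha/2) normal quantile for the default two-sided convention (or
#' 1 - alpha one-sided).
#'
#' @param s subject count (>= 1).
#' @param r2 fraction of phenotypic variance explained by the SNP, in [0, 1].
#' @param alpha significance threshold (default genome-wide 5e-8).
#' @param z_convention `"two_sided"` (default) or `"one_sided"`.
#' @return detection probability in [0, 1].
#' @examples
#' gwas_power(s = 225, r2 = 0.12)        # ~0.53
#' @export
gwas_power <- function(s, r2, alpha = 5e-8,
                       z_convention = c("two_sided", "one_sided")) {
  z_convention <- match.arg(z_convention)
  if (any(s < 1)) stop("s must be >= 1", call. = FALSE)
  if (any(r2 < 0 | r2 > 1)) stop("r2 must lie in [0, 1]", call. = FALSE)
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (any(r2 == 1)) warning("r2 = 1 gives infinite noncentrality; power = 1")
  z_crit <- if (z_convention == "two_sided")
    stats::qnorm(1 - alpha / 2) else stats::qnorm(1 - alpha)
  ncp <- sqrt(s * r2 / (1 - r2))
  pw <- stats::pnorm(ncp - z_crit)
  pw[r2 == 1] <- 1
  pmin(pmax(pw, 0), 1)
}

#' Smallest panel achieving a target power
#'
#' Solves `gwas_power(s) >= target_power` for the smallest integer s, using
#' the closed-form real solution
#' `s = (1 - r2)/r2 * (z_crit + qnorm(target_power))^2` as a seed and then
#' stepping to the exact integer crossing.
#'
#' @inheritParams gwas_power
#' @param target_power required detection probability, in (0, 1).
#' @return integer subject count.
#' @examples
#' min_subjects(r2 = 0.49, target_power = 0.9)   # 48
#' @export
min_subjects <- function(r2, alpha = 5e-8, target_power = 0.9,
                         z_convention = c("two_sided", "one_sided")) {
  z_convention <- match.arg(z_convention)
  if (target_power <= 0 || target_power >= 1)
    stop("target_power must lie in (0, 1)", call. = FALSE)
  if (r2 <= 0)
    stop("r2 = 0: the target power is unattainable at any panel size",
         call. = FALSE)
  z_crit <- if (z_convention == "two_sided")
    stats::qnorm(1 - alpha / 2) else stats::qnorm(1 - alpha)
  s0 <- (1 - r2) / r2 * (z_crit + stats::qnorm(target_power))^2
  s <- max(1L, as.integer(floor(s0)))
  while (gwas_power(s, r2, alpha, z_convention) < target_power) s <- s + 1L
  while (s > 1L && gwas_power(s - 1L, r2, alpha, z_convention) >= target_power)
    s <- s - 1L
  s
}

#' Smallest detectable variance fraction
#'
#' The smallest r2 a panel of s subjects detects with at least the target
#' power, solved by bisection to 1e-6.
#'
#' @inheritParams min_subjects
#' @param s subject count.
#' @return fraction of phenotypic variance.
#' @examples
#' min_r2(s = 225, target_power = 0.5)    # ~0.117
#' @export
min_r2 <- function(s, alpha = 5e-8, target_power = 0.5,
                   z_convention = c("two_sided", "one_sided")) {
  z_convention <- match.arg(z_convention)
  if (target_power <= 0 || target_power >= 1)
    stop("target_power must lie in (0, 1)", call. = FALSE)
  lo <- 0; hi <- 1 - 1e-12
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (gwas_power(s, mid, alpha, z_convention) >= target_power) hi <- mid
    else lo <- mid
  }
  hi
}

#' Power-to-detect curve table
#'
#' Evaluates the analytic power over a grid of panel sizes for each variance
#' fraction, reproducing the benchmark's family of power curves (49% and 38%
#' for the two phenotyping instruments, plus weaker hypothetical effects).
#'
#' @param r2_values variance fractions (one curve each).
#' @param s_values panel sizes.
#' @inheritParams gwas_power
#' @return data.frame with columns `r2`, `s`, `power`.
#' @export
power_curve <- function(r2_values = c(0.49, 0.38, 0.30, 0.20, 0.15, 0.05,
                                      0.02, 0.01),
                        s_values = seq(10, 500, by = 5),
                        alpha = 5e-8,
                        z_convention = c("two_sided", "one_sided")) {
  z_convention <- match.arg(z_convention)
  grid <- expand.grid(s = s_values, r2 = r2_values)[, c("r2", "s")]
  grid$power <- gwas_power(grid$s, grid$r2, alpha, z_convention)
  grid
}
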
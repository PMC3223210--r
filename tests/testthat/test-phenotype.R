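two_rep <- function(t1, t2, ids = NULL) {
  m <- cbind(t1, t2)
  rownames(m) <- if (is.null(ids)) sprintf("S%03d", seq_len(nrow(m))) else ids
  m
}

test_that("threshold representations compute the documented transforms", {
  th <- two_rep(0.1, 1.0)
  expect_equal(make_threshold_representation(th, "log_then_average")$values, -0.5)
  expect_equal(make_threshold_representation(th, "average_raw")$values, 0.55)
  expect_equal(make_threshold_representation(th, "log_of_average")$values,
               log10(0.55))
  # geometric mean 0.316 mM is not below the 0.2 mM cutoff: non-taster
  expect_equal(make_threshold_representation(th, "binary_taster",
                                             cutoff_mM = 0.2)$values, 0)
  # a clearly sensitive subject classifies as taster
  expect_equal(make_threshold_representation(two_rep(0.02, 0.05),
                                             "binary_taster",
                                             cutoff_mM = 0.2)$values, 1)
  # tie at the cutoff is non-taster
  expect_equal(make_threshold_representation(two_rep(0.2, 0.2),
                                             "binary_taster",
                                             cutoff_mM = 0.2)$values, 0)
  expect_error(make_threshold_representation(two_rep(-0.1, 1),
                                             "log_then_average"), "positive")
})

test_that("log-then-average never exceeds log-of-average (AM-GM)", {
  set.seed(6)
  t1 <- 10^runif(200, -3, 0.5)
  t2 <- 10^runif(200, -3, 0.5)
  lta <- make_threshold_representation(two_rep(t1, t2), "log_then_average")$values
  loa <- make_threshold_representation(two_rep(t1, t2), "log_of_average")$values
  expect_true(all(lta < loa | abs(t1 - t2) < 1e-12))
  eq <- make_threshold_representation(two_rep(t1, t1), "log_then_average")$values
  eq2 <- make_threshold_representation(two_rep(t1, t1), "log_of_average")$values
  expect_equal(eq, eq2)
})

test_that("stacked repeats duplicate subjects and average back to the log mean", {
  th <- two_rep(c(0.1, 0.5), c(0.4, 0.2))
  st <- make_threshold_representation(th, "stacked_repeats")
  expect_length(st$values, 4)
  expect_equal(as.integer(table(st$subject_id)), c(2L, 2L))
  back <- tapply(st$values, st$subject_id, mean)
  lta <- make_threshold_representation(th, "log_then_average")
  expect_equal(as.numeric(back[lta$subject_id]), lta$values)
})

test_that("gLMS session means and the AUC phenotype combine as documented", {
  ids <- c("S1", "S2")
  mk <- function(x) matrix(x, 2, 6,
                           dimnames = list(ids, c("water", "0.032", "0.1",
                                                  "0.32", "1", "3.2")))
  sessions <- list(mk(10), mk(20), mk(30))
  pcm <- glms_mean_ratings(sessions)
  expect_length(pcm, 6L)
  expect_equal(pcm[["water"]]$values, c(20, 20))

  # identical sessions average to any one of them
  same <- glms_mean_ratings(list(mk(7), mk(7), mk(7)))
  expect_equal(same[["1"]]$values, c(7, 7))

  pcm6 <- lapply(1:6, function(i) phenotype_vector(c(i, 0), ids, "glms"))
  auc <- auc_phenotype(pcm6)
  expect_equal(auc$values, c(21, 0))
  # AUC equals 6 times the mean of the six means
  expect_equal(auc$values,
               6 * rowMeans(vapply(pcm6, `[[`, numeric(2), "values")))
  expect_error(auc_phenotype(pcm6[1:5]), "6")

  bad <- sessions
  bad[[2]][1, 3] <- NA
  expect_error(glms_mean_ratings(bad), "S1")
})

test_that("variability statistics match the half-normal day-effect model", {
  expect_equal(variability_stats(two_rep(c(0.1, 0.3), c(0.1, 0.3)))$d_mean, 0)
  set.seed(8)
  n <- 20000
  theta <- runif(n, -2, 0)
  sd_day <- 0.2836
  th <- two_rep(10^(theta + rnorm(n, 0, sd_day)),
                10^(theta + rnorm(n, 0, sd_day)))
  v <- variability_stats(th)
  expect_equal(v$d_mean, 0.32, tolerance = 0.01 / 0.32)
  # Gaussian prediction for the tail fraction beyond 0.62 log10 units
  expect_equal(v$frac_exceeding(0.62), 0.122, tolerance = 0.01 / 0.122)
})

test_that("measurement-error share recovers the generating day variance", {
  set.seed(10)
  n <- 10000
  theta <- rnorm(n, -0.9, sqrt(0.168))
  sd_day <- 0.2836
  th <- two_rep(10^(theta + rnorm(n, 0, sd_day)),
                10^(theta + rnorm(n, 0, sd_day)))
  est <- measurement_error_share(th)
  expect_equal(est$error_variance, sd_day^2, tolerance = 0.05)
  expect_equal(est$share, (sd_day^2 / 2) / (0.168 + sd_day^2 / 2),
               tolerance = 0.08)
  # identical repeats: zero error share
  same <- measurement_error_share(two_rep(10^theta, 10^theta))
  expect_equal(same$share, 0)
  expect_error(measurement_error_share(two_rep(c(0.1, 0.1), c(0.1, 0.1))),
               "undefined")
})
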
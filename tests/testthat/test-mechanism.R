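# brute-force tau-b: concordant/discordant pair counting with tie correction
tau_b_oracle <- function(x, y) {
  n <- length(x); C <- 0; D <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  den <- sqrt((n0 - sum(tx * (tx - 1) / 2)) * (n0 - sum(ty * (ty - 1) / 2)))
  if (den == 0) 0 else (C - D) / den
}

test_that("Kendall tau-b matches perfect orderings and the pair-counting oracle", {
  expect_equal(kendall_tau(1:3, c(10, 20, 30))$tau, 1)
  expect_equal(kendall_tau(1:3, c(3, 2, 1))$tau, -1)
  all_tied <- kendall_tau(rep(2, 5), 1:5)
  expect_equal(all_tied$tau, 0); expect_equal(all_tied$p_value, 1)
  set.seed(401)
  for (rep in 1:30) {
    n <- sample(5:40, 1)
    x <- sample(1:4, n, replace = TRUE)       # heavy ties, like |TRO|
    y <- rnorm(n) + 0.3 * x
    res <- kendall_tau(x, y)
    expect_equal(res$tau, tau_b_oracle(x, y), tolerance = 1e-12)
    expect_true(res$p_value > 0 && res$p_value <= 1)
  }
  # no ties, small n: two-sided exact p agrees with cor.test
  for (rep in 1:10) {
    x <- rnorm(12); y <- rnorm(12)
    expect_equal(kendall_tau(x, y)$p_value,
                 cor.test(x, y, method = "kendall", exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  expect_error(kendall_tau(1:2, 1:2), "n >= 3")
})

test_that("single-Gaussian ML fit uses 1/n variance and a finite floor", {
  expect_error(fit_single_gaussian(1:3), "n >= 4")
  set.seed(402)
  v <- rnorm(25, 10, 3)
  f <- fit_single_gaussian(v)
  expect_equal(f$mu, mean(v), tolerance = 1e-12)
  expect_equal(f$sigma, sqrt(sum((v - mean(v))^2) / 25), tolerance = 1e-12)
  expect_equal(f$log_likelihood, sum(dnorm(v, f$mu, f$sigma, log = TRUE)))
  expect_equal(f$n_params, 2L)
  same <- fit_single_gaussian(rep(7, 10))
  expect_true(is.finite(same$log_likelihood))
  expect_equal(same$sigma, 1e-6)
})

test_that("equal-weight mixture EM separates clusters and dominates the single Gaussian", {
  set.seed(403)
  v <- c(rnorm(100, 5, 0.05), rnorm(100, 25, 0.05))
  m <- fit_equal_weight_mixture(v, seed = 1)
  expect_lt(abs(m$mu1 - 5), 0.1)
  expect_lt(abs(m$mu2 - 25), 0.1)
  expect_equal(m$n_params, 4L)
  expect_equal(m$weights, c(0.5, 0.5))
  deg <- fit_equal_weight_mixture(rep(3, 20), seed = 1)
  expect_equal(deg$mu1, deg$mu2)
  # recovery of a genuine equal mixture across seeded replicates
  ok <- vapply(1:40, function(i) {
    set.seed(1000 + i)
    v <- c(rnorm(100, 10, 3), rnorm(100, 30, 3))
    m <- fit_equal_weight_mixture(v, seed = i)
    abs(m$mu1 - 10) < 1 && abs(m$mu2 - 30) < 1
  }, logical(1))
  expect_gte(mean(ok), 0.95)
  # likelihood dominance over the single Gaussian on arbitrary data
  for (i in 1:20) {
    set.seed(2000 + i)
    v <- rnorm(sample(10:60, 1), 20, sample(1:6, 1))
    g <- fit_single_gaussian(v)
    m <- fit_equal_weight_mixture(v, seed = i)
    expect_gte(m$log_likelihood, g$log_likelihood - 1e-8)
  }
})

test_that("BIC arithmetic penalizes parameters as stated", {
  expect_equal(bic(-100, 4, 50), 200 + 4 * log(50))
  expect_equal(bic(-77, 4, 33) - bic(-77, 2, 33), 2 * log(33))
})

test_that("the delta-BIC test flags bimodal data and skips unimodal fits", {
  set.seed(404)
  v <- c(rnorm(50, 5, 2), rnorm(50, 40, 2))
  cmp <- delta_bic_test(v, n_resamples = 200, seed = 9)
  expect_lt(cmp$delta_bic, 0)
  expect_lt(cmp$p_value, 0.05)
  v <- rnorm(60, 20, 4)
  cmp <- delta_bic_test(v, n_resamples = 200, seed = 10)
  if (cmp$delta_bic >= 0) expect_true(is.na(cmp$p_value))
})

test_that("switch-time and rate coding tests detect their generator mechanisms", {
  s <- mech_session("switch_time", trials_per_level = 40, seed = 21)
  prof <- switch_profile(s, 1, hmm_spec(seed = 2))
  expect_true(prof$reliable)
  st <- switch_time_coding_test(prof, s$trials)
  expect_lt(st$tau, 0)           # easier trials switch earlier
  expect_lt(st$p_value, 0.01)

  # power of the rate-coding test is a distributional property: require
  # significance in most seeded replicates rather than in one draw
  wins <- list(left = c(-250, 0), right = c(-250, 0))
  hits <- vapply(1:10, function(i) {
    si <- mech_session("rate_code", trials_per_level = 40, seed = 22 + i,
                       rate_gain = 2)
    pi_ <- switch_profile(si, 1, hmm_spec(seed = 2))
    if (!pi_$reliable) return(NA)
    rt <- rate_coding_test(pi_, si, wins)
    rt$tau > 0 && rt$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.8)
  s2 <- mech_session("rate_code", trials_per_level = 40, seed = 22,
                     rate_gain = 2)
  prof2 <- switch_profile(s2, 1, hmm_spec(seed = 2))
  expect_true(prof2$reliable)
  # degenerate inputs error out
  expect_error(rate_coding_test(prof2, s2,
                                list(left = NULL, right = NULL)),
               "no usable")
  prof_bad <- prof2; prof_bad$reliable <- FALSE
  expect_error(switch_time_coding_test(prof_bad, s2$trials),
               "not reliable")
})

test_that("population classification applies per-family FDR and counts intersections", {
  ids <- 1:6
  cls <- classify_population(
    neuron_ids = ids,
    mt_flagged = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    difficulty_flagged = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE),
    hmm_reliable = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE),
    switch_p = c(NA, 1e-4, 1e-4, 0.9, NA, NA),
    rate_p = c(NA, 1e-4, 0.8, 0.9, NA, NA),
    binary_p_left = c(NA, NA, NA, 1e-5, 1e-5, NA),
    binary_p_right = c(NA, NA, NA, 1e-5, NA, NA))
  f <- cls$flags
  expect_true(f$switch_time_code[f$neuron_id == 2])
  expect_true(f$rate_code[f$neuron_id == 2])
  expect_true(f$switch_time_code[f$neuron_id == 3])
  expect_false(f$rate_code[f$neuron_id == 3])
  expect_true(f$binary_both_sides[f$neuron_id == 4])
  expect_true(f$binary_any_side[f$neuron_id == 5])
  expect_false(f$binary_both_sides[f$neuron_id == 5])
  expect_equal(unname(cls$intersections["switch_and_rate"]), 1)
  # neuron in two families appears in both flags and the intersection
  expect_equal(unname(cls$intersections["switch_time"]), 2)
  # empty input yields an empty classification
  empty <- classify_population(integer(0), logical(0), logical(0),
                               logical(0), numeric(0), numeric(0),
                               numeric(0), numeric(0))
  expect_equal(nrow(empty$flags), 0)
})
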
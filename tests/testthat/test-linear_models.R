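test_that("bin regression matches exact cases and the lm() oracle", {
  f <- fit_bin_regression(c(1, 2, 3), c(2, 4, 6))
  expect_equal(f$slope, 2); expect_equal(f$intercept, 0)
  expect_equal(f$r2, 1)
  f <- fit_bin_regression(c(1, 2, 3), c(5, 5, 5))
  expect_equal(f$slope, 0); expect_equal(f$r2, 0)
  expect_error(fit_bin_regression(c(2, 2, 2), c(1, 2, 3)), "identical")
  set.seed(201)
  for (rep in 1:50) {
    x <- rnorm(12); y <- rnorm(12)
    f <- fit_bin_regression(x, y)
    m <- stats::lm(y ~ x)
    expect_equal(f$slope, unname(coef(m)[2]), tolerance = 1e-10)
    expect_equal(f$intercept, unname(coef(m)[1]), tolerance = 1e-10)
    expect_equal(f$r2, summary(m)$r.squared, tolerance = 1e-10)
  }
})

test_that("vectorized bin fits agree with the scalar fit across bins", {
  set.seed(202)
  Y <- matrix(rnorm(40 * 25), 40, 25)
  x <- rnorm(40)
  v <- spikeswitch:::bin_regression_matrix(x, Y)
  for (k in c(1, 7, 25)) {
    f <- fit_bin_regression(x, Y[, k])
    expect_equal(v$slope[k], f$slope, tolerance = 1e-12)
    expect_equal(v$r2[k], f$r2, tolerance = 1e-12)
  }
})

test_that("the permutation null has the requested shape and per-bin marking matches a sorting oracle", {
  set.seed(203)
  Y <- matrix(rnorm(30 * 25), 30, 25)
  x <- rnorm(30)
  null <- build_permutation_null(Y, x, n_surrogates = 100, seed = 1)
  expect_equal(dim(null$slope), c(100, 25))
  expect_equal(dim(null$r2), c(100, 25))
  expect_error(build_permutation_null(Y, x, n_surrogates = 0), ">= 1")

  obs <- spikeswitch:::bin_regression_matrix(x, Y)
  sig <- per_bin_significance(obs$slope, null$slope, "slope", alpha = 0.05)
  oracle <- vapply(1:25, function(k) {
    v <- sort(null$slope[, k])
    mean(v >= obs$slope[k]) < 0.025 || mean(v <= obs$slope[k]) < 0.025
  }, logical(1))
  expect_equal(sig, oracle)
  sig2 <- per_bin_significance(obs$r2, null$r2, "r2", alpha = 0.05)
  oracle2 <- vapply(1:25, function(k)
    mean(null$r2[, k] >= obs$r2[k]) < 0.05, logical(1))
  expect_equal(sig2, oracle2)
  # observed equal to the null median everywhere -> nothing significant
  med <- apply(null$slope, 2, stats::median)
  expect_false(any(per_bin_significance(med, null$slope, "slope")))
})

test_that("run lengths and their Monte-Carlo p-values follow the stated conventions", {
  expect_equal(max_run_length(rep(FALSE, 25)), 0L)
  expect_equal(max_run_length(rep(TRUE, 25)), 25L)
  expect_equal(max_run_length(c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)), 3L)
  expect_equal(run_length_pvalue(5, rep(0, 100)), 1 / 101)
  expect_equal(run_length_pvalue(0, rep(3, 100)), 1)
  expect_equal(run_length_pvalue(4, c(rep(4, 50), rep(0, 50))), 51 / 101)
  # monotone non-increasing in the observed run
  nulls <- sample(0:8, 60, replace = TRUE)
  ps <- vapply(0:10, run_length_pvalue, numeric(1), null_runs = nulls)
  expect_true(all(diff(ps) <= 0))
})

test_that("Benjamini-Hochberg step-up matches p.adjust on random vectors", {
  expect_false(any(bh_fdr(rep(1, 5), 0.05)))
  expect_true(all(bh_fdr(c(0.001, 0.01, 0.02, 0.05), 0.05)))
  expect_error(bh_fdr(c(0.5, 0), 0.05), "0, 1")
  set.seed(204)
  for (rep in 1:200) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- runif(1, 0.01, 0.3)
    expect_identical(bh_fdr(p, q), p.adjust(p, "BH") <= q)
  }
})

test_that("neuron-level analysis is label-based, not order-based", {
  set.seed(205)
  Y <- matrix(rnorm(30 * 25, mean = 10), 30, 25)
  x <- rnorm(30)
  a <- spikeswitch:::analyze_neuron_lm(Y, x, seed = 5)
  perm <- sample(30)
  b <- spikeswitch:::analyze_neuron_lm(Y[perm, ], x[perm], seed = 5)
  expect_equal(b$slope, a$slope, tolerance = 1e-12)
  expect_equal(b$r2, a$r2, tolerance = 1e-12)
  expect_equal(b$slope_sig, a$slope_sig)
})

test_that("encoding windows intersect the slope and R2 runs and prefer the longer model", {
  mk <- function(slope_bins, r2_bins) {
    s <- rep(FALSE, 25); s[slope_bins] <- TRUE
    r <- rep(FALSE, 25); r[r2_bins] <- TRUE
    list(slope_sig = s, r2_sig = r)
  }
  w <- encoding_window(mk(5:15, 10:20))
  expect_equal(unname(w), c(10, 15))
  expect_null(encoding_window(mk(1:5, 10:20)))
  a <- mk(3:5, 3:5); b <- mk(10:14, 10:14)
  expect_equal(unname(encoding_window(a, b)), c(10, 14))
  expect_equal(unname(encoding_window(b, a)), c(10, 14))
  # tie broken toward the earlier interval
  expect_equal(unname(encoding_window(mk(c(2:4, 8:10), c(2:4, 8:10)))),
               c(2, 4))
})

test_that("an mt-coding neuron is flagged and a silent regressor case is skipped", {
  s <- mech_session(c("mt_code", "null"), trials_per_level = 40, seed = 31,
                    lambda_low = 20)
  res <- run_linear_model(s, "lm_mt", n_surrogates = 100, seed = 2)
  flags <- lm_flag_neurons(res, q = 0.05)
  expect_true(flags$flagged[flags$neuron_id == 1])
  # determinism under the same seed
  res2 <- run_linear_model(s, "lm_mt", n_surrogates = 100, seed = 2)
  expect_identical(res$neurons, res2$neurons)
})
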
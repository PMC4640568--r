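test_that("spike binarization uses half-open 2 ms bins with clipping", {
  expect_equal(binarize_spikes(numeric(0)), integer(250))
  obs <- binarize_spikes(c(-499.0, -498.5))
  expect_equal(obs[1], 1L)               # two spikes clip to one
  expect_equal(sum(obs), 1L)
  obs <- binarize_spikes(-498.0)         # boundary opens the second bin
  expect_equal(which(obs == 1L), 2L)
  expect_error(binarize_spikes(0, epoch = c(-501, 0)), "divisible")
})

test_that("Baum-Welch recovers well-separated two-state emissions", {
  set.seed(301)
  A_true <- matrix(c(0.995, 0.005, 0.005, 0.995), 2, 2, byrow = TRUE)
  E_true <- 1 - exp(-c(5, 40) * 0.002)
  obs <- t(replicate(200, {
    st <- numeric(250); st[1] <- sample(1:2, 1)
    for (t in 2:250) st[t] <- sample(1:2, 1, prob = A_true[st[t - 1], ])
    rbinom(250, 1, E_true[st])
  }))
  fit <- fit_hmm(obs, hmm_spec(seed = 4))
  expect_lt(abs(fit$emission[1] - E_true[1]) / E_true[1], 0.2)
  expect_lt(abs(fit$emission[2] - E_true[2]) / E_true[2], 0.2)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  expect_false(fit$degenerate)
})

test_that("all-zero observations give a degenerate floor fit without error", {
  fit <- fit_hmm(matrix(0L, 10, 100), hmm_spec(seed = 1))
  expect_true(fit$degenerate)
  expect_true(all(fit$emission <= 1e-6 + 1e-12))
})

test_that("Viterbi matches exhaustive enumeration on short sequences", {
  set.seed(302)
  for (rep in 1:40) {
    T_ <- sample(2:10, 1)
    h <- random_hmm()
    obs <- rbinom(T_, 1, 0.5)
    expect_true(viterbi_agrees_with_enumeration(obs, h$A, h$E, h$pi))
  }
  # prior-dominated tie: equal emissions, everything favors state 1
  fit <- list(transition = matrix(c(0.9, 0.1, 0.4, 0.6), 2, 2, byrow = TRUE),
              emission = c(0.5, 0.5), initial = c(0.9, 0.1))
  expect_equal(viterbi_decode(c(1, 0, 1, 0), fit), rep(1L, 4))
  # likelihood-dominated: dense spikes force the high state
  fit <- list(transition = matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2,
                                  byrow = TRUE),
              emission = c(1e-6, 0.5), initial = c(0.5, 0.5))
  expect_equal(viterbi_decode(rep(1L, 8), fit), rep(2L, 8))
})

test_that("switch extraction follows the first low-to-high convention", {
  p <- c(1, 1, 2, 2)
  sw <- extract_switch_times(p, epoch = c(-500, 0), bin_ms = 2)
  expect_equal(sw$switch_ms, -496)
  expect_equal(sw$n_switches, 1L)
  sw <- extract_switch_times(rep(1, 10))
  expect_true(is.na(sw$switch_ms)); expect_equal(sw$n_switches, 0L)
  sw <- extract_switch_times(c(1, 2, 1, 2))
  expect_equal(sw$switch_ms, -498); expect_equal(sw$n_switches, 3L)
})

test_that("reliability criteria a, b, c are enforced as stated", {
  long_dwell <- rep(c(1, 2), each = 100)
  # (b): one trial with four switches
  bursty <- rep(c(1, 2, 1, 2, 1), each = 10)
  r <- reliability_check(c(rep(list(long_dwell), 10), list(bursty)),
                         c(rep("left", 5), rep("right", 6)))
  expect_false(r$reliable); expect_true("b" %in% r$failed)
  # (a): high-state visits of 5 bins = 10 ms mean dwell
  brief <- c(rep(1, 95), rep(2, 5), rep(1, 100))
  r <- reliability_check(rep(list(brief), 12),
                         rep(c("left", "right"), 6))
  expect_false(r$reliable); expect_true("a" %in% r$failed)
  # (c): only 4 switching left trials
  flat <- rep(1, 200)
  r <- reliability_check(c(rep(list(long_dwell), 4), rep(list(flat), 6),
                           rep(list(long_dwell), 20)),
                         c(rep("left", 10), rep("right", 20)))
  expect_false(r$reliable); expect_true("c" %in% r$failed)
  # all criteria met
  r <- reliability_check(rep(list(long_dwell), 12),
                         rep(c("left", "right"), 6))
  expect_true(r$reliable)
})

test_that("t90 is the ceil(0.9 n)-th order statistic", {
  expect_equal(t90_switch_time(1:10), 9)
  expect_equal(t90_switch_time(rep(-200, 6)), -200)
  expect_equal(t90_switch_time(c(-400, -390, -380, -370, -360)), -360)
  expect_error(t90_switch_time(1:4), "fewer than 5")
})

test_that("switch profiles recover generator switches and BIC prefers the true state count", {
  s <- mech_session("switch_time", trials_per_level = 40, seed = 7)
  prof <- switch_profile(s, 1, hmm_spec(seed = 3))
  expect_true(prof$reliable)
  m <- merge(prof$trials, s$ground_truth$switches, by = "trial_id")
  detected <- !is.na(m$switch_ms.x)
  expect_gt(mean(detected), 0.9)
  # decoding error stays near the information bound set by the rate step
  err <- abs(m$switch_ms.x - m$switch_ms.y)[detected]
  expect_lt(median(err), 60)
  expect_true(all(!is.na(prof$t90_ms)))
  # two-state data: BIC prefers Q = 2 over Q = 3
  ids <- s$trials$trial_id[s$trials$choice == "left"]
  obs <- do.call(rbind, lapply(
    spikeswitch:::spike_trains_by_trial(s, 1, ids), binarize_spikes))
  cmp <- compare_state_counts(obs, hmm_spec(seed = 5))
  expect_equal(attr(cmp, "selected"), 2)
  expect_equal(cmp$n_params, c(5, 11))
})

test_that("state relabeling is an invariance of decoding", {
  set.seed(303)
  fit <- list(transition = matrix(c(0.95, 0.05, 0.02, 0.98), 2, 2,
                                  byrow = TRUE),
              emission = c(0.02, 0.3), initial = c(0.8, 0.2))
  swapped <- list(transition = fit$transition[2:1, 2:1],
                  emission = fit$emission[2:1], initial = fit$initial[2:1])
  obs <- rbinom(100, 1, 0.2)
  expect_equal(viterbi_decode(obs, fit), 3L - viterbi_decode(obs, swapped))
})
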
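#' Tie-corrected Kendall rank correlation (tau-b)
#'
#' Concordant/discordant pair counting with the tie correction in both
#' margins.  The two-sided p-value is exact (via [stats::cor.test()]) for
#' n <= 30 without ties, and otherwise uses the normal approximation with
#' the tie-corrected variance of S.  If every pair is tied the correlation
#' is defined as 0 with p = 1.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list with `tau`, `p_value`, `n`.
#' @export
kendall_tau <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("kendall_tau: need n >= 3", call. = FALSE)
  dx <- sign(outer(x, x, "-")); dy <- sign(outer(y, y, "-"))
  iu <- upper.tri(dx)
  s_terms <- dx[iu] * dy[iu]
  S <- sum(s_terms)
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0) return(list(tau = 0, p_value = 1, n = n))
  tau <- S / den

  has_ties <- n1 > 0 || n2 > 0
  if (!has_ties && n <= 30) {
    p <- stats::cor.test(x, y, method = "kendall", exact = TRUE)$p.value
  } else {
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    var_s <- (v0 - vt - vu) / 18 + v1 + v2
    if (var_s <= 0) return(list(tau = tau, p_value = 1, n = n))
    p <- 2 * pnorm(-abs(S) / sqrt(var_s))
    p <- min(1, p)
  }
  list(tau = tau, p_value = max(p, .Machine$double.xmin), n = n)
}

#' Switch-time coding test
#'
#' Kendall correlation between per-trial HMM switch times and trial
#' difficulty (|TRO|), over correct trials that switched, both response
#' sides pooled.  Easier trials (larger |TRO|) switching earlier yields a
#' negative tau; the test is two-sided.
#'
#' @param profile a reliable [switch_profile()].
#' @param trials the session's trial data.frame.
#' @return list with `tau`, `p_value`, `n`, `variable`.
#' @export
switch_time_coding_test <- function(profile, trials) {
  if (!profile$reliable)
    stop("switch_time_coding_test: profile not reliable", call. = FALSE)
  d <- merge(profile$trials, trials, by = "trial_id")
  d <- d[d$correct & !is.na(d$switch_ms), ]
  res <- kendall_tau(d$switch_ms, abs(d$tro_deg))
  res$variable <- "switch_time_vs_abs_tro"
  res
}

#' Rate coding test
#'
#' Kendall correlation between trial difficulty (|TRO|) and the per-trial
#' mean firing rate in the window from the side's t90 (time by which 90% of
#' switching trials switched) to the end of the side's encoding window,
#' over correct trials, sides pooled.  Sides whose t90 does not precede
#' their window end (or lacking a window/t90) are excluded.
#'
#' @param profile a reliable [switch_profile()].
#' @param session the `ss_session`.
#' @param windows_ms named list (`left`, `right`) of length-2 ms intervals:
#'   each side's encoding window (e.g. from [encoding_window()] mapped by
#'   `window_bins_to_ms`); `NULL` entries allowed.
#' @return list with `tau`, `p_value`, `n`, `variable`; errors if no trial
#'   survives the filters.
#' @export
rate_coding_test <- function(profile, session, windows_ms) {
  if (!profile$reliable)
    stop("rate_coding_test: profile not reliable", call. = FALSE)
  tr <- session$trials
  vals <- numeric(0); diffs <- numeric(0)
  for (side in c("left", "right")) {
    win <- windows_ms[[side]]
    t90 <- profile$t90_ms[[side]]
    if (is.null(win) || is.na(t90) || t90 >= win[2]) next
    ids <- tr$trial_id[tr$choice == side & tr$correct]
    trains <- spike_trains_by_trial(session, profile$neuron_id, ids)
    for (i in seq_along(ids)) {
      vals <- c(vals, mean_rate_in_window(trains[[i]], c(t90, win[2])))
      diffs <- c(diffs, abs(tr$tro_deg[tr$trial_id == ids[i]]))
    }
  }
  if (length(vals) < 3)
    stop("rate_coding_test: no usable trials (missing windows or t90 past ",
         "window end)", call. = FALSE)
  res <- kendall_tau(vals, diffs)
  res$variable <- "post_switch_rate_vs_abs_tro"
  res
}

#' Maximum-likelihood single-Gaussian fit
#'
#' Mean and 1/n-normalized SD, with the SD floored (see
#' [fit_equal_weight_mixture()] for the floor convention) so the likelihood
#' stays finite on degenerate data.
#'
#' @param values per-trial mean firing rates, n >= 4.
#' @param sd_floor SD floor; default `1e-3 * sd(values)` (1e-6 absolute when
#'   the data SD is 0).
#' @return list with `mu`, `sigma`, `log_likelihood`, `n_params = 2`.
#' @export
fit_single_gaussian <- function(values, sd_floor = NULL) {
  n <- length(values)
  if (n < 4) stop("fit_single_gaussian: need n >= 4", call. = FALSE)
  sd_floor <- sd_floor %||% default_sd_floor(values)
  mu <- mean(values)
  sigma <- max(sqrt(sum((values - mu)^2) / n), sd_floor)
  list(mu = mu, sigma = sigma,
       log_likelihood = sum(dnorm(values, mu, sigma, log = TRUE)),
       n_params = 2L)
}

default_sd_floor <- function(values) {
  s <- sd(values)
  if (!is.finite(s) || s == 0) 1e-6 else 1e-3 * s
}

#' Equal-weight two-Gaussian mixture fit by EM
#'
#' Component weights are fixed at (0.5, 0.5); only the two means and SDs are
#' free (4 parameters).  EM is restarted `n_restarts` times from seeded
#' random pairs of data points (with the pooled SD), plus one start at the
#' single-Gaussian solution — an EM fixed point, which guarantees the
#' returned log-likelihood is at least the single-Gaussian one.  Components
#' are returned in increasing-mean order.
#'
#' @param values per-trial mean firing rates, n >= 8.
#' @param n_restarts random restarts (default 10).
#' @param seed integer seed.
#' @param sd_floor SD floor; default `1e-3 * sd(values)` (1e-6 absolute if
#'   the data SD is 0).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @return list with `mu1 <= mu2`, `sigma1`, `sigma2`, `log_likelihood`,
#'   `responsibilities` (posterior probability of component 1 per value),
#'   `n_params = 4`.
#' @export
fit_equal_weight_mixture <- function(values, n_restarts = 10, seed = 1,
                                     sd_floor = NULL, max_iter = 500,
                                     tol = 1e-8) {
  n <- length(values)
  if (n < 8) stop("fit_equal_weight_mixture: need n >= 8", call. = FALSE)
  sd_floor <- sd_floor %||% default_sd_floor(values)
  s_pool <- max(sd(values), sd_floor)
  best <- NULL
  set.seed(seed)
  starts <- replicate(n_restarts, sample(values, 2), simplify = FALSE)
  starts <- c(starts, list(c(mean(values), mean(values))))
  for (st in starts) {
    fit <- .em_equal_mixture(values, st[1], st[2], s_pool, s_pool,
                             sd_floor, as.integer(max_iter), tol)
    if (is.null(best) || fit$log_likelihood > best$log_likelihood)
      best <- fit
  }
  if (best$mu1 > best$mu2) {
    best <- list(mu1 = best$mu2, mu2 = best$mu1, sigma1 = best$sigma2,
                 sigma2 = best$sigma1,
                 log_likelihood = best$log_likelihood,
                 responsibilities = 1 - best$responsibilities,
                 n_iter = best$n_iter)
  }
  best$n_params <- 4L
  best$weights <- c(0.5, 0.5)
  best
}

#' Bayesian Information Criterion
#'
#' `BIC = -2 lnL + p ln(T)`; lower is better.
#'
#' @param log_likelihood maximized log-likelihood.
#' @param n_params number of free parameters `p`.
#' @param n_obs number of observations `T` (trials).
#' @return BIC score.
#' @export
bic <- function(log_likelihood, n_params, n_obs) {
  stopifnot(n_obs >= 1)
  -2 * log_likelihood + n_params * log(n_obs)
}

#' Binary-response test by Monte-Carlo Delta-BIC
#'
#' Fits the single Gaussian and the equal-weight mixture to the per-trial
#' mean rates and compares them by `delta_bic = bic_mixture - bic_single`.
#' If `delta_bic >= 0` the neuron is not binary and no p-value is computed.
#' Otherwise the null distribution of delta-BIC is built by drawing
#' `n_resamples` datasets of the same size from the fitted single Gaussian,
#' refitting both models on each, and the (add-one) p-value is the fraction
#' of null delta-BICs at or below the observed one.
#'
#' @param values per-trial mean firing rates, n >= 8.
#' @param n_resamples Monte-Carlo resamples (default 2000).
#' @param seed integer seed.
#' @param n_restarts mixture-EM restarts per fit.
#' @return list of class `ss_mixture_comparison`: `bic_single`,
#'   `bic_mixture`, `delta_bic`, `p_value` (`NA` when `delta_bic >= 0`),
#'   `n_resamples`, `single`, `mixture`, `n`.
#' @export
delta_bic_test <- function(values, n_resamples = 2000, seed = 1,
                           n_restarts = 10) {
  n <- length(values)
  g <- fit_single_gaussian(values)
  m <- fit_equal_weight_mixture(values, n_restarts = n_restarts,
                                seed = derive_seed(seed, 0L, salt = 31L))
  bic_g <- bic(g$log_likelihood, g$n_params, n)
  bic_m <- bic(m$log_likelihood, m$n_params, n)
  dbic <- bic_m - bic_g
  p <- NA_real_
  if (dbic < 0) {
    null_dbic <- numeric(n_resamples)
    for (i in seq_len(n_resamples)) {
      set.seed(derive_seed(seed, i, salt = 37L))
      z <- rnorm(n, g$mu, g$sigma)
      g0 <- fit_single_gaussian(z)
      m0 <- fit_equal_weight_mixture(z, n_restarts = n_restarts,
                                     seed = derive_seed(seed, i, salt = 41L))
      null_dbic[i] <- bic(m0$log_likelihood, 4, n) -
        bic(g0$log_likelihood, 2, n)
    }
    p <- (1 + sum(null_dbic <= dbic)) / (n_resamples + 1)
  }
  structure(list(bic_single = bic_g, bic_mixture = bic_m, delta_bic = dbic,
                 p_value = p, n_resamples = n_resamples, n = n,
                 single = g, mixture = m),
            class = "ss_mixture_comparison")
}

#' Classify a population of neurons into coding mechanisms
#'
#' Applies Benjamini-Hochberg FDR control across neurons within each test
#' family (switch-time and rate Kendall p-values; per-side delta-BIC
#' p-values) and assembles per-neuron flags plus the pairwise/triple
#' intersection counts among the three difficulty-coding mechanisms.
#'
#' @param neuron_ids integers naming all analyzed neurons.
#' @param mt_flagged,difficulty_flagged logical vectors aligned with
#'   `neuron_ids` (linear-model verdicts).
#' @param hmm_reliable logical, aligned.
#' @param switch_p,rate_p numeric p-values aligned with `neuron_ids` (`NA`
#'   where the test was not run).
#' @param binary_p_left,binary_p_right per-side delta-BIC p-values (`NA`
#'   where skipped or `delta_bic >= 0`).
#' @param q_mechanism FDR level for the mechanism tests (default 0.05).
#' @return list with `flags` (data.frame of logical flags per neuron) and
#'   `intersections` (named counts).
#' @export
classify_population <- function(neuron_ids, mt_flagged, difficulty_flagged,
                                hmm_reliable, switch_p, rate_p,
                                binary_p_left, binary_p_right,
                                q_mechanism = 0.05) {
  n <- length(neuron_ids)
  stopifnot(length(mt_flagged) == n, length(difficulty_flagged) == n,
            length(hmm_reliable) == n, length(switch_p) == n,
            length(rate_p) == n, length(binary_p_left) == n,
            length(binary_p_right) == n)
  fdr_family <- function(p) {
    out <- rep(FALSE, n)
    ok <- !is.na(p)
    if (any(ok)) out[ok] <- bh_fdr(p[ok], q_mechanism)
    out
  }
  switch_sig <- fdr_family(switch_p) & hmm_reliable
  rate_sig <- fdr_family(rate_p) & hmm_reliable
  bin_p <- c(binary_p_left, binary_p_right)
  bin_sig <- rep(FALSE, 2 * n)
  ok <- !is.na(bin_p)
  if (any(ok)) bin_sig[ok] <- bh_fdr(bin_p[ok], q_mechanism)
  bin_left <- bin_sig[seq_len(n)]
  bin_right <- bin_sig[n + seq_len(n)]

  flags <- data.frame(
    neuron_id = neuron_ids,
    mt_code = mt_flagged,
    difficulty = difficulty_flagged,
    hmm_reliable = hmm_reliable,
    switch_time_code = switch_sig,
    rate_code = rate_sig,
    binary_any_side = bin_left | bin_right,
    binary_both_sides = bin_left & bin_right)
  inter <- c(
    switch_time = sum(flags$switch_time_code),
    rate = sum(flags$rate_code),
    binary = sum(flags$binary_any_side),
    switch_and_rate = sum(flags$switch_time_code & flags$rate_code),
    switch_and_binary = sum(flags$switch_time_code & flags$binary_any_side),
    rate_and_binary = sum(flags$rate_code & flags$binary_any_side),
    all_three = sum(flags$switch_time_code & flags$rate_code &
                      flags$binary_any_side))
  list(flags = flags, intersections = inter)
}
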
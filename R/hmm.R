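#' Binarize a spike train into 2 ms observation bins
#'
#' The analysis epoch is divided into half-open `bin_ms` bins; a bin is 1 if
#' it contains at least one spike (multi-spike bins are clipped to 1), which
#' is the Bernoulli observation model the state-switch HMM assumes.
#'
#' @param spike_ms spike times (ms).
#' @param epoch analysis window `[start, end)` (ms); its length must be
#'   divisible by `bin_ms`.
#' @param bin_ms bin width (ms, default 2).
#' @return integer 0/1 vector of length `(end - start) / bin_ms`.
#' @export
binarize_spikes <- function(spike_ms, epoch = c(-500, 0), bin_ms = 2) {
  n_bins <- (epoch[2] - epoch[1]) / bin_ms
  if (abs(n_bins - round(n_bins)) > 1e-9 || n_bins < 1)
    stop("binarize_spikes: epoch length not divisible by bin_ms",
         call. = FALSE)
  n_bins <- as.integer(round(n_bins))
  s <- spike_ms[spike_ms >= epoch[1] & spike_ms < epoch[2]]
  idx <- floor((s - epoch[1]) / bin_ms) + 1
  obs <- integer(n_bins)
  obs[unique(idx)] <- 1L
  obs
}

#' HMM fitting specification
#'
#' @param n_states number of hidden states (default 2: low/high activity).
#' @param bin_ms observation bin width (ms).
#' @param train_fraction fraction of trials used for Baum-Welch fitting
#'   (the fitted model then decodes all trials).
#' @param max_iter,tol Baum-Welch iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param n_restarts random restarts; the best-likelihood fit is kept.
#' @param seed integer seed driving the train split and restarts.
#' @return list of class `ss_hmm_spec`.
#' @export
hmm_spec <- function(n_states = 2, bin_ms = 2, train_fraction = 0.8,
                     max_iter = 100, tol = 1e-6, n_restarts = 5, seed = 1) {
  stopifnot(n_states >= 1, train_fraction > 0, train_fraction <= 1)
  structure(list(n_states = as.integer(n_states), bin_ms = bin_ms,
                 train_fraction = train_fraction, max_iter = max_iter,
                 tol = tol, n_restarts = n_restarts, seed = seed),
            class = "ss_hmm_spec")
}

# initial parameters for restart r: emissions spread around the pooled spike
# probability, near-diagonal transitions, uniform start, seeded jitter
hmm_init <- function(p_pooled, Q, seed) {
  set.seed(seed)
  spread <- seq(0.5, 1.5, length.out = Q)
  E <- p_pooled * spread * exp(rnorm(Q, 0, 0.1))
  E <- pmin(1 - 1e-6, pmax(1e-6, E))
  A <- matrix((1 - 0.98) / max(1, Q - 1), Q, Q)
  diag(A) <- if (Q > 1) 0.98 else 1
  A <- A * exp(matrix(rnorm(Q * Q, 0, 0.05), Q, Q))
  A <- A / rowSums(A)
  list(A = A, E = E, pi = rep(1 / Q, Q))
}

#' Fit a Bernoulli-emission HMM to binary spike sequences
#'
#' Baum-Welch (EM) on a seeded random `train_fraction` of the sequences,
#' with `n_restarts` seeded initializations, keeping the best-likelihood
#' solution.  States are relabeled so emission probabilities increase with
#' the state index (state 1 = low activity).  Per-state rates in Hz follow
#' from `E_q = 1 - exp(-lambda_q * bin_ms / 1000)`.
#'
#' @param observations list of equal-length 0/1 integer vectors (or a
#'   trials x bins matrix), one per trial.
#' @param spec an [hmm_spec()].
#' @return object of class `ss_hmm_fit`: `transition`, `emission`
#'   (increasing), `rate_hz`, `initial`, `log_likelihood`, `loglik_trace`
#'   (best restart), `train_idx`, `degenerate` (TRUE when no spikes were
#'   observed at all).
#' @export
fit_hmm <- function(observations, spec = hmm_spec()) {
  obs <- if (is.matrix(observations)) observations
  else do.call(rbind, observations)
  storage.mode(obs) <- "integer"
  stopifnot(nrow(obs) >= 1)
  Q <- spec$n_states
  n <- nrow(obs)
  set.seed(derive_seed(spec$seed, 0L, salt = 23L))
  n_train <- max(1L, as.integer(round(spec$train_fraction * n)))
  train_idx <- sort(sample.int(n, n_train))
  train <- obs[train_idx, , drop = FALSE]
  p_pooled <- max(mean(train), 1e-6)
  degenerate <- sum(train) == 0

  best <- NULL
  for (r in seq_len(spec$n_restarts)) {
    init <- hmm_init(p_pooled, Q, derive_seed(spec$seed, r, salt = 29L))
    fit <- .bw_bernoulli(train, init$A, init$E, init$pi,
                         as.integer(spec$max_iter), spec$tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ord <- order(best$E)
  structure(list(
    transition = best$A[ord, ord, drop = FALSE],
    emission = best$E[ord],
    rate_hz = -log(1 - best$E[ord]) / (spec$bin_ms / 1000),
    initial = best$pi[ord],
    log_likelihood = best$loglik,
    loglik_trace = best$loglik_trace,
    n_states = Q, bin_ms = spec$bin_ms,
    train_idx = train_idx, n_obs_bins = length(train),
    degenerate = degenerate),
    class = "ss_hmm_fit")
}

#' Viterbi decoding of a binary observation sequence
#'
#' Most likely state path under a fitted HMM; ties are broken toward the
#' lower-index (lower-rate) state.
#'
#' @param observation 0/1 integer vector.
#' @param fit an `ss_hmm_fit` (or any list with `transition`, `emission`,
#'   `initial`).
#' @return integer state path (1 = lowest-emission state).
#' @export
viterbi_decode <- function(observation, fit) {
  .viterbi_bernoulli(as.integer(observation), fit$transition,
                     fit$emission, fit$initial)
}

#' Switch time and switch count of one decoded trial
#'
#' The switch time is the start of the first bin in the high state that
#' follows a low-state bin; `n_switches` counts all state changes in either
#' direction.
#'
#' @param path integer state path from [viterbi_decode()] (relabeled fit:
#'   1 = low).
#' @param epoch analysis window (ms).
#' @param bin_ms bin width (ms).
#' @return list with `switch_ms` (`NA` if the path never rises from low to
#'   high) and `n_switches`.
#' @export
extract_switch_times <- function(path, epoch = c(-500, 0), bin_ms = 2) {
  ch <- which(diff(path) != 0) + 1L
  up <- ch[path[ch] > path[ch - 1L]]
  list(switch_ms = if (length(up)) epoch[1] + (up[1] - 1) * bin_ms
       else NA_real_,
       n_switches = length(ch))
}

#' Reliability of a neuron's HMM decoding
#'
#' A fit is reliable iff (a) the mean dwell duration of every visited state,
#' pooled over visits and trials, is at least `min_dwell_ms`; (b) no trial
#' has more than `max_switches` state changes; (c) at least `min_switch_trials`
#' trials of each response side contain a state change.
#'
#' @param paths list of decoded state paths (all trials, both sides).
#' @param sides character vector (`"left"`/`"right"`) aligned with `paths`.
#' @param bin_ms bin width (ms).
#' @param min_dwell_ms,max_switches,min_switch_trials criterion thresholds.
#' @return list with `reliable` (logical) and `failed` (character vector of
#'   failed criterion labels among `"a"`, `"b"`, `"c"`).
#' @export
reliability_check <- function(paths, sides, bin_ms = 2, min_dwell_ms = 25,
                              max_switches = 3, min_switch_trials = 5) {
  stopifnot(length(paths) == length(sides))
  failed <- character(0)
  dwell <- list()
  n_switch <- integer(length(paths))
  has_switch <- logical(length(paths))
  for (i in seq_along(paths)) {
    r <- rle(paths[[i]])
    for (k in seq_along(r$values)) {
      s <- as.character(r$values[k])
      dwell[[s]] <- c(dwell[[s]], r$lengths[k] * bin_ms)
    }
    n_switch[i] <- length(r$values) - 1L
    has_switch[i] <- n_switch[i] > 0L
  }
  mean_dwell <- vapply(dwell, mean, numeric(1))
  if (any(mean_dwell < min_dwell_ms)) failed <- c(failed, "a")
  if (any(n_switch > max_switches)) failed <- c(failed, "b")
  n_left <- sum(has_switch & sides == "left")
  n_right <- sum(has_switch & sides == "right")
  if (n_left < min_switch_trials || n_right < min_switch_trials)
    failed <- c(failed, "c")
  list(reliable = length(failed) == 0, failed = failed,
       mean_dwell_ms = mean_dwell,
       n_switch_trials = c(left = n_left, right = n_right))
}

#' Time by which 90% of switching trials have switched
#'
#' The `ceil(0.9 * n)`-th order statistic of the per-trial switch times.
#'
#' @param switch_times switch times of switching trials (no `NA`); at least
#'   5 values (fewer means the profile is already unreliable).
#' @return time in ms.
#' @export
t90_switch_time <- function(switch_times) {
  switch_times <- switch_times[!is.na(switch_times)]
  if (length(switch_times) < 5)
    stop("t90_switch_time: fewer than 5 switching trials", call. = FALSE)
  sort(switch_times)[ceiling(0.9 * length(switch_times))]
}

#' Per-trial switch profile of one neuron
#'
#' Splits the neuron's trials by behavioral response, fits one HMM per side
#' on a seeded 80% training subset, Viterbi-decodes all trials of that side,
#' extracts per-trial switch times, applies the reliability criteria across
#' both sides, and summarizes each side's t90.
#'
#' @param session an `ss_session`.
#' @param neuron_id neuron to analyze.
#' @param spec an [hmm_spec()].
#' @param epoch analysis window (ms).
#' @return object of class `ss_switch_profile`: `trials` (data.frame:
#'   `trial_id`, `side`, `switch_ms`, `n_switches`), `fits` (per side),
#'   `reliable`, `failed`, `t90_ms` (named per side, `NA` when fewer than 5
#'   switching trials on that side).
#' @export
switch_profile <- function(session, neuron_id, spec = hmm_spec(),
                           epoch = c(-500, 0)) {
  tr <- session$trials
  rows <- list(); fits <- list(); paths <- list(); sides_v <- character(0)
  for (side in c("left", "right")) {
    ids <- tr$trial_id[tr$choice == side]
    if (!length(ids)) next
    trains <- spike_trains_by_trial(session, neuron_id, ids)
    obs <- do.call(rbind, lapply(trains, binarize_spikes, epoch = epoch,
                                 bin_ms = spec$bin_ms))
    side_spec <- spec
    side_spec$seed <- derive_seed(spec$seed, neuron_id,
                                  salt = if (side == "left") 101L else 102L)
    fit <- fit_hmm(obs, side_spec)
    fits[[side]] <- fit
    for (i in seq_along(ids)) {
      path <- viterbi_decode(obs[i, ], fit)
      sw <- extract_switch_times(path, epoch, spec$bin_ms)
      rows[[length(rows) + 1L]] <- data.frame(
        trial_id = ids[i], side = side, switch_ms = sw$switch_ms,
        n_switches = sw$n_switches)
      paths[[length(paths) + 1L]] <- path
      sides_v <- c(sides_v, side)
    }
  }
  trials_df <- do.call(rbind, rows) %||%
    data.frame(trial_id = integer(), side = character(),
               switch_ms = numeric(), n_switches = integer())
  rel <- reliability_check(paths, sides_v, bin_ms = spec$bin_ms)
  t90 <- c(left = NA_real_, right = NA_real_)
  for (side in c("left", "right")) {
    st <- trials_df$switch_ms[trials_df$side == side &
                                !is.na(trials_df$switch_ms)]
    if (length(st) >= 5) t90[side] <- t90_switch_time(st)
  }
  structure(list(neuron_id = neuron_id, trials = trials_df, fits = fits,
                 reliable = rel$reliable, failed = rel$failed,
                 t90_ms = t90, epoch = epoch, bin_ms = spec$bin_ms),
            class = "ss_switch_profile")
}

#' Compare HMM state counts by BIC
#'
#' Fits the HMM at each candidate number of states and scores
#' `BIC = -2 lnL + p ln(T)` with `p = Q^2 - 1 + Q` free parameters
#' (Q(Q-1) transition, Q-1 initial, Q emission) and `T` the total number of
#' observed bins; the lower BIC wins.
#'
#' @param observations list/matrix of binary sequences (see [fit_hmm()]).
#' @param spec an [hmm_spec()]; its `n_states` is overridden.
#' @param state_counts candidate state counts (default `c(2, 3)`).
#' @return data.frame with `n_states`, `log_likelihood`, `n_params`, `bic`,
#'   plus an attribute `selected` (state count with minimal BIC).
#' @export
compare_state_counts <- function(observations, spec = hmm_spec(),
                                 state_counts = c(2, 3)) {
  rows <- lapply(state_counts, function(Q) {
    s <- spec; s$n_states <- as.integer(Q)
    fit <- fit_hmm(observations, s)
    p <- Q^2 - 1 + Q
    data.frame(n_states = Q, log_likelihood = fit$log_likelihood,
               n_params = p,
               bic = bic(fit$log_likelihood, p, fit$n_obs_bins))
  })
  out <- do.call(rbind, rows)
  attr(out, "selected") <- out$n_states[which.min(out$bic)]
  out
}
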
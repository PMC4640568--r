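#' Behavioral generator parameters
#'
#' Defaults emulate the two-interval, two-alternative forced-choice
#' orientation-discrimination task: a logistic psychometric curve in the test
#' relative orientation (TRO) and movement times (MT) that shorten with trial
#' ease on correct trials and lengthen on errors (the X-shaped chronometric
#' pattern).
#'
#' @param beta psychometric slope (1/degree); P(choice = left | TRO) =
#'   1 / (1 + exp(beta * TRO)).
#' @param mt_base mean MT (ms) at zero evidence.
#' @param mt_gain MT change per degree of |TRO| (ms/degree): subtracted on
#'   correct trials, added on error trials.
#' @param mt_sd MT noise SD (ms); Gaussian, truncated to (0, 1200].
#' @param tro_levels TRO levels (degrees), zero excluded.
#' @param trials_per_level trials at each level.
#' @return list of class `ss_behavior_params`.
#' @export
behavior_params <- function(beta = 0.75, mt_base = 300, mt_gain = 10,
                            mt_sd = 50, tro_levels = c(-4:-1, 1:4),
                            trials_per_level = 40) {
  stopifnot(beta >= 0, mt_sd >= 0, !0 %in% tro_levels,
            trials_per_level >= 1)
  structure(list(beta = beta, mt_base = mt_base, mt_gain = mt_gain,
                 mt_sd = mt_sd, tro_levels = sort(tro_levels),
                 trials_per_level = as.integer(trials_per_level)),
            class = "ss_behavior_params")
}

#' Generate behavioral trials
#'
#' For each TRO level draws `trials_per_level` trials: the choice from the
#' logistic psychometric model, correctness from the sign convention
#' (negative TRO maps to the left target), and MT as
#' `mt_base -+ mt_gain * |TRO| + N(0, mt_sd)` (minus on correct, plus on
#' error trials), truncated by resampling to the (0, 1200] response window.
#'
#' @param params a [behavior_params()] object.
#' @param seed integer seed; output is reproducible.
#' @return data.frame of trial records (see [new_session()]).
#' @export
generate_behavior <- function(params, seed) {
  stopifnot(inherits(params, "ss_behavior_params"))
  set.seed(seed)
  tro <- rep(params$tro_levels, each = params$trials_per_level)
  n <- length(tro)
  p_left <- 1 / (1 + exp(params$beta * tro))
  left <- runif(n) < p_left
  choice <- ifelse(left, "left", "right")
  correct <- (tro < 0 & left) | (tro > 0 & !left)
  mu <- ifelse(correct,
               params$mt_base - params$mt_gain * abs(tro),
               params$mt_base + params$mt_gain * abs(tro))
  mt <- mu + rnorm(n, 0, params$mt_sd)
  # truncate to the response window by redrawing the offending noise draws
  for (iter in 1:1000) {
    out <- which(!(mt > 0 & mt <= 1200))
    if (!length(out)) break
    mt[out] <- mu[out] + rnorm(length(out), 0, params$mt_sd)
  }
  mt[!(mt > 0 & mt <= 1200)] <- pmin(pmax(mu[!(mt > 0 & mt <= 1200)], 1), 1200)
  data.frame(trial_id = seq_len(n), s1_deg = 90, s2_deg = 90 + tro,
             tro_deg = tro, choice = choice, correct = correct,
             mt_ms = mt, saccade_ms = 0)
}

#' Sample an inhomogeneous Poisson spike train with piecewise-constant rate
#'
#' Exact sampling: per segment the spike count is Poisson(rate * duration)
#' and spike times are uniform within the segment; no refractoriness.
#'
#' @param segments data.frame/matrix-like with columns `t_start`, `t_end`
#'   (ms, non-overlapping, ordered) and `rate_hz` (>= 0).
#' @param seed integer seed.
#' @return sorted numeric vector of spike times (ms).
#' @export
sample_piecewise_poisson <- function(segments, seed) {
  segments <- as.data.frame(segments)
  stopifnot(all(c("t_start", "t_end", "rate_hz") %in% names(segments)))
  if (any(segments$t_end <= segments$t_start))
    stop("sample_piecewise_poisson: segment with t_end <= t_start",
         call. = FALSE)
  if (any(segments$rate_hz < 0))
    stop("sample_piecewise_poisson: negative rate", call. = FALSE)
  if (nrow(segments) > 1 &&
      any(segments$t_start[-1] < segments$t_end[-nrow(segments)]))
    stop("sample_piecewise_poisson: overlapping or unordered segments",
         call. = FALSE)
  set.seed(seed)
  out <- numeric(0)
  for (i in seq_len(nrow(segments))) {
    dur_s <- (segments$t_end[i] - segments$t_start[i]) / 1000
    k <- rpois(1, segments$rate_hz[i] * dur_s)
    if (k > 0)
      out <- c(out, runif(k, segments$t_start[i], segments$t_end[i]))
  }
  sort(out)
}

#' Specification of a synthetic neuron
#'
#' Each mechanism mirrors one hypothesized coding scheme for decision
#' difficulty (or movement time):
#' \describe{
#'   \item{`switch_time`}{rate steps `lambda_low` to `lambda_high` at
#'     `T_sw = switch_anchor - switch_gain * |TRO| + N(0, switch_jitter_sd)`
#'     (easier trials switch earlier).}
#'   \item{`rate_code`}{step at `switch_anchor` + jitter to
#'     `lambda_high + rate_gain * |TRO|`.}
#'   \item{`binary`}{with probability `clip(p0 + p1 * |TRO|, 0, 1)` the trial
#'     steps to `lambda_high` at `switch_anchor` + jitter, otherwise stays at
#'     `lambda_low`.}
#'   \item{`mt_code`}{constant rate
#'     `clip(lambda_low + mt_gain_hz * (mt_ms - mt_base), 0, Inf)`.}
#'   \item{`null`}{constant `lambda_low`.}
#' }
#'
#' @param neuron_id integer id.
#' @param mechanism one of `"mt_code"`, `"switch_time"`, `"rate_code"`,
#'   `"binary"`, `"null"`.
#' @param lambda_low,lambda_high baseline and post-switch rates (Hz).
#' @param switch_anchor mean switch time (ms, saccade-aligned).
#' @param switch_gain switch advance per degree of |TRO| (ms/degree).
#' @param switch_jitter_sd switch-time jitter SD (ms).
#' @param rate_gain post-switch rate gain (Hz per degree of |TRO|).
#' @param p0,p1 intercept/slope of switch probability vs |TRO| (binary).
#' @param mt_gain_hz rate gain per ms of (MT - mt_base) (mt_code).
#' @param mt_base MT reference (ms) for mt_code.
#' @return list of class `ss_neuron_spec`.
#' @export
neuron_spec <- function(neuron_id, mechanism,
                        lambda_low = 5, lambda_high = 30,
                        switch_anchor = -300, switch_gain = 25,
                        switch_jitter_sd = 20, rate_gain = 2,
                        p0 = 0.1, p1 = 0.2, mt_gain_hz = 0.1,
                        mt_base = 300) {
  mechanism <- match.arg(mechanism,
                         c("mt_code", "switch_time", "rate_code",
                           "binary", "null"))
  stopifnot(lambda_low >= 0, lambda_high >= 0, switch_jitter_sd >= 0)
  structure(list(neuron_id = as.integer(neuron_id), mechanism = mechanism,
                 lambda_low = lambda_low, lambda_high = lambda_high,
                 switch_anchor = switch_anchor, switch_gain = switch_gain,
                 switch_jitter_sd = switch_jitter_sd, rate_gain = rate_gain,
                 p0 = p0, p1 = p1, mt_gain_hz = mt_gain_hz,
                 mt_base = mt_base),
            class = "ss_neuron_spec")
}

#' Generate spike trains for one synthetic neuron
#'
#' @param spec a [neuron_spec()].
#' @param trials data.frame of trial records (non-empty).
#' @param epoch_ms recorded window, ms relative to the saccade.
#' @param seed integer seed; per-trial substreams are derived from it.
#' @return list with `spikes` (data.frame `neuron_id`, `trial_id`,
#'   `spike_ms`) and `switches` (data.frame `neuron_id`, `trial_id`,
#'   `switch_ms`; only trials where a switch occurred).
#' @export
generate_neuron <- function(spec, trials, epoch_ms = c(-1000, 100), seed = 1) {
  stopifnot(inherits(spec, "ss_neuron_spec"), nrow(trials) >= 1)
  e0 <- epoch_ms[1]; e1 <- epoch_ms[2]
  sp_list <- vector("list", nrow(trials))
  sw <- numeric(0); sw_trial <- integer(0)
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    tseed <- derive_seed(seed, i, salt = spec$neuron_id)
    set.seed(tseed)
    atro <- abs(tr$tro_deg)
    segs <- NULL
    t_sw <- NA_real_
    if (spec$mechanism == "null") {
      segs <- data.frame(t_start = e0, t_end = e1, rate_hz = spec$lambda_low)
    } else if (spec$mechanism == "mt_code") {
      r <- max(0, spec$lambda_low +
                 spec$mt_gain_hz * (tr$mt_ms - spec$mt_base))
      segs <- data.frame(t_start = e0, t_end = e1, rate_hz = r)
    } else {
      jitter <- rnorm(1, 0, spec$switch_jitter_sd)
      high <- spec$lambda_high
      do_switch <- TRUE
      if (spec$mechanism == "switch_time") {
        t_sw <- spec$switch_anchor - spec$switch_gain * atro + jitter
      } else if (spec$mechanism == "rate_code") {
        t_sw <- spec$switch_anchor + jitter
        high <- spec$lambda_high + spec$rate_gain * atro
      } else { # binary
        p <- min(1, max(0, spec$p0 + spec$p1 * atro))
        do_switch <- runif(1) < p
        t_sw <- spec$switch_anchor + jitter
      }
      if (do_switch) {
        t_sw <- min(max(t_sw, e0), e1)  # keep the step inside the epoch
        segs <- data.frame(t_start = c(e0, t_sw), t_end = c(t_sw, e1),
                           rate_hz = c(spec$lambda_low, high))
        segs <- segs[segs$t_end > segs$t_start, ]
        sw <- c(sw, t_sw); sw_trial <- c(sw_trial, tr$trial_id)
      } else {
        segs <- data.frame(t_start = e0, t_end = e1,
                           rate_hz = spec$lambda_low)
      }
    }
    st <- sample_piecewise_poisson(segs, seed = derive_seed(tseed, 1L))
    sp_list[[i]] <- if (length(st))
      data.frame(neuron_id = spec$neuron_id, trial_id = tr$trial_id,
                 spike_ms = st)
  }
  spikes <- do.call(rbind, sp_list) %||%
    data.frame(neuron_id = integer(), trial_id = integer(),
               spike_ms = numeric())
  switches <- data.frame(neuron_id = rep(spec$neuron_id, length(sw)),
                         trial_id = sw_trial, switch_ms = sw)
  list(spikes = spikes, switches = switches)
}

#' Generate a full synthetic session with ground truth
#'
#' Behavior and each neuron use independent random substreams derived from
#' the master seed, so removing one neuron does not change another's spikes.
#'
#' @param behavior a [behavior_params()] object.
#' @param neurons list of [neuron_spec()] objects (unique ids).
#' @param seed master integer seed.
#' @param epoch_ms recorded window (default `c(-1000, 100)`).
#' @return a validated `ss_session` with `ground_truth` populated.
#' @export
generate_session <- function(behavior, neurons = list(), seed = 1,
                             epoch_ms = c(-1000, 100)) {
  ids <- vapply(neurons, function(s) s$neuron_id, integer(1))
  if (anyDuplicated(ids))
    stop("generate_session: duplicate neuron_id", call. = FALSE)
  trials <- generate_behavior(behavior, seed = derive_seed(seed, 0L))
  spikes_l <- list(); switch_l <- list(); gt_l <- list()
  for (spec in neurons) {
    g <- generate_neuron(spec, trials, epoch_ms,
                         seed = derive_seed(seed, spec$neuron_id, salt = 1L))
    spikes_l[[length(spikes_l) + 1L]] <- g$spikes
    switch_l[[length(switch_l) + 1L]] <- g$switches
    gt_l[[length(gt_l) + 1L]] <- data.frame(
      neuron_id = spec$neuron_id, mechanism = spec$mechanism,
      params = as.character(jsonlite::toJSON(
        unclass(spec)[setdiff(names(spec), c("neuron_id", "mechanism"))],
        auto_unbox = TRUE, digits = NA)))
  }
  spikes <- do.call(rbind, spikes_l) %||%
    data.frame(neuron_id = integer(), trial_id = integer(),
               spike_ms = numeric())
  gt <- NULL
  if (length(neurons)) {
    gt <- list(neurons = do.call(rbind, gt_l),
               switches = do.call(rbind, switch_l) %||%
                 data.frame(neuron_id = integer(), trial_id = integer(),
                            switch_ms = numeric()))
  }
  s <- new_session(trials, spikes, epoch_ms, gt)
  s$meta <- list(generator = "spikeswitch", seed = seed)
  stop_if_invalid(s, "generate_session")
  s
}

#' Default neuron roster for demonstration and validation sessions
#'
#' @param n_per_mech neurons per coding mechanism.
#' @param mechanisms mechanisms to include.
#' @param ... overrides passed to every [neuron_spec()].
#' @return list of `ss_neuron_spec`.
#' @export
default_neuron_specs <- function(n_per_mech = 5,
                                 mechanisms = c("mt_code", "switch_time",
                                                "rate_code", "binary",
                                                "null"),
                                 ...) {
  out <- list(); id <- 0L
  for (m in mechanisms) {
    for (k in seq_len(n_per_mech)) {
      id <- id + 1L
      out[[id]] <- neuron_spec(id, m, ...)
    }
  }
  out
}
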
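#' Sliding-window firing-rate series for one spike train
#'
#' The last 500 ms before the saccade are discretized into one bin per 20 ms
#' step (25 bins); each bin's rate is the spike count in a 100 ms window
#' centered on the bin, divided by 0.1 s.  Windows are half-open
#' `[center - w/2, center + w/2)`, so a spike on a boundary is counted once;
#' the outermost windows legitimately draw on spikes up to 40 ms outside the
#' epoch (the session invariant guarantees those spikes are recorded).
#'
#' @param spike_ms sorted spike times (ms, saccade-aligned).
#' @param window_ms window width (ms).
#' @param step_ms step between bin centers (ms).
#' @param epoch length-2 analysis epoch `[start, end)` (ms); its length must
#'   be an integer multiple of `step_ms`.
#' @return list with `bin_centers_ms` and `rate_hz`, both length
#'   `(end - start) / step_ms`.
#' @export
compute_rate_series <- function(spike_ms, window_ms = 100, step_ms = 20,
                                epoch = c(-500, 0)) {
  span <- epoch[2] - epoch[1]
  n_bins <- span / step_ms
  if (abs(n_bins - round(n_bins)) > 1e-9 || n_bins < 1)
    stop("compute_rate_series: epoch length must be a positive integer ",
         "multiple of step_ms", call. = FALSE)
  n_bins <- as.integer(round(n_bins))
  centers <- epoch[1] + step_ms / 2 + step_ms * (seq_len(n_bins) - 1)
  spike_ms <- sort(spike_ms)
  lo <- centers - window_ms / 2
  hi <- centers + window_ms / 2
  # #{spikes < x} via findInterval with left-open intervals
  n_lt <- function(x) findInterval(x, spike_ms, left.open = TRUE)
  counts <- n_lt(hi) - n_lt(lo)
  list(bin_centers_ms = centers, rate_hz = counts / (window_ms / 1000))
}

#' Mean firing rate in a time window
#'
#' Spike count in the half-open window divided by its duration.
#'
#' @param spike_ms sorted spike times (ms).
#' @param window length-2 interval `[a, b)` in ms, non-empty.
#' @return rate in Hz.
#' @export
mean_rate_in_window <- function(spike_ms, window) {
  if (window[2] <= window[1])
    stop("mean_rate_in_window: empty window", call. = FALSE)
  spike_ms <- sort(spike_ms)
  n <- findInterval(window[2], spike_ms, left.open = TRUE) -
    findInterval(window[1], spike_ms, left.open = TRUE)
  n / ((window[2] - window[1]) / 1000)
}

#' Per-trial rate matrix for one neuron
#'
#' Stacks [compute_rate_series()] across trials.
#'
#' @param session an `ss_session`.
#' @param neuron_id neuron to extract.
#' @param trial_ids trials (rows), default all trials in session order.
#' @inheritParams compute_rate_series
#' @return numeric matrix trials x bins with `rownames` = trial ids; the
#'   attribute `bin_centers_ms` holds the bin centers.
#' @export
rate_matrix <- function(session, neuron_id, trial_ids = NULL,
                        window_ms = 100, step_ms = 20, epoch = c(-500, 0)) {
  trial_ids <- trial_ids %||% session$trials$trial_id
  trains <- spike_trains_by_trial(session, neuron_id, trial_ids)
  rs <- lapply(trains, compute_rate_series, window_ms = window_ms,
               step_ms = step_ms, epoch = epoch)
  m <- do.call(rbind, lapply(rs, `[[`, "rate_hz"))
  rownames(m) <- as.character(trial_ids)
  attr(m, "bin_centers_ms") <- rs[[1]]$bin_centers_ms
  m
}
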
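#' Ordinary least-squares fit of one time bin
#'
#' Closed-form simple regression of per-trial rates on a per-trial scalar
#' regressor.  If the rates are constant (`SS_tot = 0`) the slope and R^2 are
#' defined as 0.
#'
#' @param x per-trial regressor values (at least two distinct).
#' @param y per-trial rates at one bin.
#' @return list with `slope`, `intercept`, `r2`.
#' @export
fit_bin_regression <- function(x, y) {
  if (length(x) < 2 || length(x) != length(y))
    stop("fit_bin_regression: need >= 2 paired observations", call. = FALSE)
  if (length(unique(x)) < 2)
    stop("fit_bin_regression: all regressor values identical", call. = FALSE)
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2); syy <- sum(yc^2); sxy <- sum(xc * yc)
  if (syy == 0) return(list(slope = 0, intercept = mean(y), r2 = 0))
  slope <- sxy / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       r2 = sxy^2 / (sxx * syy))
}

# Vectorized OLS of every column of Y on x: returns slope/intercept/r2
# vectors of length ncol(Y).  Columns with zero variance get slope 0, r2 0.
bin_regression_matrix <- function(x, Y) {
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  ym <- colMeans(Y)
  Yc <- sweep(Y, 2, ym)
  sxy <- as.numeric(crossprod(xc, Yc))
  syy <- colSums(Yc^2)
  slope <- sxy / sxx
  r2 <- ifelse(syy == 0, 0, sxy^2 / (sxx * syy))
  slope[syy == 0] <- 0
  list(slope = slope, intercept = ym - slope * mean(x), r2 = r2)
}

#' Monte-Carlo permutation null for bin-wise slope and R^2
#'
#' Each surrogate permutes the regressor labels across trials once and
#' refits every bin with the same permutation, preserving the temporal
#' correlation of the rate series under the null.  Surrogate `i` uses random
#' substream `i` of `seed`.
#'
#' @param Y trials x bins rate matrix.
#' @param x per-trial regressor.
#' @param n_surrogates number of label permutations (>= 1).
#' @param seed integer seed.
#' @return list with matrices `slope` and `r2`, each `n_surrogates` x bins.
#' @export
build_permutation_null <- function(Y, x, n_surrogates = 100, seed = 1) {
  if (n_surrogates < 1)
    stop("build_permutation_null: n_surrogates must be >= 1", call. = FALSE)
  n <- nrow(Y)
  # permutation leaves sum(xc^2) and the column sums of squares unchanged,
  # so all surrogates reduce to one crossprod of permuted-x columns with Y
  Xp <- matrix(0, n, n_surrogates)
  for (i in seq_len(n_surrogates)) {
    set.seed(derive_seed(seed, i))
    Xp[, i] <- x[sample.int(n)]
  }
  Xpc <- sweep(Xp, 2, colMeans(Xp))
  sxx <- colSums(Xpc^2)          # identical across surrogates up to fp noise
  Yc <- sweep(Y, 2, colMeans(Y))
  syy <- colSums(Yc^2)
  sxy <- crossprod(Xpc, Yc)      # n_surrogates x bins
  slope <- sxy / sxx
  r2 <- sweep(slope^2 * sxx, 2, syy, "/")
  r2[, syy == 0] <- 0
  slope[, syy == 0] <- 0
  list(slope = slope, r2 = r2)
}

# Fraction-based tail counts of each column's values against the same
# column's null sample; returns matrices of P(null >= obs) and P(null <= obs)
null_tail_fracs <- function(observed, null) {
  n <- nrow(null)
  ge <- numeric(ncol(null)); le <- numeric(ncol(null))
  for (k in seq_len(ncol(null))) {
    ge[k] <- sum(null[, k] >= observed[k]) / n
    le[k] <- sum(null[, k] <= observed[k]) / n
  }
  list(ge = ge, le = le)
}

#' Per-bin significance against an empirical permutation null
#'
#' Slopes are tested two-sided (outside the central `1 - alpha` envelope of
#' the bin's null); R^2 one-sided (above the upper `alpha` tail).
#'
#' @param observed per-bin statistics (length = bins).
#' @param null surrogate statistics, `n_surrogates` x bins.
#' @param statistic_kind `"slope"` (two-sided) or `"r2"` (upper one-sided).
#' @param alpha per-bin level (default 0.05).
#' @return logical vector, one flag per bin.
#' @export
per_bin_significance <- function(observed, null,
                                 statistic_kind = c("slope", "r2"),
                                 alpha = 0.05) {
  statistic_kind <- match.arg(statistic_kind)
  stopifnot(length(observed) == ncol(null))
  tails <- null_tail_fracs(observed, null)
  if (statistic_kind == "slope") {
    tails$ge < alpha / 2 | tails$le < alpha / 2
  } else {
    tails$ge < alpha
  }
}

# Per-bin significance of every surrogate row scored against the pooled null
# of all rows (rank counting, vectorized per bin).
surrogate_bin_masks <- function(null, statistic_kind, alpha = 0.05) {
  n <- nrow(null)
  ge <- le <- matrix(NA_real_, n, ncol(null))
  for (k in seq_len(ncol(null))) {
    v <- null[, k]
    ge[, k] <- (n - rank(v, ties.method = "min") + 1) / n  # P(null >= v_i)
    le[, k] <- rank(v, ties.method = "max") / n            # P(null <= v_i)
  }
  if (statistic_kind == "slope") ge < alpha / 2 | le < alpha / 2
  else ge < alpha
}

#' Longest run of TRUE values
#' @param mask logical vector.
#' @return integer run length (0 if none true).
#' @export
max_run_length <- function(mask) {
  if (!length(mask) || !any(mask)) return(0L)
  r <- rle(as.logical(mask))
  max(r$lengths[r$values])
}

# start/end (indices) of the longest TRUE run; earlier run wins ties;
# NULL if none
longest_run_interval <- function(mask) {
  if (!length(mask) || !any(mask)) return(NULL)
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  best <- cand[which.max(r$lengths[cand])]   # which.max takes the first max
  c(start = starts[best], end = ends[best])
}

#' Monte-Carlo p-value of an observed run length
#'
#' Add-one rule, so p is always in (0, 1] and monotone non-increasing in the
#' observed run.
#'
#' @param observed_run observed longest run (integer).
#' @param null_runs longest runs of the surrogates.
#' @return p = (1 + #\{null >= observed\}) / (n + 1).
#' @export
run_length_pvalue <- function(observed_run, null_runs) {
  stopifnot(length(null_runs) >= 1)
  (1 + sum(null_runs >= observed_run)) / (length(null_runs) + 1)
}

#' Benjamini-Hochberg step-up rejections
#'
#' Sorts the p-values ascending, finds the largest `i` with
#' `p(i) <= i * q / m`, and rejects every hypothesis with `p <= p(i)`.
#'
#' @param pvalues p-values in (0, 1].
#' @param q target false discovery rate, in (0, 1).
#' @return logical rejection vector aligned with `pvalues`.
#' @export
bh_fdr <- function(pvalues, q) {
  stopifnot(q > 0, q < 1)
  if (!length(pvalues)) return(logical(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop("bh_fdr: p-values must lie in (0, 1]", call. = FALSE)
  m <- length(pvalues)
  ps <- sort(pvalues)
  ok <- which(ps <= seq_len(m) * q / m)
  if (!length(ok)) return(rep(FALSE, m))
  pvalues <= ps[max(ok)]
}

#' Trial filter and regressor of one linear model
#'
#' `lm_mt` regresses r(t) on movement time over all completed trials;
#' `lm_tro_pos`/`lm_tro_neg` on signed TRO over correct trials of one sign;
#' `lm_diff` on |TRO| over all correct trials.
#'
#' @param name one of `"lm_mt"`, `"lm_tro_pos"`, `"lm_tro_neg"`, `"lm_diff"`.
#' @return list of class `ss_model_spec` with `name`, `filter(trials)` and
#'   `regressor(trials)` functions.
#' @export
model_spec <- function(name = c("lm_mt", "lm_tro_pos", "lm_tro_neg",
                                "lm_diff")) {
  name <- match.arg(name)
  filter <- switch(name,
    lm_mt = function(tr) rep(TRUE, nrow(tr)),
    lm_tro_pos = function(tr) tr$correct & tr$tro_deg > 0,
    lm_tro_neg = function(tr) tr$correct & tr$tro_deg < 0,
    lm_diff = function(tr) tr$correct)
  regressor <- switch(name,
    lm_mt = function(tr) tr$mt_ms,
    lm_tro_pos = function(tr) tr$tro_deg,
    lm_tro_neg = function(tr) tr$tro_deg,
    lm_diff = function(tr) abs(tr$tro_deg))
  structure(list(name = name, filter = filter, regressor = regressor),
            class = "ss_model_spec")
}

# Full bin-wise analysis of one neuron under one model: observed fits,
# permutation null, per-bin masks, run lengths, run-length p-values.
analyze_neuron_lm <- function(Y, x, alpha = 0.05, n_surrogates = 100,
                              seed = 1) {
  obs <- bin_regression_matrix(x, Y)
  null <- build_permutation_null(Y, x, n_surrogates, seed)
  slope_sig <- per_bin_significance(obs$slope, null$slope, "slope", alpha)
  r2_sig <- per_bin_significance(obs$r2, null$r2, "r2", alpha)
  null_masks_slope <- surrogate_bin_masks(null$slope, "slope", alpha)
  null_masks_r2 <- surrogate_bin_masks(null$r2, "r2", alpha)
  null_runs_slope <- apply(null_masks_slope, 1, max_run_length)
  null_runs_r2 <- apply(null_masks_r2, 1, max_run_length)
  max_run_slope <- max_run_length(slope_sig)
  max_run_r2 <- max_run_length(r2_sig)
  list(slope = obs$slope, intercept = obs$intercept, r2 = obs$r2,
       slope_sig = slope_sig, r2_sig = r2_sig,
       max_run_slope = max_run_slope, max_run_r2 = max_run_r2,
       p_run_slope = run_length_pvalue(max_run_slope, null_runs_slope),
       p_run_r2 = run_length_pvalue(max_run_r2, null_runs_r2),
       n_surrogates = n_surrogates)
}

#' Run one linear model over every neuron of a session
#'
#' For each neuron: bin-wise OLS of the 25-bin rate series on the model's
#' regressor; per-bin significance against a label-permutation null (one
#' permutation per surrogate, shared by all bins); the longest run of
#' significant bins scored against the surrogates' own longest runs (each
#' surrogate compared to the pooled null of all surrogates); Monte-Carlo
#' run-length p-values for the slope and for R^2.
#'
#' @param session an `ss_session`.
#' @param model a [model_spec()] or its name.
#' @param alpha per-bin significance level.
#' @param n_surrogates label permutations per neuron.
#' @param seed master seed (neuron `i` and surrogate `j` get derived
#'   substreams, so results do not depend on neuron ordering).
#' @param window_ms,step_ms,epoch rate-series parameters
#'   (see [compute_rate_series()]).
#' @return object of class `ss_lm_results`: list with `model`, `neurons`
#'   (per-neuron summary data.frame with `p_run_slope`, `p_run_r2`, run
#'   lengths), `details` (per-neuron full results incl. per-bin masks),
#'   `skipped` (data.frame of neuron_id + reason), `bin_centers_ms`.
#' @export
run_linear_model <- function(session, model, alpha = 0.05,
                             n_surrogates = 100, seed = 1,
                             window_ms = 100, step_ms = 20,
                             epoch = c(-500, 0)) {
  if (is.character(model)) model <- model_spec(model)
  stopifnot(inherits(model, "ss_model_spec"))
  keep <- model$filter(session$trials)
  trials <- session$trials[keep, , drop = FALSE]
  x_all <- model$regressor(trials)
  neurons <- session_neurons(session)
  details <- list(); rows <- list(); skipped <- list()
  centers <- NULL
  for (nid in neurons) {
    if (nrow(trials) < 2 || length(unique(x_all)) < 2) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        neuron_id = nid, reason = "fewer than 2 distinct regressor values")
      next
    }
    Y <- rate_matrix(session, nid, trials$trial_id,
                     window_ms = window_ms, step_ms = step_ms, epoch = epoch)
    centers <- attr(Y, "bin_centers_ms")
    res <- analyze_neuron_lm(Y, x_all, alpha = alpha,
                             n_surrogates = n_surrogates,
                             seed = derive_seed(seed, nid, salt = 11L))
    details[[as.character(nid)]] <- res
    rows[[length(rows) + 1L]] <- data.frame(
      neuron_id = nid, model = model$name, n_trials = nrow(trials),
      max_run_slope = res$max_run_slope, max_run_r2 = res$max_run_r2,
      p_run_slope = res$p_run_slope, p_run_r2 = res$p_run_r2)
  }
  structure(list(
    model = model$name,
    neurons = do.call(rbind, rows) %||% data.frame(),
    details = details,
    skipped = do.call(rbind, skipped) %||%
      data.frame(neuron_id = integer(), reason = character()),
    bin_centers_ms = centers, alpha = alpha),
    class = "ss_lm_results")
}

#' Neuron-level linear-model verdicts under FDR control
#'
#' A neuron is flagged only if its run-length p-values for both the slope and
#' R^2 survive Benjamini-Hochberg at rate `q` across the tested population,
#' and the two significance profiles overlap in at least one run of
#' consecutive bins (a non-empty encoding window).
#'
#' @param results an `ss_lm_results` from [run_linear_model()].
#' @param q target false discovery rate.
#' @return the per-neuron summary data.frame with logical columns
#'   `sig_slope`, `sig_r2`, `has_window`, `flagged`.
#' @export
lm_flag_neurons <- function(results, q = 0.05) {
  tab <- results$neurons
  if (!nrow(tab)) {
    tab$sig_slope <- tab$sig_r2 <- tab$has_window <- tab$flagged <- logical(0)
    return(tab)
  }
  tab$sig_slope <- bh_fdr(tab$p_run_slope, q)
  tab$sig_r2 <- bh_fdr(tab$p_run_r2, q)
  tab$has_window <- vapply(as.character(tab$neuron_id), function(id) {
    d <- results$details[[id]]
    any(d$slope_sig & d$r2_sig)
  }, logical(1))
  tab$flagged <- tab$sig_slope & tab$sig_r2 & tab$has_window
  tab
}

#' Encoding window of a neuron
#'
#' The largest run of consecutive bins where the per-bin slope and R^2 are
#' both significant.  With two model results (e.g. the signed-TRO model and
#' the |TRO| model for one response side), the longest interval across the
#' two is taken; ties go to the earlier interval (and, across models, to the
#' first argument).
#'
#' @param result_a per-neuron detail entry of an `ss_lm_results`
#'   (`results$details[[id]]`).
#' @param result_b optional second detail entry for the same neuron.
#' @return integer `c(start, end)` bin indices, or `NULL` if no bin has both
#'   statistics significant.
#' @export
encoding_window <- function(result_a, result_b = NULL) {
  iv_a <- longest_run_interval(result_a$slope_sig & result_a$r2_sig)
  iv_b <- if (!is.null(result_b))
    longest_run_interval(result_b$slope_sig & result_b$r2_sig)
  if (is.null(iv_b)) return(iv_a)
  if (is.null(iv_a)) return(iv_b)
  len_a <- iv_a["end"] - iv_a["start"]
  len_b <- iv_b["end"] - iv_b["start"]
  if (len_b > len_a) iv_b
  else if (len_a > len_b) iv_a
  else if (iv_b["start"] < iv_a["start"]) iv_b else iv_a
}

# ms interval covered by an encoding window: the union of the member bins'
# sliding windows, i.e. from the first bin's window start (center - w/2) to
# the last bin's window end (center + w/2)
window_bins_to_ms <- function(window, step_ms = 20, window_ms = 100,
                              epoch = c(-500, 0)) {
  if (is.null(window)) return(NULL)
  center <- function(k) epoch[1] + step_ms / 2 + step_ms * (k - 1)
  c(center(window["start"]) - window_ms / 2,
    center(window["end"]) + window_ms / 2)
}
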
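#' Pipeline configuration
#'
#' Bundles the stage parameters of the full analysis.  Defaults follow the
#' package's standard settings: per-bin level 0.05 with 100 label
#' permutations; FDR Q = 0.05 for the movement-time model and Q = 0.1 for
#' the TRO/|TRO| models; mechanism-test FDR Q = 0.05; 2000 delta-BIC
#' resamples; two-state HMM on 2 ms bins trained on 80% of trials.
#'
#' @param seed master seed (mandatory for reproducibility).
#' @param alpha per-bin significance level of the permutation tests.
#' @param n_surrogates label permutations per neuron and model.
#' @param q_mt,q_tro,q_mechanism FDR levels.
#' @param hmm an [hmm_spec()].
#' @param n_resamples delta-BIC Monte-Carlo resamples.
#' @param mix_restarts mixture-EM restarts.
#' @param hmm_scope `"difficulty"` (default: HMM only on neurons flagged by
#'   the TRO/|TRO| models) or `"all"`.
#' @param epoch analysis epoch (ms).
#' @return list of class `ss_pipeline_config`.
#' @export
pipeline_config <- function(seed, alpha = 0.05, n_surrogates = 100,
                            q_mt = 0.05, q_tro = 0.1, q_mechanism = 0.05,
                            hmm = hmm_spec(), n_resamples = 2000,
                            mix_restarts = 10,
                            hmm_scope = c("difficulty", "all"),
                            epoch = c(-500, 0)) {
  stopifnot(!missing(seed))
  structure(list(seed = as.integer(seed), alpha = alpha,
                 n_surrogates = n_surrogates, q_mt = q_mt, q_tro = q_tro,
                 q_mechanism = q_mechanism, hmm = hmm,
                 n_resamples = n_resamples, mix_restarts = mix_restarts,
                 hmm_scope = match.arg(hmm_scope), epoch = epoch),
            class = "ss_pipeline_config")
}

# encoding windows (ms) for both response sides of one neuron:
# left <-> TRO < 0 (signed-TRO model on negative trials), right <-> TRO > 0;
# per side the longest interval across the signed-TRO and |TRO| models
side_windows_ms <- function(neuron_id, lm_results, epoch = c(-500, 0)) {
  id <- as.character(neuron_id)
  get <- function(model) lm_results[[model]]$details[[id]]
  win <- list(
    left = encoding_window(get("lm_tro_neg"), get("lm_diff")),
    right = encoding_window(get("lm_tro_pos"), get("lm_diff")))
  lapply(win, window_bins_to_ms, epoch = epoch)
}

#' Run the full analysis pipeline on a session
#'
#' Stages, in order: behavioral summaries; the four bin-wise linear models
#' with permutation/run-length/FDR inference; per-trial HMM switch decoding
#' of the difficulty-flagged neurons; the switch-time, rate and binary
#' (delta-BIC) mechanism tests; population classification with intersection
#' counts.  Fully deterministic given the config seed.
#'
#' @param session an `ss_session` (or a path readable by [read_session()]).
#' @param config a [pipeline_config()].
#' @return list of class `ss_pipeline_report`; see [make_report()] for
#'   serialization.
#' @export
run_pipeline <- function(session, config) {
  stopifnot(inherits(config, "ss_pipeline_config"))
  if (is.character(session)) session <- read_session(session)
  stop_if_invalid(session, "run_pipeline")
  seed <- config$seed
  neurons <- session_neurons(session)
  report <- list(config = unclass(config[setdiff(names(config), "hmm")]),
                 n_neurons = length(neurons), n_trials = nrow(session$trials))

  report$behavior <- list(
    psychometric = psychometric_table(session$trials),
    chronometric = mt_tro_correlations(session$trials))

  models <- c("lm_mt", "lm_tro_pos", "lm_tro_neg", "lm_diff")
  lm_results <- list(); lm_flags <- list()
  for (k in seq_along(models)) {
    m <- models[k]
    res <- run_linear_model(session, m, alpha = config$alpha,
                            n_surrogates = config$n_surrogates,
                            seed = derive_seed(seed, k, salt = 201L),
                            epoch = config$epoch)
    q <- if (m == "lm_mt") config$q_mt else config$q_tro
    lm_results[[m]] <- res
    lm_flags[[m]] <- lm_flag_neurons(res, q)
  }
  report$lm <- lapply(lm_flags, function(f)
    f[, c("neuron_id", "p_run_slope", "p_run_r2", "flagged")])

  flag_of <- function(model) {
    f <- lm_flags[[model]]
    neurons %in% f$neuron_id[f$flagged]
  }
  mt_flagged <- flag_of("lm_mt")
  difficulty_flagged <- flag_of("lm_tro_pos") | flag_of("lm_tro_neg") |
    flag_of("lm_diff")

  hmm_set <- if (config$hmm_scope == "all") neurons
             else neurons[difficulty_flagged]
  profiles <- list()
  hmm_reliable <- setNames(rep(FALSE, length(neurons)),
                           as.character(neurons))
  for (nid in hmm_set) {
    spec <- config$hmm
    spec$seed <- derive_seed(seed, nid, salt = 301L)
    prof <- switch_profile(session, nid, spec, epoch = config$epoch)
    profiles[[as.character(nid)]] <- prof
    hmm_reliable[as.character(nid)] <- prof$reliable
  }

  switch_p <- rate_p <- rep(NA_real_, length(neurons))
  bin_p_left <- bin_p_right <- rep(NA_real_, length(neurons))
  skipped <- list()
  skip <- function(nid, stage, reason) skipped[[length(skipped) + 1L]] <<-
    data.frame(neuron_id = nid, stage = stage, reason = reason)
  for (j in seq_along(neurons)) {
    nid <- neurons[j]
    id <- as.character(nid)
    if (!difficulty_flagged[j]) next
    wins <- side_windows_ms(nid, lm_results, epoch = config$epoch)
    prof <- profiles[[id]]
    if (!is.null(prof) && prof$reliable) {
      st <- tryCatch(switch_time_coding_test(prof, session$trials),
                     error = function(e) NULL)
      if (!is.null(st)) switch_p[j] <- st$p_value
      else skip(nid, "switch_time", "test not computable")
      rt <- tryCatch(rate_coding_test(prof, session, wins),
                     error = function(e) NULL)
      if (!is.null(rt)) rate_p[j] <- rt$p_value
      else skip(nid, "rate_code", "no usable window/t90")
    } else if (!is.null(prof)) {
      skip(nid, "hmm", paste("unreliable:",
                             paste(prof$failed, collapse = ",")))
    }
    for (side in c("left", "right")) {
      win <- wins[[side]]
      if (is.null(win)) { skip(nid, paste0("binary_", side),
                               "no encoding window"); next }
      tr <- session$trials
      ids <- tr$trial_id[tr$choice == side & tr$correct]
      if (length(ids) < 8) { skip(nid, paste0("binary_", side),
                                  "fewer than 8 trials"); next }
      trains <- spike_trains_by_trial(session, nid, ids)
      vals <- vapply(trains, mean_rate_in_window, numeric(1), window = win)
      cmp <- delta_bic_test(vals, n_resamples = config$n_resamples,
                            seed = derive_seed(seed, nid,
                                               salt = if (side == "left")
                                                 401L else 402L),
                            n_restarts = config$mix_restarts)
      if (side == "left") bin_p_left[j] <- cmp$p_value
      else bin_p_right[j] <- cmp$p_value
    }
  }

  cls <- classify_population(neurons, mt_flagged, difficulty_flagged,
                             unname(hmm_reliable), switch_p, rate_p,
                             bin_p_left, bin_p_right,
                             q_mechanism = config$q_mechanism)
  report$classification <- cls$flags
  report$intersections <- cls$intersections
  report$mechanism_p <- data.frame(neuron_id = neurons,
                                   switch_p = switch_p, rate_p = rate_p,
                                   binary_p_left = bin_p_left,
                                   binary_p_right = bin_p_right)
  report$skipped <- do.call(rbind, skipped) %||%
    data.frame(neuron_id = integer(), stage = character(),
               reason = character())
  report$profiles <- profiles
  if (!is.null(session$ground_truth)) {
    gt <- session$ground_truth$neurons[, c("neuron_id", "mechanism")]
    report$ground_truth <- gt
    report$confusion <- confusion_table(cls$flags, gt)
  }
  structure(report, class = "ss_pipeline_report")
}

# recall of each generator mechanism on its designated flag, plus the
# fraction of null neurons acquiring any flag
confusion_table <- function(flags, gt) {
  m <- merge(flags, gt, by = "neuron_id")
  designated <- c(mt_code = "mt_code", switch_time = "switch_time_code",
                  rate_code = "rate_code", binary = "binary_any_side")
  rows <- lapply(names(designated), function(mech) {
    sub <- m[m$mechanism == mech, ]
    if (!nrow(sub)) return(NULL)
    data.frame(mechanism = mech, n = nrow(sub),
               recall = mean(sub[[designated[[mech]]]]))
  })
  out <- do.call(rbind, rows) %||% data.frame()
  nulls <- m[m$mechanism == "null", ]
  if (nrow(nulls)) {
    any_flag <- nulls$mt_code | nulls$switch_time_code | nulls$rate_code |
      nulls$binary_any_side
    out <- rbind(out, data.frame(mechanism = "null", n = nrow(nulls),
                                 recall = mean(!any_flag)))
  }
  out
}

#' Serialize a pipeline report
#'
#' Writes `report.json` plus CSV sidecars (classification, mechanism
#' p-values, skipped neurons, behavioral tables) into a directory.
#'
#' @param report an `ss_pipeline_report`.
#' @param path output directory (created if needed).
#' @return invisibly, the path.
#' @export
make_report <- function(report, path) {
  stopifnot(inherits(report, "ss_pipeline_report"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  core <- report[setdiff(names(report), "profiles")]
  jsonlite::write_json(core, file.path(path, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null")
  wr <- function(df, file) if (!is.null(df))
    write.csv(df, file.path(path, file), row.names = FALSE)
  wr(report$classification, "classification.csv")
  wr(report$mechanism_p, "mechanism_pvalues.csv")
  wr(report$skipped, "skipped.csv")
  wr(report$behavior$psychometric, "psychometric.csv")
  wr(report$behavior$chronometric, "chronometric.csv")
  invisible(path)
}
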
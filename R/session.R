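#' Session container for trial-aligned spike data
#'
#' A session couples per-trial behavioral records with saccade-aligned spike
#' trains.  Times are in milliseconds relative to saccade onset at 0 ms
#' (negative = before the saccade); the test bar appears near -510 ms.
#'
#' @param trials data.frame with columns `trial_id`, `s1_deg`, `s2_deg`,
#'   `tro_deg` (test relative orientation, `s2_deg - s1_deg`), `choice`
#'   (`"left"`/`"right"`), `correct` (logical), `mt_ms` (movement time),
#'   `saccade_ms` (saccade onset on the session clock; 0 if pre-aligned).
#' @param spikes data.frame with columns `neuron_id`, `trial_id`, `spike_ms`
#'   (one row per spike, saccade-aligned ms).
#' @param epoch_ms numeric length-2, recorded window relative to the saccade;
#'   must cover at least \[-600, +50\] so all analysis windows are computable.
#' @param ground_truth optional list with elements `neurons` (data.frame:
#'   `neuron_id`, `mechanism`, `params` JSON string) and `switches`
#'   (data.frame: `neuron_id`, `trial_id`, `switch_ms`); synthetic sessions
#'   only.
#'
#' @return An object of class `ss_session`.
#' @export
new_session <- function(trials, spikes, epoch_ms, ground_truth = NULL) {
  trials <- as.data.frame(trials)
  spikes <- as.data.frame(spikes)
  trials$choice <- as.character(trials$choice)
  trials$correct <- as.logical(trials$correct)
  structure(
    list(trials = trials, spikes = spikes,
         epoch_ms = as.numeric(epoch_ms), ground_truth = ground_truth),
    class = "ss_session")
}

#' @export
print.ss_session <- function(x, ...) {
  cat(sprintf(
    "<ss_session> %d trials, %d neurons, epoch [%g, %g] ms%s\n",
    nrow(x$trials), length(session_neurons(x)),
    x$epoch_ms[1], x$epoch_ms[2],
    if (!is.null(x$ground_truth)) ", with ground truth" else ""))
  invisible(x)
}

#' Neuron ids present in a session
#' @param session an `ss_session`.
#' @return sorted integer vector (may be empty).
#' @export
session_neurons <- function(session) {
  sort(unique(as.integer(session$spikes$neuron_id)))
}

#' Spike times of one neuron on one trial
#' @param session an `ss_session`.
#' @param neuron_id,trial_id integer ids.
#' @return sorted numeric vector of saccade-aligned spike times (ms).
#' @export
session_spike_train <- function(session, neuron_id, trial_id) {
  sp <- session$spikes
  sort(sp$spike_ms[sp$neuron_id == neuron_id & sp$trial_id == trial_id])
}

# Split one neuron's spikes into a list of per-trial sorted spike vectors,
# one entry per requested trial id (empty vector where the neuron was silent).
spike_trains_by_trial <- function(session, neuron_id, trial_ids) {
  sp <- session$spikes[session$spikes$neuron_id == neuron_id, ]
  f <- factor(sp$trial_id, levels = trial_ids)
  out <- split(sp$spike_ms, f)
  lapply(out, sort)
}

#' Validate a session against its invariants
#'
#' Checks referential integrity and field invariants; collects violations
#' instead of raising, so malformed sessions can be inspected.
#'
#' @param session an `ss_session`.
#' @return data.frame with columns `rule` and `detail`; zero rows when valid.
#' @export
validate_session <- function(session) {
  v <- list()
  bad <- function(rule, detail) v[[length(v) + 1L]] <<-
      data.frame(rule = rule, detail = detail)
  tr <- session$trials
  sp <- session$spikes

  need_tr <- c("trial_id", "s1_deg", "s2_deg", "tro_deg", "choice",
               "correct", "mt_ms", "saccade_ms")
  miss <- setdiff(need_tr, names(tr))
  if (length(miss))
    bad("trials_columns", paste("missing:", paste(miss, collapse = ", ")))
  need_sp <- c("neuron_id", "trial_id", "spike_ms")
  miss <- setdiff(need_sp, names(sp))
  if (length(miss))
    bad("spikes_columns", paste("missing:", paste(miss, collapse = ", ")))
  if (nrow(do.call(rbind, v) %||% data.frame()) > 0)
    return(do.call(rbind, v))

  if (anyDuplicated(tr$trial_id))
    bad("trial_id_unique", "duplicated trial_id in trials")
  off <- which(abs(tr$tro_deg - (tr$s2_deg - tr$s1_deg)) > 1e-9)
  for (i in off) bad("tro_consistency",
                     sprintf("trial_id %s: tro_deg != s2_deg - s1_deg",
                             tr$trial_id[i]))
  for (i in which(tr$tro_deg == 0))
    bad("tro_nonzero", sprintf("trial_id %s: tro_deg is 0", tr$trial_id[i]))
  for (i in which(!(tr$mt_ms > 0 & tr$mt_ms <= 1200)))
    bad("mt_range", sprintf("trial_id %s: mt_ms %s outside (0, 1200]",
                            tr$trial_id[i], tr$mt_ms[i]))
  for (i in which(!tr$choice %in% c("left", "right")))
    bad("choice_levels", sprintf("trial_id %s: choice '%s'",
                                 tr$trial_id[i], tr$choice[i]))
  # sign convention: negative TRO (counterclockwise test) maps to the left
  # target, so correct <=> sign(TRO) matches the chosen side
  exp_correct <- (tr$tro_deg < 0 & tr$choice == "left") |
    (tr$tro_deg > 0 & tr$choice == "right")
  for (i in which(tr$correct != exp_correct))
    bad("correct_convention",
        sprintf("trial_id %s: correct inconsistent with choice/TRO",
                tr$trial_id[i]))

  if (length(session$epoch_ms) != 2 ||
      !(session$epoch_ms[1] <= -600 && session$epoch_ms[2] >= 50))
    bad("epoch_cover", "epoch_ms must cover [-600, +50]")

  if (nrow(sp)) {
    unk <- unique(sp$trial_id[!sp$trial_id %in% tr$trial_id])
    for (u in unk) bad("spike_trial_ref",
                       sprintf("spikes reference unknown trial_id %s", u))
    out_ep <- sp$spike_ms < session$epoch_ms[1] |
      sp$spike_ms > session$epoch_ms[2]
    if (any(out_ep))
      bad("spike_epoch", sprintf("%d spikes outside epoch", sum(out_ep)))
    key <- paste(sp$neuron_id, sp$trial_id)
    dupt <- tapply(sp$spike_ms, key, function(z) anyDuplicated(round(z / 1e-6)))
    for (k in names(dupt)[dupt > 0])
      bad("spike_times_distinct",
          sprintf("duplicate spike times (<=1e-6 ms apart) for (neuron, trial) %s", k))
  }
  do.call(rbind, v) %||%
    data.frame(rule = character(), detail = character())
}

stop_if_invalid <- function(session, context) {
  rep <- validate_session(session)
  if (nrow(rep)) {
    stop(sprintf("%s: invalid session (%d violation%s), first: [%s] %s",
                 context, nrow(rep), if (nrow(rep) > 1) "s" else "",
                 rep$rule[1], rep$detail[1]), call. = FALSE)
  }
  invisible(session)
}

#' Read a session directory
#'
#' Expects `trials.csv`, `spikes.csv` and `meta.json` (fields `epoch_ms`,
#' optionally generator provenance), plus optional `ground_truth.csv` and
#' `ground_truth_switches.csv` written for synthetic sessions.  All files are
#' UTF-8 CSV with a header row and '.' decimal separator.
#'
#' @param path directory produced by [write_session()] (or hand-assembled in
#'   the same layout).
#' @return a validated `ss_session`; invariant violations raise an error.
#' @export
read_session <- function(path) {
  need <- c("trials.csv", "spikes.csv", "meta.json")
  for (f in need) {
    if (!file.exists(file.path(path, f)))
      stop(sprintf("session format error: missing %s in %s", f, path),
           call. = FALSE)
  }
  trials <- read.csv(file.path(path, "trials.csv"),
                     colClasses = c(choice = "character"))
  spikes <- read.csv(file.path(path, "spikes.csv"))
  if (!nrow(spikes))
    spikes <- data.frame(neuron_id = integer(), trial_id = integer(),
                         spike_ms = numeric())
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  gt <- NULL
  gtf <- file.path(path, "ground_truth.csv")
  if (file.exists(gtf)) {
    gt <- list(neurons = read.csv(gtf, colClasses =
                                    c(mechanism = "character",
                                      params = "character")))
    gsf <- file.path(path, "ground_truth_switches.csv")
    if (file.exists(gsf)) gt$switches <- read.csv(gsf)
  }
  s <- new_session(trials, spikes, meta$epoch_ms, gt)
  s$meta <- meta
  stop_if_invalid(s, sprintf("read_session('%s')", path))
  s
}

#' Write a session directory
#'
#' Inverse of [read_session()]; lossless round trip (exact for integers and
#' categoricals, below 1e-6 ms for times).
#'
#' @param session a valid `ss_session`.
#' @param path directory to create/overwrite.
#' @export
write_session <- function(session, path) {
  stop_if_invalid(session, "write_session")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path))
    stop(sprintf("write_session: cannot create directory %s", path),
         call. = FALSE)
  wr <- function(df, file)
    write.csv(df, file.path(path, file), row.names = FALSE, quote = FALSE)
  wr(session$trials, "trials.csv")
  wr(session$spikes, "spikes.csv")
  meta <- session$meta %||% list()
  meta$epoch_ms <- session$epoch_ms
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(session$ground_truth)) {
    gtn <- session$ground_truth$neurons
    write.csv(gtn, file.path(path, "ground_truth.csv"), row.names = FALSE)
    if (!is.null(session$ground_truth$switches))
      wr(session$ground_truth$switches, "ground_truth_switches.csv")
  }
  invisible(path)
}
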
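# Small session builders shared across tests.  All fixtures are generated
# in code; nothing is read from disk.

# minimal hand-built valid session (no neurons unless spikes supplied)
tiny_session <- function(n_trials = 6, spikes = NULL) {
  tro <- rep(c(-2, 2), length.out = n_trials)
  trials <- data.frame(
    trial_id = seq_len(n_trials), s1_deg = 90, s2_deg = 90 + tro,
    tro_deg = tro,
    choice = ifelse(tro < 0, "left", "right"),
    correct = TRUE, mt_ms = 300, saccade_ms = 0)
  spikes <- spikes %||% data.frame(neuron_id = integer(),
                                   trial_id = integer(),
                                   spike_ms = numeric())
  new_session(trials, spikes, epoch_ms = c(-1000, 100))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# session with one neuron per requested mechanism
mech_session <- function(mechanisms, trials_per_level = 40, seed = 1, ...) {
  specs <- lapply(seq_along(mechanisms), function(i)
    neuron_spec(i, mechanisms[i], ...))
  generate_session(behavior_params(trials_per_level = trials_per_level),
                   specs, seed = seed)
}
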
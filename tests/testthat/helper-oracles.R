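# Independent oracles shared across test files.

# log-probability of one state path under a Bernoulli-emission HMM
hmm_path_logprob <- function(pth, obs, A, E, pi) {
  p <- log(pi[pth[1]]) + log(ifelse(obs[1] == 1, E[pth[1]], 1 - E[pth[1]]))
  for (t in seq_len(length(obs) - 1)) {
    p <- p + log(A[pth[t], pth[t + 1]]) +
      log(ifelse(obs[t + 1] == 1, E[pth[t + 1]], 1 - E[pth[t + 1]]))
  }
  p
}

# Exhaustive-enumeration check of Viterbi: the decoded path must attain the
# maximal path log-probability, and must equal the enumeration argmax
# whenever that argmax is unique.  Ties are structural, not flukes: a
# single-bin excursion flanked by one state and covering equal observations
# has exactly the same probability wherever it sits among those bins, so
# tied instances admit several MAP paths and any of them is correct.
viterbi_agrees_with_enumeration <- function(obs, A, E, pi, tol = 1e-9) {
  Q <- length(E)
  paths <- as.matrix(do.call(expand.grid, rep(list(seq_len(Q)),
                                              length(obs))))
  lps <- apply(paths, 1, hmm_path_logprob, obs = obs, A = A, E = E, pi = pi)
  best <- max(lps)
  v <- viterbi_decode(obs, list(transition = A, emission = E, initial = pi))
  if (hmm_path_logprob(v, obs, A, E, pi) < best - tol) return(FALSE)
  if (sum(lps >= best - tol) == 1)
    return(identical(as.integer(v), as.integer(paths[which.max(lps), ])))
  TRUE
}

random_hmm <- function(Q = 2) {
  A <- matrix(runif(Q * Q), Q, Q); A <- A / rowSums(A)
  list(A = A, E = runif(Q, 0.05, 0.95), pi = {p <- runif(Q); p / sum(p)})
}
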
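#' Psychometric table: P(choose left) by TRO level
#'
#' @param trials trial data.frame (see [new_session()]).
#' @return data.frame sorted by TRO with `tro_deg`, `n_trials`, `p_left`,
#'   `se` (binomial standard error); levels without trials are omitted.
#' @export
psychometric_table <- function(trials) {
  lv <- sort(unique(trials$tro_deg))
  rows <- lapply(lv, function(t) {
    sub <- trials[trials$tro_deg == t, ]
    p <- mean(sub$choice == "left")
    data.frame(tro_deg = t, n_trials = nrow(sub), p_left = p,
               se = sqrt(p * (1 - p) / nrow(sub)))
  })
  do.call(rbind, rows)
}

#' Movement-time vs TRO correlations by sign and correctness
#'
#' Pearson correlation of MT with signed TRO within each of the four cells
#' {TRO<0, TRO>0} x {correct, error}.  On X-patterned behavior (MT falls
#' with ease on correct trials, rises on errors) the expected sign pattern
#' is (+, -, -, +) for (neg/correct, pos/correct, neg/error, pos/error).
#'
#' @param trials trial data.frame.
#' @return data.frame with one row per cell: `tro_sign`, `outcome`, `r`,
#'   `p_value`, `n`; cells with fewer than 3 trials or fewer than 2 distinct
#'   TRO values are reported with `NA` statistics.
#' @export
mt_tro_correlations <- function(trials) {
  cells <- expand.grid(tro_sign = c("neg", "pos"),
                       outcome = c("correct", "error"),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    keep <- if (cells$tro_sign[i] == "neg") trials$tro_deg < 0
            else trials$tro_deg > 0
    keep <- keep & (trials$correct == (cells$outcome[i] == "correct"))
    sub <- trials[keep, ]
    if (nrow(sub) < 3 || length(unique(sub$tro_deg)) < 2)
      return(data.frame(tro_sign = cells$tro_sign[i],
                        outcome = cells$outcome[i], r = NA_real_,
                        p_value = NA_real_, n = nrow(sub)))
    ct <- cor.test(sub$mt_ms, sub$tro_deg, method = "pearson")
    data.frame(tro_sign = cells$tro_sign[i], outcome = cells$outcome[i],
               r = unname(ct$estimate), p_value = ct$p.value, n = nrow(sub))
  })
  do.call(rbind, rows)
}
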
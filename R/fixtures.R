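#' Worked-example transition fixture for state 120223
#'
#' A reconstructed set of 33 single-epoch transitions from pretreatment
#' state `120223` (aged 18-45, two prior diseases, no complications,
#' haemorrhagic, phlegm-blocking syndrome, level 3): 17 under action `111`
#' improving from score 8 to 5 (level 2, state `120222`), 1 under `111`
#' from 8 to 7 (self-transition, reward 1), 11 under `001` and 4 under
#' `101` with no score change. The resulting outcome table has joint
#' frequencies 0.5151, 0.0303, 0.3333 and 0.1212 and displayed rewards
#' 3, 1, 0, 0. The exact score pairs behind the reward-1 self-transition
#' are one consistent reconstruction (8 to 7).
#'
#' @param score_pairs return the underlying (before, after) score pairs as
#'   columns `score_before` / `score_after` (default `TRUE`).
#' @return `data.table` of 33 episode steps.
#' @export
worked_example_steps <- function(score_pairs = TRUE) {
  spec <- data.table::data.table(
    action = c("111", "111", "001", "101"),
    next_state = c("120222", "120223", "120223", "120223"),
    score_before = c(8L, 8L, 8L, 8L),
    score_after = c(5L, 7L, 8L, 8L),
    n = c(17L, 1L, 11L, 4L))
  steps <- spec[rep(seq_len(.N), n)]
  steps[, `:=`(patient_id = sprintf("W%02d", seq_len(.N)),
               day = 1L,
               state = "120223",
               reward = compute_reward(score_before, score_after),
               terminal = 1L)]
  cols <- c("patient_id", "day", "state", "action", "reward", "next_state",
            "terminal")
  if (score_pairs) cols <- c(cols, "score_before", "score_after")
  steps[, cols, with = FALSE]
}
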
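#' Estimate the empirical finite MDP from episode steps
#'
#' Frequency estimation, no smoothing: for every observed triple
#' `(s, a, s')` the transition count, the conditional probability
#' `P(s'|s,a) = count / support(s,a)`, the joint frequency
#' `count / (steps from s)` and the arithmetic mean of the observed rewards.
#' States and actions are exactly those observed; unobserved pairs carry no
#' estimate and are excluded from optimisation.
#'
#' @param steps episode steps from [build_episodes()].
#' @return object of class `transition_model`: list with `transitions`
#'   (`state`, `action`, `next_state`, `count`, `prob`, `joint_freq`,
#'   `mean_reward`), `support` (`state`, `action`, `n`), `states`, `actions`
#'   and `n_steps`.
#' @export
estimate_model <- function(steps) {
  steps <- data.table::as.data.table(steps)
  if (nrow(steps) == 0L)
    stop("cannot estimate a transition model from zero steps", call. = FALSE)
  need <- c("state", "action", "reward", "next_state")
  if (!all(need %in% names(steps)))
    stop("steps must carry ", paste(need, collapse = ", "), call. = FALSE)
  tr <- steps[, .(count = .N, mean_reward = mean(reward)),
              by = .(state, action, next_state)]
  tr[, prob := count / sum(count), by = .(state, action)]
  tr[, joint_freq := count / sum(count), by = state]
  support <- tr[, .(n = sum(count)), by = .(state, action)]
  data.table::setorder(tr, state, action, next_state)
  data.table::setorder(support, state, action)
  structure(list(transitions = tr[], support = support[],
                 states = sort(unique(c(tr$state, tr$next_state))),
                 actions = sort(unique(tr$action)),
                 n_steps = nrow(steps)),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat("Empirical transition model:", length(x$states), "states,",
      length(x$actions), "actions,", nrow(x$support),
      "supported (s,a) pairs,", x$n_steps, "steps\n")
  invisible(x)
}

trunc4 <- function(x) trunc(x * 1e4) / 1e4

#' Outcome table for one pretreatment state
#'
#' One row per observed (action, next state) pair from the given state, with
#' the mean reward (displayed rounded to the nearest integer) and the joint
#' frequency of the pair among all recorded transitions from that state,
#' displayed truncated to 4 decimals (so the printed column can sum slightly
#' below 1). Rows are ordered by descending count.
#'
#' @param steps episode steps.
#' @param state a six-digit pretreatment state code.
#' @return `data.table` with columns `state`, `action`, `next_state`,
#'   `reward`, `frequency` (plus exact `count` and `mean_reward`).
#' @export
joint_outcome_table <- function(steps, state) {
  steps <- data.table::as.data.table(steps)
  s <- state
  sub <- steps[state == s]
  if (nrow(sub) == 0L)
    stop("state ", s, " never observed as a pretreatment state",
         call. = FALSE)
  out <- sub[, .(count = .N, mean_reward = mean(reward)),
             by = .(action, next_state)]
  out[, `:=`(state = s,
             reward = as.integer(round(mean_reward)),
             frequency = trunc4(count / sum(count)))]
  data.table::setorder(out, -count, action, next_state)
  out[, .(state, action, next_state, reward, frequency, count, mean_reward)]
}

#' Inventory of observed states
#'
#' Distinct pretreatment states with the number of distinct patients
#' observed in each and the distinct treatment combinations taken there,
#' ordered by descending patient count.
#'
#' @param steps episode steps (may be empty).
#' @return `data.table` with columns `state`, `n_patients`, `actions`
#'   (comma-separated codes), `n_actions`.
#' @export
state_inventory <- function(steps) {
  steps <- data.table::as.data.table(steps)
  if (nrow(steps) == 0L)
    return(data.table::data.table(state = character(),
                                  n_patients = integer(),
                                  actions = character(),
                                  n_actions = integer()))
  inv <- steps[, .(n_patients = data.table::uniqueN(patient_id),
                   actions = paste(sort(unique(action)), collapse = ","),
                   n_actions = data.table::uniqueN(action)),
               by = state]
  data.table::setorder(inv, -n_patients, state)
  inv[]
}

#' Write a transition model as delimited text
#'
#' One row per (state, action, next_state) with count, conditional
#' probability and mean reward at full precision. Codes are written as
#' strings so leading zeros survive the round trip.
#'
#' @param model a `transition_model`.
#' @param path output file path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "transition_model"))
  data.table::fwrite(
    model$transitions[, .(state, action, next_state, count,
                          cond_prob = prob, mean_reward)],
    path, sep = "\t", quote = TRUE)
  invisible(path)
}

#' Read a transition model written by [write_model()]
#'
#' @param path file path.
#' @return a `transition_model` (joint frequencies recomputed from counts).
#' @export
read_model <- function(path) {
  tr <- data.table::fread(path, sep = "\t",
                          colClasses = list(character = c("state", "action",
                                                          "next_state")))
  tr[, `:=`(prob = cond_prob, cond_prob = NULL)]
  tr[, joint_freq := count / sum(count), by = state]
  support <- tr[, .(n = sum(count)), by = .(state, action)]
  structure(list(transitions = tr[], support = support[],
                 states = sort(unique(c(tr$state, tr$next_state))),
                 actions = sort(unique(tr$action)),
                 n_steps = sum(tr$count)),
            class = "transition_model")
}
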
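#' Monte Carlo control solver configuration
#'
#' @param n_episodes number of exploring-starts episodes (default 500,000,
#'   the reference episode budget).
#' @param seed integer RNG seed.
#' @param horizon maximum steps per simulated episode (default 21, the
#'   number of 7-day epochs in 147 days).
#' @param visit_mode `"first_visit"` (default) or `"every_visit"` return
#'   averaging. First-visit is the classical exploring-starts formulation;
#'   on cyclic empirical chains it recovers the exact-oracle optimum more
#'   reliably, because every-visit mixes suffix returns of many depths into
#'   one mean (see the methods vignette).
#' @param q_init `"zero"` (default) or `"random"` (uniform on \[-1, 1\])
#'   initialisation of the action-value table.
#' @return object of class `solver_config`.
#' @export
solver_config <- function(n_episodes = 500000L, seed = 1L, horizon = 21L,
                          visit_mode = c("first_visit", "every_visit"),
                          q_init = c("zero", "random")) {
  if (!is.numeric(n_episodes) || n_episodes < 1)
    stop("n_episodes must be >= 1", call. = FALSE)
  if (!is.numeric(horizon) || horizon < 1)
    stop("horizon must be >= 1", call. = FALSE)
  structure(list(n_episodes = as.integer(n_episodes),
                 seed = as.integer(seed), horizon = as.integer(horizon),
                 visit_mode = match.arg(visit_mode),
                 q_init = match.arg(q_init)),
            class = "solver_config")
}

# Flatten a transition_model into integer-indexed arrays for the C++ loop
# and the R episode simulator. States and actions are sorted, so action
# index order is the lexicographic tie-break order.
model_index <- function(model) {
  stopifnot(inherits(model, "transition_model"))
  states <- model$states
  actions <- model$actions
  tr <- data.table::copy(model$transitions)
  tr[, `:=`(si = match(state, states) - 1L,
            ai = match(action, actions) - 1L,
            ni = match(next_state, states) - 1L)]
  data.table::setorder(tr, si, ai, ni)
  pairs <- tr[, .(first = .I[1], len = .N), by = .(si, ai)]
  data.table::setorder(pairs, si, ai)
  pairs[, pair := .I - 1L]
  state_pairs <- pairs[, .(first_pair = pair[1], n_pairs = .N), by = si]
  sp_first <- sp_n <- integer(length(states))
  sp_first[state_pairs$si + 1L] <- state_pairs$first_pair
  sp_n[state_pairs$si + 1L] <- state_pairs$n_pairs
  cum <- tr[, .(c = cumsum(prob)), by = .(si, ai)]$c
  list(states = states, actions = actions,
       pair_s = pairs$si, pair_a = pairs$ai,
       pair_off = pairs$first - 1L, pair_len = pairs$len,
       t_next = tr$ni, t_cum = cum, t_rew = tr$mean_reward,
       sp_first = sp_first, sp_n = sp_n)
}

#' Simulate one episode on the empirical model
#'
#' The first transition is sampled from the model at the given
#' state-action pair; thereafter actions follow `policy` where defined and
#' a uniform draw over the supported actions elsewhere. The episode ends on
#' reaching a state with no supported actions (e.g. one only ever observed
#' as a post-treatment state) or after `horizon` steps. Uses R's RNG: seed
#' with `set.seed()` for reproducibility.
#'
#' @param model a `transition_model`.
#' @param start_state,start_action a supported pair.
#' @param policy optional policy `data.table` (`state`, `action`).
#' @param horizon maximum number of steps.
#' @return `data.table` with columns `state`, `action`, `reward`.
#' @export
simulate_episode <- function(model, start_state, start_action, policy = NULL,
                             horizon = 21L) {
  stopifnot(inherits(model, "transition_model"))
  sup <- model$support
  if (nrow(sup[state == start_state & action == start_action]) == 0L)
    stop("unsupported start pair (", start_state, ", ", start_action, ")",
         call. = FALSE)
  pol <- NULL
  if (!is.null(policy)) {
    policy <- data.table::as.data.table(policy)
    pol <- setNames(policy$action, policy$state)
  }
  tr <- model$transitions
  s <- start_state; a <- start_action
  out <- vector("list", horizon)
  for (k in seq_len(horizon)) {
    cand <- tr[state == s & action == a]
    out_k <- cand[findInterval(runif(1), cumsum(prob) - 1e-12) + 1L]
    out[[k]] <- data.table::data.table(state = s, action = a,
                                       reward = out_k$mean_reward)
    s <- out_k$next_state
    sup_a <- sup[state == s, action]
    if (length(sup_a) == 0L) break
    a <- if (!is.null(pol) && !is.na(pol[s])) pol[[s]]
         else sup_a[sample.int(length(sup_a), 1L)]
    if (!a %in% sup_a) a <- sup_a[sample.int(length(sup_a), 1L)]
  }
  data.table::rbindlist(out)
}

#' Solve the empirical MDP by Monte Carlo control with exploring starts
#'
#' Each episode starts at a uniformly drawn supported state-action pair,
#' then follows the current greedy policy on the empirical model. The
#' undiscounted return from every (first) visit is appended to that pair's
#' return list and the action value is its running mean; after each episode
#' the policy is set to the action-value-maximising action at the visited
#' states (ties broken by lexicographically smallest action code). Fully
#' reproducible from the seed.
#'
#' @param model a `transition_model`.
#' @param config a [solver_config()].
#' @return list with `q` (`data.table`: `state`, `action`, `q_value`,
#'   `n_returns`) and `policy` (`state`, `action`, `q_value`), plus the
#'   `config` used.
#' @export
run_mc_control <- function(model, config = solver_config()) {
  stopifnot(inherits(model, "transition_model"),
            inherits(config, "solver_config"))
  idx <- model_index(model)
  if (length(idx$pair_s) == 0L)
    stop("model has no supported state-action pairs", call. = FALSE)
  set.seed(config$seed)
  res <- mc_control_cpp(idx$pair_s, idx$pair_a, idx$pair_off, idx$pair_len,
                        idx$t_next, idx$t_cum, idx$t_rew,
                        idx$sp_first, idx$sp_n,
                        length(idx$states), config$n_episodes,
                        config$horizon,
                        config$visit_mode == "first_visit",
                        config$q_init == "random")
  q <- data.table::data.table(state = idx$states[idx$pair_s + 1L],
                              action = idx$actions[idx$pair_a + 1L],
                              q_value = res$q, n_returns = res$n)
  data.table::setorder(q, state, action)
  list(q = q[], policy = extract_policy(q), config = config)
}

#' Exact finite-horizon action values by backward induction
#'
#' Verification oracle for the Monte Carlo estimate:
#' `Q_1(s,a) = sum_s' P(s'|s,a) R(s,a,s')` and
#' `Q_{k+1}(s,a) = sum_s' P(s'|s,a) [R(s,a,s') + max_a' Q_k(s',a')]`,
#' with the maximum over an empty supported-action set taken as 0.
#'
#' @param model a `transition_model`.
#' @param horizon number of backward-induction sweeps (>= 1).
#' @return `data.table` with columns `state`, `action`, `q_value`.
#' @export
exact_q <- function(model, horizon = 21L) {
  stopifnot(inherits(model, "transition_model"))
  if (!is.numeric(horizon) || horizon < 1)
    stop("horizon must be >= 1", call. = FALSE)
  tr <- model$transitions[, .(state, action, next_state, prob, mean_reward)]
  v <- setNames(numeric(length(model$states)), model$states)
  q <- NULL
  for (k in seq_len(horizon)) {
    tr[, vn := v[next_state]]
    q <- tr[, .(q_value = sum(prob * (mean_reward + vn))),
            by = .(state, action)]
    vmax <- q[, .(v = max(q_value)), by = state]
    v[] <- 0
    v[vmax$state] <- vmax$v
  }
  data.table::setorder(q, state, action)
  q[]
}

#' Extract the greedy policy from an action-value table
#'
#' Per state, the supported action with maximal value; exact ties go to the
#' lexicographically smallest action code. States with no supported action
#' are omitted.
#'
#' @param q `data.table` with columns `state`, `action`, `q_value`.
#' @return `data.table` with columns `state`, `action`, `q_value`.
#' @export
extract_policy <- function(q) {
  q <- data.table::as.data.table(q)
  if (nrow(q) == 0L) stop("empty action-value table", call. = FALSE)
  pol <- q[order(state, -q_value, action),
           .SD[1L, .(action, q_value)], by = state]
  data.table::setorder(pol, state)
  pol[]
}
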
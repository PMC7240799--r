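# Builders shared across test files. All fixtures are constructed in code.

# Assemble a transition_model directly from a transitions table
# (state, action, next_state, prob, mean_reward [, count]).
make_model <- function(tr) {
  tr <- data.table::as.data.table(tr)
  if (!"count" %in% names(tr)) tr[, count := 10L]
  tr[, joint_freq := count / sum(count), by = state]
  support <- tr[, .(n = sum(count)), by = .(state, action)]
  data.table::setorder(tr, state, action, next_state)
  structure(list(transitions = tr[], support = support[],
                 states = sort(unique(c(tr$state, tr$next_state))),
                 actions = sort(unique(tr$action)),
                 n_steps = sum(tr$count)),
            class = "transition_model")
}

# Random episodic 5-state, 3-action model: transitions go only to strictly
# later states or the absorbing terminal "T", so every episode ends within
# n_states steps and finite-horizon backward induction (horizon >= n_states)
# equals the episodic optimum the Monte Carlo solver estimates.
layered_model <- function(seed, n_states = 5, n_actions = 3) {
  set.seed(seed)
  states <- sprintf("S%d", seq_len(n_states))
  actions <- sprintf("a%d", seq_len(n_actions))
  rows <- list()
  for (i in seq_len(n_states)) {
    succ <- c(if (i < n_states) states[(i + 1):n_states], "T")
    for (a in actions) {
      k <- sample(seq_along(succ), 1L)
      dest <- sample(succ, k)
      w <- runif(k) + 0.05
      rows[[length(rows) + 1L]] <- data.table::data.table(
        state = states[i], action = a, next_state = dest,
        prob = w / sum(w),
        mean_reward = sample(-3:3, k, replace = TRUE))
    }
  }
  make_model(data.table::rbindlist(rows))
}

# Two-action bandit: one state, both actions absorbing.
bandit_model <- function(r_good = 3, r_bad = 0) {
  make_model(data.table::data.table(
    state = "s", action = c("111", "000"), next_state = "T",
    prob = 1, mean_reward = c(r_good, r_bad)))
}

# Deterministic chain s1 -a-> s2 -a-> T with rewards 1 then 2.
chain_model <- function() {
  make_model(data.table::data.table(
    state = c("s1", "s2"), action = "a", next_state = c("s2", "T"),
    prob = 1, mean_reward = c(1, 2)))
}

# Small default-world cohort for integration tests.
tiny_cohort <- function(n = 300, seed = 11, ...) {
  generate_cohort(cohort_config(n_patients = n, seed = seed, ...))
}

# Max-norm difference between two q tables on their shared pairs.
q_maxdiff <- function(q1, q2) {
  m <- merge(q1, q2, by = c("state", "action"))
  max(abs(m$q_value.x - m$q_value.y))
}
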
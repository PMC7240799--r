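test_that("degenerate bandit: Q is exact and the policy picks the payer", {
  m <- bandit_model(r_good = 3, r_bad = 0)
  sol <- run_mc_control(m, solver_config(n_episodes = 200, seed = 1))
  expect_identical(sol$policy$action, "111")
  # deterministic absorbing rewards: the running mean has zero variance
  expect_identical(sol$q[action == "111", q_value], 3)
  expect_identical(sol$q[action == "000", q_value], 0)
  expect_identical(sum(sol$q$n_returns), 200L)

  ex <- exact_q(m, horizon = 7)
  expect_identical(ex[action == "111", q_value], 3)
})

test_that("chain model: returns add up and episodes replay deterministically", {
  m <- chain_model()
  expect_identical(exact_q(m, horizon = 1)[state == "s1", q_value], 1)
  expect_identical(exact_q(m, horizon = 2)[state == "s1", q_value], 3)
  expect_identical(exact_q(m, horizon = 21)[state == "s1", q_value], 3)
  expect_error(exact_q(m, horizon = 0), "horizon")

  set.seed(99)
  ep <- simulate_episode(m, "s1", "a")
  expect_identical(ep$state, c("s1", "s2"))
  expect_identical(ep$reward, c(1, 2))
  set.seed(123); e1 <- simulate_episode(m, "s1", "a")
  set.seed(123); e2 <- simulate_episode(m, "s1", "a")
  expect_identical(e1, e2)
  expect_error(simulate_episode(m, "s1", "zzz"), "unsupported start")

  sol <- run_mc_control(m, solver_config(n_episodes = 100, seed = 2))
  expect_identical(sol$q[state == "s1", q_value], 3)
  expect_identical(sol$q[state == "s2", q_value], 2)
})

test_that("exact_q reproduces the worked-example expectation", {
  m <- estimate_model(worked_example_steps())
  q1 <- exact_q(m, horizon = 1)
  expect_equal(q1[state == "120223" & action == "111", q_value],
               (17 * 3 + 1 * 1) / 18, tolerance = 1e-12)
  expect_equal(q1[state == "120223" & action == "111", q_value], 2.8889,
               tolerance = 1e-4)
})

test_that("Monte Carlo control matches backward induction on random models", {
  for (sd in c(101, 202)) {
    m <- layered_model(seed = sd)
    ex <- exact_q(m, horizon = 6)
    sol <- run_mc_control(m, solver_config(n_episodes = 200000, seed = sd))
    expect_lt(q_maxdiff(sol$q, ex), 0.1)
  }
})

test_that("solver runs are reproducible and visit modes agree on DAGs", {
  m <- layered_model(seed = 7)
  cfg <- solver_config(n_episodes = 5000, seed = 11)
  s1 <- run_mc_control(m, cfg)
  s2 <- run_mc_control(m, cfg)
  expect_identical(s1$q, s2$q)
  expect_identical(s1$policy, s2$policy)

  # no state is revisited in a layered model, so first-visit and
  # every-visit averaging coincide step for step
  ev <- run_mc_control(m, solver_config(n_episodes = 5000, seed = 11,
                                        visit_mode = "every_visit"))
  expect_identical(s1$q, ev$q)

  # random Q init is seeded and washes out with episodes
  r1 <- run_mc_control(m, solver_config(n_episodes = 100000, seed = 5,
                                        q_init = "random"))
  expect_lt(q_maxdiff(r1$q, exact_q(m, horizon = 6)), 0.15)
})

test_that("policy extraction maximises with lexicographic tie-break", {
  q <- data.table::data.table(
    state = c("s", "s", "t", "t"),
    action = c("001", "100", "100", "001"),
    q_value = c(2, 1, 2, 2))
  pol <- extract_policy(q)
  expect_identical(pol[state == "s", action], "001")
  expect_identical(pol[state == "t", action], "001")  # exact tie
  expect_identical(nrow(pol), 2L)
  expect_error(extract_policy(q[0]), "empty")

  # positive rescaling of all rewards leaves the argmax unchanged
  m <- layered_model(seed = 31)
  m2 <- m
  m2$transitions <- data.table::copy(m$transitions)[
    , mean_reward := mean_reward * 2.5]
  p1 <- extract_policy(exact_q(m, horizon = 6))
  p2 <- extract_policy(exact_q(m2, horizon = 6))
  expect_identical(p1$action, p2$action)
})

test_that("episodes terminate on unsupported states and the horizon cap", {
  # self-loop with reward 1: only the horizon stops it
  loop <- make_model(data.table::data.table(
    state = "s", action = "a", next_state = "s", prob = 1, mean_reward = 1))
  set.seed(1)
  ep <- simulate_episode(loop, "s", "a", horizon = 4)
  expect_identical(nrow(ep), 4L)
  expect_identical(exact_q(loop, horizon = 21)[, q_value], 21)

  # every-visit averaging on the cycle sees suffix returns 21, 20, ..., 1;
  # first-visit sees only the full 21-step return
  ev <- run_mc_control(loop, solver_config(n_episodes = 50, seed = 3,
                                           horizon = 21,
                                           visit_mode = "every_visit"))
  expect_equal(ev$q$q_value, mean(1:21))
  fv <- run_mc_control(loop, solver_config(n_episodes = 50, seed = 3,
                                           horizon = 21,
                                           visit_mode = "first_visit"))
  expect_identical(fv$q$q_value, 21)
})
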
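test_that("estimate_model computes exact frequency estimates", {
  one <- data.table::data.table(patient_id = "P1", day = 1L,
                                state = "120223", action = "111",
                                reward = 3L, next_state = "120222",
                                terminal = 1L)
  m <- estimate_model(one)
  expect_identical(m$transitions$prob, 1)
  expect_identical(m$transitions$mean_reward, 3)
  expect_identical(m$n_steps, 1L)
  expect_error(estimate_model(one[0]), "zero steps")

  wx <- worked_example_steps()
  mw <- estimate_model(wx)
  tr <- mw$transitions
  expect_equal(tr[state == "120223" & action == "111" &
                  next_state == "120222", prob], 17 / 18)
  expect_identical(mw$support[state == "120223" & action == "001", n], 11L)
  expect_identical(mw$support[state == "120223" & action == "111", n], 18L)
})

test_that("the worked-example outcome table matches the printed cells", {
  wx <- worked_example_steps()
  tab <- joint_outcome_table(wx, "120223")
  expect_identical(nrow(tab), 4L)
  row111 <- tab[action == "111" & next_state == "120222"]
  expect_identical(row111$frequency, 0.5151)
  expect_identical(row111$reward, 3L)
  expect_identical(tab[action == "111" & next_state == "120223",
                       .(frequency, reward)],
                   data.table::data.table(frequency = 0.0303, reward = 1L))
  expect_identical(tab[action == "001", frequency], 0.3333)
  expect_identical(tab[action == "101", frequency], 0.1212)
  # joint frequencies sum to 1 within 4-decimal truncation error
  expect_lt(abs(sum(tab$count / sum(tab$count)) - 1), 1e-12)
  expect_lt(abs(sum(tab$frequency) - 1), 4e-4)
  expect_error(joint_outcome_table(wx, "999999"), "never observed")

  single <- wx[1]
  expect_identical(joint_outcome_table(single, "120223")$frequency, 1)
})

test_that("conservation and normalization hold on a generated cohort", {
  coh <- tiny_cohort(n = 400, seed = 17)
  steps <- build_episodes(coh$patients, coh$visits)
  m <- estimate_model(steps)
  expect_identical(sum(m$transitions$count), nrow(steps))
  norm <- m$transitions[, .(s = sum(prob)), by = .(state, action)]
  expect_lt(max(abs(norm$s - 1)), 1e-9)
  joint <- m$transitions[, .(s = sum(joint_freq)), by = state]
  expect_lt(max(abs(joint$s - 1)), 1e-9)
  expect_identical(
    m$support[order(state, action)],
    steps[, .(n = .N), by = .(state, action)][order(state, action)])
})

test_that("estimates converge to a known generating kernel", {
  # two states, one action, hand-specified kernel as the oracle
  kernel <- c(A = 0.7, B = 0.3)
  set.seed(42)
  n <- 2000L
  dest <- sample(names(kernel), n, replace = TRUE, prob = kernel)
  steps <- data.table::data.table(
    patient_id = sprintf("P%d", seq_len(n)), day = 1L, state = "A",
    action = "x", reward = ifelse(dest == "A", 1L, 0L),
    next_state = dest, terminal = 1L)
  m <- estimate_model(steps)
  est <- setNames(m$transitions$prob, m$transitions$next_state)
  expect_lt(max(abs(est[names(kernel)] - kernel)), 0.05)
})

test_that("state_inventory counts distinct patients per state", {
  expect_identical(nrow(state_inventory(worked_example_steps()[0])), 0L)

  steps <- data.table::rbindlist(lapply(1:34, function(i)
    data.table::data.table(patient_id = sprintf("Q%02d", i), day = 1L,
                           state = "320123", action = c("000", "111")[1 + i %% 2],
                           reward = 0L, next_state = "320123",
                           terminal = 1L)))
  inv <- state_inventory(steps)
  expect_identical(inv$state, "320123")
  expect_identical(inv$n_patients, 34L)
  expect_identical(inv$actions, "000,111")

  # one patient revisiting a state is counted once
  rep2 <- data.table::copy(steps)[, patient_id := "Q01"]
  expect_identical(state_inventory(rep2)$n_patients, 1L)

  coh <- tiny_cohort(n = 120, seed = 23)
  st <- build_episodes(coh$patients, coh$visits)
  inv2 <- state_inventory(st)
  expect_true(all(diff(inv2$n_patients) <= 0))
  expect_identical(sort(unique(st$state)), sort(inv2$state))
})

test_that("models round-trip through delimited text", {
  coh <- tiny_cohort(n = 80, seed = 29)
  m <- estimate_model(build_episodes(coh$patients, coh$visits))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(m2$states, m$states)
  expect_identical(m2$actions, m$actions)
  expect_equal(as.data.frame(m2$transitions[order(state, action, next_state),
                                            .(state, action, next_state,
                                              count, prob, mean_reward)]),
               as.data.frame(m$transitions[order(state, action, next_state),
                                           .(state, action, next_state,
                                             count, prob, mean_reward)]))
})
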
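mk_visits <- function(days, scores, acts = NULL, death = NULL,
                      pid = "P1") {
  k <- length(days)
  if (is.null(acts)) acts <- rep("111", k)
  if (is.null(death)) death <- rep(0L, k)
  data.table::data.table(
    patient_id = pid, day = as.integer(days), score = as.integer(scores),
    a1 = as.integer(substr(acts, 1, 1)), a2 = as.integer(substr(acts, 2, 2)),
    a3 = as.integer(substr(acts, 3, 3)), death_flag = as.integer(death))
}

mk_patient <- function(pid = "P1", age = 1, hist = 2, comp = 0, diag = 2,
                       synd = 2) {
  data.table::data.table(patient_id = pid, age_band = age, history = hist,
                         complication = comp, diagnosis = diag,
                         syndrome = synd)
}

test_that("clean_records drops abnormal rows and reports counts", {
  v <- mk_visits(c(1, 8, 15), c(8, 35, 5))
  out <- suppressMessages(clean_records(v))
  expect_identical(nrow(out), 2L)
  expect_identical(attr(out, "n_removed"), 1L)

  ok <- mk_visits(c(1, 8), c(8, 5))
  out2 <- suppressMessages(clean_records(ok))
  expect_equal(as.data.frame(out2), as.data.frame(ok), ignore_attr = TRUE)
  expect_identical(attr(out2, "n_removed"), 0L)

  bad_bit <- mk_visits(c(1, 8), c(8, 5))
  bad_bit$a2[2] <- 7L
  expect_identical(nrow(suppressMessages(clean_records(bad_bit))), 1L)

  dup <- rbind(mk_visits(1, 8), mk_visits(c(1, 8), c(8, 5)))
  expect_error(clean_records(dup), "duplicate")

  p <- mk_patient(); p$syndrome <- 9L
  expect_identical(nrow(suppressMessages(clean_records(p))), 0L)
})

test_that("fill_missing draws uniformly over valid categories, seeded", {
  p <- mk_patient(pid = sprintf("P%02d", 1:40))
  p$syndrome[1:20] <- NA_integer_
  f1 <- suppressMessages(fill_missing(p, seed = 7))
  f2 <- suppressMessages(fill_missing(p, seed = 7))
  expect_identical(f1, f2)
  expect_true(all(f1$syndrome %in% 1:5))
  expect_identical(attr(f1, "n_filled"), 20L)

  v <- mk_visits(c(1, 8), c(8, NA))
  fv <- suppressMessages(fill_missing(v, seed = 1))
  expect_true(fv$score[2] %in% 0:29)

  clean <- mk_visits(c(1, 8), c(8, 5))
  expect_equal(
    as.data.frame(suppressMessages(fill_missing(clean, seed = 1))),
    as.data.frame(clean), ignore_attr = TRUE)

  v2 <- mk_visits(c(1, 8), c(8, 5)); v2$day[1] <- NA_integer_
  expect_error(fill_missing(v2, seed = 1), "never fillable")
  v3 <- mk_visits(c(1, 8), c(8, 5)); v3$a3[1] <- NA_integer_
  expect_error(fill_missing(v3, seed = 1), "never fillable")
})

test_that("build_episodes reproduces the worked-example step", {
  steps <- build_episodes(mk_patient(), mk_visits(c(1, 8), c(8, 5)))
  expect_identical(nrow(steps), 1L)
  expect_identical(steps$state, "120223")
  expect_identical(steps$action, "111")
  expect_identical(steps$reward, 3L)
  expect_identical(steps$next_state, "120222")
  expect_identical(steps$terminal, 1L)
})

test_that("the day cap keeps decision epochs through day 147 only", {
  days <- seq(1, 197, by = 7)  # a 200-day stay
  v <- mk_visits(days, rep(10, length(days)))
  steps <- build_episodes(mk_patient(), v)
  expect_true(all(steps$day <= 147))
  expect_identical(nrow(steps), 21L)   # starts at days 1, 8, ..., 141
  expect_identical(max(steps$day), 141L)
  expect_identical(steps$terminal, c(rep(0L, 20), 1L))
})

test_that("death terminates the episode with score 29 and level 5", {
  v <- mk_visits(c(1, 8), c(8, 29), death = c(0, 1))
  steps <- build_episodes(mk_patient(), v)
  expect_identical(nrow(steps), 1L)
  expect_identical(steps$next_state, "120225")
  expect_identical(steps$reward, -21L)
  expect_identical(steps$terminal, 1L)
  # nothing may follow a death visit
  v2 <- rbind(v, mk_visits(15, 10))
  expect_identical(build_episodes(mk_patient(), v2), steps)
})

test_that("off-grid visit days raise an alignment error", {
  expect_error(build_episodes(mk_patient(), mk_visits(c(1, 5), c(8, 5))),
               "epoch grid")
  # gaps on the grid do not form steps
  steps <- build_episodes(mk_patient(), mk_visits(c(1, 15), c(8, 5)))
  expect_identical(nrow(steps), 0L)
})

test_that("step counts and reward telescoping hold on generated cohorts", {
  coh <- tiny_cohort(n = 150, seed = 13)
  steps <- build_episodes(coh$patients, coh$visits)

  n_visits <- coh$visits[, .N, by = patient_id]
  n_steps <- steps[, .N, by = patient_id]
  both <- merge(n_visits, n_steps, by = "patient_id", all.x = TRUE)
  both[is.na(N.y), N.y := 0L]
  expect_identical(both$N.y, pmax(both$N.x - 1L, 0L))

  sums <- steps[, .(total = sum(reward)), by = patient_id]
  ends <- coh$visits[order(patient_id, day),
                     .(first = score[1L], last = score[.N]),
                     by = patient_id]
  both2 <- merge(sums, ends, by = "patient_id")
  expect_identical(both2$total, both2$first - both2$last)

  expect_true(all(steps$action %in% action_set()))
  expect_silent(decode_state(unique(c(steps$state, steps$next_state))))
  # exactly one terminal step per contributing patient, and it is the last
  expect_true(all(steps[, sum(terminal), by = patient_id]$V1 == 1L))
  expect_true(all(steps[order(patient_id, day), .SD[.N], by = patient_id,
                        .SDcols = "terminal"]$terminal == 1L))
})
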
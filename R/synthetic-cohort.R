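#' Default attribute marginals for the synthetic cohort
#'
#' Category frequencies of the six state attributes in the reference
#' convalescence cohort (N = 835): age band 51/251/533, disease history
#' 76/262/497, complications 614/221, diagnosis 637/198, TCM syndrome
#' 13/498/64/227/33, and admission impairment level 89/138/398/171/8
#' (levels among the 804 complete records). Each vector sums to 1.
#'
#' @return named list of per-attribute probability vectors, names matching
#'   the category digits.
#' @export
reference_marginals <- function() {
  list(
    age_band     = c(`1` = 51, `2` = 251, `3` = 533) / 835,
    history      = c(`0` = 76, `1` = 262, `2` = 497) / 835,
    complication = c(`0` = 614, `1` = 221) / 835,
    diagnosis    = c(`1` = 637, `2` = 198) / 835,
    syndrome     = c(`1` = 13, `2` = 498, `3` = 64, `4` = 227, `5` = 33) / 835,
    level        = c(`1` = 89, `2` = 138, `3` = 398, `4` = 171, `5` = 8) / 804
  )
}

#' Treatment-effect model for the synthetic cohort
#'
#' Describes per-epoch score dynamics: the score change of an untreated
#' patient (`baseline_drift`, negative mean = deterioration), the additional
#' mean improvement of each treatment combination (`action_effects`),
#' an optional per-severity-band multiplier on the action effects
#' (`severity_modifier`), Gaussian score noise (`noise_sd`) and a per-epoch
#' probability of death from other causes (`death_prob`). Deterioration past
#' the top of the score scale (29) is always fatal and absorbing.
#'
#' Exactly one action per severity band must have strictly maximal expected
#' improvement: this is the planted optimum that [planted_policy()] exposes
#' and solver-recovery tests target.
#'
#' The defaults state a stylised world in which the finite decision horizon
#' is informative: untreated patients deteriorate by 2.5 points/epoch,
#' single and dual therapies only slow deterioration, and the full
#' rehabilitation + herbal + acupuncture combination ("111") achieves net
#' recovery (+1.5 points/epoch). The planted gap between the best and
#' second-best action effect is 3 points.
#'
#' @param baseline_drift numeric `c(mean, sd)` of the untreated per-epoch
#'   score improvement (negative mean = worsening), points.
#' @param action_effects named numeric vector over all eight action codes:
#'   mean additional improvement per epoch, points.
#' @param severity_modifier multiplier applied to the action effects per
#'   severity band: a list with elements `mild` and `moderate_to_severe`,
#'   each either a single number or a named vector over the eight action
#'   codes (so the best action may differ between bands).
#' @param noise_sd standard deviation of additional per-epoch score noise.
#' @param death_prob per-epoch probability of death, in `[0, 1)`.
#' @return an object of class `effect_model`.
#' @export
effect_model <- function(baseline_drift = c(mean = -2.5, sd = 0.5),
                         action_effects = c(
                           "000" = 0, "001" = 0.5, "010" = 0.5, "100" = 0.5,
                           "011" = 1, "101" = 1, "110" = 1, "111" = 4),
                         severity_modifier = list(mild = 1,
                                                  moderate_to_severe = 1),
                         noise_sd = 1,
                         death_prob = 0.005) {
  if (length(baseline_drift) != 2L || baseline_drift[[2]] < 0)
    stop("baseline_drift must be c(mean, sd) with sd >= 0", call. = FALSE)
  if (!setequal(names(action_effects), action_set()))
    stop("action_effects must name all eight action codes", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.numeric(death_prob) || death_prob < 0 || death_prob >= 1)
    stop("death_prob must lie in [0, 1)", call. = FALSE)
  if (!setequal(names(severity_modifier), c("mild", "moderate_to_severe")))
    stop("severity_modifier must name both severity bands", call. = FALSE)
  acts <- action_set("lexicographic")
  norm_mod <- function(x) {
    if (length(x) == 1L && is.null(names(x))) return(setNames(rep(x, 8), acts))
    if (!setequal(names(x), acts))
      stop("a per-action severity modifier must name all eight actions",
           call. = FALSE)
    x[acts]
  }
  severity_modifier <- lapply(severity_modifier, norm_mod)
  m <- structure(
    list(baseline_drift = c(mean = unname(baseline_drift[[1]]),
                            sd = unname(baseline_drift[[2]])),
         action_effects = action_effects[acts],
         severity_modifier = severity_modifier,
         noise_sd = noise_sd, death_prob = death_prob),
    class = "effect_model")
  for (band in names(severity_modifier)) {
    eff <- sort(expected_improvement(m, action_set(), band),
                decreasing = TRUE)
    if (eff[1] == eff[2])
      stop("ambiguous planted optimum in band ", band,
           ": two actions tie at maximal expected improvement",
           call. = FALSE)
  }
  m
}

#' Expected one-epoch score improvement under an effect model
#'
#' @param model an [effect_model()].
#' @param action character vector of action codes.
#' @param band `"mild"` or `"moderate_to_severe"`.
#' @return named numeric vector of expected improvements, points.
#' @export
expected_improvement <- function(model, action, band) {
  stopifnot(inherits(model, "effect_model"))
  band <- match.arg(band, c("mild", "moderate_to_severe"))
  eff <- model$action_effects[action] *
    model$severity_modifier[[band]][action]
  setNames(model$baseline_drift[["mean"]] + unname(eff), action)
}

#' Configuration of a synthetic longitudinal cohort
#'
#' @param n_patients number of patients (>= 0).
#' @param seed integer RNG seed; the whole cohort is reproducible from it.
#' @param marginals per-attribute category frequencies, default
#'   [reference_marginals()]. Each vector must sum to 1 (tolerance 1e-9).
#' @param effect_model an [effect_model()].
#' @param max_day last admissible decision day (default 147).
#' @param epoch_days spacing of decision epochs in days (default 7).
#' @param missing_rate fraction of eligible attribute/score cells blanked,
#'   in `[0, 1)` (default 0).
#' @param logging_policy `"uniform"` assigns each epoch's treatment uniformly
#'   over the eight actions (guaranteeing support of every state-action
#'   pair); `"weighted"` draws actions with probability proportional to
#'   `logging_weights`.
#' @param logging_weights named non-negative weights over the eight action
#'   codes, used when `logging_policy = "weighted"`.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients, seed = 1L,
                          marginals = reference_marginals(),
                          effect_model = strokemdp::effect_model(),
                          max_day = 147L, epoch_days = 7L,
                          missing_rate = 0,
                          logging_policy = c("uniform", "weighted"),
                          logging_weights = NULL) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 0)
    stop("n_patients must be a single count >= 0", call. = FALSE)
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  if (!setequal(names(marginals), ATTR_NAMES))
    stop("marginals must name all six attributes", call. = FALSE)
  for (nm in ATTR_NAMES) {
    p <- marginals[[nm]]
    if (!setequal(names(p), as.character(ATTR_DOMAINS[[nm]])))
      stop("marginals$", nm, " must name every category", call. = FALSE)
    if (abs(sum(p) - 1) > 1e-9 || any(p < 0))
      stop("marginals$", nm, " must be non-negative and sum to 1",
           call. = FALSE)
  }
  logging_policy <- match.arg(logging_policy)
  if (logging_policy == "weighted") {
    if (is.null(logging_weights) ||
        !setequal(names(logging_weights), action_set()) ||
        any(logging_weights < 0) || sum(logging_weights) <= 0)
      stop("logging_weights must be non-negative over all eight actions",
           call. = FALSE)
  }
  stopifnot(inherits(effect_model, "effect_model"),
            epoch_days >= 1, max_day >= 1)
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 marginals = marginals[ATTR_NAMES],
                 effect_model = effect_model,
                 max_day = as.integer(max_day),
                 epoch_days = as.integer(epoch_days),
                 missing_rate = missing_rate,
                 logging_policy = logging_policy,
                 logging_weights = logging_weights),
            class = "cohort_config")
}

#' Ground-truth optimal action per state under an effect model
#'
#' For every encodable state, the action with strictly maximal expected
#' one-epoch improvement under the configured effect model. This is the
#' planted optimum that Monte Carlo control is expected to recover from a
#' sufficiently large cohort.
#'
#' @param config a [cohort_config()] (only its effect model is used).
#' @return `data.table` with columns `state`, `action`.
#' @export
planted_policy <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  best <- vapply(c("mild", "moderate_to_severe"), function(band) {
    eff <- expected_improvement(config$effect_model,
                                action_set("lexicographic"), band)
    names(eff)[which.max(eff)]
  }, character(1))
  grid <- do.call(data.table::CJ, ATTR_DOMAINS)
  state <- with(grid, encode_state(age_band, history, complication,
                                   diagnosis, syndrome, level))
  data.table::data.table(
    state = state,
    action = unname(best[severity_band(grid$level)]))[order(state)]
}

sample_cat <- function(n, p) {
  as.integer(names(p))[sample.int(length(p), n, replace = TRUE, prob = p)]
}

#' Generate a seeded synthetic longitudinal cohort
#'
#' Draws `n_patients` patients with admission attributes from the configured
#' marginals, then simulates visit sequences on the epoch grid (day 1, 8,
#' 15, ... up to `max_day`). Each epoch the logging policy assigns one of
#' the eight treatment combinations; the score then changes by the baseline
#' drift plus the action's effect plus Gaussian noise, rounded and clipped
#' to 0..29. A score driven to the top of the scale, or a random death
#' event, records a final visit with score 29 and `death_flag = 1` and
#' terminates the patient's series. Attributes i1-i5 are fixed over a stay;
#' severity re-grades from the score at every epoch.
#'
#' @param config a [cohort_config()].
#' @return list with `patients` (`patient_id`, `age_band`, `history`,
#'   `complication`, `diagnosis`, `syndrome`) and `visits` (`patient_id`,
#'   `day`, `score`, `a1`, `a2`, `a3`, `death_flag`) data.tables.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  empty_p <- data.table::data.table(
    patient_id = character(), age_band = integer(), history = integer(),
    complication = integer(), diagnosis = integer(), syndrome = integer())
  empty_v <- data.table::data.table(
    patient_id = character(), day = integer(), score = integer(),
    a1 = integer(), a2 = integer(), a3 = integer(), death_flag = integer())
  if (n == 0L) return(list(patients = empty_p, visits = empty_v))

  set.seed(config$seed)
  mg <- config$marginals
  patients <- data.table::data.table(
    patient_id = sprintf("P%05d", seq_len(n)),
    age_band = sample_cat(n, mg$age_band),
    history = sample_cat(n, mg$history),
    complication = sample_cat(n, mg$complication),
    diagnosis = sample_cat(n, mg$diagnosis),
    syndrome = sample_cat(n, mg$syndrome))

  lev0 <- sample_cat(n, mg$level)
  score <- GRADE_LO[lev0] +
    floor(runif(n) * (GRADE_HI[lev0] - GRADE_LO[lev0] + 1L))
  score <- as.integer(score)

  em <- config$effect_model
  acts <- action_set("lexicographic")
  act_bits <- decode_action_bits(acts)
  act_prob <- if (config$logging_policy == "uniform") rep(1 / 8, 8)
              else unname(config$logging_weights[acts] /
                          sum(config$logging_weights))
  days <- seq(1L, config$max_day, by = config$epoch_days)
  sd_step <- sqrt(em$baseline_drift[["sd"]]^2 + em$noise_sd^2)

  active <- rep(TRUE, n)
  out <- vector("list", length(days))
  for (k in seq_along(days)) {
    idx <- which(active)
    if (length(idx) == 0L) break
    m <- length(idx)
    ai <- sample.int(8L, m, replace = TRUE, prob = act_prob)
    band <- severity_band(grade_score(score[idx]))
    mult <- ifelse(band == "mild", em$severity_modifier$mild[ai],
                   em$severity_modifier$moderate_to_severe[ai])
    mu <- em$baseline_drift[["mean"]] + em$action_effects[ai] * mult
    improvement <- round(rnorm(m, mu, sd_step))
    nxt <- score[idx] - improvement
    dead <- nxt >= SCORE_MAX | runif(m) < em$death_prob
    nxt <- as.integer(pmin(pmax(nxt, 0L), SCORE_MAX))
    nxt[dead] <- DEATH_SCORE
    last_epoch <- k == length(days)
    out[[k]] <- data.table::data.table(
      patient_id = patients$patient_id[idx], day = days[k],
      score = score[idx],
      a1 = act_bits$a1[ai], a2 = act_bits$a2[ai], a3 = act_bits$a3[ai],
      death_flag = 0L,
      .next_score = nxt, .dead = dead, .last = last_epoch)
    score[idx] <- nxt
    active[idx[dead]] <- FALSE
  }
  vis <- data.table::rbindlist(out)
  # materialise follow-up rows: the next epoch's visit carries the new score;
  # deaths are recorded as a terminal visit with score 29 and no treatment
  death_rows <- vis[.dead == TRUE & day + config$epoch_days <= config$max_day,
                    .(patient_id, day = day + config$epoch_days,
                      score = DEATH_SCORE, a1 = 0L, a2 = 0L, a3 = 0L,
                      death_flag = 1L)]
  vis <- vis[, .(patient_id, day, score, a1, a2, a3, death_flag)]
  visits <- data.table::rbindlist(list(vis, death_rows))
  data.table::setorder(visits, patient_id, day)

  if (config$missing_rate > 0) {
    patients <- inject_missingness(patients, config$missing_rate,
                                   seed = config$seed + 1L)
    visits <- inject_missingness(visits, config$missing_rate,
                                 seed = config$seed + 2L)
  }
  list(patients = patients[], visits = visits[])
}

decode_action_bits <- function(codes) {
  list(a1 = as.integer(substr(codes, 1, 1)),
       a2 = as.integer(substr(codes, 2, 2)),
       a3 = as.integer(substr(codes, 3, 3)))
}

#' Blank attribute cells at random to emulate incomplete records
#'
#' Each eligible cell is independently set to `NA` with probability `rate`.
#' Eligible cells are the five admission attributes in a patients table and
#' the score of non-death rows in a visits table; `patient_id`, `day`,
#' treatment bits and death flags are never blanked.
#'
#' @param tbl a patients or visits data.table.
#' @param rate blanking probability per cell, in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return a copy of `tbl` with blanked cells.
#' @export
inject_missingness <- function(tbl, rate, seed) {
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate >= 1)
    stop("rate must lie in [0, 1)", call. = FALSE)
  tbl <- data.table::as.data.table(tbl)
  if (rate == 0) return(tbl)
  set.seed(seed)
  eligible <- intersect(names(tbl),
                        c("age_band", "history", "complication",
                          "diagnosis", "syndrome", "score"))
  for (col in eligible) {
    hit <- runif(nrow(tbl)) < rate
    if (col == "score" && "death_flag" %in% names(tbl))
      hit <- hit & tbl$death_flag == 0L
    if (any(hit)) tbl[hit, (col) := NA]
  }
  tbl[]
}
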
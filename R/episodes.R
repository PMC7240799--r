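#' Remove abnormal rows from a patients or visits table
#'
#' Drops rows carrying values outside their admissible ranges: impairment
#' scores outside 0..29, non-binary treatment bits or death flags, and
#' attribute categories outside their enumerations. Missing (`NA`) cells are
#' retained for [fill_missing()]. Duplicate `(patient_id, day)` rows are an
#' integrity error, not silently resolved.
#'
#' @param tbl a patients or visits data.table / data.frame.
#' @param quiet suppress the removal-count message.
#' @return the cleaned table, with attribute `n_removed`.
#' @export
clean_records <- function(tbl, quiet = FALSE) {
  tbl <- data.table::as.data.table(tbl)
  if (!"patient_id" %in% names(tbl))
    stop("table must carry a patient_id column", call. = FALSE)
  if ("day" %in% names(tbl)) {
    dup <- tbl[, .N, by = .(patient_id, day)][N > 1L]
    if (nrow(dup) > 0L)
      stop("duplicate (patient_id, day) rows: ",
           paste(utils::head(paste0(dup$patient_id, "/day", dup$day), 5L),
                 collapse = ", "), call. = FALSE)
  }
  ok <- rep(TRUE, nrow(tbl))
  flag <- function(x, valid) is.na(x) | valid  # NA survives cleaning
  if ("score" %in% names(tbl))
    ok <- ok & flag(tbl$score, tbl$score %in% 0:SCORE_MAX)
  for (b in intersect(c("a1", "a2", "a3", "death_flag"), names(tbl)))
    ok <- ok & flag(tbl[[b]], tbl[[b]] %in% 0:1)
  for (nm in intersect(ATTR_NAMES, names(tbl)))
    ok <- ok & flag(tbl[[nm]], tbl[[nm]] %in% ATTR_DOMAINS[[nm]])
  removed <- sum(!ok)
  if (!quiet)
    message("clean_records: removed ", removed, " abnormal row(s)")
  out <- tbl[ok]
  data.table::setattr(out, "n_removed", removed)
  out
}

#' Fill missing cells by uniform random draws
#'
#' Each `NA` attribute cell is replaced by a uniform draw over that
#' attribute's categories; an `NA` score by a uniform draw over 0..29.
#' Identifier, day, treatment-bit and death-flag cells are never fillable:
#' a blank there is an integrity error. Deterministic given `seed`.
#'
#' @param tbl a patients or visits table (after [clean_records()]).
#' @param seed integer RNG seed.
#' @param quiet suppress the filled-count message.
#' @return the filled table, with attribute `n_filled`.
#' @export
fill_missing <- function(tbl, seed, quiet = FALSE) {
  tbl <- data.table::as.data.table(tbl)
  for (col in intersect(c("patient_id", "day", "a1", "a2", "a3",
                          "death_flag"), names(tbl)))
    if (anyNA(tbl[[col]]))
      stop("column ", col, " has blank cells; it is never fillable",
           call. = FALSE)
  set.seed(seed)
  filled <- 0L
  fillable <- intersect(c(setdiff(ATTR_NAMES, "level"), "score"), names(tbl))
  for (col in fillable) {
    miss <- which(is.na(tbl[[col]]))
    if (length(miss) == 0L) next
    dom <- if (col == "score") 0:SCORE_MAX else ATTR_DOMAINS[[col]]
    tbl[miss, (col) := dom[sample.int(length(dom), length(miss),
                                      replace = TRUE)]]
    filled <- filled + length(miss)
  }
  if (!quiet) message("fill_missing: filled ", filled, " cell(s)")
  data.table::setattr(tbl, "n_filled", filled)
  tbl[]
}

#' Convert patient stays into (state, action, reward, next state) steps
#'
#' Visits must lie on the epoch grid (day 1, `1 + epoch_days`, ...); off-grid
#' days raise an alignment error rather than being snapped. Decision epochs
#' after `max_day` are discarded: a step is retained when it *starts* at or
#' before `max_day`, and its endpoint visit is used even if it falls one
#' epoch beyond the cap. For each pair of consecutive retained visits one
#' epoch apart, a step is emitted: the state encodes the patient's fixed
#' admission attributes plus the severity level re-graded from the score at
#' the epoch start; the action is the treatment bits logged at the start;
#' the reward is the score decrease across the epoch. A death visit (score
#' 29) terminates the episode. Patients with a single retained visit
#' contribute no steps.
#'
#' @param patients patients table (`patient_id` + the five admission
#'   attributes), cleaned and filled.
#' @param visits visits table (`patient_id`, `day`, `score`, `a1`, `a2`,
#'   `a3`, `death_flag`), cleaned and filled.
#' @param epoch_days epoch spacing in days (default 7).
#' @param max_day last admissible decision day (default 147).
#' @return `data.table` of episode steps: `patient_id`, `day`, `state`,
#'   `action`, `reward`, `next_state`, `terminal`.
#' @export
build_episodes <- function(patients, visits, epoch_days = 7L,
                           max_day = 147L) {
  patients <- data.table::as.data.table(patients)
  visits <- data.table::as.data.table(visits)
  need_p <- c("patient_id", setdiff(ATTR_NAMES, "level"))
  need_v <- c("patient_id", "day", "score", "a1", "a2", "a3", "death_flag")
  if (!all(need_p %in% names(patients)))
    stop("patients table must carry ", paste(need_p, collapse = ", "),
         call. = FALSE)
  if (!all(need_v %in% names(visits)))
    stop("visits table must carry ", paste(need_v, collapse = ", "),
         call. = FALSE)
  off <- (visits$day - 1L) %% epoch_days != 0L | visits$day < 1L
  if (any(off))
    stop("visit days off the epoch grid (1, ", 1L + epoch_days,
         ", ...): e.g. day ", visits$day[which(off)[1]], call. = FALSE)

  # endpoint visits one epoch beyond the cap are kept as next-state sources
  v <- visits[day <= max_day + epoch_days]
  data.table::setorder(v, patient_id, day)
  # nothing after a death visit
  v[, .after_death := cumsum(data.table::shift(death_flag, fill = 0L)) > 0L,
    by = patient_id]
  v <- v[.after_death == FALSE][, .after_death := NULL]

  v <- merge(v, patients[, need_p, with = FALSE], by = "patient_id",
             sort = FALSE)
  v[, level := grade_score(score)]
  v[, state := encode_state(age_band, history, complication, diagnosis,
                            syndrome, level)]
  v[, `:=`(nxt_day = data.table::shift(day, type = "lead"),
           nxt_state = data.table::shift(state, type = "lead"),
           nxt_score = data.table::shift(score, type = "lead")),
    by = patient_id]
  steps <- v[!is.na(nxt_day) & nxt_day == day + epoch_days & day <= max_day]
  if (nrow(steps) == 0L)
    return(data.table::data.table(
      patient_id = character(), day = integer(), state = character(),
      action = character(), reward = integer(), next_state = character(),
      terminal = integer()))
  steps[, `:=`(action = encode_action(a1, a2, a3),
               reward = compute_reward(score, nxt_score))]
  # terminal: no step starts at this step's end epoch
  starts <- steps[, paste(patient_id, day)]
  steps[, terminal := as.integer(!(paste(patient_id, nxt_day) %in% starts))]
  out <- steps[, .(patient_id, day, state, action, reward,
                   next_state = nxt_state, terminal)]
  data.table::setorder(out, patient_id, day)
  out[]
}
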
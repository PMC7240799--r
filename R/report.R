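#' Define a stratum of patient states
#'
#' A partial constraint over the six state attributes. Each supplied
#' argument is a vector of allowed categories; `band` constrains the
#' severity band derived from the impairment level (i6). Unconstrained
#' attributes match anything.
#'
#' @param age_band,history,complication,diagnosis,syndrome,level optional
#'   vectors of allowed categories.
#' @param band optional `"mild"` or `"moderate_to_severe"`.
#' @return object of class `stratum`.
#' @examples
#' # >= 66 years, some disease history, no complications
#' stratum(age_band = 3, history = c(1, 2), complication = 0)
#' @export
stratum <- function(age_band = NULL, history = NULL, complication = NULL,
                    diagnosis = NULL, syndrome = NULL, level = NULL,
                    band = NULL) {
  cons <- list(age_band = age_band, history = history,
               complication = complication, diagnosis = diagnosis,
               syndrome = syndrome, level = level)
  cons <- cons[!vapply(cons, is.null, logical(1))]
  for (nm in names(cons)) {
    if (any(!cons[[nm]] %in% ATTR_DOMAINS[[nm]]))
      stop("stratum constraint on ", nm, " uses invalid categories",
           call. = FALSE)
    cons[[nm]] <- as.integer(cons[[nm]])
  }
  if (!is.null(band))
    band <- match.arg(band, c("mild", "moderate_to_severe"))
  structure(list(constraints = cons, band = band), class = "stratum")
}

match_stratum <- function(attrs, strat) {
  keep <- rep(TRUE, nrow(attrs))
  for (nm in names(strat$constraints))
    keep <- keep & attrs[[nm]] %in% strat$constraints[[nm]]
  if (!is.null(strat$band))
    keep <- keep & severity_band(attrs$level) == strat$band
  keep
}

#' Optimal-action frequency table for a stratum
#'
#' Decodes each policy state, keeps those matching the stratum, and counts
#' how many states have each action as their optimum, split by severity
#' band. Frequencies count states, not patients (each observed state
#' carries one optimal decision); set `weights` to a [state_inventory()]
#' to count patients instead.
#'
#' @param policy policy `data.table` (`state`, `action`).
#' @param strat a [stratum()].
#' @param band_split group rows by severity band (default `TRUE`).
#' @param weights optional [state_inventory()] table; when given, each
#'   state contributes its `n_patients` instead of 1.
#' @return `data.table` with columns `band` (if `band_split`), `action`,
#'   `frequency`, ordered by band then action code.
#' @export
stratified_decision_table <- function(policy, strat, band_split = TRUE,
                                      weights = NULL) {
  if (!inherits(strat, "stratum"))
    stop("strat must be a stratum()", call. = FALSE)
  policy <- data.table::as.data.table(policy)
  if (nrow(policy) == 0L) stop("empty policy", call. = FALSE)
  attrs <- decode_state(policy$state)
  keep <- match_stratum(attrs, strat)
  if (!any(keep)) {
    out <- data.table::data.table(band = character(), action = character(),
                                  frequency = integer())
    if (!band_split) out[, band := NULL]
    return(out)
  }
  sub <- data.table::data.table(
    state = policy$state[keep], action = policy$action[keep],
    band = severity_band(attrs$level[keep]))
  if (!is.null(weights)) {
    weights <- data.table::as.data.table(weights)
    sub <- merge(sub, weights[, .(state, w = n_patients)], by = "state",
                 all.x = TRUE)
    sub[is.na(w), w := 0L]
  } else sub[, w := 1L]
  by_cols <- if (band_split) c("band", "action") else "action"
  out <- sub[, .(frequency = sum(w)), by = by_cols]
  data.table::setorderv(out, by_cols)
  out[]
}

#' Cohort summary in count (percentage) form
#'
#' Per-attribute category counts and percentages of the cohort, overall and
#' by sex when the patients table carries a `sex` column. The impairment
#' level is graded from each patient's first-visit score; patients with any
#' missing attribute or missing admission score are tallied in an
#' `incomplete` row of the level block.
#'
#' @param patients patients table.
#' @param visits optional visits table supplying admission scores.
#' @return `data.table` with columns `attribute`, `category`, `n`, `pct`
#'   (and per-sex columns when available).
#' @export
cohort_summary <- function(patients, visits = NULL) {
  patients <- data.table::as.data.table(patients)
  if (nrow(patients) == 0L)
    stop("cannot summarise an empty patient table", call. = FALSE)
  p <- data.table::copy(patients)
  if (!is.null(visits)) {
    visits <- data.table::as.data.table(visits)
    adm <- visits[order(patient_id, day), .SD[1L, .(score)],
                  by = patient_id]
    p <- merge(p, adm, by = "patient_id", all.x = TRUE)
    p[, level := NA_integer_]
    ok <- !is.na(p$score)
    p$level[ok] <- grade_score(p$score[ok])
  }
  N <- nrow(p)
  one_block <- function(nm, sub, n_tot) {
    x <- sub[[nm]]
    cats <- ATTR_DOMAINS[[nm]]
    cnt <- vapply(cats, function(cc) sum(x == cc, na.rm = TRUE), integer(1))
    data.table::data.table(attribute = nm, category = as.character(cats),
                           n = cnt, pct = round(100 * cnt / n_tot, 2))
  }
  blocks <- function(sub, n_tot) {
    nms <- intersect(ATTR_NAMES, names(sub))
    out <- data.table::rbindlist(lapply(nms, one_block, sub = sub,
                                        n_tot = n_tot))
    inc <- Reduce(`|`, lapply(nms, function(nm) is.na(sub[[nm]])))
    rbind(out, data.table::data.table(
      attribute = "level", category = "incomplete",
      n = sum(inc), pct = round(100 * sum(inc) / n_tot, 2)))
  }
  out <- blocks(p, N)
  if ("sex" %in% names(p)) {
    for (sx in sort(unique(p$sex))) {
      sub <- p[sex == sx]
      b <- blocks(sub, nrow(sub))
      data.table::setnames(b, c("n", "pct"),
                           paste0(c("n_", "pct_"), sx))
      out <- merge(out, b, by = c("attribute", "category"), sort = FALSE)
    }
  }
  out[]
}

#' Run the full analysis pipeline
#'
#' Executes clean, fill, episode building, model estimation, Monte Carlo
#' solving and reporting, writing every intermediate plus a manifest to
#' `out_dir`. The configuration either names input files
#' (`patients_file`, `visits_file`) or requests synthesis (`n_patients`,
#' plus any [cohort_config()] field). Idempotent for identical inputs and
#' seeds.
#'
#' @param config a named list, or path to a JSON file of one. Recognised
#'   fields: `patients_file`, `visits_file`, `n_patients`, `seed`,
#'   `missing_rate`, `epoch_days`, `max_day`, `n_episodes`, `horizon`.
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with the pipeline objects (`patients`,
#'   `visits`, `steps`, `model`, `q`, `policy`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- function(nm, default) if (!is.null(config[[nm]])) config[[nm]]
                               else default
  seed <- as.integer(cfg("seed", 1L))
  epoch_days <- as.integer(cfg("epoch_days", 7L))
  max_day <- as.integer(cfg("max_day", 147L))
  log_stage <- function(...) message("[strokemdp] ", ...)

  if (!is.null(config$patients_file)) {
    for (f in c(config$patients_file, config$visits_file))
      if (is.null(f) || !file.exists(f))
        stop("input file not found: ", if (is.null(f)) "(unset)" else f,
             call. = FALSE)
    log_stage("reading ", config$patients_file, ", ", config$visits_file)
    patients <- data.table::fread(config$patients_file)
    visits <- data.table::fread(config$visits_file)
  } else {
    n <- cfg("n_patients", NULL)
    if (is.null(n))
      stop("config needs either patients_file/visits_file or n_patients",
           call. = FALSE)
    cc <- cohort_config(n_patients = n, seed = seed,
                        missing_rate = cfg("missing_rate", 0),
                        max_day = max_day, epoch_days = epoch_days)
    log_stage("synthesising cohort: n=", n, " seed=", seed)
    cohort <- generate_cohort(cc)
    patients <- cohort$patients
    visits <- cohort$visits
  }

  log_stage("cleaning")
  patients <- clean_records(patients, quiet = TRUE)
  visits <- clean_records(visits, quiet = TRUE)
  n_removed <- attr(patients, "n_removed") + attr(visits, "n_removed")
  log_stage("removed ", n_removed, " abnormal row(s)")
  patients <- fill_missing(patients, seed = seed + 10L, quiet = TRUE)
  visits <- fill_missing(visits, seed = seed + 11L, quiet = TRUE)
  n_filled <- attr(patients, "n_filled") + attr(visits, "n_filled")
  log_stage("filled ", n_filled, " missing cell(s)")

  steps <- build_episodes(patients, visits, epoch_days = epoch_days,
                          max_day = max_day)
  log_stage(nrow(steps), " episode steps")
  model <- estimate_model(steps)
  log_stage(length(model$states), " states, ", nrow(model$support),
            " supported pairs")
  scfg <- solver_config(n_episodes = cfg("n_episodes", 500000L),
                        seed = seed + 20L,
                        horizon = cfg("horizon", 21L))
  log_stage("Monte Carlo control: ", scfg$n_episodes, " episodes")
  sol <- run_mc_control(model, scfg)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) data.table::fwrite(x, file.path(out_dir, f),
                                          sep = "\t", quote = TRUE)
  wr(patients, "patients.tsv")
  wr(visits, "visits.tsv")
  wr(steps, "episodes.tsv")
  write_model(model, file.path(out_dir, "model.tsv"))
  wr(sol$q, "q_table.tsv")
  wr(sol$policy, "policy.tsv")
  wr(state_inventory(steps), "state_inventory.tsv")
  wr(cohort_summary(patients, visits), "cohort_summary.tsv")
  strata <- list(
    history_no_complication = stratum(history = c(1, 2), complication = 0),
    age66_no_complication = stratum(age_band = 3, complication = 0),
    phlegm_blocking = stratum(syndrome = 2),
    qi_deficiency_blood_stasis = stratum(syndrome = 4))
  for (nm in names(strata)) {
    tab <- stratified_decision_table(sol$policy, strata[[nm]])
    wr(tab, paste0("decisions_", nm, ".tsv"))
  }
  manifest <- list(
    seed = seed, n_patients = nrow(patients), n_visits = nrow(visits),
    n_removed = n_removed, n_filled = n_filled, n_steps = nrow(steps),
    n_states = length(model$states),
    n_supported_pairs = nrow(model$support),
    solver = unclass(scfg),
    package_version = as.character(utils::packageVersion("strokemdp")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage("outputs written to ", out_dir)
  invisible(list(patients = patients, visits = visits, steps = steps,
                 model = model, q = sol$q, policy = sol$policy,
                 manifest = manifest))
}
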
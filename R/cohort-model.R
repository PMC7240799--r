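#' strokemdp: finite-MDP comparative effectiveness for stroke convalescence
#'
#' Tools to encode longitudinal stroke-convalescence records as a finite
#' Markov decision process, estimate the empirical transition model, solve
#' for the optimal treatment policy by Monte Carlo control with exploring
#' starts, and report stratified optimal-action tables. A seeded synthetic
#' cohort generator with a planted optimal action supports end-to-end
#' solver-recovery testing.
#'
#' @import data.table
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif setNames
#' @importFrom utils head
#' @useDynLib strokemdp, .registration = TRUE
#' @keywords internal
"_PACKAGE"

# Enumerations for the six state attributes i1..i6.
# i1 age band: 1 = 18-45 y, 2 = 46-65 y, 3 = >= 66 y
# i2 disease history: 0 none, 1 one, 2 at least two
# i3 complication: 0 none, 1 at least one
# i4 Western diagnosis: 1 ischaemic, 2 haemorrhagic
# i5 TCM syndrome: 1 wind-fired disturbance, 2 phlegm-blocking,
#    3 yin-deficiency, 4 qi deficiency and blood stasis, 5 phlegm-heat
# i6 impairment level: 1..5 from grade_score()
ATTR_DOMAINS <- list(
  age_band     = 1:3,
  history      = 0:2,
  complication = 0:1,
  diagnosis    = 1:2,
  syndrome     = 1:5,
  level        = 1:5
)

ATTR_NAMES <- names(ATTR_DOMAINS)

# Score grading cut points: level k covers GRADE_LO[k]..GRADE_HI[k].
GRADE_LO <- c(0L, 3L, 6L, 13L, 20L)
GRADE_HI <- c(2L, 5L, 12L, 19L, 29L)

# Maximum impairment score; also the default score recorded at death.
SCORE_MAX <- 29L
DEATH_SCORE <- 29L

assert_score <- function(score, what = "score") {
  if (length(score) == 0L) stop(what, " must be non-empty", call. = FALSE)
  if (anyNA(score)) stop(what, " contains missing values", call. = FALSE)
  if (any(score != as.integer(score)))
    stop(what, " must be integer-valued", call. = FALSE)
  bad <- score < 0L | score > SCORE_MAX
  if (any(bad))
    stop(what, " out of range 0..", SCORE_MAX, ": ",
         paste(utils::head(score[bad], 5L), collapse = ", "), call. = FALSE)
  as.integer(score)
}

#' Grade a neurological-impairment score into one of five levels
#'
#' The 0-29 impairment score is partitioned into five severity levels:
#' level 1 (0-2), level 2 (3-5), level 3 (6-12), level 4 (13-19) and
#' level 5 (20-29). A score of 29 is also the default recorded for a
#' patient whose outcome is death, so death always grades to level 5.
#'
#' @param score integer vector of impairment scores in 0..29.
#' @return integer vector of levels in 1..5.
#' @examples
#' grade_score(c(0, 12, 29))
#' @export
grade_score <- function(score) {
  score <- assert_score(score)
  findInterval(score, GRADE_LO)
}

#' Collapse an impairment level into a severity band
#'
#' Levels 1-2 are mild neurological deficit; level 3 (moderate) and levels
#' 4-5 (severe) together form the moderate-to-severe band used as the row
#' grouping of the stratified decision tables.
#'
#' @param level integer vector of levels in 1..5.
#' @return character vector, `"mild"` or `"moderate_to_severe"`.
#' @examples
#' severity_band(1:5)
#' @export
severity_band <- function(level) {
  if (length(level) == 0L) stop("level must be non-empty", call. = FALSE)
  if (anyNA(level) || any(!level %in% 1:5))
    stop("level must lie in 1..5", call. = FALSE)
  ifelse(level <= 2L, "mild", "moderate_to_severe")
}

assert_attr <- function(x, name) {
  dom <- ATTR_DOMAINS[[name]]
  if (anyNA(x)) stop(name, " contains missing values", call. = FALSE)
  if (any(!x %in% dom))
    stop(name, " outside its enumeration {", paste(dom, collapse = ","), "}",
         call. = FALSE)
  as.integer(x)
}

#' Encode patient attributes as a six-digit state code
#'
#' Position k of the code carries attribute i_k: age band, disease history,
#' complications, Western diagnosis, TCM syndrome, impairment level. Codes
#' are plain digit strings (e.g. `"200112"`), never integers, so leading
#' digits are preserved in files.
#'
#' @param age_band 1 (18-45 y), 2 (46-65 y) or 3 (>= 66 y).
#' @param history 0 (none), 1 (one) or 2 (at least two prior diseases).
#' @param complication 0 (none) or 1 (at least one).
#' @param diagnosis 1 (ischaemic) or 2 (haemorrhagic).
#' @param syndrome TCM syndrome type 1..5.
#' @param level impairment level 1..5 (see [grade_score()]).
#' @return character vector of six-digit state codes.
#' @examples
#' encode_state(2, 0, 0, 1, 1, 2)  # "200112"
#' @export
encode_state <- function(age_band, history, complication, diagnosis,
                         syndrome, level) {
  vals <- list(age_band, history, complication, diagnosis, syndrome, level)
  vals <- mapply(assert_attr, vals, ATTR_NAMES, SIMPLIFY = FALSE)
  n <- unique(lengths(vals))
  if (length(n) != 1L)
    stop("attribute vectors must share a common length", call. = FALSE)
  do.call(paste0, vals)
}

#' Decode a six-digit state code into patient attributes
#'
#' Inverse of [encode_state()]. Malformed codes and digits outside their
#' position's enumeration raise an error.
#'
#' @param code character vector of six-digit state codes.
#' @return a `data.table` with one row per code and columns
#'   `age_band`, `history`, `complication`, `diagnosis`, `syndrome`, `level`.
#' @examples
#' decode_state("200112")
#' @export
decode_state <- function(code) {
  if (length(code) == 0L) stop("code must be non-empty", call. = FALSE)
  if (anyNA(code) || any(!grepl("^[0-9]{6}$", code)))
    stop("state codes must be six-digit strings", call. = FALSE)
  out <- data.table::as.data.table(
    lapply(seq_along(ATTR_NAMES), function(k)
      as.integer(substr(code, k, k))))
  data.table::setnames(out, ATTR_NAMES)
  for (nm in ATTR_NAMES) {
    bad <- !out[[nm]] %in% ATTR_DOMAINS[[nm]]
    if (any(bad))
      stop("invalid digit for ", nm, " in code(s): ",
           paste(utils::head(code[bad], 5L), collapse = ", "), call. = FALSE)
  }
  out[]
}

#' Encode a treatment combination as a three-bit action code
#'
#' Bits are, in order: rehabilitation therapy (a1), Chinese herbal decoction
#' (a2), acupuncture (a3). The full action set has exactly eight members,
#' see [action_set()].
#'
#' @param rehab,herbal,acupuncture 0/1 treatment indicators.
#' @return character vector of three-bit action codes (e.g. `"101"`).
#' @examples
#' encode_action(1, 0, 1)
#' @export
encode_action <- function(rehab, herbal, acupuncture) {
  bits <- list(rehab, herbal, acupuncture)
  for (b in bits) {
    if (anyNA(b) || any(!b %in% 0:1))
      stop("treatment indicators must be 0 or 1", call. = FALSE)
  }
  n <- unique(lengths(bits))
  if (length(n) != 1L)
    stop("indicator vectors must share a common length", call. = FALSE)
  paste0(as.integer(rehab), as.integer(herbal), as.integer(acupuncture))
}

#' The eight treatment-combination action codes
#'
#' @param order `"table"` (the conventional listing order, 111 first) or
#'   `"lexicographic"` (000 first; the solver's tie-break order).
#' @return character vector of the eight action codes.
#' @export
action_set <- function(order = c("table", "lexicographic")) {
  order <- match.arg(order)
  tab <- c("111", "110", "101", "100", "011", "010", "001", "000")
  if (order == "table") tab else sort(tab)
}

#' Reward of one treatment epoch
#'
#' The reward is the decrease in impairment score across the epoch:
#' `score_before - score_after`. Positive rewards mean improvement, zero
#' means no change, negative means deterioration.
#'
#' @param score_before,score_after integer scores in 0..29.
#' @return integer vector of rewards in -29..29.
#' @examples
#' compute_reward(8, 5)  # 3, improvement
#' @export
compute_reward <- function(score_before, score_after) {
  before <- assert_score(score_before, "score_before")
  after <- assert_score(score_after, "score_after")
  before - after
}
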
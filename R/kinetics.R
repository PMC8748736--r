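# The three kinetic parameters.
#
# KS  - kinesia score: number of target-key presses inside the half-open
#       task window [t0, t0 + 1000*window_s). Counts unreleased presses:
#       a keystroke happened even if capture ended mid-dwell.
# AT  - akinesia time: mean dwell (press -> release) over complete
#       in-window target taps, ms.
# IS  - incoordination score: sample variance (n-1) of travelling times,
#       ms^2, where travelling time is flight time: release of tap i to
#       press of tap i+1. Intervals adjacent to an unreleased tap are
#       skipped, and negative intervals (overlapping taps, a capture
#       artifact on some keyboards) are excluded from IS while the taps
#       themselves still count for KS and AT.
#
# Identical logic serves the DFT and BRAIN tasks; only the key set and
# window differ. BRAIN alternation errors (consecutive presses of the
# same key) are counted and reported, never subtracted from KS.

#' Extract in-window target taps
#'
#' Returns the target-key events of a session whose press falls in the
#' half-open task window `[t0, t0 + 1000 * window_s)`, ordered by press
#' time. Off-target keys — and, for DFT, the hold key — are excluded;
#' a press at exactly the window end is excluded.
#'
#' @param session a [tap_session()].
#' @return data.frame with columns `key`, `t_press`, `t_release`
#'   (`t_release` is `NA` for unreleased presses).
#' @export
target_taps <- function(session) {
  stopifnot(inherits(session, "tap_session"))
  ev <- session$events
  win <- c(session$t0, session$t0 + 1000 * session$window_s)
  keep <- ev$key %in% task_keys(session$task) &
    ev$t_press >= win[1] & ev$t_press < win[2]
  out <- ev[keep, c("key", "t_press", "t_release"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kinesia score: taps in the window
#'
#' The number of target-key presses inside the task window, including
#' presses never released before capture ended. Reflects tapping speed.
#'
#' @param session a [tap_session()].
#' @return non-negative integer count.
#' @export
kinesia_score <- function(session) {
  nrow(target_taps(session))
}

#' Akinesia time: mean key dwell
#'
#' Arithmetic mean of dwell time (release minus press, ms) over complete
#' in-window target taps. Reflects hesitancy on the key.
#'
#' @param session a [tap_session()].
#' @return mean dwell in ms, or `NA` when the session has no complete tap.
#' @export
akinesia_time <- function(session) {
  taps <- target_taps(session)
  dwell <- taps$t_release - taps$t_press
  dwell <- dwell[!is.na(dwell)]
  if (!length(dwell)) return(NA_real_)
  mean(dwell)
}

.travel_times <- function(taps) {
  n <- nrow(taps)
  if (n < 2) return(numeric())
  # flight time: release of tap i to press of tap i+1; undefined when
  # tap i is unreleased
  tt <- taps$t_press[-1] - taps$t_release[-n]
  tt <- tt[!is.na(tt)]
  tt[tt >= 0]  # overlapping taps excluded
}

#' Incoordination score: travelling-time variance
#'
#' Sample variance (denominator n-1) of the travelling (flight) times
#' between consecutive in-window target taps, in ms^2. Reflects rhythm.
#' Intervals adjacent to an unreleased tap, and negative intervals from
#' overlapping key events, are excluded.
#'
#' @param session a [tap_session()].
#' @return variance in ms^2, or `NA` when fewer than 2 travelling times
#'   remain.
#' @export
incoordination_score <- function(session) {
  tt <- .travel_times(target_taps(session))
  if (length(tt) < 2) return(NA_real_)
  var(tt)
}

#' Score a session
#'
#' Bundles the three kinetic parameters with tap counts and validity
#' flags. Degenerate sessions never raise an error; they come back with
#' absent values and reason codes.
#'
#' @param session a [tap_session()].
#' @param report optional [validate_session()] report; when supplied, its
#'   verdict (e.g. insufficient hold-key coverage on DFT) is folded into
#'   the validity flag.
#' @return object of class `kinetic_scores`: `ks`, `at` (ms, `NA` if no
#'   complete tap), `is_` (ms^2, `NA` if fewer than 2 travelling times),
#'   `n_taps_complete`, `n_travel`, `alternation_errors` (BRAIN only:
#'   consecutive presses of the same key; informational, not subtracted
#'   from `ks`), `valid`, `reasons`.
#' @examples
#' p <- seq(0, by = 250, length.out = 80)
#' s <- tap_session("p1", "DFT", "left",
#'                  events = data.frame(key = "ArrowDown",
#'                                      t_press = p, t_release = p + 100))
#' score_session(s)
#' @export
score_session <- function(session, report = NULL) {
  taps <- target_taps(session)
  ks <- nrow(taps)
  dwell <- taps$t_release - taps$t_press
  n_complete <- sum(!is.na(dwell))
  at <- if (n_complete) mean(dwell[!is.na(dwell)]) else NA_real_
  tt <- .travel_times(taps)
  is_ <- if (length(tt) >= 2) var(tt) else NA_real_
  alt_err <- if (session$task == "BRAIN" && ks >= 2) {
    sum(taps$key[-1] == taps$key[-ks])
  } else NA_integer_
  reasons <- character()
  if (ks == 0) reasons <- c(reasons, "no_taps")
  if (is.na(at)) reasons <- c(reasons, "no_complete_tap")
  if (is.na(is_)) reasons <- c(reasons, "too_few_travel_times")
  if (!is.null(report) && !report$valid) {
    reasons <- c(reasons, report$reasons)
  }
  valid <- ks > 0 && n_complete > 0 &&
    (is.null(report) || report$valid)
  structure(list(ks = ks, at = at, is_ = is_,
                 n_taps_complete = n_complete, n_travel = length(tt),
                 alternation_errors = alt_err,
                 valid = valid, reasons = unique(reasons)),
            class = "kinetic_scores")
}

#' @export
print.kinetic_scores <- function(x, ...) {
  cat(sprintf("<kinetic_scores> KS %d | AT %s ms | IS %s ms^2 | %s\n",
              x$ks,
              if (is.na(x$at)) "--" else sprintf("%.1f", x$at),
              if (is.na(x$is_)) "--" else sprintf("%.1f", x$is_),
              if (x$valid) "valid" else
                paste("invalid:", paste(x$reasons, collapse = ","))))
  invisible(x)
}

#' Score every session of a cohort
#'
#' Applies [validate_session()] and [score_session()] to each session of
#' each record and stacks the results into a long table, one row per
#' participant x task x hand x trial.
#'
#' @param records list of [participant_record()] objects.
#' @param hold_threshold passed to [validate_session()].
#' @return data.frame with metadata columns, `ks`, `at`, `is_`, counts,
#'   `hold_coverage`, `valid` and collapsed `reasons`.
#' @export
score_cohort <- function(records, hold_threshold = 0.90) {
  rows <- lapply(records, function(rec) {
    do.call(rbind, lapply(rec$sessions, function(s) {
      rep_ <- validate_session(s, hold_threshold = hold_threshold)
      sc <- score_session(s, report = rep_)
      data.frame(participant_id = rec$participant_id, group = rec$group,
                 task = s$task, hand = s$hand, trial = s$trial,
                 state = s$state,
                 ks = sc$ks, at = sc$at, is_ = sc$is_,
                 n_taps_complete = sc$n_taps_complete,
                 n_travel = sc$n_travel,
                 alternation_errors = sc$alternation_errors,
                 hold_coverage = rep_$hold_coverage,
                 valid = sc$valid,
                 reasons = paste(sc$reasons, collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(participant_id = character(), group = character(),
                      task = character(), hand = character(),
                      trial = integer(), state = character(),
                      ks = integer(), at = numeric(), is_ = numeric(),
                      n_taps_complete = integer(), n_travel = integer(),
                      alternation_errors = integer(),
                      hold_coverage = numeric(), valid = logical(),
                      reasons = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
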
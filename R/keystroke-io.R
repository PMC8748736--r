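# Reading, validating and writing keystroke event logs and score tables.
#
# All timestamps are milliseconds relative to the session start (t0 = 0);
# the capture clock's epoch is discarded at parse time because every
# derived quantity is a duration. Unreleased presses (capture ended while
# the key was still down) are kept with t_release = NA and flagged, never
# dropped: the kinesia score counts them while dwell/travel statistics
# exclude them.

.log_columns <- c("participant_id", "group", "task", "hand", "trial",
                  "state", "key", "t_press_ms", "t_release_ms")

#' Construct a tapping session
#'
#' A `tap_session` holds every key event of one hand x task x trial,
#' sorted by press time (stable on ties), together with the task window
#' metadata. It is the unit that [score_session()] consumes.
#'
#' @param participant_id participant identifier.
#' @param task `"DFT"` or `"BRAIN"`.
#' @param hand `"left"` or `"right"`.
#' @param trial trial index, integer >= 1.
#' @param state therapy state: `"On"`, `"Off"` or `"none"`.
#' @param events data.frame with columns `key`, `t_press`, `t_release`
#'   (ms from session start; `t_release` may be `NA` for presses that were
#'   never released before capture ended).
#' @param window_s task window in seconds; defaults to the task's standard
#'   window (20 for DFT, 30 for BRAIN).
#' @param t0 window start, ms (default 0).
#' @return object of class `tap_session`.
#' @examples
#' ev <- data.frame(key = "ArrowDown", t_press = c(0, 300), t_release = c(90, 410))
#' tap_session("p1", "DFT", "left", events = ev)
#' @export
tap_session <- function(participant_id, task, hand, trial = 1L,
                        state = "none", events = NULL,
                        window_s = task_window_s(task), t0 = 0) {
  task <- match.arg(task, c("DFT", "BRAIN"))
  hand <- match.arg(hand, c("left", "right"))
  state <- match.arg(state, c("none", "On", "Off"))
  if (is.null(events)) {
    events <- data.frame(key = character(), t_press = numeric(),
                         t_release = numeric())
  }
  stopifnot(all(c("key", "t_press", "t_release") %in% names(events)))
  events$key <- normalize_key(events$key)
  events$t_press <- as.numeric(events$t_press)
  events$t_release <- as.numeric(events$t_release)
  if (any(!is.finite(events$t_press)) || any(events$t_press < 0)) {
    stop("press times must be finite and non-negative")
  }
  bad <- !is.na(events$t_release) & events$t_release < events$t_press
  if (any(bad)) {
    stop("t_release < t_press at event ", which(bad)[1])
  }
  if (window_s <= 0) stop("window_s must be positive")
  events <- events[order(events$t_press), , drop = FALSE]  # stable sort
  rownames(events) <- NULL
  structure(
    list(participant_id = as.character(participant_id), task = task,
         hand = hand, trial = as.integer(trial), state = state,
         window_s = window_s, t0 = as.numeric(t0), events = events),
    class = "tap_session")
}

#' @export
print.tap_session <- function(x, ...) {
  cat(sprintf("<tap_session> %s  %s %s hand, trial %d, state %s\n",
              x$participant_id, x$task, x$hand, x$trial, x$state))
  cat(sprintf("  window: [%g, %g) ms, %d events\n",
              x$t0, x$t0 + 1000 * x$window_s, nrow(x$events)))
  invisible(x)
}

#' Construct a participant record
#'
#' Metadata plus tapping sessions for one participant: the analysis unit
#' from which the cohort table is built.
#'
#' @param participant_id unique identifier.
#' @param group `"PD"` or `"control"`.
#' @param age years (optional).
#' @param sex `"F"`, `"M"` or `NA`.
#' @param most_affected_side `"left"`, `"right"`, `"equal"` or `"unknown"`
#'   (PD only; controls carry `NA`).
#' @param updrs_iii_total MDS-UPDRS part III total (PD only, optional).
#' @param updrs_ft_subscore MDS-UPDRS finger-tapping item, sum of both
#'   hands 0-8 (PD only, optional).
#' @param sessions list of [tap_session()] objects.
#' @return object of class `participant_record`.
#' @export
participant_record <- function(participant_id, group, age = NA_real_,
                               sex = NA_character_,
                               most_affected_side = NA_character_,
                               updrs_iii_total = NA_real_,
                               updrs_ft_subscore = NA_real_,
                               sessions = list()) {
  group <- match.arg(group, c("PD", "control"))
  if (group == "control") {
    most_affected_side <- NA_character_
    updrs_iii_total <- NA_real_
    updrs_ft_subscore <- NA_real_
  } else if (!is.na(most_affected_side)) {
    most_affected_side <- match.arg(most_affected_side,
                                    c("left", "right", "equal", "unknown"))
  }
  structure(
    list(participant_id = as.character(participant_id), group = group,
         age = as.numeric(age), sex = as.character(sex),
         most_affected_side = most_affected_side,
         updrs_iii_total = as.numeric(updrs_iii_total),
         updrs_ft_subscore = as.numeric(updrs_ft_subscore),
         sessions = sessions),
    class = "participant_record")
}

#' @export
print.participant_record <- function(x, ...) {
  cat(sprintf("<participant_record> %s (%s), %d session(s)\n",
              x$participant_id, x$group, length(x$sessions)))
  invisible(x)
}

.check_log_frame <- function(df) {
  missing <- setdiff(.log_columns, names(df))
  if (length(missing)) {
    stop("keystroke log is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df$t_press_ms <- suppressWarnings(as.numeric(df$t_press_ms))
  df$t_release_ms <- suppressWarnings(as.numeric(df$t_release_ms))
  if (nrow(df)) {
    badp <- which(!is.finite(df$t_press_ms) | df$t_press_ms < 0)
    if (length(badp)) {
      stop("invalid press time at row ", badp[1],
           ": must be finite and non-negative")
    }
    badr <- which(!is.na(df$t_release_ms) &
                    df$t_release_ms < df$t_press_ms)
    if (length(badr)) {
      stop("t_release_ms < t_press_ms at row ", badr[1])
    }
    badt <- which(!toupper(df$task) %in% c("DFT", "BRAIN"))
    if (length(badt)) {
      stop("unknown task '", df$task[badt[1]], "' at row ", badt[1])
    }
    badh <- which(!tolower(df$hand) %in% c("left", "right"))
    if (length(badh)) {
      stop("unknown hand '", df$hand[badh[1]], "' at row ", badh[1])
    }
  }
  df
}

#' Read a keystroke event log
#'
#' Parses a keystroke log (one row per key event) and groups the rows into
#' [tap_session()] objects keyed by (participant, task, hand, trial), each
#' attached to a [participant_record()]. Parsing is order-insensitive:
#' shuffled input rows yield identical sessions.
#'
#' Required columns: `participant_id`, `group`, `task`, `hand`, `trial`,
#' `state`, `key`, `t_press_ms`, `t_release_ms`. Absent values are coded
#' `NA` (CSV: the string `"NA"` or empty). An `NA` release marks a press
#' that was never released before capture ended; it is preserved and
#' flagged, not dropped.
#'
#' @param source path to the log file.
#' @param format `"csv"` or `"jsonl"` (one event object per line).
#' @param metadata optional data.frame or CSV path with participant
#'   metadata (columns `participant_id`, `group`, `age`, `sex`,
#'   `most_affected_side`, `updrs_iii_total`, `updrs_ft_subscore`).
#' @return list of `participant_record` objects, ordered by first
#'   appearance of each participant in the file after sorting by id.
#' @seealso [write_keystroke_log()] for the inverse operation.
#' @export
read_keystroke_log <- function(source, format = c("csv", "jsonl"),
                               metadata = NULL) {
  format <- match.arg(format)
  if (!file.exists(source)) stop("no such file: ", source)
  df <- if (format == "csv") {
    classes <- c(t_press_ms = "numeric", t_release_ms = "numeric",
                 participant_id = "character")
    header <- names(read.csv(source, nrows = 0))
    read.csv(source, stringsAsFactors = FALSE, na.strings = c("NA", ""),
             colClasses = classes[names(classes) %in% header])
  } else {
    lines <- readLines(source, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      as.data.frame(setNames(rep(list(character(0)), length(.log_columns)),
                             .log_columns))
    } else {
      rows <- lapply(lines, function(l) {
        as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }
  }
  df <- .check_log_frame(df)
  keystroke_frame_to_records(df, metadata = metadata)
}

#' Assemble participant records from a keystroke event data.frame
#'
#' The in-memory counterpart of [read_keystroke_log()]; useful when events
#' are produced programmatically.
#'
#' @param df data.frame with the keystroke log columns.
#' @inheritParams read_keystroke_log
#' @return list of `participant_record` objects.
#' @export
keystroke_frame_to_records <- function(df, metadata = NULL) {
  df <- .check_log_frame(df)
  if (is.character(metadata)) {
    metadata <- read.csv(metadata, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""),
                         colClasses = c(participant_id = "character"))
  }
  if (!nrow(df)) return(list())
  df$participant_id <- as.character(df$participant_id)
  df$task <- toupper(df$task)
  df$hand <- tolower(df$hand)
  df$state <- ifelse(is.na(df$state) | df$state == "", "none", df$state)
  ids <- sort(unique(df$participant_id))
  records <- lapply(ids, function(id) {
    sub <- df[df$participant_id == id, , drop = FALSE]
    keys <- unique(sub[, c("task", "hand", "trial", "state")])
    keys <- keys[order(keys$task, keys$hand, keys$trial), , drop = FALSE]
    sessions <- lapply(seq_len(nrow(keys)), function(i) {
      k <- keys[i, ]
      ev <- sub[sub$task == k$task & sub$hand == k$hand &
                  sub$trial == k$trial, , drop = FALSE]
      tap_session(id, k$task, k$hand, trial = k$trial, state = k$state,
                  events = data.frame(key = ev$key,
                                      t_press = ev$t_press_ms,
                                      t_release = ev$t_release_ms))
    })
    meta <- list(group = sub$group[1])
    if (!is.null(metadata)) {
      m <- metadata[as.character(metadata$participant_id) == id, , drop = FALSE]
      if (nrow(m) == 1) {
        meta <- list(group = m$group,
                     age = m$age, sex = m$sex,
                     most_affected_side = m$most_affected_side,
                     updrs_iii_total = m$updrs_iii_total,
                     updrs_ft_subscore = m$updrs_ft_subscore)
      }
    }
    do.call(participant_record,
            c(list(participant_id = id, sessions = sessions), meta))
  })
  records
}

#' Write a keystroke event log
#'
#' Serialises participant records back to the tabular event-log format so
#' that `read_keystroke_log(write_keystroke_log(x))` reproduces the same
#' sessions (round-trip identity at the written precision).
#'
#' @param records list of `participant_record` objects.
#' @param path destination file.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_keystroke_log <- function(records, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  rows <- lapply(records, function(rec) {
    do.call(rbind, lapply(rec$sessions, function(s) {
      if (!nrow(s$events)) return(NULL)
      data.frame(participant_id = rec$participant_id, group = rec$group,
                 task = s$task, hand = s$hand, trial = s$trial,
                 state = s$state, key = s$events$key,
                 t_press_ms = s$events$t_press,
                 t_release_ms = s$events$t_release,
                 stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- as.data.frame(setNames(rep(list(character(0)),
                                     length(.log_columns)), .log_columns))
  }
  if (format == "csv") {
    write.csv(df, path, row.names = FALSE, na = "NA")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(df))) {
      writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE,
                                  na = "null", digits = NA), con)
    }
  }
  invisible(path)
}

#' Write participant metadata
#'
#' @param records list of `participant_record` objects.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r) {
    data.frame(participant_id = r$participant_id, group = r$group,
               age = r$age, sex = r$sex,
               most_affected_side = r$most_affected_side,
               updrs_iii_total = r$updrs_iii_total,
               updrs_ft_subscore = r$updrs_ft_subscore,
               stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Validate a tapping session
#'
#' Produces a validity report for one session. For the DFT task this
#' operationalises the protocol's hold-key requirement (the middle finger
#' must keep the left-arrow key depressed throughout the window): the
#' report gives the fraction of the window covered by hold-key depression
#' and marks the session invalid when coverage falls below
#' `hold_threshold`. Validation never throws; degenerate sessions simply
#' come back flagged.
#'
#' @param session a [tap_session()].
#' @param hold_threshold minimum hold-key coverage fraction for a DFT
#'   session to count as valid (default 0.90).
#' @return list of class `session_report`: `hold_coverage` (fraction of
#'   the window with the hold key depressed; `NA` for tasks without a hold
#'   key), `n_off_target` (events on keys that are neither target nor
#'   hold), `n_unreleased`, `n_outside_window` (target presses outside the
#'   half-open window), `n_target` and `valid` with `reasons`.
#' @export
validate_session <- function(session, hold_threshold = 0.90) {
  stopifnot(inherits(session, "tap_session"))
  ev <- session$events
  win <- c(session$t0, session$t0 + 1000 * session$window_s)
  targets <- task_keys(session$task)
  hk <- hold_key(session$task)
  is_target <- ev$key %in% targets
  is_hold <- !is.na(hk) & ev$key %in% hk
  coverage <- NA_real_
  if (!is.na(hk)) {
    hev <- ev[is_hold, , drop = FALSE]
    if (!nrow(hev)) {
      coverage <- 0
    } else {
      # union of hold intervals clipped to the window; unreleased holds
      # extend to the window end
      lo <- pmax(hev$t_press, win[1])
      hi <- pmin(ifelse(is.na(hev$t_release), win[2], hev$t_release), win[2])
      keep <- hi > lo
      lo <- lo[keep]; hi <- hi[keep]
      if (!length(lo)) {
        coverage <- 0
      } else {
        o <- order(lo)
        lo <- lo[o]; hi <- hi[o]
        tot <- 0; cur_lo <- lo[1]; cur_hi <- hi[1]
        for (i in seq_along(lo)[-1]) {
          if (lo[i] <= cur_hi) cur_hi <- max(cur_hi, hi[i])
          else { tot <- tot + (cur_hi - cur_lo); cur_lo <- lo[i]; cur_hi <- hi[i] }
        }
        tot <- tot + (cur_hi - cur_lo)
        coverage <- tot / diff(win)
      }
    }
  }
  in_window <- ev$t_press >= win[1] & ev$t_press < win[2]
  reasons <- character()
  if (!any(is_target & in_window)) reasons <- c(reasons, "no_target_taps")
  if (!is.na(coverage) && coverage < hold_threshold) {
    reasons <- c(reasons, "hold_coverage_below_threshold")
  }
  structure(list(
    hold_coverage = coverage,
    n_off_target = sum(!is_target & !is_hold),
    n_unreleased = sum(is.na(ev$t_release)),
    n_outside_window = sum(is_target & !in_window),
    n_target = sum(is_target & in_window),
    valid = length(reasons) == 0L,
    reasons = reasons), class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf(
    "<session_report> valid: %s%s\n  hold coverage %.3f | off-target %d | unreleased %d | outside window %d\n",
    x$valid, if (length(x$reasons)) paste0(" (", paste(x$reasons, collapse = ", "), ")") else "",
    x$hold_coverage, x$n_off_target, x$n_unreleased, x$n_outside_window))
  invisible(x)
}

#' Write a score table
#'
#' One row per participant x task x hand x trial with the three kinetic
#' parameters, tap counts, validity flags and session metadata; stable
#' column order and fixed numeric precision so the file round-trips.
#'
#' @param scores data.frame as produced by [score_cohort()].
#' @param path destination CSV.
#' @param digits decimal places for the kinetic parameters (default 6).
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, digits = 6) {
  cols <- c("participant_id", "group", "task", "hand", "trial", "state",
            "ks", "at", "is_", "n_taps_complete", "n_travel",
            "alternation_errors", "valid", "reasons")
  missing <- setdiff(cols, names(scores))
  for (m in missing) scores[[m]] <- NA
  out <- scores[, cols, drop = FALSE]
  for (col in c("ks", "at", "is_")) out[[col]] <- round(out[[col]], digits)
  write.csv(out, path, row.names = FALSE, na = "NA")
  invisible(path)
}
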
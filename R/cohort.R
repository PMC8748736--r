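# Reduction of per-session scores to one analysis value per participant
# and parameter.
#
# Hand-selection rule: hand performance differs in healthy controls, so
# controls contribute the average of both hands; PD is an asymmetric
# disease, so patients contribute the most affected side (ties, coded
# "equal", average both hands). Within a hand, the first valid trial is
# used — mirroring a deployed protocol in which only the first successful
# test is recorded — and later trials are reserved for the reliability
# analyses.

.parameters <- c("ks", "at", "is_")
.param_labels <- function(task) {
  suffix <- if (task == "DFT") "20" else "30"
  setNames(paste0(c("KS", "AT", "IS"), suffix), .parameters)
}

.first_valid <- function(scores) {
  v <- scores[scores$valid, , drop = FALSE]
  if (!nrow(v)) return(NULL)
  v[which.min(v$trial), , drop = FALSE]
}

#' Per-participant analysis value
#'
#' Reduces a participant's session scores to the single value used in the
#' group analyses: controls average left and right hands (a single
#' available hand is used alone, flagged); PD participants contribute the
#' most affected side, averaging both when the sides are coded as equally
#' affected. One trial per hand (the first valid one) enters.
#'
#' @param record a [participant_record()].
#' @param parameter `"ks"`, `"at"` or `"is_"`.
#' @param task `"DFT"` or `"BRAIN"`.
#' @param scores optional pre-computed [score_cohort()] table for this
#'   participant; computed from the record's sessions when absent.
#' @return list with `value` (numeric or `NA`), `flags` (character).
#' @export
analysis_value <- function(record, parameter = c("ks", "at", "is_"),
                           task = c("DFT", "BRAIN"), scores = NULL) {
  parameter <- match.arg(parameter)
  task <- match.arg(task)
  if (is.null(scores)) scores <- score_cohort(list(record))
  scores <- scores[scores$task == task &
                     scores$participant_id == record$participant_id, ,
                   drop = FALSE]
  per_hand <- setNames(rep(NA_real_, 2), c("left", "right"))
  for (h in c("left", "right")) {
    first <- .first_valid(scores[scores$hand == h, , drop = FALSE])
    if (!is.null(first)) per_hand[h] <- first[[parameter]]
  }
  flags <- character()
  avail <- !is.na(per_hand)
  if (!any(avail)) {
    return(list(value = NA_real_, flags = "no_valid_session"))
  }
  if (record$group == "control") {
    if (!all(avail)) flags <- c(flags, "single_hand")
    value <- mean(per_hand[avail])
  } else {
    side <- record$most_affected_side
    if (is.na(side) || identical(side, "unknown")) {
      flags <- c(flags, "most_affected_side_unknown")
      value <- mean(per_hand[avail])
    } else if (side == "equal") {
      value <- mean(per_hand[avail])
    } else if (avail[side]) {
      value <- per_hand[[side]]
    } else {
      flags <- c(flags, "most_affected_hand_missing")
      value <- per_hand[avail][1]
    }
  }
  list(value = unname(value), flags = flags)
}

#' Build the cohort analysis table
#'
#' Assembles one row per participant carrying the analysis value of every
#' kinetic parameter for every task present, plus covariates and clinical
#' scores. Participants lacking a valid value for some parameter keep
#' their row with an `NA` entry — never a silent drop; the number of
#' absent entries per column is recorded in the `"n_missing"` attribute.
#' Construction is invariant to the input order of records.
#'
#' @param records list of [participant_record()] objects.
#' @param hold_threshold passed to [score_cohort()].
#' @return data.frame of class `cohort_table` with columns
#'   `participant_id`, `group`, `age`, `sex`, `updrs_iii_total`,
#'   `updrs_ft_subscore` and one column per parameter (`KS20`, `AT20`,
#'   `IS20` and, when BRAIN sessions exist, `KS30`, `AT30`, `IS30`).
#' @export
build_cohort_table <- function(records, hold_threshold = 0.90) {
  ids <- vapply(records, `[[`, "", "participant_id")
  if (anyDuplicated(ids)) {
    stop("duplicate participant_id: ", ids[duplicated(ids)][1])
  }
  records <- records[order(ids)]
  scores <- score_cohort(records, hold_threshold = hold_threshold)
  tasks <- intersect(c("DFT", "BRAIN"), unique(scores$task))
  rows <- lapply(records, function(rec) {
    row <- data.frame(participant_id = rec$participant_id,
                      group = rec$group, age = rec$age, sex = rec$sex,
                      updrs_iii_total = rec$updrs_iii_total,
                      updrs_ft_subscore = rec$updrs_ft_subscore,
                      stringsAsFactors = FALSE)
    for (task in tasks) {
      labels <- .param_labels(task)
      for (p in .parameters) {
        row[[labels[[p]]]] <-
          analysis_value(rec, p, task,
                         scores = scores[scores$participant_id ==
                                           rec$participant_id, ,
                                         drop = FALSE])$value
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  value_cols <- setdiff(names(out),
                        c("participant_id", "group", "age", "sex",
                          "updrs_iii_total", "updrs_ft_subscore"))
  attr(out, "n_missing") <- vapply(out[value_cols],
                                   function(v) sum(is.na(v)), 0L)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d participants (%d PD, %d control)\n",
              nrow(x), sum(x$group == "PD"), sum(x$group == "control")))
  print.data.frame(head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("  ...\n")
  nm <- attr(x, "n_missing")
  if (any(nm > 0)) {
    cat("  missing analysis values:",
        paste(sprintf("%s=%d", names(nm)[nm > 0], nm[nm > 0]),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a cohort table to CSV
#'
#' @param table a [build_cohort_table()] result.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' @param path CSV written by [write_cohort_table()].
#' @return `cohort_table` data.frame.
#' @export
read_cohort_table <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""),
                  colClasses = c(participant_id = "character"))
  class(out) <- c("cohort_table", "data.frame")
  out
}
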
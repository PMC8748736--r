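# Test-retest reliability on repeated sessions: two-way mixed-effects
# consistency ICC, single measure (ICC(3,1)), and a one-way
# repeated-measures ANOVA for a learning effect across sessions.

#' Build a subjects x sessions repeat matrix
#'
#' Pivots a long table of repeated measurements into the complete
#' subjects-by-sessions grid that the reliability statistics require.
#' Subjects with any missing session are dropped (their count is kept in
#' the `"n_dropped"` attribute).
#'
#' @param df data.frame with columns `participant_id`, `session_index`,
#'   `value` (alternative column names can be given).
#' @param id,session,value column names.
#' @return numeric matrix of class `repeat_matrix` (rows = subjects,
#'   columns = sessions).
#' @export
repeat_matrix <- function(df, id = "participant_id",
                          session = "session_index", value = "value") {
  df <- as.data.frame(df)[, c(id, session, value)]
  names(df) <- c("id", "session", "value")
  if (anyDuplicated(df[, c("id", "session")])) {
    stop("duplicate (participant, session) measurement")
  }
  sessions <- sort(unique(df$session))
  ids <- sort(unique(df$id))
  m <- matrix(NA_real_, length(ids), length(sessions),
              dimnames = list(as.character(ids), as.character(sessions)))
  m[cbind(match(df$id, ids), match(df$session, sessions))] <- df$value
  complete <- rowSums(is.na(m)) == 0
  out <- m[complete, , drop = FALSE]
  if (nrow(out) < 2 || ncol(out) < 2) {
    stop("repeat matrix needs >= 2 complete subjects and >= 2 sessions")
  }
  attr(out, "n_dropped") <- sum(!complete)
  class(out) <- c("repeat_matrix", class(out))
  out
}

.two_way_ms <- function(m) {
  # two-way (subject x session) ANOVA mean squares on a complete grid
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_sess <- n * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_sess
  list(ms_subj = ss_subj / (n - 1),
       ms_sess = ss_sess / (k - 1),
       ms_err = ss_err / ((n - 1) * (k - 1)),
       df_sess = k - 1, df_err = (n - 1) * (k - 1))
}

#' Intraclass correlation, two-way mixed, consistency, single measure
#'
#' ICC(3,1) from the two-way ANOVA decomposition of a complete
#' subjects x sessions grid:
#' \deqn{ICC(3,1) = (MS_S - MS_E) / (MS_S + (k - 1) MS_E)}
#' where \eqn{MS_S} is the between-subjects mean square, \eqn{MS_E} the
#' residual mean square and \eqn{k} the number of sessions. Consistency
#' ICC discounts session-level shifts, so a constant learning offset does
#' not reduce reliability. The qualitative band follows Koo & Li (2016):
#' below 0.5 poor, 0.5-0.75 moderate, 0.75-0.9 good, above 0.9 excellent.
#'
#' @param m a [repeat_matrix()] (or plain numeric matrix, subjects in
#'   rows).
#' @return list with `icc`, `band`, `ms` (the ANOVA mean squares), `n`,
#'   `k`.
#' @export
icc_consistency <- function(m) {
  m <- unclass(m)
  stopifnot(is.matrix(m), nrow(m) >= 2, ncol(m) >= 2, !anyNA(m))
  if (all(m == m[1, 1])) stop("zero total variance")
  ms <- .two_way_ms(m)
  icc <- (ms$ms_subj - ms$ms_err) /
    (ms$ms_subj + (ncol(m) - 1) * ms$ms_err)
  band <- if (icc < 0.5) "poor" else if (icc < 0.75) "moderate"
          else if (icc <= 0.9) "good" else "excellent"
  list(icc = icc, band = band, ms = ms, n = nrow(m), k = ncol(m))
}

#' One-way repeated-measures ANOVA for a learning effect
#'
#' Tests whether the session factor shifts performance across repeated
#' administrations (a learning effect) with a within-subject one-way
#' ANOVA: F = MS_sessions / MS_residual on (k-1) and (n-1)(k-1) df. No
#' sphericity correction is applied by default; Greenhouse-Geisser
#' adjustment of the degrees of freedom is available.
#'
#' @param m a [repeat_matrix()].
#' @param correction `"none"` (default) or `"greenhouse-geisser"`.
#' @return list with `F`, `p_value`, `df1`, `df2`, `correction`,
#'   `epsilon` (GG epsilon when requested).
#' @export
learning_effect_anova <- function(m, correction = c("none",
                                                    "greenhouse-geisser")) {
  correction <- match.arg(correction)
  m <- unclass(m)
  stopifnot(is.matrix(m), nrow(m) >= 2, ncol(m) >= 2, !anyNA(m))
  ms <- .two_way_ms(m)
  if (ms$ms_err == 0) {
    f <- if (ms$ms_sess == 0) 0 else Inf
  } else {
    f <- ms$ms_sess / ms$ms_err
  }
  df1 <- ms$df_sess; df2 <- ms$df_err
  eps <- NA_real_
  if (correction == "greenhouse-geisser") {
    s <- cov(m)  # k x k covariance across sessions
    k <- ncol(m)
    dbar <- mean(diag(s)); mbar <- mean(s)
    num <- (k * (dbar - mbar))^2
    den <- (k - 1) * (sum(s^2) - 2 * k * sum(rowMeans(s)^2) + k^2 * mbar^2)
    eps <- if (den == 0) 1 else max(1 / (k - 1), min(1, num / den))
    df1 <- df1 * eps; df2 <- df2 * eps
  }
  p <- if (is.infinite(f)) 0 else stats::pf(f, df1, df2, lower.tail = FALSE)
  if (f == 0) p <- 1
  list(F = f, p_value = p, df1 = df1, df2 = df2,
       correction = correction, epsilon = eps)
}
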
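# Seeded hierarchical simulator of tapping cohorts.
#
# Layer 1: subject-level target triples (ks_t, at_t, is_t) drawn from a
#   group profile. KS and AT targets are normal (both were analysed
#   parametrically in validation work); IS targets are lognormal matched
#   to printed medians/IQRs (IS was analysed non-parametrically). A
#   single latent severity factor with configurable loadings induces the
#   within-subject correlation between the three parameters.
# Layer 2: session synthesis. Given a target triple, a keystroke stream
#   is emitted whose *computed* scores hit the targets: exactly
#   round(ks_t) presses inside the window, dwells rescaled to sample mean
#   at_t exactly, travelling times rescaled to sample variance is_t
#   exactly. Travelling-time shapes are lognormal (right-skewed, strictly
#   positive), so large IS targets remain feasible without negative
#   flight times.
#
# All randomness flows through R's global RNG: set.seed(seed) gives full
# determinism.

#' Derive a between-subject SD from a printed 95% CI
#'
#' Inverts the normal-theory confidence interval of a group mean:
#' `sd = (CI half-width / 1.96) * sqrt(n)`. Asymmetric intervals use the
#' half-range, with a warning.
#'
#' @param mean group mean.
#' @param ci_lo,ci_hi 95% CI bounds, `ci_lo < mean < ci_hi`.
#' @param n group size, n >= 2.
#' @return the implied standard deviation.
#' @examples
#' derive_sd_from_ci(89.3, 85.6, 93.0, 65)  # ~15.2
#' @export
derive_sd_from_ci <- function(mean, ci_lo, ci_hi, n) {
  if (!(ci_lo <= mean && mean <= ci_hi) || ci_hi < ci_lo) {
    stop("malformed CI: need ci_lo <= mean <= ci_hi")
  }
  if (n < 2) stop("n must be >= 2")
  lo_half <- mean - ci_lo; hi_half <- ci_hi - mean
  half <- (ci_hi - ci_lo) / 2
  if (half > 0 && abs(lo_half - hi_half) / half > 0.05) {
    warning("asymmetric CI; using the half-range")
  }
  half / 1.96 * sqrt(n)
}

#' Lognormal parameters from a printed median and IQR
#'
#' `meanlog = log(median)`; `sdlog` is the half-range of the log quartiles
#' divided by the standard normal upper quartile 0.6745. Log-asymmetric
#' quartiles trigger a warning.
#'
#' @param median,q1,q3 printed median and quartiles, all > 0, `q1 <= q3`.
#' @return list with `meanlog`, `sdlog`.
#' @export
lognormal_from_median_iqr <- function(median, q1, q3) {
  if (min(median, q1, q3) <= 0 || q3 < q1) stop("malformed median/IQR")
  lmed <- log(median); l1 <- log(q1); l3 <- log(q3)
  half <- (l3 - l1) / 2
  if (half > 0 && abs((lmed - l1) - (l3 - lmed)) / half > 0.05) {
    warning("quartiles asymmetric on the log scale; using the half-range")
  }
  list(meanlog = lmed, sdlog = half / qnorm(0.75))
}

#' Group profile for the cohort simulator
#'
#' Bundles the subject-level distribution of the three kinetic-parameter
#' targets for one group, the latent-severity loadings that correlate
#' them, and the within-subject session noise scales.
#'
#' @param n group size.
#' @param ks_mean,ks_sd normal distribution of subject KS targets (taps).
#' @param at_mean,at_sd normal distribution of subject AT targets (ms).
#' @param is_meanlog,is_sdlog lognormal distribution of subject IS
#'   targets (ms^2).
#' @param loadings latent severity loadings, `c(ks=, at=, is=)`; the
#'   severity factor is standard normal, and each parameter's standard
#'   score is `loading * severity + sqrt(1 - loading^2) * noise`.
#' @param session_noise within-subject session-to-session noise:
#'   `ks_sd` (taps), `at_sd` (ms), `is_sdlog` (log scale). Defaults give
#'   test-retest ICC around 0.9 for KS.
#' @param age_mean,age_sd,p_female demographics.
#' @param task task whose window constrains feasibility (default DFT).
#' @return list of class `group_profile`.
#' @export
group_profile <- function(n, ks_mean, ks_sd, at_mean, at_sd,
                          is_meanlog, is_sdlog,
                          loadings = c(ks = -0.6, at = 0.6, is = 0.6),
                          session_noise = list(ks_sd = 5, at_sd = 11,
                                               is_sdlog = 0.19),
                          age_mean = 68, age_sd = 9.5, p_female = 0.5,
                          task = "DFT") {
  stopifnot(n >= 1, ks_sd >= 0, at_sd >= 0, is_sdlog >= 0,
            all(abs(loadings) <= 1))
  structure(list(n = n, ks_mean = ks_mean, ks_sd = ks_sd,
                 at_mean = at_mean, at_sd = at_sd,
                 is_meanlog = is_meanlog, is_sdlog = is_sdlog,
                 loadings = loadings, session_noise = session_noise,
                 age_mean = age_mean, age_sd = age_sd,
                 p_female = p_female, task = task),
            class = "group_profile")
}

#' Default group profiles
#'
#' Reference profiles reproducing the DFT group summary statistics of the
#' test's clinical validation cohort: 55 PD patients with mean KS20 55.0
#' (95% CI 48.9-61.1), mean AT20 195.6 ms (168.7-222.5) and median IS20
#' 4589 ms^2 (IQR 1137-13464); 65 controls with mean KS20 89.3
#' (85.6-93.0), mean AT20 105.5 ms (97.5-113.4) and median IS20 779.5
#' ms^2 (IQR 357.7-779.5). Between-subject SDs are derived from the
#' printed CIs with [derive_sd_from_ci()]; IS lognormal parameters from
#' the printed median/IQR with [lognormal_from_median_iqr()].
#'
#' @return a `group_profile`.
#' @export
pd_profile <- function() {
  is_par <- suppressWarnings(lognormal_from_median_iqr(4589, 1137, 13464))
  group_profile(
    n = 55,
    ks_mean = 55.0, ks_sd = derive_sd_from_ci(55.0, 48.9, 61.1, 55),
    at_mean = 195.6, at_sd = derive_sd_from_ci(195.6, 168.7, 222.5, 55),
    is_meanlog = is_par$meanlog, is_sdlog = is_par$sdlog,
    age_mean = 66.8, age_sd = 9.6, p_female = 0.44)
}

#' @rdname pd_profile
#' @export
control_profile <- function() {
  is_par <- suppressWarnings(lognormal_from_median_iqr(779.5, 357.7, 779.5))
  group_profile(
    n = 65,
    ks_mean = 89.3, ks_sd = derive_sd_from_ci(89.3, 85.6, 93.0, 65),
    at_mean = 105.5, at_sd = derive_sd_from_ci(105.5, 97.5, 113.4, 65),
    is_meanlog = is_par$meanlog, is_sdlog = is_par$sdlog,
    age_mean = 71.2, age_sd = 9.5, p_female = 0.55)
}

# feasibility: the dwell must fit into the mean tap cycle
# window_ms / ks with room to spare, and the travelling-time spread must
# not swamp the mean travelling time (cv <= 3 is what the right-skewed
# flight-time shape can realise with strictly positive times)
.feasible_targets <- function(ks, at, is_, window_s, margin = 0.90) {
  if (ks < 0.5) return(FALSE)
  cycle <- 1000 * window_s / round(ks)  # the session emits round(ks) taps
  gap <- cycle - at
  at >= 10 && is_ >= 0 && at <= margin * cycle && sqrt(is_) <= 3 * gap
}

#' Draw subject-level target triples from a group profile
#'
#' Samples (ks_t, at_t, is_t) for each subject, correlated through the
#' latent severity factor, truncated to physically feasible ranges
#' (ks >= 1, at > 0, dwell fitting the mean tap cycle). Infeasible draws
#' are redrawn up to 100 times, then an error is raised.
#'
#' @param profile a [group_profile()].
#' @param n number of subjects (default `profile$n`).
#' @return data.frame with columns `ks_t`, `at_t`, `is_t`, `severity`.
#' @export
sample_subject_profile <- function(profile, n = profile$n) {
  stopifnot(inherits(profile, "group_profile"))
  l <- profile$loadings
  win <- task_window_s(profile$task)
  # the idiosyncratic residual of each parameter is redrawn conditionally
  # on the parameters already fixed, so feasibility truncation of AT and
  # IS does not select on (and hence bias) the KS draw
  redraw <- function(gen, ok) {
    for (i in seq_len(100)) {
      val <- gen()
      if (ok(val)) return(val)
    }
    stop("no feasible target triple after 100 redraws; ",
         "check the profile's location/scale parameters")
  }
  draw_one <- function() {
    z <- rnorm(1)
    ks <- redraw(
      function() profile$ks_mean + profile$ks_sd *
        (l[["ks"]] * z + sqrt(1 - l[["ks"]]^2) * rnorm(1)),
      function(v) v >= 1)
    cycle <- 1000 * win / round(ks)
    at <- redraw(
      function() profile$at_mean + profile$at_sd *
        (l[["at"]] * z + sqrt(1 - l[["at"]]^2) * rnorm(1)),
      function(v) v >= 10 && v <= 0.90 * cycle)
    is_ <- redraw(
      function() exp(profile$is_meanlog + profile$is_sdlog *
                       (l[["is"]] * z + sqrt(1 - l[["is"]]^2) * rnorm(1))),
      function(v) sqrt(v) <= 3 * (cycle - at))
    c(ks_t = ks, at_t = at, is_t = is_, severity = z)
  }
  out <- as.data.frame(t(vapply(seq_len(n), function(i) draw_one(),
                                numeric(4))))
  out
}

# draw m values with sample mean `centre` exactly and sample sd `spread`
# exactly, using a lognormal shape so values stay positive for any
# spread < centre * sqrt(m - 1) (right-skew absorbs large variances)
.match_moments_positive <- function(m, centre, spread, floor = 1) {
  if (m == 1) return(centre)
  if (spread == 0) return(rep(centre, m))
  cv <- spread / centre
  sdlog <- sqrt(log(1 + cv^2))
  for (i in seq_len(100)) {
    x <- rlnorm(m, meanlog = log(centre) - sdlog^2 / 2, sdlog = sdlog)
    if (sd(x) == 0) next
    g <- centre + spread * (x - mean(x)) / sd(x)
    if (min(g) > floor) return(g)
  }
  stop("cannot fit spread ", signif(spread, 3),
       " around ", signif(centre, 3), " with positive values")
}

#' Synthesize a tapping session hitting a target triple
#'
#' Emits a keystroke session whose computed scores reproduce the targets:
#' exactly `round(ks_t)` complete target-key presses inside the window;
#' dwell times with sample mean exactly `at_t`; travelling (flight) times
#' with sample variance exactly `is_t`. The mean travelling time is set
#' so the taps span 98% of the window. DFT sessions include a hold-key
#' event covering the whole window; BRAIN sessions alternate the two
#' target keys.
#'
#' @param ks_t,at_t,is_t target kinesia score (taps), akinesia time (ms)
#'   and incoordination score (ms^2).
#' @param task `"DFT"` or `"BRAIN"`.
#' @param participant_id,hand,trial,state session metadata.
#' @param dwell_cv coefficient of variation of individual dwells around
#'   `at_t` (shape only; the sample mean is exact). Default 0.15.
#' @param fill fraction of the window spanned by the taps (default 0.98).
#' @return a [tap_session()].
#' @export
synthesize_session <- function(ks_t, at_t, is_t, task = "DFT",
                               participant_id = "sim", hand = "left",
                               trial = 1L, state = "none",
                               dwell_cv = 0.15, fill = 0.98) {
  task <- match.arg(task, c("DFT", "BRAIN"))
  window_s <- task_window_s(task)
  window_ms <- 1000 * window_s
  n <- max(0L, as.integer(round(ks_t)))
  if (n == 0) {
    return(tap_session(participant_id, task, hand, trial, state))
  }
  if (!.feasible_targets(n, at_t, is_t, window_s)) {
    stop("infeasible targets: dwell ", signif(at_t, 4),
         " ms does not fit the mean tap cycle ",
         signif(window_ms / n, 4), " ms")
  }
  dwell <- if (n == 1) at_t else {
    .match_moments_positive(n, at_t, dwell_cv * at_t, floor = 1)
  }
  if (n >= 2) {
    gap_mean <- (fill * window_ms - sum(dwell[-n])) / (n - 1)
    if (gap_mean <= 0) {
      stop("infeasible targets: dwells leave no room for travelling time")
    }
    gaps <- if (n == 2) gap_mean else {
      .match_moments_positive(n - 1, gap_mean, sqrt(is_t), floor = 0.5)
    }
    press <- cumsum(c(0, dwell[-n] + gaps))
  } else {
    press <- window_ms / 2
  }
  release <- press + dwell
  keys <- if (task == "DFT") rep("ArrowDown", n) else {
    rep_len(c("s", ";"), n)
  }
  events <- data.frame(key = keys, t_press = press, t_release = release)
  if (task == "DFT") {
    events <- rbind(
      data.frame(key = "ArrowLeft", t_press = 0, t_release = window_ms),
      events)
  }
  tap_session(participant_id, task, hand, trial, state, events = events)
}

.clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

.session_targets <- function(base, noise, window_s) {
  # apply within-subject session noise to a subject target triple,
  # re-truncating to feasibility; the noise of each parameter is redrawn
  # conditionally on the ones already fixed (KS first) so truncation
  # does not bias the KS marginal
  try_n <- function(gen, ok, fallback) {
    for (i in seq_len(100)) {
      val <- gen()
      if (ok(val)) return(val)
    }
    fallback
  }
  ks <- try_n(function() base[["ks_t"]] + rnorm(1, 0, noise$ks_sd),
              function(v) v >= 1, base[["ks_t"]])
  cycle <- 1000 * window_s / max(1, round(ks))
  at <- try_n(function() base[["at_t"]] + rnorm(1, 0, noise$at_sd),
              function(v) v >= 10 && v <= 0.90 * cycle,
              min(base[["at_t"]], 0.90 * cycle))
  is_ <- try_n(function() base[["is_t"]] * exp(rnorm(1, 0, noise$is_sdlog)),
               function(v) sqrt(v) <= 3 * (cycle - at),
               min(base[["is_t"]], (3 * (cycle - at))^2))
  c(ks_t = ks, at_t = at, is_t = is_)
}

#' Generate a synthetic tapping cohort
#'
#' Draws a full cohort of participant records with keystroke-level
#' sessions: by default 55 PD and 65 controls, two hands per subject, one
#' trial per hand and task. For PD subjects the drawn targets describe
#' the most affected side (matching the hand-selection rule used in the
#' analysis); the other hand is generated milder by the configurable
#' `better_hand` factors. MDS-UPDRS finger-tapping subscores are derived
#' from a monotone-decreasing noisy map of the subject's KS target, and
#' part-III totals from the latent severity, so correlation analyses have
#' signal.
#'
#' @param n_pd,n_control group sizes (defaults 55 and 65).
#' @param pd,control [group_profile()]s for the two groups.
#' @param tasks tasks to generate, subset of `c("DFT", "BRAIN")`. BRAIN
#'   targets reuse the DFT subject targets with the tap count scaled to
#'   the 30 s window.
#' @param seed optional seed for full determinism.
#' @param better_hand multiplicative adjustments for a PD subject's less
#'   affected hand: `ks_gain` added fraction of KS, `at_drop` removed
#'   fraction of AT, `is_factor` multiplier on IS.
#' @param trials number of trials per hand and task (default 1).
#' @return list of [participant_record()]s.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(n_pd = 5, n_control = 5, seed = 1)
#' build_cohort_table(cohort)
#' }
#' @export
generate_cohort <- function(n_pd = 55, n_control = 65,
                            pd = pd_profile(), control = control_profile(),
                            tasks = c("DFT", "BRAIN"), seed = NULL,
                            better_hand = list(ks_gain = 0.15,
                                               at_drop = 0.15,
                                               is_factor = 0.5),
                            trials = 1L) {
  if (!is.null(seed)) set.seed(seed)
  tasks <- match.arg(tasks, several.ok = TRUE)
  make_sessions <- function(id, targets_by_hand, noise, state = "none") {
    sessions <- list()
    for (task in tasks) {
      win <- task_window_s(task)
      scale_ks <- win / 20  # subject targets are parameterised on 20 s
      for (h in names(targets_by_hand)) {
        base <- targets_by_hand[[h]]
        base[["ks_t"]] <- base[["ks_t"]] * scale_ks
        for (tr in seq_len(trials)) {
          tg <- .session_targets(base, noise, win)
          sessions[[length(sessions) + 1L]] <-
            synthesize_session(tg[["ks_t"]], tg[["at_t"]], tg[["is_t"]],
                               task = task, participant_id = id,
                               hand = h, trial = tr, state = state)
        }
      }
    }
    sessions
  }
  records <- list()
  ctrl_targets <- sample_subject_profile(control, n_control)
  for (i in seq_len(n_control)) {
    id <- sprintf("C%03d", i)
    base <- unlist(ctrl_targets[i, c("ks_t", "at_t", "is_t")])
    # small independent hand-to-hand variation around the subject target
    hands <- lapply(setNames(nm = c("left", "right")), function(h) {
      .session_targets(base, control$session_noise,
                       task_window_s("DFT"))
    })
    records[[length(records) + 1L]] <- participant_record(
      id, "control",
      age = round(rnorm(1, control$age_mean, control$age_sd)),
      sex = if (runif(1) < control$p_female) "F" else "M",
      sessions = make_sessions(id, hands, control$session_noise))
  }
  pd_targets <- sample_subject_profile(pd, n_pd)
  sides <- sample(c("left", "right", "equal"), n_pd, replace = TRUE,
                  prob = c(0.65, 0.31, 0.04))
  for (i in seq_len(n_pd)) {
    id <- sprintf("P%03d", i)
    base <- unlist(pd_targets[i, c("ks_t", "at_t", "is_t")])
    better <- c(ks_t = base[["ks_t"]] * (1 + better_hand$ks_gain),
                at_t = base[["at_t"]] * (1 - better_hand$at_drop),
                is_t = base[["is_t"]] * better_hand$is_factor)
    win <- task_window_s("DFT")
    if (!.feasible_targets(better[["ks_t"]], better[["at_t"]],
                           better[["is_t"]], win)) {
      better <- base
    }
    side <- sides[i]
    hands <- switch(side,
      left = list(left = base, right = better),
      right = list(left = better, right = base),
      equal = list(left = base, right = base))
    z <- pd_targets$severity[i]
    ft <- round(.clamp(3.8 - 0.4 * 1.6 * (base[["ks_t"]] - pd$ks_mean) /
                         pd$ks_sd + 1.6 * sqrt(1 - 0.4^2) * rnorm(1),
                       0, 8))
    updrs <- round(.clamp(38.2 + 16.4 * (0.6 * z + 0.8 * rnorm(1)), 5, 90))
    records[[length(records) + 1L]] <- participant_record(
      id, "PD",
      age = round(rnorm(1, pd$age_mean, pd$age_sd)),
      sex = if (runif(1) < pd$p_female) "F" else "M",
      most_affected_side = side,
      updrs_iii_total = updrs, updrs_ft_subscore = ft,
      sessions = make_sessions(id, hands, pd$session_noise))
  }
  records
}

#' Fluctuation-study profile
#'
#' Per-outcome generative parameters for the On/Off fluctuation
#' simulator: Off-state level, additive On effect, between-subject SD,
#' trial-level SD and residual SD. Defaults reproduce the fluctuation
#' sub-study summaries (e.g. KS20 Off mean 62.78, On mean 71.78, so an On
#' effect of +9.0 taps) with between-subject SDs derived from the printed
#' CIs (n = 9); IS outcomes are generated on the log scale from the
#' printed medians/IQRs. Residual and trial SDs are free parameters of
#' the simulator.
#'
#' @param outcomes named list; each element a list with `off`, `effect`,
#'   `subject_sd`, `trial_sd`, `residual_sd`, and optionally
#'   `log_scale = TRUE` (the four parameters then live on the log scale)
#'   or `integer = TRUE` with `lo`/`hi` (clinical rating, rounded and
#'   clamped).
#' @return list of class `fluctuation_profile`.
#' @export
fluctuation_profile <- function(outcomes = NULL) {
  if (is.null(outcomes)) {
    is_off <- suppressWarnings(lognormal_from_median_iqr(3452, 1833, 20178))
    is_on <- suppressWarnings(lognormal_from_median_iqr(1232, 845.3, 10017))
    outcomes <- list(
      KS20 = list(off = 62.78, effect = 71.78 - 62.78,
                  subject_sd = derive_sd_from_ci(62.78, 50.06, 75.50, 9),
                  trial_sd = 2, residual_sd = 7),
      AT20 = list(off = 155.0, effect = 153.1 - 155.0,
                  subject_sd = derive_sd_from_ci(155.0, 118.3, 191.7, 9),
                  trial_sd = 3, residual_sd = 12),
      IS20 = list(off = is_off$meanlog,
                  effect = is_on$meanlog - is_off$meanlog,
                  subject_sd = is_off$sdlog, trial_sd = 0.1,
                  residual_sd = 0.4, log_scale = TRUE),
      KS30 = list(off = 1.5 * 62.78, effect = 9.0, subject_sd = 25,
                  trial_sd = 2, residual_sd = 9),
      AT30 = list(off = 150, effect = -2, subject_sd = 50,
                  trial_sd = 3, residual_sd = 12),
      IS30 = list(off = is_off$meanlog, effect = -0.5,
                  subject_sd = is_off$sdlog, trial_sd = 0.1,
                  residual_sd = 0.4, log_scale = TRUE),
      ft_subscore = list(off = 2.0, effect = 1.5 - 2.0,
                         subject_sd = derive_sd_from_ci(2, 1.37, 2.63, 8),
                         trial_sd = 0.1, residual_sd = 0.35,
                         integer = TRUE, lo = 0, hi = 8))
  }
  structure(list(outcomes = outcomes), class = "fluctuation_profile")
}

#' Generate an On/Off fluctuation series
#'
#' Simulates a day of repeated testing for fluctuating PD patients: each
#' subject completes `n_trials` tests at 90-minute intervals, states
#' alternating Off/On around levodopa doses (taken at the start of every
#' Off-to-On transition). Each outcome is baseline + subject intercept +
#' trial intercept + On effect + residual noise, per the profile.
#'
#' @param profile a [fluctuation_profile()].
#' @param n_subjects number of patients (default 9).
#' @param n_trials tests per patient (default 8).
#' @param seed optional seed.
#' @param start_hour clock time of the first test (default 8).
#' @param interval_h hours between tests (default 1.5).
#' @return long data.frame of class `fluctuation_series`: columns
#'   `participant_id`, `trial`, `clock_time` (hours), `state`,
#'   `levodopa_time` (hours, `NA` when no dose preceded the trial) and
#'   one column per outcome.
#' @export
generate_fluctuation_series <- function(profile = fluctuation_profile(),
                                        n_subjects = 9, n_trials = 8,
                                        seed = NULL, start_hour = 8,
                                        interval_h = 1.5) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(profile, "fluctuation_profile"),
            n_subjects >= 1, n_trials >= 2)
  states <- rep_len(c("Off", "On"), n_trials)
  clock <- start_hour + (seq_len(n_trials) - 1) * interval_h
  levodopa <- ifelse(states == "On", clock - 0.5, NA_real_)
  out <- expand.grid(trial = seq_len(n_trials),
                     participant_id = sprintf("F%02d", seq_len(n_subjects)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("participant_id", "trial")]
  out$clock_time <- clock[out$trial]
  out$state <- states[out$trial]
  out$levodopa_time <- levodopa[out$trial]
  on <- as.integer(out$state == "On")
  for (oc in names(profile$outcomes)) {
    p <- profile$outcomes[[oc]]
    subj_int <- rnorm(n_subjects, 0, p$subject_sd)
    trial_int <- rnorm(n_trials, 0, p$trial_sd)
    idx_s <- match(out$participant_id,
                   sprintf("F%02d", seq_len(n_subjects)))
    y <- p$off + subj_int[idx_s] + trial_int[out$trial] +
      p$effect * on + rnorm(nrow(out), 0, p$residual_sd)
    if (isTRUE(p$log_scale)) y <- exp(y)
    if (isTRUE(p$integer)) y <- round(.clamp(y, p$lo, p$hi))
    out[[oc]] <- y
  }
  rownames(out) <- NULL
  class(out) <- c("fluctuation_series", "data.frame")
  out
}
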
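# On/Off motor-fluctuation analysis: paired comparisons of each
# participant's best On vs best Off measurement, and a random-intercept
# mixed model of the therapy-state effect across repeated trials.

.better_direction <- c(KS20 = "high", KS30 = "high",
                       AT20 = "low", AT30 = "low",
                       IS20 = "low", IS30 = "low",
                       ft_subscore = "low")

#' Best-state values per participant
#'
#' For each participant, selects the best recorded measurement in each
#' therapy state: the extreme value in the clinically better direction
#' (e.g. the highest KS20 and the lowest AT20 within On trials, and
#' likewise within Off trials).
#'
#' @param series long data.frame with columns `participant_id`, `state`
#'   (`"On"`/`"Off"`) and the outcome column.
#' @param outcome outcome column name.
#' @param better direction that is clinically better: `"high"` (kinesia
#'   scores) or `"low"` (akinesia time, incoordination score, clinical
#'   ratings). Defaults from the outcome name when recognised.
#' @return data.frame with columns `participant_id`, `on`, `off`;
#'   participants lacking either state are dropped (count in the
#'   `"n_dropped"` attribute).
#' @export
best_state_values <- function(series, outcome,
                              better = .better_direction[[outcome]]) {
  better <- match.arg(better, c("high", "low"))
  pick <- if (better == "high") max else min
  df <- as.data.frame(series)
  df <- df[!is.na(df[[outcome]]) & df$state %in% c("On", "Off"), ]
  ids <- unique(df$participant_id)
  rows <- lapply(ids, function(id) {
    sub <- df[df$participant_id == id, ]
    on <- sub[[outcome]][sub$state == "On"]
    off <- sub[[outcome]][sub$state == "Off"]
    if (!length(on) || !length(off)) return(NULL)
    data.frame(participant_id = id, on = pick(on), off = pick(off),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  n_dropped <- length(ids) - NROW(out)
  if (is.null(out)) out <- data.frame(participant_id = character(),
                                      on = numeric(), off = numeric())
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Paired On/Off comparison
#'
#' Compares paired On and Off measurements: the normality gate on the
#' paired differences chooses between a two-tailed paired t-test and the
#' Wilcoxon matched-pairs signed-rank test. Group summaries mirror the
#' gated style: mean (95% CI) when parametric, median (IQR) otherwise.
#'
#' @param on_values,off_values numeric vectors paired by participant
#'   (same order), n >= 3.
#' @param alpha significance level (default 0.0025).
#' @return list of class `paired_comparison`: `test_used` (`"paired-t"`
#'   or `"wilcoxon-signed-rank"`), `statistic`, `p_value`, `summary_on`,
#'   `summary_off`, `mean_difference`, `significant`, `n`.
#' @export
paired_state_compare <- function(on_values, off_values,
                                 alpha = .keytap_alpha) {
  keep <- !is.na(on_values) & !is.na(off_values)
  on <- as.numeric(on_values[keep]); off <- as.numeric(off_values[keep])
  n <- length(on)
  if (n < 3) stop("paired comparison requires n >= 3 complete pairs")
  d <- on - off
  parametric <- if (sd(d) == 0) TRUE else normality_gate(d)$is_normal
  if (parametric) {
    if (sd(d) == 0) {
      statistic <- 0; p <- 1
      if (any(d != 0)) { statistic <- Inf; p <- 0 }
      test_used <- "paired-t"
    } else {
      tt <- t.test(on, off, paired = TRUE)
      statistic <- unname(tt$statistic); p <- tt$p.value
      test_used <- "paired-t"
    }
  } else {
    wt <- suppressWarnings(wilcox.test(on, off, paired = TRUE,
                                       exact = FALSE))
    statistic <- unname(wt$statistic); p <- wt$p.value
    test_used <- "wilcoxon-signed-rank"
  }
  structure(list(test_used = test_used, statistic = statistic,
                 p_value = p,
                 summary_on = .summary_for(on, parametric),
                 summary_off = .summary_for(off, parametric),
                 mean_difference = mean(d),
                 significant = p < alpha, alpha = alpha, n = n),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  fmt <- function(s) sprintf("%.4g (%.4g, %.4g)", s$location, s$lo, s$hi)
  cat(sprintf("<paired_comparison> %s: p = %.3g, n = %d\n",
              x$test_used, x$p_value, x$n))
  cat(sprintf("  On  %s\n  Off %s\n", fmt(x$summary_on), fmt(x$summary_off)))
  invisible(x)
}

#' Mixed model of the therapy-state effect
#'
#' Fits the linear mixed-effects model
#' `outcome ~ state + (1 | participant) + (1 | trial)` by REML: therapy
#' state (Off as reference, so the coefficient is the On effect) as the
#' fixed effect, with crossed random intercepts for subject and trial
#' number. The 95% CI on the state coefficient is Wald; the p-value is a
#' Wald z-test.
#'
#' @param series long data.frame with columns `participant_id`, `trial`,
#'   `state` and the outcome column (see
#'   [generate_fluctuation_series()]).
#' @param outcome outcome column name.
#' @return list of class `state_mixed_fit`: `coefficient` (On - Off),
#'   `ci95`, `se`, `p_value`, `intercept`, `variance_components` (subject,
#'   trial, residual), `singular` flag, `n_obs`, `n_subjects`.
#' @export
fit_state_mixed_model <- function(series, outcome) {
  df <- as.data.frame(series)
  df <- df[!is.na(df[[outcome]]) & df$state %in% c("On", "Off"), ]
  if (length(unique(df$state)) < 2) {
    stop("therapy state is constant; the state effect is not estimable")
  }
  if (length(unique(df$participant_id)) < 2) {
    stop("need >= 2 subjects")
  }
  dat <- data.frame(y = df[[outcome]],
                    state = factor(df$state, levels = c("Off", "On")),
                    subject = factor(df$participant_id),
                    trial = factor(df$trial))
  notes <- character()
  fit <- withCallingHandlers(
    suppressMessages(lme4::lmer(
      y ~ state + (1 | subject) + (1 | trial), data = dat, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore"))),
    warning = function(w) {
      # optimizer chatter (e.g. marginal gradient checks) is recorded on
      # the fit object instead of being raised mid-simulation
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  est <- unname(b["stateOn"]); s <- unname(se[2])
  z <- if (s > 0) est / s else Inf * sign(est)
  vc <- as.data.frame(lme4::VarCorr(fit))
  vcomp <- setNames(vc$vcov, vc$grp)
  structure(list(coefficient = est,
                 ci95 = c(est - qnorm(0.975) * s, est + qnorm(0.975) * s),
                 se = s,
                 p_value = 2 * pnorm(-abs(z)),
                 intercept = unname(b["(Intercept)"]),
                 variance_components = c(
                   subject = unname(vcomp["subject"]),
                   trial = unname(vcomp["trial"]),
                   residual = unname(vcomp["Residual"])),
                 singular = lme4::isSingular(fit),
                 notes = notes,
                 n_obs = nrow(dat),
                 n_subjects = nlevels(dat$subject),
                 fit = fit),
            class = "state_mixed_fit")
}

#' @export
print.state_mixed_fit <- function(x, ...) {
  cat(sprintf("<state_mixed_fit> On effect %.3f (95%% CI %.3f, %.3f), p = %.3g%s\n",
              x$coefficient, x$ci95[1], x$ci95[2], x$p_value,
              if (x$singular) " [singular fit]" else ""))
  cat(sprintf("  variances: subject %.3g | trial %.3g | residual %.3g | n = %d obs, %d subjects\n",
              x$variance_components["subject"],
              x$variance_components["trial"],
              x$variance_components["residual"], x$n_obs, x$n_subjects))
  invisible(x)
}

#' Full fluctuation analysis of a series
#'
#' For every outcome column present, runs [paired_state_compare()] on the
#' best-state values and [fit_state_mixed_model()] across all trials.
#'
#' @param series a fluctuation series (long data.frame).
#' @param outcomes outcome columns to analyse; defaults to the recognised
#'   tapping parameters and the finger-tapping subscore that are present.
#' @return list of class `fluctuation_analysis` with one element per
#'   outcome: `paired` and `mixed`.
#' @export
analyze_fluctuations <- function(series,
                                 outcomes = intersect(
                                   names(.better_direction),
                                   names(series))) {
  res <- lapply(outcomes, function(oc) {
    best <- best_state_values(series, oc)
    list(outcome = oc,
         paired = paired_state_compare(best$on, best$off),
         mixed = fit_state_mixed_model(series, oc))
  })
  names(res) <- outcomes
  structure(res, class = "fluctuation_analysis")
}

#' @export
print.fluctuation_analysis <- function(x, ...) {
  for (oc in names(x)) {
    cat(sprintf("== %s ==\n", oc))
    print(x[[oc]]$paired)
    print(x[[oc]]$mixed)
  }
  invisible(x)
}
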
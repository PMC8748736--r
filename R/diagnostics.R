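# PD-vs-control discrimination: normality-gated two-group tests,
# empirical ROC analysis, sensitivity at fixed specificity,
# logistic-regression combination and clinical-score correlation.
#
# Orientation convention: every parameter has a direction of abnormality
# — low KS is abnormal, high AT and high IS are abnormal. Internally all
# values are mapped to an "abnormality score" (negated for
# direction = "low") so that cases are expected to score high; AUC is the
# probability that a random case scores more abnormally than a random
# control, ties counted 1/2.

.abnormality_direction <- c(ks = "low", at = "high", is_ = "high",
                            KS = "low", AT = "high", IS = "high")

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardised sample skewness and kurtosis into the K^2
#' statistic, referred to a chi-squared distribution with 2 df. Requires
#' n >= 8 (the skewness normalisation is undefined below that).
#'
#' @param x numeric vector, n >= 8.
#' @return list with `statistic` (K^2), `p_value`, `z_skewness`,
#'   `z_kurtosis`.
#' @references D'Agostino, Belanger & D'Agostino Jr (1990), Am Stat 44:316.
#' @export
dagostino_pearson_test <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires n >= 8")
  if (sd(x) == 0) stop("zero variance")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  # skewness transform (D'Agostino 1970)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z_s <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis transform (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  denom <- 1 + xs * sqrt(2 / (a - 4))
  term2 <- sign(denom) * ((1 - 2 / a) / abs(denom))^(1 / 3)
  z_k <- ((1 - 2 / (9 * a)) - term2) / sqrt(2 / (9 * a))
  k2 <- z_s^2 + z_k^2
  list(statistic = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skewness = z_s, z_kurtosis = z_k)
}

#' Normality gate
#'
#' Decides whether a sample is treated as normally distributed for the
#' downstream choice between parametric and non-parametric procedures:
#' the D'Agostino-Pearson omnibus test for n >= 8, Shapiro-Wilk for
#' smaller samples; normal iff p >= 0.05.
#'
#' @param x numeric vector, n >= 3.
#' @return list with `is_normal`, `method`, `p_value`, `n`.
#' @export
normality_gate <- function(x) {
  x <- as.numeric(x[!is.na(x)])
  n <- length(x)
  if (n < 3) stop("normality assessment requires n >= 3")
  if (n >= 8) {
    res <- dagostino_pearson_test(x)
    list(is_normal = res$p_value >= 0.05, method = "dagostino-pearson",
         p_value = res$p_value, n = n)
  } else {
    res <- shapiro.test(x)
    list(is_normal = res$p.value >= 0.05, method = "shapiro-wilk",
         p_value = res$p.value, n = n)
  }
}

.mean_ci <- function(x, level = 0.95) {
  n <- length(x)
  half <- qt(1 - (1 - level) / 2, df = n - 1) * sd(x) / sqrt(n)
  c(mean = mean(x), lo = mean(x) - half, hi = mean(x) + half)
}

.summary_for <- function(x, parametric) {
  if (parametric) {
    ci <- .mean_ci(x)
    list(style = "mean_ci95", location = unname(ci["mean"]),
         lo = unname(ci["lo"]), hi = unname(ci["hi"]))
  } else {
    q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
    list(style = "median_iqr", location = q[2], lo = q[1], hi = q[3])
  }
}

#' Two-group comparison with normality gate
#'
#' Compares a PD sample with a control sample: when both groups pass the
#' [normality_gate()], an unpaired (equal-variance) t-test is used and
#' groups are summarised as mean (95% CI); otherwise a Mann-Whitney U
#' test with median (IQR) summaries. Significance is judged against the
#' Bonferroni-adjusted level 0.0025.
#'
#' @param x_pd,y_ctrl numeric vectors, each n >= 3.
#' @param alpha significance level (default 0.0025).
#' @return list of class `group_comparison`: `test_used`
#'   (`"unpaired-t"` or `"mann-whitney"`), `statistic`, `p_value`,
#'   `summary_pd`, `summary_ctrl`, `significant`, `alpha`, the per-group
#'   gate results.
#' @export
compare_groups <- function(x_pd, y_ctrl, alpha = .keytap_alpha) {
  x <- as.numeric(x_pd[!is.na(x_pd)])
  y <- as.numeric(y_ctrl[!is.na(y_ctrl)])
  if (length(x) < 3 || length(y) < 3) stop("each group needs n >= 3")
  gx <- normality_gate(x)
  gy <- normality_gate(y)
  parametric <- gx$is_normal && gy$is_normal
  if (parametric) {
    if (sd(x) == 0 && sd(y) == 0) stop("zero variance in both groups")
    tt <- t.test(x, y, var.equal = TRUE)
    statistic <- unname(tt$statistic)
    p <- tt$p.value
    test_used <- "unpaired-t"
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
    statistic <- unname(wt$statistic)
    p <- wt$p.value
    test_used <- "mann-whitney"
  }
  structure(list(test_used = test_used, statistic = statistic,
                 p_value = p,
                 summary_pd = .summary_for(x, parametric),
                 summary_ctrl = .summary_for(y, parametric),
                 significant = p < alpha, alpha = alpha,
                 gate_pd = gx, gate_ctrl = gy),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  fmt <- function(s) sprintf("%.4g (%.4g, %.4g)", s$location, s$lo, s$hi)
  cat(sprintf("<group_comparison> %s: p = %.3g (%ssignificant at %.4f)\n",
              x$test_used, x$p_value, if (x$significant) "" else "not ",
              x$alpha))
  cat(sprintf("  PD      %s [%s]\n", fmt(x$summary_pd), x$summary_pd$style))
  cat(sprintf("  control %s [%s]\n", fmt(x$summary_ctrl), x$summary_ctrl$style))
  invisible(x)
}

.abnormality_score <- function(values, direction) {
  direction <- match.arg(direction, c("low", "high"))
  if (direction == "low") -as.numeric(values) else as.numeric(values)
}

#' Empirical ROC analysis
#'
#' Computes the empirical AUC separating cases from controls with ties
#' counted 1/2 (the Mann-Whitney U statistic scaled by n1*n2), a DeLong
#' 95% confidence interval, and the full threshold sweep of
#' (cutoff, sensitivity, specificity) points.
#'
#' @param cases,controls numeric parameter values for each group.
#' @param direction direction of abnormality in cases: `"low"` (e.g.
#'   kinesia score) or `"high"` (e.g. akinesia time, incoordination
#'   score).
#' @param conf_level confidence level for the DeLong interval.
#' @return list of class `roc_result`: `auc`, `auc_ci95`, `se`, `points`
#'   (data.frame `cutoff` on the original value scale, `sensitivity`,
#'   `specificity`; a value is classified abnormal when it is at or
#'   beyond the cutoff in the abnormal direction), `direction`, `n_cases`,
#'   `n_controls`.
#' @export
empirical_auc <- function(cases, controls, direction = c("low", "high"),
                          conf_level = 0.95) {
  direction <- match.arg(direction)
  cases <- as.numeric(cases[!is.na(cases)])
  controls <- as.numeric(controls[!is.na(controls)])
  if (!length(cases) || !length(controls)) {
    stop("both groups must be non-empty")
  }
  cs <- .abnormality_score(cases, direction)
  ct <- .abnormality_score(controls, direction)
  m <- length(cs); n <- length(ct)
  # placement values: psi(case_i, control_j) = 1 / 0.5 / 0 for > / = / <
  # computed via ranks for O((m+n) log(m+n))
  r <- rank(c(cs, ct), ties.method = "average")
  auc <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  v10 <- (rank(c(cs, ct))[seq_len(m)] - rank(cs)) / n       # per-case
  v01 <- 1 - (rank(c(ct, cs))[seq_len(n)] - rank(ct)) / m   # per-control
  # rank() above uses average ties => placements already count ties 1/2
  s10 <- if (m > 1) var(v10) else 0
  s01 <- if (n > 1) var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - z * se), min(1, auc + z * se))
  # threshold sweep on the abnormality-score scale
  cuts <- sort(unique(c(cs, ct)))
  cuts <- c(cuts, Inf)
  sens <- vapply(cuts, function(cc) mean(cs >= cc), 0)
  spec <- vapply(cuts, function(cc) mean(ct < cc), 0)
  cutoff_values <- if (direction == "low") -cuts else cuts
  points <- data.frame(cutoff = cutoff_values, sensitivity = sens,
                       specificity = spec)
  structure(list(auc = auc, auc_ci95 = ci, se = se, points = points,
                 direction = direction, n_cases = m, n_controls = n),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f, %.3f), %d cases vs %d controls, abnormal = %s\n",
              x$auc, x$auc_ci95[1], x$auc_ci95[2], x$n_cases,
              x$n_controls, x$direction))
  invisible(x)
}

#' Wilson score confidence interval for a proportion
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf_level confidence level (default 0.95).
#' @return numeric `c(lo, hi)`.
#' @export
wilson_ci <- function(k, n, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lo = centre - half, hi = centre + half)
}

#' Sensitivity at a fixed specificity
#'
#' Chooses the most permissive decision threshold that achieves at least
#' the target specificity on the controls, and evaluates the cases'
#' sensitivity at that threshold. Candidate thresholds are midpoints
#' between adjacent observed values, so the returned cutoff never sits on
#' a data point.
#'
#' @inheritParams empirical_auc
#' @param spec_target target specificity in (0, 1), typically 0.80, 0.85
#'   or 0.90.
#' @return list with `sensitivity`, `specificity` (achieved), `cutoff`
#'   (original value scale; abnormal at or beyond it in the abnormal
#'   direction), `sensitivity_ci95` (Wilson).
#' @export
sensitivity_at_specificity <- function(cases, controls, spec_target,
                                       direction = c("low", "high")) {
  direction <- match.arg(direction)
  stopifnot(spec_target > 0, spec_target < 1)
  cases <- as.numeric(cases[!is.na(cases)])
  controls <- as.numeric(controls[!is.na(controls)])
  if (!length(cases) || !length(controls)) {
    stop("both groups must be non-empty")
  }
  cs <- .abnormality_score(cases, direction)
  ct <- .abnormality_score(controls, direction)
  vals <- sort(unique(c(cs, ct)))
  mids <- if (length(vals) > 1) (vals[-1] + vals[-length(vals)]) / 2 else numeric()
  cand <- c(min(vals) - 1, mids, max(vals) + 1)
  spec <- vapply(cand, function(cc) mean(ct < cc), 0)
  ok <- which(spec >= spec_target)
  if (!length(ok)) stop("specificity target unattainable")
  cc <- cand[min(ok)]  # most permissive qualifying threshold
  sens <- mean(cs >= cc)
  list(sensitivity = sens, specificity = spec[min(ok)],
       cutoff = if (direction == "low") -cc else cc,
       sensitivity_ci95 = wilson_ci(sum(cs >= cc), length(cs)))
}

#' Logistic-regression combination of parameters
#'
#' Fits a maximum-likelihood logistic regression of group on
#' z-standardised features (complete cases only; dropped rows are
#' counted), scores the in-sample fitted probabilities by
#' [empirical_auc()] (apparent AUC), and classifies at the requested
#' probability cutoffs. Perfect separation is flagged — the coefficients
#' are then reported as non-convergent but the AUC of the separating
#' score is still valid.
#'
#' @param features data.frame of numeric predictors (e.g. KS20, AT20,
#'   IS20 columns of a cohort table).
#' @param labels vector distinguishing cases from controls: logical
#'   (TRUE = case) or character with `"PD"` as the case label.
#' @param prob_cutoffs probability cutoffs at which sensitivity and
#'   specificity are reported (default 0.5 and 0.6).
#' @return list of class `combination_result`: `model` (the `glm` fit),
#'   `coefficients`, `auc` (a `roc_result`), `classification`
#'   (data.frame per cutoff), `separation` flag, `n_used`, `n_dropped`.
#' @export
combine_logistic <- function(features, labels, prob_cutoffs = c(0.5, 0.6)) {
  features <- as.data.frame(features)
  y <- if (is.logical(labels)) labels else labels %in% c("PD", "case", "1")
  keep <- complete.cases(features) & !is.na(y)
  n_dropped <- sum(!keep)
  features <- features[keep, , drop = FALSE]
  y <- y[keep]
  if (!any(y) || all(y)) stop("need both cases and controls")
  zfeat <- as.data.frame(lapply(features, function(v) {
    s <- sd(v)
    if (s == 0) stop("constant feature cannot be standardised")
    (v - mean(v)) / s
  }))
  dat <- cbind(zfeat, .y = as.integer(y))
  suspect <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        suspect <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  p_hat <- fit$fitted.values
  # perfect separation: the fitted score splits the groups exactly (the
  # MLE then diverges); extreme probabilities alone are not enough
  separation <- suspect && min(p_hat[y]) > max(p_hat[!y])
  roc <- empirical_auc(p_hat[y], p_hat[!y], direction = "high")
  classification <- do.call(rbind, lapply(prob_cutoffs, function(ct) {
    data.frame(prob_cutoff = ct,
               sensitivity = mean(p_hat[y] >= ct),
               specificity = mean(p_hat[!y] < ct))
  }))
  structure(list(model = fit,
                 coefficients = if (separation) NULL else coef(fit),
                 auc = roc, classification = classification,
                 separation = separation,
                 n_used = sum(keep), n_dropped = n_dropped),
            class = "combination_result")
}

#' @export
print.combination_result <- function(x, ...) {
  cat(sprintf("<combination_result> apparent AUC %.3f%s, n = %d (%d dropped)\n",
              x$auc$auc, if (x$separation) " [perfect separation]" else "",
              x$n_used, x$n_dropped))
  print(x$classification, row.names = FALSE)
  invisible(x)
}

#' Correlation with clinical scores
#'
#' Pearson's correlation and Spearman's rank correlation between a test
#' parameter and a clinical score, with two-sided p-values.
#'
#' @param values numeric test-parameter values.
#' @param clinical_scores paired clinical ratings (e.g. MDS-UPDRS
#'   finger-tapping subscores).
#' @return list with `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`, `n`.
#' @export
correlate_clinical <- function(values, clinical_scores) {
  keep <- !is.na(values) & !is.na(clinical_scores)
  x <- as.numeric(values[keep]); y <- as.numeric(clinical_scores[keep])
  if (length(x) < 4) stop("correlation requires n >= 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
  pe <- cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       n = length(x))
}

#' Evaluate a cohort table
#'
#' Runs the full discrimination battery on every kinetic-parameter column
#' of a cohort table: gated group comparison, empirical ROC with DeLong
#' CI, sensitivity at the standard specificity targets, plus
#' logistic-regression combinations (DFT parameters alone and DFT + BRAIN
#' when present) and correlation of each DFT parameter with the
#' finger-tapping subscore.
#'
#' @param cohort a [build_cohort_table()] result (or equivalent
#'   data.frame).
#' @param spec_targets specificity targets (default 0.90, 0.85, 0.80).
#' @param prob_cutoffs passed to [combine_logistic()].
#' @param alpha significance level (default 0.0025).
#' @return list of class `cohort_evaluation`: `parameters` (data.frame,
#'   one row per parameter x specificity target), `comparisons` (named
#'   list of `group_comparison`), `rocs` (named list of `roc_result`),
#'   `combinations`, `correlations`.
#' @export
evaluate_cohort <- function(cohort, spec_targets = c(0.90, 0.85, 0.80),
                            prob_cutoffs = c(0.5, 0.6),
                            alpha = .keytap_alpha) {
  cohort <- as.data.frame(cohort)
  param_cols <- intersect(c("KS20", "AT20", "IS20", "KS30", "AT30", "IS30"),
                          names(cohort))
  is_pd <- cohort$group == "PD"
  comparisons <- list(); rocs <- list(); rows <- list()
  for (p in param_cols) {
    dirn <- unname(.abnormality_direction[substr(p, 1, 2)])
    cases <- cohort[[p]][is_pd]; controls <- cohort[[p]][!is_pd]
    cmp <- compare_groups(cases, controls, alpha = alpha)
    roc <- empirical_auc(cases, controls, direction = dirn)
    comparisons[[p]] <- cmp; rocs[[p]] <- roc
    for (st in spec_targets) {
      sas <- sensitivity_at_specificity(cases, controls, st, direction = dirn)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, direction = dirn, test_used = cmp$test_used,
        p_value = cmp$p_value, significant = cmp$significant,
        auc = roc$auc, auc_lo = roc$auc_ci95[1], auc_hi = roc$auc_ci95[2],
        spec_target = st, sensitivity = sas$sensitivity,
        cutoff = sas$cutoff, stringsAsFactors = FALSE)
    }
  }
  combinations <- list()
  dft <- intersect(c("KS20", "AT20", "IS20"), param_cols)
  if (length(dft) >= 2) {
    combinations$dft <- combine_logistic(cohort[, dft, drop = FALSE],
                                         cohort$group,
                                         prob_cutoffs = prob_cutoffs)
  }
  if (length(param_cols) > length(dft) && length(param_cols) >= 2) {
    combinations$dft_brain <- combine_logistic(
      cohort[, param_cols, drop = FALSE], cohort$group,
      prob_cutoffs = prob_cutoffs)
  }
  correlations <- list()
  if ("updrs_ft_subscore" %in% names(cohort) &&
      sum(is_pd & !is.na(cohort$updrs_ft_subscore)) >= 4) {
    for (p in dft) {
      correlations[[p]] <- tryCatch(
        correlate_clinical(cohort[[p]][is_pd],
                           cohort$updrs_ft_subscore[is_pd]),
        error = function(e) NULL)
    }
  }
  structure(list(parameters = do.call(rbind, rows),
                 comparisons = comparisons, rocs = rocs,
                 combinations = combinations,
                 correlations = correlations),
            class = "cohort_evaluation")
}

#' @export
print.cohort_evaluation <- function(x, ...) {
  cat("<cohort_evaluation>\n")
  df <- x$parameters
  df$p_value <- signif(df$p_value, 3)
  df$auc <- round(df$auc, 3)
  df$sensitivity <- round(df$sensitivity, 3)
  df$cutoff <- round(df$cutoff, 1)
  print(df[, c("parameter", "test_used", "p_value", "auc",
               "spec_target", "sensitivity", "cutoff")],
        row.names = FALSE)
  for (nm in names(x$combinations)) {
    cat(sprintf("combination [%s]: ", nm)); print(x$combinations[[nm]])
  }
  invisible(x)
}
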
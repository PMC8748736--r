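test_that("the K^2 omnibus statistic matches an independent reference", {
  # reference values computed with an independent implementation of the
  # D'Agostino-Pearson omnibus test (scipy.stats.normaltest)
  x <- c(2, 5, 3, 8, 7, 1, 4, 9, 6, 5, 7, 3, 2, 8, 10, 4)
  res <- dagostino_pearson_test(x)
  expect_equal(res$statistic, 1.5358536027557057, tolerance = 1e-10)
  expect_equal(res$p_value, 0.46397398210488405, tolerance = 1e-10)
  expect_equal(res$z_skewness, 0.28736676075369294, tolerance = 1e-10)
  expect_equal(res$z_kurtosis, -1.205518124114953, tolerance = 1e-10)

  y <- c(1.2, 3.4, 0.5, 9.9, 2.2, 4.4, 3.1, 0.9, 5.5, 2.8, 7.7, 1.1)
  expect_equal(dagostino_pearson_test(y)$statistic, 3.797599145035125,
               tolerance = 1e-10)
})

test_that("the normality gate picks the test by sample size", {
  expect_error(normality_gate(c(1, 2)), "n >= 3")
  g5 <- normality_gate(c(1.2, 2.4, 1.8, 3.1, 2.2))
  expect_equal(g5$method, "shapiro-wilk")
  g8 <- normality_gate(c(1.2, 2.4, 1.8, 3.1, 2.2, 2.9, 1.5, 2.0))
  expect_equal(g8$method, "dagostino-pearson")
})

test_that("the gate accepts normal and rejects heavy-tailed samples", {
  set.seed(11)
  pass_normal <- 0; fail_lnorm <- 0
  for (i in 1:100) {
    pass_normal <- pass_normal + normality_gate(rnorm(200))$is_normal
    fail_lnorm <- fail_lnorm +
      !normality_gate(rlnorm(200, 0, 1.5))$is_normal
  }
  expect_gte(pass_normal, 90)
  expect_gte(fail_lnorm, 99)
})

test_that("compare_groups gates the test and judges Bonferroni significance", {
  set.seed(12)
  x <- rnorm(30); y <- x + rnorm(30, 0, 1e-3)
  same <- compare_groups(x, y)
  expect_gt(same$p_value, 0.9)
  expect_false(same$significant)
  expect_equal(same$test_used, "unpaired-t")
  expect_equal(same$summary_pd$style, "mean_ci95")

  far <- compare_groups(rnorm(30, 10, 1), rnorm(30, 0, 1))
  expect_lt(far$p_value, 0.0025)
  expect_true(far$significant)

  skewed <- compare_groups(rlnorm(60, 2, 1.5), rlnorm(60, 0, 1.5))
  expect_equal(skewed$test_used, "mann-whitney")
  expect_equal(skewed$summary_pd$style, "median_iqr")
})

test_that("simulated KS20 groups separate at p < 0.001 in nearly all runs", {
  hits <- 0
  for (seed in 1:50) {
    set.seed(seed)
    pd <- rnorm(55, 55.0, derive_sd_from_ci(55.0, 48.9, 61.1, 55))
    ct <- rnorm(65, 89.3, derive_sd_from_ci(89.3, 85.6, 93.0, 65))
    hits <- hits + (compare_groups(pd, ct)$p_value < 0.001)
  }
  expect_gte(hits, 50 * 0.99)
})

test_that("empirical AUC matches hand-enumerated and degenerate cases", {
  # perfectly separated
  expect_equal(empirical_auc(c(1, 2, 3), c(10, 11), "low")$auc, 1.0)
  # identical values -> ties count 1/2
  expect_equal(empirical_auc(rep(5, 4), rep(5, 6), "high")$auc, 0.5)
  # cases {1,2,3}, controls {2.5,3.5,4}, higher = more normal:
  # concordant pairs: 8 of 9
  expect_equal(empirical_auc(c(1, 2, 3), c(2.5, 3.5, 4), "low")$auc, 8 / 9)
  expect_error(empirical_auc(numeric(), c(1, 2), "low"), "non-empty")
})

test_that("AUC equals exhaustive pairwise concordance on random inputs", {
  set.seed(13)
  for (i in 1:25) {
    dirn <- sample(c("low", "high"), 1)
    n1 <- sample(2:60, 1); n2 <- sample(2:60, 1)
    cases <- round(rnorm(n1, 0, 2), sample(0:1, 1))  # force some ties
    controls <- round(rnorm(n2, 1, 2), sample(0:1, 1))
    got <- empirical_auc(cases, controls, dirn)$auc
    expect_equal(got, brute_force_auc(cases, controls, dirn),
                 tolerance = 1e-12)
  }
})

test_that("AUC is monotone-invariant and direction-reversal maps to 1-AUC", {
  set.seed(14)
  cases <- rnorm(40, 1); controls <- rnorm(50)
  a <- empirical_auc(cases, controls, "high")$auc
  expect_equal(empirical_auc(exp(cases), exp(controls), "high")$auc, a)
  expect_equal(empirical_auc(cases, controls, "low")$auc, 1 - a)
})

test_that("the DeLong interval agrees with pROC", {
  set.seed(15)
  cases <- rnorm(40, 1.2); controls <- rnorm(55)
  got <- empirical_auc(cases, controls, "high")
  ref <- pROC::ci.auc(pROC::roc(
    response = c(rep(1, 40), rep(0, 55)),
    predictor = c(cases, controls), quiet = TRUE, direction = "<"),
    method = "delong")
  expect_equal(got$auc, as.numeric(ref[2]), tolerance = 1e-12)
  expect_equal(got$auc_ci95[1], as.numeric(ref[1]), tolerance = 1e-6)
  expect_equal(got$auc_ci95[2], as.numeric(ref[3]), tolerance = 1e-6)
})

test_that("sensitivity at fixed specificity picks the most permissive cutoff", {
  # perfect separation -> sensitivity 1 at every target
  for (st in c(0.80, 0.85, 0.90)) {
    expect_equal(sensitivity_at_specificity(c(1, 2, 3), c(9, 10, 11),
                                            st, "low")$sensitivity, 1.0)
  }
  # cases {1,2,3,4}, controls {3,4,5,6}, low = abnormal, target 0.75:
  # the most permissive qualifying threshold sits between 3 and 4
  # (abnormal <= cutoff): exactly one control {3} misclassified, spec
  # 3/4, and cases {1,2,3} caught, sensitivity 3/4
  r <- sensitivity_at_specificity(c(1, 2, 3, 4), c(3, 4, 5, 6),
                                  0.75, "low")
  expect_equal(r$sensitivity, 0.75)
  expect_gt(r$cutoff, 3); expect_lt(r$cutoff, 4)
  expect_gte(r$specificity, 0.75)
})

test_that("the reported operating point lies on the ROC curve", {
  set.seed(16)
  cases <- rnorm(60, 50, 15); controls <- rnorm(80, 90, 15)
  roc <- empirical_auc(cases, controls, "low")
  for (st in c(0.80, 0.85, 0.90)) {
    op <- sensitivity_at_specificity(cases, controls, st, "low")
    on_curve <- any(abs(roc$points$sensitivity - op$sensitivity) < 1e-12 &
                      roc$points$specificity >= st)
    expect_true(on_curve)
  }
})

test_that("logistic combination flags separation and resists noise features", {
  # one perfectly separating feature
  sep <- combine_logistic(data.frame(f = c(1:10, 21:30)),
                          rep(c("control", "PD"), each = 10))
  expect_true(sep$separation)
  expect_null(sep$coefficients)
  expect_equal(sep$auc$auc, 1.0)

  set.seed(17)
  y <- rep(c(TRUE, FALSE), each = 250)
  informative <- rnorm(500) + 2 * y
  a1 <- combine_logistic(data.frame(x = informative), y)$auc$auc
  a2 <- combine_logistic(data.frame(x = informative, z = rnorm(500)),
                         y)$auc$auc
  expect_lt(abs(a1 - a2), 0.05)

  # combining never loses much against the best single feature
  f3 <- data.frame(a = rnorm(500) + 1.5 * y, b = rnorm(500) + 0.8 * y,
                   c = rnorm(500) + 0.4 * y)
  best_single <- max(vapply(f3, function(v) {
    empirical_auc(v[y], v[!y], "high")$auc
  }, 0))
  expect_gte(combine_logistic(f3, y)$auc$auc, best_single - 0.02)

  # complete-case handling reports dropped rows
  f3$a[1:5] <- NA
  expect_equal(combine_logistic(f3, y)$n_dropped, 5)
})

test_that("correlation returns both coefficients with expected behaviour", {
  x <- c(1, 2, 3, 4, 5, 6)
  r <- correlate_clinical(x, -x)
  expect_equal(r$pearson_r, -1)
  expect_equal(r$spearman_rho, -1)

  y <- exp(x)  # monotone nonlinear
  r2 <- correlate_clinical(x, y)
  expect_equal(r2$spearman_rho, 1)
  expect_lt(r2$pearson_r, 1)

  expect_error(correlate_clinical(x, rep(1, 6)), "zero variance")
  expect_error(correlate_clinical(1:3, 3:1), "n >= 4")
})

test_that("correlation estimates recover a planted r = -0.40 on average", {
  set.seed(18)
  r_target <- -0.40
  est <- replicate(1000, {
    z <- rnorm(55)
    x <- z
    y <- r_target * z + sqrt(1 - r_target^2) * rnorm(55)
    cor(x, y)
  })
  expect_lt(abs(mean(est) - r_target), 0.03)
})
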
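test_that("tie-corrected AUC equals exhaustive pair counting", {
  expect_equal(auc_mann_whitney(c(1, 3, 2, 4),
                                c("term", "term", "sptb", "sptb")), 0.75)
  expect_equal(auc_mann_whitney(c(1, 2, 9, 10),
                                c("term", "term", "sptb", "sptb")), 1)
  expect_equal(auc_mann_whitney(rep(2, 6), rep(c("sptb", "term"), 3)), 0.5)
  set.seed(10)
  for (i in 1:10) {
    n1 <- sample(5:40, 1); n0 <- sample(5:40, 1)
    scores <- round(c(rnorm(n1, 0.5), rnorm(n0)), 1)
    labels <- c(rep("sptb", n1), rep("term", n0))
    expect_equal(auc_mann_whitney(scores, labels),
                 oracle_auc_pairs(scores, labels), tolerance = 1e-12)
    expect_equal(auc_mann_whitney(scores, labels),
                 oracle_auc_trapezoid(scores, labels), tolerance = 1e-12)
  }
  expect_error(auc_mann_whitney(1:3, rep("sptb", 3)), "both classes")
})

test_that("AUC agrees with pROC on tied data", {
  skip_if_not_installed("pROC")
  set.seed(20)
  scores <- round(c(rnorm(60, 0.7), rnorm(80)), 1)
  labels <- c(rep("sptb", 60), rep("term", 80))
  ref <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(labels, scores, levels = c("term", "sptb"),
                        direction = "<"))))
  expect_equal(auc_mann_whitney(scores, labels), ref, tolerance = 1e-12)
})

test_that("bootstrap CIs are deterministic given the seed", {
  set.seed(30)
  scores <- c(rnorm(30, 1), rnorm(30))
  labels <- rep(c("sptb", "term"), each = 30)
  a <- bootstrap_ci(scores, labels, B = 200, seed = 9L)
  b <- bootstrap_ci(scores, labels, B = 200, seed = 9L)
  expect_identical(a$reps, b$reps)
  expect_lte(a$lo, a$hi)
  # a metric constant across resamples collapses the interval
  const <- bootstrap_ci(scores, labels, metric = function(s, l) 0.42,
                        B = 50, seed = 1L)
  expect_equal(const$lo, 0.42)
  expect_equal(const$hi, 0.42)
})

test_that("bootstrap intervals cover the true AUC at close to nominal rate", {
  set.seed(40)
  delta <- calibrate_effect_size(0.80)
  cover <- 0
  n_rep <- 60
  for (i in seq_len(n_rep)) {
    scores <- c(rnorm(100, delta), rnorm(100))
    labels <- rep(c("sptb", "term"), each = 100)
    ci <- bootstrap_ci(scores, labels, B = 200, seed = i)
    cover <- cover + (ci$lo <= 0.80 && 0.80 <= ci$hi)
  }
  expect_gte(cover / n_rep, 0.85)  # nominal 0.95 less MC/percentile slack
})

test_that("confusion metrics follow the 2x2 definitions and flag gaps", {
  cls <- c(rep("high", 17), rep("low", 83))
  labs <- c(rep("sptb", 8), rep("term", 9), rep("sptb", 2), rep("term", 81))
  cm <- confusion_metrics(cls, labs)
  expect_equal(cm$sensitivity, 0.8)
  expect_equal(cm$specificity, 0.9)
  expect_equal(cm$ppv, 8 / 17, tolerance = 1e-3)
  expect_equal(cm$npv, 81 / 83, tolerance = 1e-3)
  perfect <- confusion_metrics(c("high", "high", "low"),
                               c("sptb", "sptb", "term"))
  expect_equal(unlist(perfect[1:4]), c(sensitivity = 1, specificity = 1,
                                       ppv = 1, npv = 1))
  none <- confusion_metrics(rep("low", 4), c("sptb", "term", "term", "term"))
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 1)
  expect_true(is.na(none$ppv))
  expect_equal(none$undefined, "ppv")
})

test_that("stratification respects boundaries and the minimum stratum size", {
  m <- derive_youden_threshold(c(0, 1), c("term", "sptb"),
                               derivation_cohort = "disc")
  # 13+6 boundary: a draw at 13.8 weeks is below 13+6/7 and stays in T1
  d <- data.frame(score = rnorm(40),
                  group = rep(c("sptb", "term"), 20),
                  ga_sample_wk = c(13.8, rep(10, 19), rep(18, 10),
                                   rep(22, 10)))
  sch <- strat_scheme("trimester", min_stratum_n = 15)
  got <- stratified_performance(d, sch, m, B = 20, seed = 1L)
  expect_equal(got$n_case[got$stratum == "T1"] +
                 got$n_control[got$stratum == "T1"], 20)
  # a 14-sample stratum is suppressed with the stated reason
  d14 <- data.frame(score = rnorm(34),
                    group = rep(c("sptb", "term"), 17),
                    ga_sample_wk = c(rep(10, 14), rep(18, 20)))
  got14 <- stratified_performance(d14, strat_scheme("trimester"), m,
                                  B = 20, seed = 1L)
  t1 <- got14[got14$stratum == "T1", ]
  expect_equal(t1$reason, "insufficient n")
  expect_true(is.na(t1$auc))
  # scheme "none" is the whole cohort
  got_all <- stratified_performance(d, strat_scheme("none"), m, B = 20,
                                    seed = 1L)
  expect_equal(nrow(got_all), 1)
  expect_equal(got_all$n_case + got_all$n_control, 40)
})

test_that("trimester boundary arithmetic places 13+6 in T1 and 14.0 in T2", {
  m <- derive_youden_threshold(c(0, 1), c("term", "sptb"))
  d <- data.frame(score = rep(c(1, 0), 10),
                  group = rep(c("sptb", "term"), 10),
                  ga_sample_wk = c(rep(13 + 6 / 7, 10), rep(14, 10)))
  got <- stratified_performance(d, strat_scheme("trimester",
                                                min_stratum_n = 5), m,
                                B = 10, seed = 1L)
  expect_equal(got$n_case[got$stratum == "T1"] +
                 got$n_control[got$stratum == "T1"], 10)
  expect_equal(got$n_case[got$stratum == "T2"] +
                 got$n_control[got$stratum == "T2"], 10)
})

test_that("prevalence-weighted bootstrap converges to the Bayes predictive value", {
  # population with sensitivity 0.8 and specificity 0.9 at cutoff 0.5
  scores <- c(rep(1, 80), rep(0, 20), rep(1, 50), rep(0, 450))
  labels <- c(rep("sptb", 100), rep("term", 500))
  m <- structure(list(predictor = "panel", cutoff = 0.5,
                      derivation_cohort = "disc", youden_j = 0.7,
                      sensitivity = 0.8, specificity = 0.9),
                 class = "threshold_model")
  bayes_ppv <- function(se, sp, pi) se * pi / (se * pi + (1 - sp) * (1 - pi))
  for (pi in c(0.104, 0.059)) {
    got <- prevalence_weighted_bootstrap(scores, labels, m, prevalence = pi,
                                         B = 1000, seed = 3L)
    se_boot <- stats::sd(got$ppv_reps, na.rm = TRUE) / sqrt(1000)
    expect_lt(abs(got$ppv[["mean"]] - bayes_ppv(0.8, 0.9, pi)),
              3 * se_boot + 0.01)
  }
  # point values from the Bayes oracle
  expect_equal(bayes_ppv(0.8, 0.9, 0.104), 0.4815, tolerance = 1e-3)
  expect_equal(bayes_ppv(0.8, 0.9, 0.059), 0.334, tolerance = 1e-2)
  # perfect classifier: PPV 1 in every replicate
  perf <- prevalence_weighted_bootstrap(
    c(rep(1, 50), rep(0, 200)), c(rep("sptb", 50), rep("term", 200)),
    m, prevalence = 0.104, B = 100, seed = 4L)
  expect_equal(unname(perf$ppv[["mean"]]), 1)
  # determinism
  g1 <- prevalence_weighted_bootstrap(scores, labels, m, 0.104, B = 50,
                                      seed = 8L)
  g2 <- prevalence_weighted_bootstrap(scores, labels, m, 0.104, B = 50,
                                      seed = 8L)
  expect_identical(g1$ppv_reps, g2$ppv_reps)
  expect_error(prevalence_weighted_bootstrap(1:3, c("sptb", "term", "term"),
                                             m, prevalence = 0.01, B = 10,
                                             seed = 1L), "larger")
})

test_that("cross-platform agreement reproduces hand-computed cases", {
  same <- cross_platform_agreement(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$r, 1)
  expect_equal(same$bias, 0)
  expect_equal(same$limits, c(0, 0))
  half <- cross_platform_agreement(c(1, 2, 3), c(1, 3, 2))
  expect_equal(half$r, 0.5)
  shift <- cross_platform_agreement(c(1, 2, 3), c(2, 3, 4))
  expect_equal(shift$r, 1)
  expect_equal(shift$bias, -1)
  expect_equal(shift$limits, c(-1, -1))
  flat <- cross_platform_agreement(c(1, 1, 1), c(1, 2, 3))
  expect_true(flat$r_undefined)
  expect_error(cross_platform_agreement(1:2, 1:2), "three")
})

test_that("pooled t from printed summaries reproduces the cohort table", {
  r <- pooled_t_from_summary(11, 25.5, 5.1, 14, 26.9, 4.7)
  expect_equal(round(r$statistic, 1), 0.7)
  expect_equal(r$df, 23)
  r2 <- pooled_t_from_summary(50, 31.5, 4.8, 23, 32.6, 3.8)
  expect_equal(round(r2$statistic, 2), 0.97)
  expect_equal(r2$df, 71)
})

test_that("Fisher exact p-values match enumeration and printed values", {
  expect_equal(round(fisher_exact_2x2(matrix(c(0, 11, 6, 7), 2,
                                             byrow = TRUE)), 3), 0.016)
  expect_equal(fisher_exact_2x2(matrix(c(3, 3, 5, 5), 2)), 1)
  tab <- matrix(c(1, 9, 9, 1), 2)
  expect_equal(fisher_exact_2x2(tab), oracle_fisher_enum(tab),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(tab), 0.001093, tolerance = 1e-3)
  set.seed(50)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 5) + 1, 2)
    expect_equal(fisher_exact_2x2(tab), oracle_fisher_enum(tab),
                 tolerance = 1e-10)
    expect_equal(fisher_exact_2x2(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
  expect_error(fisher_exact_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("chi-square on a perfectly separated table equals the total count", {
  set.seed(60)
  for (i in 1:5) {
    n1 <- sample(5:60, 1); n2 <- sample(5:60, 1)
    part <- data.frame(group = c(rep("term", n1), rep("sptb", n2)),
                       age_yr = rnorm(n1 + n2, 30, 4),
                       bmi = rnorm(n1 + n2, 24, 3),
                       category = c(rep("ctrl", n1), rep("case", n2)))
    got <- cohort_table_stats(part, continuous = c(age_yr = "t",
                                                   bmi = "ranksum"),
                              categorical = "category")
    chisq <- got$statistic[got$variable == "category" & got$test == "chisq"]
    if (length(chisq) == 1) expect_equal(chisq, n1 + n2, tolerance = 1e-9)
  }
})

test_that("demographic statistics choose chi-square or Fisher appropriately", {
  part <- data.frame(
    group = c(rep("term", 11), rep("sptb", 13)),
    age_yr = c(rnorm(11, 25.5, 5.1), rnorm(13, 26.9, 4.7)),
    bmi = c(rnorm(11, 28, 7), rnorm(13, 30, 9)),
    mode_delivery = c(rep("vaginal", 11), rep("cesarean", 6),
                      rep("vaginal", 7)))
  got <- cohort_table_stats(part)
  expect_equal(got$test[got$variable == "mode_delivery"], "fisher")
  expect_equal(got$test[got$variable == "age_yr"], "t")
  expect_equal(got$df[got$variable == "age_yr"], 22)
  big <- data.frame(group = rep(c("term", "sptb"), c(194, 114)),
                    age_yr = rnorm(308, 30, 3), bmi = rnorm(308, 25, 3),
                    mode_delivery = c(rep(c("cesarean", "vaginal"),
                                          c(61, 133)),
                                      rep(c("cesarean", "vaginal"),
                                          c(67, 47))))
  got_big <- cohort_table_stats(big)
  md <- got_big[got_big$variable == "mode_delivery", ]
  expect_equal(md$test, "chisq")
  expect_equal(md$statistic, 22.08, tolerance = 1e-3)
})
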
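#' Tie-corrected AUC via the Mann-Whitney statistic
#'
#' `AUC = [#(case > control) + 0.5 #(case = control)] / (n_case n_control)`,
#' computed through midranks.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Character/factor per score; `case_level` marks cases.
#' @param case_level Case label (default `"sptb"`).
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, labels, case_level = "sptb") {
  labels <- as.character(labels)
  is_case <- labels == case_level
  n1 <- sum(is_case); n0 <- sum(!is_case)
  stop_if_not(n1 > 0 && n0 > 0, "both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified nonparametric bootstrap confidence interval
#'
#' Resamples cases and controls separately with replacement, recomputes the
#' metric per replicate, and reports the percentile 2.5/97.5 bounds.
#' Deterministic given the seed.
#'
#' @param scores Numeric scores.
#' @param labels Group labels; `case_level` marks cases.
#' @param metric Function `(scores, labels) -> number` (default
#'   [auc_mann_whitney()]).
#' @param B Number of replicates (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @param case_level Case label (default `"sptb"`).
#' @return List with `lo`, `hi`, `reps` (the replicate metrics).
#' @export
bootstrap_ci <- function(scores, labels, metric = auc_mann_whitney,
                         B = 1000, seed = 1L, conf = 0.95,
                         case_level = "sptb") {
  labels <- as.character(labels)
  case_idx <- which(labels == case_level)
  ctrl_idx <- which(labels != case_level)
  stop_if_not(length(case_idx) > 0 && length(ctrl_idx) > 0,
              "both classes must be present")
  with_seed(seed, {
    reps <- vapply(seq_len(B), function(b) {
      i <- c(sample(case_idx, length(case_idx), replace = TRUE),
             sample(ctrl_idx, length(ctrl_idx), replace = TRUE))
      metric(scores[i], labels[i])
    }, 0)
    a <- (1 - conf) / 2
    qs <- stats::quantile(reps, c(a, 1 - a), na.rm = TRUE, names = FALSE)
    list(lo = qs[1], hi = qs[2], reps = reps)
  })
}

#' Confusion-matrix metrics at a fixed classification
#'
#' Standard 2x2 definitions. Cells that are undefined (e.g. PPV when nothing
#' is predicted high) are reported as `NA` with the corresponding flag set,
#' never silently as zero.
#'
#' @param risk_class Character `"high"`/`"low"` per sample.
#' @param labels Group labels; `case_level` marks cases.
#' @param case_level Case label (default `"sptb"`).
#' @return List with `sensitivity`, `specificity`, `ppv`, `npv`, the 2x2
#'   counts, and `undefined` (names of undefined metrics).
#' @export
confusion_metrics <- function(risk_class, labels, case_level = "sptb") {
  labels <- as.character(labels)
  is_case <- labels == case_level
  stop_if_not(any(is_case) && any(!is_case), "both classes must be present")
  high <- risk_class == "high"
  tp <- sum(high & is_case); fn <- sum(!high & is_case)
  fp <- sum(high & !is_case); tn <- sum(!high & !is_case)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(sensitivity = safe_div(tp, tp + fn),
              specificity = safe_div(tn, tn + fp),
              ppv = safe_div(tp, tp + fp),
              npv = safe_div(tn, tn + fn),
              tp = tp, fn = fn, fp = fp, tn = tn)
  out$undefined <- names(which(vapply(out[1:4], is.na, TRUE)))
  out
}

#' Stratification scheme for subgroup performance
#'
#' @param kind One of `"none"`, `"ga_bins"` (< 16, 16 to 20+6/7, > 20+6/7
#'   weeks), `"trimester"` (T1 <= 13+6, T2 14 to 27+6, T3 >= 28 weeks),
#'   `"pprom"` (PPROM+ and PPROM- cases, each against all controls),
#'   `"severity"` (deliveries < 37 and < 34 weeks against all controls).
#' @param min_stratum_n Minimum total samples for a stratum to be reported
#'   (default 15).
#' @return Object of class `strat_scheme`.
#' @export
strat_scheme <- function(kind = c("none", "ga_bins", "trimester", "pprom",
                                  "severity"),
                         min_stratum_n = 15) {
  kind <- match.arg(kind)
  structure(list(kind = kind, min_stratum_n = min_stratum_n),
            class = "strat_scheme")
}

#' Assign samples to the strata of a scheme
#'
#' Returns a list of logical index vectors, one per stratum. For the
#' case-subtype schemes (`pprom`, `severity`) every stratum contains all
#' controls plus the qualifying cases.
#' @noRd
stratum_masks <- function(scheme, ga_sample_wk, group, pprom = NULL,
                          ga_delivery_wk = NULL) {
  n <- length(ga_sample_wk)
  is_ctrl <- group != "sptb"
  b1 <- 20 + 6 / 7  # "16-20 weeks" read through 20 weeks 6 days
  t1 <- 13 + 6 / 7  # trimester 1 upper bound, inclusive
  t2 <- 27 + 6 / 7
  switch(scheme$kind,
    none = list(all = rep(TRUE, n)),
    ga_bins = list(
      "ga_lt16" = ga_sample_wk < 16,
      "ga_16_20" = ga_sample_wk >= 16 & ga_sample_wk <= b1,
      "ga_gt20" = ga_sample_wk > b1),
    trimester = list(
      T1 = ga_sample_wk <= t1,
      T2 = ga_sample_wk > t1 & ga_sample_wk <= t2,
      T3 = ga_sample_wk > t2),
    pprom = list(
      pprom_pos = is_ctrl | (!is.na(pprom) & pprom == "pos"),
      pprom_neg = is_ctrl | (!is.na(pprom) & pprom == "neg")),
    severity = list(
      lt37 = rep(TRUE, n),
      lt34 = is_ctrl | ga_delivery_wk < 34))
}

#' Stratified predictor performance
#'
#' One result row per stratum of the scheme: class counts, tie-corrected
#' AUC with a stratified bootstrap CI, and confusion metrics at the
#' transferred threshold. Strata with fewer than `min_stratum_n` samples, or
#' with a class absent, are emitted with metrics suppressed and the reason
#' recorded.
#'
#' @param data Data frame with columns `score`, `group`, `ga_sample_wk`, and
#'   (as needed by the scheme) `pprom`, `ga_delivery_wk`.
#' @param scheme A [strat_scheme()].
#' @param model A [derive_youden_threshold()] threshold model.
#' @param cohort Cohort label for the output rows.
#' @param B Bootstrap replicates for the AUC CI.
#' @param seed Bootstrap seed.
#' @return Data frame of class/stratum metrics (`reason` = `""` or
#'   `"insufficient n"` / `"single class"`).
#' @export
stratified_performance <- function(data, scheme, model, cohort = "cohort",
                                   B = 1000, seed = 1L) {
  masks <- stratum_masks(scheme, data$ga_sample_wk, data$group,
                         pprom = data$pprom,
                         ga_delivery_wk = data$ga_delivery_wk)
  rows <- lapply(names(masks), function(nm) {
    idx <- masks[[nm]] & !is.na(data$score)
    d <- data[idx, , drop = FALSE]
    n_case <- sum(d$group == "sptb"); n_ctrl <- sum(d$group != "sptb")
    base <- data.frame(cohort = cohort, predictor = model$predictor,
                       stratum = nm, n_case = n_case, n_control = n_ctrl,
                       auc = NA_real_, auc_lo = NA_real_, auc_hi = NA_real_,
                       sensitivity = NA_real_, specificity = NA_real_,
                       ppv = NA_real_, npv = NA_real_,
                       threshold_source = model$derivation_cohort,
                       reason = "", stringsAsFactors = FALSE)
    if (n_case + n_ctrl < scheme$min_stratum_n) {
      base$reason <- "insufficient n"
      return(base)
    }
    if (n_case == 0 || n_ctrl == 0) {
      base$reason <- "single class"
      return(base)
    }
    base$auc <- auc_mann_whitney(d$score, d$group)
    ci <- bootstrap_ci(d$score, d$group, B = B, seed = seed)
    base$auc_lo <- ci$lo; base$auc_hi <- ci$hi
    cm <- confusion_metrics(apply_threshold(d$score, model), d$group)
    base$sensitivity <- cm$sensitivity; base$specificity <- cm$specificity
    base$ppv <- cm$ppv; base$npv <- cm$npv
    base
  })
  do.call(rbind, rows)
}

#' Prevalence-weighted bootstrap of predictive values
#'
#' Case-enriched analytic sets overstate PPV; this resamples each replicate
#' at a target population prevalence. With `N` the analytic total, each of
#' the `B` replicates draws `round(prevalence * N)` cases and the remaining
#' controls with replacement, classifies at the fixed transferred threshold,
#' and recomputes PPV/NPV. Summaries are the replicate mean and percentile
#' 95\% interval.
#'
#' @param scores Numeric scores.
#' @param labels Group labels; `case_level` marks cases.
#' @param model Threshold model (fixed; never re-derived).
#' @param prevalence Target prevalence in (0, 1) (e.g. 0.104 for the US,
#'   0.059 for Asia).
#' @param B Replicates (default 1000).
#' @param seed Integer seed.
#' @param case_level Case label (default `"sptb"`).
#' @return List with `ppv` and `npv` (each `c(mean, lo, hi)`), the replicate
#'   vectors, and `n_undefined` counts of replicates with an undefined value.
#' @export
prevalence_weighted_bootstrap <- function(scores, labels, model, prevalence,
                                          B = 1000, seed = 1L,
                                          case_level = "sptb") {
  stop_if_not(prevalence > 0 && prevalence < 1,
              "prevalence must lie in (0, 1)")
  stop_if_not(B >= 1, "B must be at least 1")
  labels <- as.character(labels)
  case_idx <- which(labels == case_level)
  ctrl_idx <- which(labels != case_level)
  stop_if_not(length(case_idx) > 0 && length(ctrl_idx) > 0,
              "both classes must be present")
  n_total <- length(scores)
  n_case_star <- round(prevalence * n_total)
  stop_if_not(n_case_star >= 1,
              "prevalence * N < 1; a larger analytic set is required")
  with_seed(seed, {
    ppv <- npv <- numeric(B)
    for (b in seq_len(B)) {
      i <- c(sample(case_idx, n_case_star, replace = TRUE),
             sample(ctrl_idx, n_total - n_case_star, replace = TRUE))
      cm <- confusion_metrics(apply_threshold(scores[i], model), labels[i],
                              case_level = case_level)
      ppv[b] <- cm$ppv; npv[b] <- cm$npv
    }
    summ <- function(x) {
      c(mean = mean(x, na.rm = TRUE),
        stats::quantile(x, c(0.025, 0.975), na.rm = TRUE, names = FALSE))
    }
    list(ppv = stats::setNames(summ(ppv), c("mean", "lo", "hi")),
         npv = stats::setNames(summ(npv), c("mean", "lo", "hi")),
         ppv_reps = ppv, npv_reps = npv,
         n_undefined = c(ppv = sum(is.na(ppv)), npv = sum(is.na(npv))))
  })
}

#' Cross-platform agreement: Pearson correlation and Bland-Altman analysis
#'
#' @param a,b Paired measurements from the two platforms (e.g. z-scored
#'   mass-spectrometry and ELISA abundances); incomplete pairs are dropped.
#' @return List with `r` (`NA` with `r_undefined = TRUE` when either vector
#'   has zero variance), `bias` (`mean(a - b)`), and `limits`
#'   (`bias +/- 1.96 sd(a - b)`).
#' @export
cross_platform_agreement <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  stop_if_not(length(a) >= 3, "at least three complete pairs required")
  undef <- stats::sd(a) == 0 || stats::sd(b) == 0
  r <- if (undef) NA_real_ else stats::cor(a, b)
  d <- a - b
  bias <- mean(d)
  loa <- bias + c(-1.96, 1.96) * stats::sd(d)
  list(r = r, r_undefined = undef, bias = bias, limits = loa,
       n = length(a))
}

#' Pooled two-sample t statistic from printed summaries
#'
#' Equal-variance two-sample t-test computed from group sizes, means and
#' SDs, as used in demographic tables; `df = n1 + n2 - 2`.
#'
#' @param n1,mean1,sd1,n2,mean2,sd2 Group summaries.
#' @return List with `statistic` (absolute t), `df`, `p`.
#' @export
pooled_t_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stop_if_not(n1 >= 2 && n2 >= 2, "each group needs n >= 2")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  tt <- (mean2 - mean1) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = abs(tt), df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Two-sided Fisher exact test for a 2x2 table (point-probability method)
#'
#' Sums hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table.
#'
#' @param tab 2x2 matrix of nonnegative integer counts with positive margins.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stop_if_not(all(dim(tab) == 2), "a 2x2 table is required")
  stop_if_not(all(tab >= 0) && all(tab == round(tab)),
              "counts must be nonnegative integers")
  stop_if_not(all(rowSums(tab) > 0) && all(colSums(tab) > 0),
              "all margins must be positive")
  m <- sum(tab[1, ])          # row-1 total
  n <- sum(tab[2, ])          # row-2 total
  k <- sum(tab[, 1])          # column-1 total
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(x, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Demographic-table statistics for a participant table
#'
#' Reproduces the test battery of cohort demographic tables: continuous
#' variables as a pooled two-sample t-test (or two-sided rank-sum when
#' requested), categorical variables as Pearson chi-square without
#' continuity correction, falling back to the two-sided Fisher exact test
#' for 2x2 tables with any expected cell below 5.
#'
#' @param participants Participant table with a `group` column.
#' @param continuous Named character vector: column -> `"t"` or `"ranksum"`.
#' @param categorical Character vector of categorical columns.
#' @param case_level Case label (default `"sptb"`).
#' @return Data frame with one row per variable: `variable`, `test`,
#'   `statistic`, `df`, `p`.
#' @export
cohort_table_stats <- function(participants,
                               continuous = c(age_yr = "t", bmi = "ranksum"),
                               categorical = "mode_delivery",
                               case_level = "sptb") {
  grp <- participants$group
  stop_if_not(any(grp == case_level) && any(grp != case_level),
              "both groups must be non-empty")
  rows <- list()
  for (v in names(continuous)) {
    x <- participants[[v]][grp != case_level]
    y <- participants[[v]][grp == case_level]
    if (continuous[[v]] == "t") {
      r <- pooled_t_from_summary(length(x), mean(x), stats::sd(x),
                                 length(y), mean(y), stats::sd(y))
      rows[[v]] <- data.frame(variable = v, test = "t",
                              statistic = r$statistic, df = r$df, p = r$p,
                              stringsAsFactors = FALSE)
    } else {
      w <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = FALSE))
      rows[[v]] <- data.frame(variable = v, test = "ranksum",
                              statistic = unname(w$statistic), df = NA_real_,
                              p = w$p.value, stringsAsFactors = FALSE)
    }
  }
  for (v in categorical) {
    tab <- table(participants[[v]], grp)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(dim(tab) == 2) && any(expected < 5)) {
      rows[[v]] <- data.frame(variable = v, test = "fisher",
                              statistic = NA_real_, df = NA_real_,
                              p = fisher_exact_2x2(tab),
                              stringsAsFactors = FALSE)
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      rows[[v]] <- data.frame(variable = v, test = "chisq",
                              statistic = unname(ct$statistic),
                              df = unname(ct$parameter), p = ct$p.value,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
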
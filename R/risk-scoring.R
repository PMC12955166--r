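#' Three-protein composite risk score
#'
#' The unweighted sum of the within-cohort z-scores of GPX3, NID1 and
#' PAPPA2. All three inputs must be present; there is no silent
#' renormalization when one is missing.
#'
#' @param z_gpx3,z_nid1,z_pappa2 Finite z-scores (vectors of equal length).
#' @return Composite score(s), strictly increasing in each argument.
#' @export
panel_score <- function(z_gpx3, z_nid1, z_pappa2) {
  for (z in list(z_gpx3, z_nid1, z_pappa2)) {
    stop_if_not(all(is.finite(z)),
                "all three analyte z-scores must be present and finite")
  }
  z_gpx3 + z_nid1 + z_pappa2
}

#' IBP4/SHBG ratio comparator score
#'
#' Log-ratio of MoM-adjusted IBP4 to SHBG: `ln(ibp4_mom / shbg_mom)`.
#' Strictly increasing in IBP4 and decreasing in SHBG; antisymmetric under
#' swapping the two inputs.
#'
#' @param ibp4_mom,shbg_mom Positive MoM-adjusted abundances.
#' @return Ratio score(s) in log units.
#' @export
ratio_score <- function(ibp4_mom, shbg_mom) {
  stop_if_not(all(ibp4_mom > 0, na.rm = TRUE) &&
                all(shbg_mom > 0, na.rm = TRUE),
              "ratio inputs must be positive (MoM scale)")
  log(ibp4_mom / shbg_mom)
}

#' Derive the Youden-optimal classification threshold
#'
#' Scans candidate cutoffs (midpoints between adjacent distinct sorted
#' scores, plus -Inf and +Inf) and picks the one maximizing the Youden index
#' `J = sensitivity + specificity - 1` under the rule "high risk iff
#' score >= cutoff". Ties in J are broken toward higher specificity, then
#' toward the lower cutoff, so derivation is deterministic.
#'
#' @param scores Numeric risk scores.
#' @param labels Character/factor per score; `case_level` marks cases.
#' @param predictor Label stored in the model (e.g. `"three_protein"`).
#' @param derivation_cohort Cohort label stored in the model.
#' @param case_level Case label (default `"sptb"`).
#' @return Object of class `threshold_model` with `cutoff`, `youden_j`,
#'   `sensitivity`, `specificity` at derivation.
#' @export
derive_youden_threshold <- function(scores, labels,
                                    predictor = "three_protein",
                                    derivation_cohort = "discovery",
                                    case_level = "sptb") {
  labels <- as.character(labels)
  is_case <- labels == case_level
  stop_if_not(any(is_case) && any(!is_case),
              "both classes must be present to derive a threshold")
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  perf <- vapply(cand, function(cut) {
    high <- scores >= cut
    se <- sum(high & is_case) / sum(is_case)
    sp <- sum(!high & !is_case) / sum(!is_case)
    c(se = se, sp = sp, j = se + sp - 1)
  }, c(se = 0, sp = 0, j = 0))
  best_j <- max(perf["j", ])
  at_best <- which(perf["j", ] == best_j)
  at_best <- at_best[perf["sp", at_best] == max(perf["sp", at_best])]
  pick <- at_best[which.min(cand[at_best])]
  structure(list(predictor = predictor, cutoff = cand[pick],
                 derivation_cohort = derivation_cohort,
                 youden_j = best_j,
                 sensitivity = perf["se", pick],
                 specificity = perf["sp", pick]),
            class = "threshold_model")
}

#' Apply a transferred threshold to new scores
#'
#' Classifies scores with the fixed rule "high iff score >= cutoff"; the
#' threshold is never re-derived on validation data.
#'
#' @param scores Numeric risk scores.
#' @param model A [derive_youden_threshold()] model.
#' @return Character vector `"high"`/`"low"`.
#' @export
apply_threshold <- function(scores, model) {
  stop_if_not(inherits(model, "threshold_model"),
              "model must be a threshold_model")
  ifelse(scores >= model$cutoff, "high", "low")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf(paste0("Threshold model '%s' (derived on %s)\n",
                     "  cutoff %.4f, J = %.3f (se %.3f, sp %.3f)\n"),
              x$predictor, x$derivation_cohort, x$cutoff, x$youden_j,
              x$sensitivity, x$specificity))
  invisible(x)
}

#' Serialize a threshold model as a small structured text record
#'
#' @param model A `threshold_model`.
#' @param path Output path (key-value text).
#' @return The path, invisibly.
#' @export
write_threshold_model <- function(model, path) {
  lines <- c(sprintf("predictor\t%s", model$predictor),
             sprintf("cutoff\t%.10g", model$cutoff),
             sprintf("derivation_cohort\t%s", model$derivation_cohort),
             sprintf("youden_j\t%.10g", model$youden_j),
             sprintf("sensitivity\t%.10g", model$sensitivity),
             sprintf("specificity\t%.10g", model$specificity))
  writeLines(lines, path)
  invisible(path)
}
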
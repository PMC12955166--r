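#' Fit a gestational-age-specific reference median curve
#'
#' Bins reference samples by completed week of gestation and takes the
#' per-week sample median. Weeks with fewer than `min_n` reference samples
#' (and empty in-range weeks) are filled by linear interpolation between the
#' neighbouring well-populated weeks; outside the populated range the curve
#' extrapolates as the nearest populated week's median. Standard
#' multiples-of-median practice uses unaffected (term) pregnancies as the
#' reference set.
#'
#' @param values Positive reference concentrations.
#' @param ga_weeks Gestational age at draw (weeks) per value.
#' @param analyte,cohort Labels carried into the curve object.
#' @param min_n Minimum per-week count for a week to anchor the curve
#'   (default 5); if no week reaches it, every populated week anchors.
#' @param week_range Evaluable week range (default `c(5, 36)`).
#' @return Object of class `ref_median_curve`.
#' @export
fit_reference_curve <- function(values, ga_weeks, analyte = "analyte",
                                cohort = "cohort", min_n = 5,
                                week_range = c(5, 36)) {
  stop_if_not(length(values) == length(ga_weeks),
              "values and ga_weeks must align")
  keep <- !is.na(values)
  values <- values[keep]
  ga_weeks <- ga_weeks[keep]
  stop_if_not(length(values) > 0, "empty reference set")
  stop_if_not(all(values > 0), "reference concentrations must be positive")
  wk <- floor(ga_weeks)
  tab <- table(wk)
  counts <- as.integer(tab)
  weeks <- as.integer(names(tab))
  anchor_weeks <- weeks[counts >= min_n]
  if (length(anchor_weeks) == 0) anchor_weeks <- weeks
  med <- vapply(anchor_weeks,
                function(w) stats::median(values[wk == w]), 0)
  structure(list(analyte = analyte, cohort = cohort,
                 week_grid = anchor_weeks, median_by_week = med,
                 week_range = week_range, min_n = min_n),
            class = "ref_median_curve")
}

#' Evaluate a reference median curve at given weeks
#'
#' @param curve A [fit_reference_curve()] object.
#' @param week Completed weeks (may be fractional; floored internally by
#'   [to_mom()], not here).
#' @return Positive median values.
#' @export
curve_value <- function(curve, week) {
  stop_if_not(inherits(curve, "ref_median_curve"),
              "curve must be a ref_median_curve")
  w <- pmin(pmax(week, curve$week_range[1]), curve$week_range[2])
  if (length(curve$week_grid) == 1) {
    return(rep(curve$median_by_week, length(w)))
  }
  stats::approx(curve$week_grid, curve$median_by_week, xout = w,
                rule = 2)$y
}

#' Multiples-of-median adjustment
#'
#' Expresses a concentration relative to the gestational-age-specific
#' reference median: `mom = value / curve(floor(ga))`.
#'
#' @param value Positive concentration(s).
#' @param ga Gestational age at draw (weeks).
#' @param curve A [fit_reference_curve()] object.
#' @return MoM value(s), dimensionless and positive.
#' @export
to_mom <- function(value, ga, curve) {
  stop_if_not(all(value > 0, na.rm = TRUE),
              "concentrations must be positive")
  value / curve_value(curve, floor(ga))
}

#' Log-transform and z-standardize MoM values within cohorts
#'
#' `z = (ln mom - cohort mean of ln mom) / cohort SD of ln mom`, with the
#' n-1 SD denominator. Standardizing within cohort harmonizes scale across
#' cohorts and measurement platforms.
#'
#' @param mom Positive MoM values.
#' @param cohort Cohort label per value.
#' @return List with `log_mom` and `z` vectors.
#' @export
log_z_standardize <- function(mom, cohort = rep("cohort", length(mom))) {
  stop_if_not(all(mom > 0, na.rm = TRUE), "MoM values must be positive")
  lm <- log(mom)
  z <- rep(NA_real_, length(lm))
  for (co in unique(cohort)) {
    idx <- cohort == co & !is.na(lm)
    stop_if_not(sum(idx) >= 2,
                "cohort '%s' needs at least two observed samples", co)
    s <- stats::sd(lm[idx])
    if (s == 0) {
      stop(sprintf("zero variance of log MoM in cohort '%s'", co),
           call. = FALSE)
    }
    z[idx] <- (lm[idx] - mean(lm[idx])) / s
  }
  list(log_mom = lm, z = z)
}

#' MoM/z normalization of a cohort's analyte measurements
#'
#' Glue over the normalization primitives: per analyte and platform, fits
#' the reference median curve on the reference samples (term-outcome samples
#' of the same cohort by default), converts every sample to MoM, and
#' z-standardizes log MoM within cohort and platform. Adds `mom_<analyte>`
#' and `z_<analyte>` columns to the sample table.
#'
#' @param samples Sample table from [generate_cohort()] (or same layout).
#' @param participants Matching participant table.
#' @param analytes Analyte columns to normalize (default the five panel and
#'   comparator proteins present).
#' @param reference `"term"` (default) or `"all"`: which samples define the
#'   median curves.
#' @param min_n Per-week anchor count passed to [fit_reference_curve()].
#' @return List with `samples` (augmented table) and `curves` (named list of
#'   fitted curves, `<platform>.<analyte>`).
#' @export
normalize_cohort <- function(samples, participants,
                             analytes = intersect(all_analytes(),
                                                  names(samples)),
                             reference = c("term", "all"), min_n = 5) {
  reference <- match.arg(reference)
  grp <- participants$group[match(samples$participant_id,
                                  participants$participant_id)]
  cohort_id <- participants$cohort[1]
  curves <- list()
  for (pf in unique(samples$platform)) {
    on_pf <- samples$platform == pf
    ref_idx <- on_pf & (if (reference == "term") grp == "term" else TRUE)
    stop_if_not(any(ref_idx), "empty reference set for platform '%s'", pf)
    for (a in analytes) {
      mom_col <- paste0("mom_", a)
      if (!mom_col %in% names(samples)) samples[[mom_col]] <- NA_real_
      if (all(is.na(samples[[a]][on_pf]))) next  # analyte not on platform
      curve <- fit_reference_curve(samples[[a]][ref_idx],
                                   samples$ga_sample_wk[ref_idx],
                                   analyte = a, cohort = cohort_id,
                                   min_n = min_n)
      curves[[paste(pf, a, sep = ".")]] <- curve
      samples[[mom_col]][on_pf] <- to_mom(samples[[a]][on_pf],
                                          samples$ga_sample_wk[on_pf], curve)
    }
  }
  for (a in analytes) {
    z_col <- paste0("z_", a)
    samples[[z_col]] <- NA_real_
    for (pf in unique(samples$platform)) {
      on_pf <- samples$platform == pf
      mom <- samples[[paste0("mom_", a)]][on_pf]
      if (all(is.na(mom))) next
      std <- log_z_standardize(mom, rep(cohort_id, sum(on_pf)))
      samples[[z_col]][on_pf] <- std$z
    }
  }
  list(samples = samples, curves = curves)
}

#' Serialize reference curves to a TSV file
#'
#' @param curves Named list of [fit_reference_curve()] objects.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_curves_tsv <- function(curves, path) {
  rows <- lapply(curves, function(cu) {
    data.frame(analyte = cu$analyte, cohort = cu$cohort,
               week = cu$week_grid, median = cu$median_by_week,
               stringsAsFactors = FALSE)
  })
  write_tsv_file(do.call(rbind, rows), path)
}
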
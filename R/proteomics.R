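#' Construct a peptide-level intensity matrix
#'
#' Raw fragment-ion peak areas for targeted proteomics, with peptides in
#' rows and samples in columns. Each peptide maps to exactly one protein.
#' Technical replicates, when present, are encoded by `replicate_of`, a
#' named vector mapping a sample column to the biological sample it
#' re-measures (replicate groups are the connected columns).
#'
#' @param intensities Numeric matrix, peptides x samples, `NA` for missing;
#'   observed cells must be nonnegative.
#' @param protein Character vector, parent protein per peptide row.
#' @param replicate_of Optional named character vector: column name ->
#'   replicate-group label.
#' @return Object of class `peptide_matrix`.
#' @export
peptide_matrix <- function(intensities, protein, replicate_of = NULL) {
  stop_if_not(is.matrix(intensities) && nrow(intensities) > 0,
              "intensities must be a non-empty matrix")
  stop_if_not(length(protein) == nrow(intensities),
              "one protein per peptide row required")
  obs <- intensities[!is.na(intensities)]
  stop_if_not(all(obs >= 0), "observed intensities must be nonnegative")
  if (is.null(rownames(intensities)))
    rownames(intensities) <- sprintf("pep%04d", seq_len(nrow(intensities)))
  structure(list(intensities = intensities,
                 protein = stats::setNames(as.character(protein),
                                           rownames(intensities)),
                 replicate_of = replicate_of,
                 normalized = FALSE),
            class = "peptide_matrix")
}

#' Peptide-level quality filtering
#'
#' Drops a peptide when its missing fraction across samples strictly exceeds
#' `max_missing_fraction`, or - when technical-replicate annotations are
#' present - when its mean coefficient of variation across replicate groups
#' is at or above `max_replicate_cv`. If every peptide of a panel protein
#' (GPX3, NID1, PAPPA2, IBP4, SHBG) is dropped, a warning is raised and the
#' loss is flagged in the report.
#'
#' @param pm A [peptide_matrix()].
#' @param max_missing_fraction Missing-fraction bound (default 0.20,
#'   exclusive: exactly 20 percent missing is retained).
#' @param max_replicate_cv Replicate CV bound (default 0.15, inclusive:
#'   CV at or above 15 percent is dropped).
#' @return List with `matrix` (filtered [peptide_matrix()]) and `report`
#'   (per-peptide data frame with the measured fractions and drop reasons).
#' @export
filter_peptides <- function(pm, max_missing_fraction = 0.20,
                            max_replicate_cv = 0.15) {
  stop_if_not(inherits(pm, "peptide_matrix"), "pm must be a peptide_matrix")
  stop_if_not(max_missing_fraction > 0 && max_missing_fraction < 1 &&
                max_replicate_cv > 0 && max_replicate_cv < 1,
              "filter fractions must lie in (0, 1)")
  x <- pm$intensities
  miss_frac <- rowMeans(is.na(x))
  rep_cv <- rep(NA_real_, nrow(x))
  if (!is.null(pm$replicate_of)) {
    groups <- split(names(pm$replicate_of), pm$replicate_of)
    groups <- groups[lengths(groups) >= 2]
    if (length(groups) > 0) {
      rep_cv <- vapply(seq_len(nrow(x)), function(i) {
        cvs <- vapply(groups, function(cols) {
          v <- x[i, cols]
          v <- v[!is.na(v)]
          if (length(v) < 2 || mean(v) == 0) return(NA_real_)
          stats::sd(v) / mean(v)
        }, 0)
        if (all(is.na(cvs))) NA_real_ else mean(cvs, na.rm = TRUE)
      }, 0)
    }
  }
  drop_missing <- miss_frac > max_missing_fraction
  drop_cv <- !is.na(rep_cv) & rep_cv >= max_replicate_cv
  dropped <- drop_missing | drop_cv
  reason <- rep("", nrow(x))
  reason[drop_missing] <- "missing_fraction"
  reason[drop_cv & !drop_missing] <- "replicate_cv"
  reason[drop_cv & drop_missing] <- "missing_fraction;replicate_cv"
  report <- data.frame(peptide_id = rownames(x),
                       protein = unname(pm$protein),
                       missing_fraction = miss_frac,
                       replicate_cv = rep_cv,
                       dropped = dropped, reason = reason,
                       row.names = NULL, stringsAsFactors = FALSE)
  lost <- setdiff(intersect(all_analytes(), pm$protein),
                  pm$protein[!dropped])
  if (length(lost) > 0) {
    warning("all peptides dropped for panel protein(s): ",
            paste(lost, collapse = ", "), call. = FALSE)
  }
  keep <- !dropped
  out <- pm
  out$intensities <- x[keep, , drop = FALSE]
  out$protein <- pm$protein[keep]
  list(matrix = out, report = report, lost_panel_proteins = lost)
}

#' Log2 transformation and global median normalization
#'
#' Log2-transforms raw peak areas and centres each sample column so its
#' median of observed log2 values is zero. Missing cells stay missing.
#' Applying the operation to an already-normalized matrix only re-centres
#' (a no-op), so the operation is idempotent.
#'
#' @param pm A [peptide_matrix()] with positive observed intensities.
#' @return The normalized [peptide_matrix()] (`normalized = TRUE`).
#' @export
normalize_peptides <- function(pm) {
  stop_if_not(inherits(pm, "peptide_matrix"), "pm must be a peptide_matrix")
  x <- pm$intensities
  if (!isTRUE(pm$normalized)) {
    bad <- which(!is.na(x) & x <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf("nonpositive intensity at peptide '%s', sample '%s'",
                   rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]),
           call. = FALSE)
    }
    x <- log2(x)
  }
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  x <- sweep(x, 2, med)
  out <- pm
  out$intensities <- x
  out$normalized <- TRUE
  out
}

#' Peptide-to-protein roll-up
#'
#' Protein abundance per sample is the mean of that protein's observed
#' peptide values; it is missing only when all peptides are missing.
#'
#' @param pm A normalized [peptide_matrix()].
#' @return Numeric matrix, proteins x samples.
#' @export
rollup_proteins <- function(pm) {
  stop_if_not(inherits(pm, "peptide_matrix"), "pm must be a peptide_matrix")
  prots <- unique(pm$protein)
  out <- t(vapply(prots, function(p) {
    sub <- pm$intensities[pm$protein == p, , drop = FALSE]
    colMeans(sub, na.rm = TRUE)
  }, numeric(ncol(pm$intensities))))
  out[is.nan(out)] <- NA_real_
  rownames(out) <- prots
  out
}

#' Z-score a protein matrix within cohorts
#'
#' @param protmat Proteins x samples matrix.
#' @param cohort Cohort label per sample column.
#' @return Matrix of the same shape with per-cohort, per-protein mean 0 and
#'   SD 1 (n-1 denominator) over observed cells.
#' @export
scale_within_cohort <- function(protmat, cohort) {
  stop_if_not(length(cohort) == ncol(protmat),
              "one cohort label per sample column required")
  out <- protmat
  for (co in unique(cohort)) {
    idx <- cohort == co
    sub <- protmat[, idx, drop = FALSE]
    m <- rowMeans(sub, na.rm = TRUE)
    s <- apply(sub, 1, stats::sd, na.rm = TRUE)
    if (any(!is.na(s) & s == 0)) {
      stop(sprintf("zero variance for protein '%s' in cohort '%s'",
                   rownames(protmat)[which(s == 0)[1]], co), call. = FALSE)
    }
    out[, idx] <- (sub - m) / s
  }
  out
}

#' Mann-Whitney p-value with the conventions used for candidate screening
#'
#' Exact enumeration when both groups have at most eight observations and no
#' ties; otherwise the tie-corrected normal approximation (no continuity
#' correction). Identical distributions with all values tied return p = 1.
#' @noRd
mw_test <- function(case, control) {
  u_all <- sum(rank(c(case, control))[seq_along(case)]) -
    length(case) * (length(case) + 1) / 2
  has_ties <- anyDuplicated(c(case, control)) > 0
  if (stats::sd(c(case, control)) == 0) return(list(u = u_all, p = 1))
  if (!has_ties && length(case) <= 8 && length(control) <= 8) {
    p <- stats::wilcox.test(case, control, exact = TRUE)$p.value
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(case, control, exact = FALSE,
                         correct = FALSE)$p.value)
    if (is.nan(p)) p <- 1
  }
  list(u = u_all, p = p)
}

#' Candidate screen: per-protein Mann-Whitney tests with FDR control
#'
#' Two-sided Mann-Whitney U-test of case versus control samples for every
#' protein, Benjamini-Hochberg adjustment across the screened proteins, and
#' a direction call from the group-median difference.
#'
#' @param protmat Proteins x samples matrix (normalized abundances).
#' @param labels Character per sample; `case_level` marks cases.
#' @param alpha_fdr FDR threshold for significance (default 0.05).
#' @param case_level Case label (default `"sptb"`).
#' @return Data frame with `protein`, `u_statistic`, `effect` (case minus
#'   control median), `direction`, `p`, `q`, `significant`.
#' @export
screen_candidates <- function(protmat, labels, alpha_fdr = 0.05,
                              case_level = "sptb") {
  labels <- as.character(labels)
  stop_if_not(length(labels) == ncol(protmat),
              "one label per sample column required")
  case <- labels == case_level
  stop_if_not(sum(case) >= 2 && sum(!case) >= 2,
              "both groups need at least two samples")
  rows <- lapply(rownames(protmat), function(p) {
    x <- protmat[p, case]; y <- protmat[p, !case]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    mw <- mw_test(x, y)
    eff <- stats::median(x) - stats::median(y)
    data.frame(protein = p, u_statistic = mw$u, effect = eff,
               direction = if (eff >= 0) "up" else "down", p = mw$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < alpha_fdr
  rownames(out) <- NULL
  out
}

#' Validation concordance of screened candidates
#'
#' A discovery hit is concordant when the validation cohort's group-median
#' difference has the same sign and an absolute magnitude of at least
#' `min_effect_fraction` of the discovery effect. Proteins absent from the
#' validation matrix are flagged non-evaluable and not concordant.
#'
#' @param screen Data frame from [screen_candidates()] (discovery cohort).
#' @param validation_mat Proteins x samples matrix for the validation cohort.
#' @param validation_labels Group labels for the validation columns.
#' @param min_effect_fraction Minimum validation/discovery effect ratio
#'   (default 0.5).
#' @param case_level Case label (default `"sptb"`).
#' @return `screen` with added `validation_effect`, `evaluable` and
#'   `concordant_in_validation` columns.
#' @export
concordance_check <- function(screen, validation_mat, validation_labels,
                              min_effect_fraction = 0.5,
                              case_level = "sptb") {
  labels <- as.character(validation_labels)
  case <- labels == case_level
  val_eff <- vapply(screen$protein, function(p) {
    if (!p %in% rownames(validation_mat)) return(NA_real_)
    x <- validation_mat[p, case]; y <- validation_mat[p, !case]
    stats::median(x, na.rm = TRUE) - stats::median(y, na.rm = TRUE)
  }, 0)
  screen$validation_effect <- val_eff
  screen$evaluable <- !is.na(val_eff)
  same_sign <- sign(val_eff) == sign(screen$effect)
  big_enough <- abs(val_eff) >= min_effect_fraction * abs(screen$effect)
  screen$concordant_in_validation <- screen$evaluable & same_sign & big_enough
  screen
}

#' Synthetic targeted-proteomics data for a cohort
#'
#' Builds a raw peptide-level peak-area matrix over a cohort's samples:
#' the three panel proteins carry a planted case shift of `planted_shift`
#' log2 units, `n_decoy_proteins` additional proteins carry no shift,
#' each protein contributes 2-3 peptides, and a small fraction of cells is
#' missing. A configurable set of samples is re-measured as technical
#' replicates with the stated analytical CV.
#'
#' @param cohort List from [generate_cohort()].
#' @param planted_shift Case shift (log2 units) on the panel proteins.
#' @param n_decoy_proteins Number of unshifted background proteins.
#' @param missing_rate Fraction of cells set missing at random.
#' @param replicate_cv Analytical CV of technical replicates.
#' @param n_replicated Number of samples re-measured as technical replicates.
#' @param seed Integer seed.
#' @return List with `pm` (a [peptide_matrix()]) and `labels` (group per
#'   sample column, replicate columns carrying their source sample's label).
#' @export
generate_peptide_data <- function(cohort, planted_shift = 1.5,
                                  n_decoy_proteins = 18, missing_rate = 0.05,
                                  replicate_cv = 0.08, n_replicated = 4,
                                  seed = 1L) {
  samples <- cohort$samples[cohort$samples$platform == "msms", ]
  participants <- cohort$participants
  grp <- participants$group[match(samples$participant_id,
                                  participants$participant_id)]
  with_seed(seed, {
    panel <- panel_analytes()
    decoys <- sprintf("DECOY%02d", seq_len(n_decoy_proteins))
    prots <- c(panel, decoys)
    pep_per <- sample(2:3, length(prots), replace = TRUE)
    protein <- rep(prots, pep_per)
    n_pep <- length(protein)
    n_s <- nrow(samples)
    base <- stats::rnorm(n_pep, mean = 20, sd = 2)  # log2 peak-area scale
    x <- matrix(stats::rnorm(n_pep * n_s, 0, 1), n_pep, n_s) + base
    for (a in panel) {
      x[protein == a, grp == "sptb"] <-
        x[protein == a, grp == "sptb"] + planted_shift
    }
    colnames(x) <- samples$sample_id
    rownames(x) <- sprintf("%s_pep%d", protein,
                           unlist(lapply(pep_per, seq_len)))
    raw <- 2^x
    raw[stats::runif(length(raw)) < missing_rate] <- NA
    replicate_of <- NULL
    labels <- stats::setNames(grp, samples$sample_id)
    if (n_replicated > 0 && n_s >= n_replicated) {
      rep_idx <- sample.int(n_s, n_replicated)
      rep_cols <- raw[, rep_idx, drop = FALSE] *
        matrix(exp(stats::rnorm(n_pep * n_replicated, 0, replicate_cv)),
               n_pep, n_replicated)
      colnames(rep_cols) <- paste0(samples$sample_id[rep_idx], "_rep")
      raw <- cbind(raw, rep_cols)
      replicate_of <- stats::setNames(
        c(samples$sample_id[rep_idx], colnames(rep_cols)),
        c(samples$sample_id[rep_idx], colnames(rep_cols)))
      replicate_of[] <- rep(samples$sample_id[rep_idx], 2)
      labels <- c(labels, stats::setNames(grp[rep_idx], colnames(rep_cols)))
    }
    list(pm = peptide_matrix(raw, protein, replicate_of = replicate_of),
         labels = labels)
  })
}
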
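#' Standardized case shift that yields a target single-marker AUC
#'
#' Under the equal-variance binormal model, a standardized mean shift
#' \eqn{\delta} between cases and controls gives AUC \eqn{\Phi(\delta/\sqrt 2)}.
#' Inverting that identity lets the cohort generator plant effect sizes that
#' hit a requested discrimination level.
#'
#' @param target_auc Target area under the ROC curve, in `[0.5, 1)`.
#' @return The standardized shift \eqn{\delta = \sqrt{2}\,\Phi^{-1}(AUC) \ge 0}.
#' @examples
#' calibrate_effect_size(0.93) # ~2.087
#' @export
calibrate_effect_size <- function(target_auc) {
  stop_if_not(length(target_auc) == 1L && is.numeric(target_auc) &&
                is.finite(target_auc),
              "target_auc must be a single finite number")
  stop_if_not(target_auc >= 0.5 && target_auc < 1,
              "target_auc must lie in [0.5, 1), got %g", target_auc)
  sqrt(2) * stats::qnorm(target_auc)
}

#' Specification of one synthetic nested case-control cohort
#'
#' Captures the design facts the generator needs: arm sizes, the gestational
#' window in which pre-outcome serum draws occur, gestational-age-at-delivery
#' distributions for term and spontaneous preterm (sPTB) arms, and the
#' fraction of sPTB deliveries preceded by preterm premature rupture of
#' membranes (PPROM).
#'
#' @param cohort_id Cohort label.
#' @param n_term,n_sptb Number of term / sPTB participants.
#' @param samples_per_participant Integer range `c(min, max)`: each
#'   participant contributes a uniform number of serial draws in this range.
#' @param ga_sampling_window Weeks `c(lo, hi)` within `[5, 36]` in which
#'   samples may be drawn (always truncated below the delivery week).
#' @param ga_delivery_term `c(mean, sd)` of a normal truncated to `[37, 42]`.
#' @param ga_delivery_sptb List with components `early = c(mean, sd)`
#'   (truncated to `[24, 34)`), `late = c(mean, sd)` (truncated to
#'   `[34, 37)`) and `weight_early` in `[0, 1]` mixing the two.
#' @param pprom_fraction Fraction of sPTB participants labelled PPROM+.
#' @param demographics List of per-arm summaries used only for the
#'   demographic-table statistics: `age = list(term = c(mean, sd), sptb = ...)`,
#'   `bmi = ...`, `cesarean = c(term = p, sptb = p)`.
#' @param seed Integer seed; mandatory so cohorts are reproducible.
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [default_cohort_specs()]
#' @export
cohort_spec <- function(cohort_id, n_term, n_sptb,
                        samples_per_participant = c(1L, 1L),
                        ga_sampling_window = c(5, 30),
                        ga_delivery_term = c(mean = 39.2, sd = 1.1),
                        ga_delivery_sptb = list(early = c(mean = 31, sd = 2.5),
                                                late = c(mean = 35.3, sd = 0.8),
                                                weight_early = 0.3),
                        pprom_fraction = 0.35,
                        demographics = default_demographics(),
                        seed = 1L) {
  stop_if_not(is_count(n_term) && is_count(n_sptb),
              "n_term and n_sptb must be nonnegative integers")
  stop_if_not(length(ga_sampling_window) == 2 &&
                ga_sampling_window[1] >= 5 && ga_sampling_window[2] <= 36 &&
                ga_sampling_window[1] < ga_sampling_window[2],
              "ga_sampling_window must be an increasing pair within [5, 36]")
  stop_if_not(length(samples_per_participant) == 2 &&
                all(samples_per_participant >= 1) &&
                samples_per_participant[1] <= samples_per_participant[2],
              "samples_per_participant must be an integer range >= 1")
  w <- ga_delivery_sptb$weight_early
  stop_if_not(is.numeric(w) && w >= 0 && w <= 1,
              "ga_delivery_sptb$weight_early must lie in [0, 1]")
  stop_if_not(pprom_fraction >= 0 && pprom_fraction <= 1,
              "pprom_fraction must lie in [0, 1]")
  stop_if_not(is_count(abs(seed)), "seed must be an integer")
  structure(list(cohort_id = as.character(cohort_id),
                 n_term = as.integer(n_term), n_sptb = as.integer(n_sptb),
                 samples_per_participant = as.integer(samples_per_participant),
                 ga_sampling_window = as.numeric(ga_sampling_window),
                 ga_delivery_term = ga_delivery_term,
                 ga_delivery_sptb = ga_delivery_sptb,
                 pprom_fraction = pprom_fraction,
                 demographics = demographics,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

default_demographics <- function() {
  list(age = list(term = c(mean = 30, sd = 4), sptb = c(mean = 31, sd = 4)),
       bmi = list(term = c(mean = 24, sd = 4), sptb = c(mean = 25, sd = 4)),
       cesarean = c(term = 0.3, sptb = 0.6))
}

#' Model of one serum analyte on the log-concentration scale
#'
#' Analyte abundance for a draw at gestational age `ga` is generated as
#' `exp(baseline_curve(ga) + delta * is_sptb + b_participant + noise)` where
#' `b_participant ~ N(0, participant_sd^2)` is shared across a participant's
#' serial draws and `noise ~ N(0, residual_sd^2)` is draw-specific. The
#' default SDs satisfy `participant_sd^2 + residual_sd^2 = 1` so `case_shift`
#' is a standardized effect.
#'
#' @param analyte One of `"GPX3"`, `"NID1"`, `"PAPPA2"`, `"IBP4"`, `"SHBG"`.
#' @param baseline_curve Function of GA (weeks) returning the median
#'   log-concentration for unaffected pregnancies.
#' @param case_shift Standardized shift added for sPTB participants.
#' @param participant_sd Between-participant SD (log scale).
#' @param residual_sd Within-participant SD (log scale), must be positive.
#' @param cohort_shift_overrides Optional named numeric vector of per-cohort
#'   case shifts, e.g. to emulate a marker whose direction is inconsistent
#'   across populations.
#' @return An object of class `analyte_model`.
#' @export
analyte_model <- function(analyte, baseline_curve, case_shift,
                          participant_sd = 0.5,
                          residual_sd = sqrt(1 - 0.5^2),
                          cohort_shift_overrides = NULL) {
  stop_if_not(is.function(baseline_curve), "baseline_curve must be a function")
  stop_if_not(residual_sd > 0, "residual_sd must be positive")
  stop_if_not(participant_sd >= 0, "participant_sd must be nonnegative")
  structure(list(analyte = as.character(analyte),
                 baseline_curve = baseline_curve,
                 case_shift = case_shift,
                 participant_sd = participant_sd,
                 residual_sd = residual_sd,
                 cohort_shift_overrides = cohort_shift_overrides),
            class = "analyte_model")
}

panel_analytes <- function() c("GPX3", "NID1", "PAPPA2")
all_analytes <- function() c("GPX3", "NID1", "PAPPA2", "IBP4", "SHBG")

#' Default analyte models calibrated to the published cohort AUCs
#'
#' The three panel markers (GPX3, NID1, PAPPA2) each carry a per-cohort shift
#' `calibrate_effect_size(panel_auc) / sqrt(3)`, so the equal-weight sum of
#' their z-scores reaches the cohort's target panel AUC under the binormal
#' model. IBP4 gets a small uniform positive shift; SHBG gets cohort-varying
#' shifts chosen so the log IBP4/SHBG ratio reaches the comparator AUCs,
#' which makes the ratio markedly weaker in the Asian cohorts.
#'
#' @param panel_auc Named per-cohort target AUC for the three-protein panel.
#' @param ratio_auc Named per-cohort target AUC for the IBP4/SHBG comparator.
#' @return Named list of [analyte_model()] objects, one per analyte.
#' @export
default_analyte_models <- function(panel_auc = c(UAB = 0.74, Stanford = 0.93,
                                                 Asia1 = 0.80, Asia2 = 0.83),
                                   ratio_auc = c(UAB = 0.68, Stanford = 0.77,
                                                 Asia1 = 0.59, Asia2 = 0.61)) {
  panel_delta <- vapply(panel_auc, calibrate_effect_size, 0) / sqrt(3)
  ibp4_delta <- 0.25
  # ratio score ~ N(delta_IBP4 - delta_SHBG, 2) => AUC = pnorm(Delta / 2)
  shbg_delta <- ibp4_delta - 2 * stats::qnorm(ratio_auc)
  curves <- list(
    GPX3   = function(ga) log(150) + 0.010 * ga,
    NID1   = function(ga) log(80) + 0.008 * ga - 1e-4 * ga^2,
    PAPPA2 = function(ga) log(5) + 0.120 * ga,
    IBP4   = function(ga) log(400) + 0.030 * ga - 5e-4 * ga^2,
    SHBG   = function(ga) log(250) + 0.050 * ga - 1e-3 * ga^2)
  models <- list(
    GPX3 = analyte_model("GPX3", curves$GPX3, case_shift = mean(panel_delta),
                         cohort_shift_overrides = panel_delta),
    NID1 = analyte_model("NID1", curves$NID1, case_shift = mean(panel_delta),
                         cohort_shift_overrides = panel_delta),
    PAPPA2 = analyte_model("PAPPA2", curves$PAPPA2,
                           case_shift = mean(panel_delta),
                           cohort_shift_overrides = panel_delta),
    IBP4 = analyte_model("IBP4", curves$IBP4, case_shift = ibp4_delta),
    SHBG = analyte_model("SHBG", curves$SHBG, case_shift = mean(shbg_delta),
                         cohort_shift_overrides = shbg_delta))
  models
}

#' Cohort specifications emulating the four study sites
#'
#' Arm sizes, sampling windows and per-participant draw counts follow the
#' published design (UAB 11 term / 14 sPTB single draws at 13-29 wk; Stanford
#' 19/31 with serial draws at 7-36 wk; Asia 1 194/114 at 5-30 wk; Asia 2
#' 50/23 single draws at 5-28 wk). Delivery-age distributions are set to match
#' the published cohort medians and interquartile ranges; demographic
#' summaries come from the published cohort tables.
#'
#' @param seed Base seed; each cohort gets `seed + offset` so cohorts are
#'   independently reproducible.
#' @return Named list of [cohort_spec()] objects.
#' @export
default_cohort_specs <- function(seed = 20260101L) {
  list(
    UAB = cohort_spec(
      "UAB", n_term = 11, n_sptb = 14,
      samples_per_participant = c(1L, 1L),
      ga_sampling_window = c(13, 29),
      ga_delivery_term = c(mean = 37.8, sd = 1.0),
      ga_delivery_sptb = list(early = c(mean = 28.5, sd = 3.0),
                              late = c(mean = 35.0, sd = 1.0),
                              weight_early = 0.8),
      pprom_fraction = 0.4,
      demographics = list(
        age = list(term = c(mean = 25.5, sd = 5.1),
                   sptb = c(mean = 26.9, sd = 4.7)),
        bmi = list(term = c(mean = 28.1, sd = 7.6),
                   sptb = c(mean = 30.2, sd = 10.1)),
        cesarean = c(term = 0.02, sptb = 0.45)),
      seed = seed + 1L),
    Stanford = cohort_spec(
      "Stanford", n_term = 19, n_sptb = 31,
      samples_per_participant = c(1L, 4L),
      ga_sampling_window = c(7, 36),
      ga_delivery_term = c(mean = 39.9, sd = 1.2),
      ga_delivery_sptb = list(early = c(mean = 32.0, sd = 1.8),
                              late = c(mean = 35.3, sd = 0.8),
                              weight_early = 0.45),
      pprom_fraction = 0.35,
      demographics = list(
        age = list(term = c(mean = 31.9, sd = 4.9),
                   sptb = c(mean = 31.7, sd = 6.5)),
        bmi = list(term = c(mean = 22.9, sd = 3.2),
                   sptb = c(mean = 28.0, sd = 5.5)),
        cesarean = c(term = 0.32, sptb = 0.65)),
      seed = seed + 2L),
    Asia1 = cohort_spec(
      "Asia1", n_term = 194, n_sptb = 114,
      samples_per_participant = c(1L, 2L),
      ga_sampling_window = c(5, 30),
      ga_delivery_term = c(mean = 39.4, sd = 0.9),
      ga_delivery_sptb = list(early = c(mean = 32.5, sd = 1.8),
                              late = c(mean = 35.2, sd = 0.8),
                              weight_early = 0.25),
      pprom_fraction = 0.35,
      demographics = list(
        age = list(term = c(mean = 30.0, sd = 3.0),
                   sptb = c(mean = 31.3, sd = 3.5)),
        bmi = list(term = c(mean = 25.6, sd = 2.8),
                   sptb = c(mean = 24.4, sd = 3.2)),
        cesarean = c(term = 0.314, sptb = 0.588)),
      seed = seed + 3L),
    Asia2 = cohort_spec(
      "Asia2", n_term = 50, n_sptb = 23,
      samples_per_participant = c(1L, 1L),
      ga_sampling_window = c(5, 28),
      ga_delivery_term = c(mean = 39.0, sd = 1.2),
      ga_delivery_sptb = list(early = c(mean = 32.0, sd = 2.0),
                              late = c(mean = 35.0, sd = 1.0),
                              weight_early = 0.4),
      pprom_fraction = 0.35,
      demographics = list(
        age = list(term = c(mean = 31.5, sd = 4.8),
                   sptb = c(mean = 32.6, sd = 3.8)),
        bmi = list(term = c(mean = 20.8, sd = 2.6),
                   sptb = c(mean = 20.3, sd = 1.9)),
        cesarean = c(term = 0.28, sptb = 0.739)),
      seed = seed + 4L)
  )
}

#' Generate one synthetic cohort
#'
#' Produces a participant table and a pre-outcome sample table with the
#' statistical structure the downstream pipeline assumes: every sample is
#' drawn strictly before delivery, sPTB deliveries fall below 37 completed
#' weeks and term deliveries at or above 37, and analyte abundances follow
#' the per-analyte models with participant-level random effects.
#'
#' @param spec A [cohort_spec()].
#' @param models Named list of [analyte_model()] objects (one per analyte,
#'   unique labels).
#' @return List with elements `participants` (columns `participant_id`,
#'   `cohort`, `group`, `pprom`, `ga_delivery_wk`, `mode_delivery`, `age_yr`,
#'   `bmi`) and `samples` (columns `sample_id`, `participant_id`,
#'   `ga_sample_wk`, `platform`, `batch`, plus one column per analyte).
#' @examples
#' spec <- default_cohort_specs()$Asia2
#' cohort <- generate_cohort(spec, default_analyte_models())
#' nrow(cohort$participants) # 73
#' @export
generate_cohort <- function(spec, models = default_analyte_models()) {
  stop_if_not(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  labels <- vapply(models, function(m) m$analyte, "")
  stop_if_not(!anyDuplicated(labels), "duplicate analyte labels in models")
  names(models) <- labels

  n <- spec$n_term + spec$n_sptb
  empty_participants <- data.frame(
    participant_id = character(), cohort = character(), group = character(),
    pprom = character(), ga_delivery_wk = numeric(),
    mode_delivery = character(), age_yr = numeric(), bmi = numeric(),
    stringsAsFactors = FALSE)
  empty_samples <- data.frame(
    sample_id = character(), participant_id = character(),
    ga_sample_wk = numeric(), platform = character(), batch = character(),
    stringsAsFactors = FALSE)
  for (a in labels) empty_samples[[a]] <- numeric()
  if (n == 0L) return(list(participants = empty_participants,
                           samples = empty_samples))

  with_seed(spec$seed, {
    group <- c(rep("term", spec$n_term), rep("sptb", spec$n_sptb))
    pid <- sprintf("%s_P%03d", spec$cohort_id, seq_len(n))

    ga_del <- numeric(n)
    if (spec$n_term > 0) {
      p <- spec$ga_delivery_term
      ga_del[group == "term"] <- rtruncnorm(spec$n_term, p[["mean"]],
                                            p[["sd"]], 37, 42)
    }
    if (spec$n_sptb > 0) {
      p <- spec$ga_delivery_sptb
      early <- stats::runif(spec$n_sptb) < p$weight_early
      g <- numeric(spec$n_sptb)
      g[early] <- rtruncnorm(sum(early), p$early[["mean"]], p$early[["sd"]],
                             24, 34 - 1e-9)
      g[!early] <- rtruncnorm(sum(!early), p$late[["mean"]], p$late[["sd"]],
                              34, 37 - 1e-9)
      ga_del[group == "sptb"] <- g
    }

    pprom <- rep("na", n)
    is_case <- group == "sptb"
    pprom[is_case] <- ifelse(stats::runif(sum(is_case)) < spec$pprom_fraction,
                             "pos", "neg")

    dem <- spec$demographics
    draw_dem <- function(par) {
      out <- numeric(n)
      for (g in c("term", "sptb")) {
        idx <- group == g
        out[idx] <- stats::rnorm(sum(idx), par[[g]][["mean"]],
                                 par[[g]][["sd"]])
      }
      round(out, 1)
    }
    age <- draw_dem(dem$age)
    bmi <- pmax(15, draw_dem(dem$bmi))
    cs_p <- dem$cesarean[group]
    mode_del <- ifelse(stats::runif(n) < cs_p, "cesarean", "vaginal")

    participants <- data.frame(
      participant_id = pid, cohort = spec$cohort_id, group = group,
      pprom = pprom, ga_delivery_wk = round(ga_del, 2),
      mode_delivery = mode_del, age_yr = age, bmi = round(bmi, 1),
      stringsAsFactors = FALSE)

    # Pre-outcome sampling: sorted uniform GAs in the window, truncated
    # strictly below delivery.
    rng <- spec$samples_per_participant
    k <- if (rng[1] == rng[2]) rep(rng[1], n) else
      sample(seq(rng[1], rng[2]), n, replace = TRUE)
    win <- spec$ga_sampling_window
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      hi <- min(win[2], participants$ga_delivery_wk[i] - 0.5)
      lo <- win[1]
      if (hi <= lo) hi <- lo + 0.1  # delivery always well beyond window start
      ga_s <- sort(round(stats::runif(k[i], lo, hi), 2))
      rows[[i]] <- data.frame(participant_id = pid[i], ga_sample_wk = ga_s,
                              stringsAsFactors = FALSE)
    }
    samples <- do.call(rbind, rows)
    samples$sample_id <- sprintf("%s_S%04d", spec$cohort_id,
                                 seq_len(nrow(samples)))
    samples$platform <- "msms"
    samples$batch <- sprintf("B%d", ((seq_len(nrow(samples)) - 1L) %/% 48L) + 1L)

    # Analyte abundances on the natural-log scale, then exponentiated.
    sptb_of_sample <- is_case[match(samples$participant_id, pid)]
    for (a in labels) {
      m <- models[[a]]
      ov <- m$cohort_shift_overrides
      delta <- if (!is.null(ov) && spec$cohort_id %in% names(ov)) {
        ov[[spec$cohort_id]]
      } else m$case_shift
      b <- stats::rnorm(n, 0, m$participant_sd)
      b_s <- b[match(samples$participant_id, pid)]
      eps <- stats::rnorm(nrow(samples), 0, m$residual_sd)
      logval <- m$baseline_curve(samples$ga_sample_wk) +
        delta * sptb_of_sample + b_s + eps
      samples[[a]] <- exp(logval)
    }
    samples <- samples[, c("sample_id", "participant_id", "ga_sample_wk",
                           "platform", "batch", labels)]
    rownames(samples) <- NULL
    list(participants = participants, samples = samples)
  })
}

#' Add paired immunoassay measurements to a sample table
#'
#' Emulates re-assaying the three panel proteins on an orthogonal ELISA
#' platform: for each mass-spectrometry sample row a paired row with
#' `platform = "elisa"` is appended whose log-abundance is the original
#' log-abundance plus independent noise sized so the log-scale Pearson
#' correlation between platforms is approximately `target_r` per analyte,
#' after an analyte-specific affine recalibration (ELISA units differ).
#'
#' @param samples Sample table from [generate_cohort()].
#' @param target_r Named correlation targets per analyte.
#' @param seed Integer seed.
#' @return Sample table with the ELISA rows appended.
#' @export
add_elisa_platform <- function(samples,
                               target_r = c(GPX3 = 0.78, NID1 = 0.65,
                                            PAPPA2 = 0.81),
                               seed = 1L) {
  stop_if_not(all(names(target_r) %in% names(samples)),
              "target_r names must be analyte columns of samples")
  with_seed(seed, {
    el <- samples
    el$platform <- "elisa"
    el$sample_id <- paste0(el$sample_id, "_E")
    for (a in names(samples)) {
      if (!a %in% c("sample_id", "participant_id", "ga_sample_wk",
                    "platform", "batch")) {
        if (a %in% names(target_r)) {
          r <- target_r[[a]]
          lg <- log(samples[[a]])
          s <- stats::sd(lg)
          noise_sd <- s * sqrt(1 / r^2 - 1)
          # arbitrary affine recalibration: ELISA reports ng/mL-like units
          el[[a]] <- exp(0.8 * (lg + stats::rnorm(nrow(el), 0, noise_sd)) - 1)
        } else {
          el[[a]] <- NA_real_
        }
      }
    }
    rbind(samples, el)
  })
}

#' Specification for a set of synthetic expression studies
#'
#' @param n_studies Number of studies (at least 2).
#' @param n_genes Number of genes per study.
#' @param n_per_group Samples per group (case/control) per study, at least 2.
#' @param de_fraction Fraction of genes carrying a planted differential
#'   effect, in (0, 1); 0 is accepted and means no planted genes.
#' @param planted_lfc Log2 fold-change magnitude of planted genes.
#' @param heterogeneity_sd Between-study SD of the planted effect.
#' @param seed Integer seed.
#' @return Object of class `meta_study_spec`.
#' @export
meta_study_spec <- function(n_studies = 6L, n_genes = 1000L,
                            n_per_group = 20L, de_fraction = 0.05,
                            planted_lfc = 1, heterogeneity_sd = 0.2,
                            seed = 1L) {
  stop_if_not(is_count(n_studies) && n_studies >= 2,
              "n_studies must be an integer >= 2")
  stop_if_not(is_count(n_per_group) && n_per_group >= 2,
              "n_per_group must be an integer >= 2")
  stop_if_not(de_fraction >= 0 && de_fraction < 1,
              "de_fraction must lie in [0, 1)")
  stop_if_not(heterogeneity_sd >= 0, "heterogeneity_sd must be >= 0")
  structure(list(n_studies = as.integer(n_studies),
                 n_genes = as.integer(n_genes),
                 n_per_group = as.integer(n_per_group),
                 de_fraction = de_fraction, planted_lfc = planted_lfc,
                 heterogeneity_sd = heterogeneity_sd,
                 seed = as.integer(seed)),
            class = "meta_study_spec")
}

#' Generate multi-study expression matrices with planted differential genes
#'
#' Each study is a `n_genes x 2*n_per_group` log2-expression matrix with
#' the first `n_per_group` columns labelled `term` and the rest `sptb`.
#' Planted genes share their direction across studies; the per-study effect
#' is drawn from `Normal(planted_lfc, heterogeneity_sd^2)` and applied with
#' the gene's shared sign. Non-planted genes have zero expected group
#' difference.
#'
#' @param spec A [meta_study_spec()].
#' @return List with `studies` (each a list of `expr` matrix and `groups`
#'   factor), `de_mask` (logical per gene) and `de_sign` (+1/-1 per gene,
#'   0 for nulls).
#' @export
generate_meta_studies <- function(spec) {
  stop_if_not(inherits(spec, "meta_study_spec"),
              "spec must be a meta_study_spec")
  with_seed(spec$seed, {
    g <- spec$n_genes
    genes <- sprintf("gene%05d", seq_len(g))
    n_de <- round(spec$de_fraction * g)
    de_mask <- c(rep(TRUE, n_de), rep(FALSE, g - n_de))
    de_mask <- de_mask[sample.int(g)]
    de_sign <- integer(g)
    de_sign[de_mask] <- sample(c(-1L, 1L), n_de, replace = TRUE)
    mu <- stats::rnorm(g, mean = 7, sd = 2)
    groups <- factor(rep(c("term", "sptb"), each = spec$n_per_group),
                     levels = c("term", "sptb"))
    studies <- lapply(seq_len(spec$n_studies), function(s) {
      eff <- numeric(g)
      eff[de_mask] <- de_sign[de_mask] *
        stats::rnorm(n_de, spec$planted_lfc, spec$heterogeneity_sd)
      expr <- matrix(stats::rnorm(g * 2 * spec$n_per_group, mean = mu, sd = 1),
                     nrow = g)
      expr[, groups == "sptb"] <- expr[, groups == "sptb"] + eff
      dimnames(expr) <- list(genes, sprintf("st%02d_s%03d", s,
                                            seq_len(2 * spec$n_per_group)))
      list(study_id = sprintf("study%02d", s), expr = expr, groups = groups)
    })
    names(de_mask) <- names(de_sign) <- genes
    list(studies = studies, de_mask = de_mask, de_sign = de_sign)
  })
}

#' Subsample a participant table to a target case fraction
#'
#' Emulates the nested case-control analytic set: all cases are kept and
#' controls are frequency-matched by sampling without replacement so the
#' realized case fraction is within one participant of the target. If the
#' source already has at least the target fraction of cases, the table is
#' returned unchanged.
#'
#' @param participants Participant table with a `group` column.
#' @param target_case_fraction Desired sPTB fraction in (0, 1).
#' @param seed Integer seed for the control draw.
#' @return Subsampled participant table.
#' @export
enrich_case_control <- function(participants, target_case_fraction, seed = 1L) {
  stop_if_not(target_case_fraction > 0 && target_case_fraction < 1,
              "target_case_fraction must lie in (0, 1)")
  is_case <- participants$group == "sptb"
  n_case <- sum(is_case)
  n_ctrl <- sum(!is_case)
  stop_if_not(n_case > 0, "no sPTB cases available to enrich")
  n_ctrl_keep <- round(n_case * (1 - target_case_fraction) /
                         target_case_fraction)
  if (n_ctrl_keep >= n_ctrl) {
    realized <- n_case / (n_case + n_ctrl)
    if (realized > target_case_fraction + 1 / nrow(participants)) {
      stop(sprintf(paste0("cannot reach case fraction %.3f: limited by the ",
                          "%d available term controls"),
                   target_case_fraction, n_ctrl), call. = FALSE)
    }
    return(participants)
  }
  with_seed(seed, {
    keep_ctrl <- sample(which(!is_case), n_ctrl_keep)
    out <- participants[sort(c(which(is_case), keep_ctrl)), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
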
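#' Default pipeline configuration
#'
#' All tunable constants of the analysis in one nested list: candidate
#' filter thresholds (fold change 1.2, meta p 0.05), peptide QC bounds
#' (missing fraction 0.20, replicate CV 0.15), screening FDR 0.05, stratum
#' minimum 15, primary-analysis sampling cutoff 24 weeks, bootstrap size
#' 1000, and population prevalence priors (US 0.104, Asia 0.059). Every
#' stochastic stage derives its seed from the single top-level seed.
#'
#' @param seed Master seed for the run.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 20260101L) {
  list(
    seed = as.integer(seed),
    stages = c("simulate", "meta", "proteomics", "normalize", "score",
               "evaluate", "survive", "report"),
    discovery_cohort = "UAB",
    elisa_cohort = "Stanford",
    meta = list(n_studies = 6L, n_genes = 1000L, n_per_group = 20L,
                de_fraction = 0.05, planted_lfc = 1.0,
                heterogeneity_sd = 0.2),
    thresholds = list(fold_change = 1.2, meta_p = 0.05, max_missing = 0.20,
                      max_replicate_cv = 0.15, fdr = 0.05,
                      min_stratum_n = 15, ga_primary_max = 24),
    bootstrap = list(B = 1000L),
    prevalence = list(us = 0.104, asia = 0.059),
    reference = list(set = "term", min_n = 5)
  )
}

config_schema <- function() {
  list(seed = NULL, stages = NULL, discovery_cohort = NULL,
       elisa_cohort = NULL,
       meta = c("n_studies", "n_genes", "n_per_group", "de_fraction",
                "planted_lfc", "heterogeneity_sd"),
       thresholds = c("fold_change", "meta_p", "max_missing",
                      "max_replicate_cv", "fdr", "min_stratum_n",
                      "ga_primary_max"),
       bootstrap = "B",
       prevalence = c("us", "asia"),
       reference = c("set", "min_n"))
}

#' Load and validate a pipeline configuration
#'
#' Reads YAML (or accepts a list), merges over [default_config()], and
#' rejects unknown keys before any stage runs.
#'
#' @param config Path to a YAML file, a configuration list, or `NULL` for
#'   the defaults.
#' @return Validated configuration list.
#' @export
load_config <- function(config = NULL) {
  if (is.null(config)) return(default_config())
  if (is.character(config)) config <- yaml::read_yaml(config)
  schema <- config_schema()
  bad <- setdiff(names(config), names(schema))
  stop_if_not(length(bad) == 0, "unknown configuration key(s): %s",
              paste(bad, collapse = ", "))
  for (sec in names(config)) {
    allowed <- schema[[sec]]
    if (!is.null(allowed) && is.list(config[[sec]])) {
      bad <- setdiff(names(config[[sec]]), allowed)
      stop_if_not(length(bad) == 0, "unknown key(s) in '%s': %s",
                  sec, paste(bad, collapse = ", "))
    }
  }
  out <- default_config()
  for (sec in names(config)) {
    if (is.list(config[[sec]]) && is.list(out[[sec]])) {
      for (k in names(config[[sec]])) out[[sec]][[k]] <- config[[sec]][[k]]
    } else {
      out[[sec]] <- config[[sec]]
    }
  }
  stop_if_not(!is.null(out$seed), "configuration must carry a seed")
  out
}

prevalence_for_cohort <- function(cohort_id, prevalence) {
  if (grepl("^Asia", cohort_id)) prevalence$asia else prevalence$us
}

#' Run the full analysis pipeline on synthetic cohorts
#'
#' Executes the stages in dependency order - simulate, meta, proteomics,
#' normalize, score, evaluate, survive, report - writing each stage's
#' tables as TSV under `out_dir` together with a JSON manifest recording
#' the configuration, seeds and per-stage row counts. Re-running with the
#' same configuration reproduces identical tables.
#'
#' @param config Configuration (path, list, or `NULL` for defaults); see
#'   [load_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("ptbrun")) {
  cfg <- load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg, stages = list())
  res <- list(config = cfg)
  th <- cfg$thresholds
  stages <- cfg$stages

  if ("simulate" %in% stages) {
    specs <- default_cohort_specs(seed = cfg$seed)
    models <- default_analyte_models()
    cohorts <- lapply(specs, generate_cohort, models = models)
    el <- cfg$elisa_cohort
    if (!is.null(el) && el %in% names(cohorts)) {
      cohorts[[el]]$samples <- add_elisa_platform(cohorts[[el]]$samples,
                                                  seed = cfg$seed + 100L)
    }
    meta_spec <- meta_study_spec(n_studies = cfg$meta$n_studies,
                                 n_genes = cfg$meta$n_genes,
                                 n_per_group = cfg$meta$n_per_group,
                                 de_fraction = cfg$meta$de_fraction,
                                 planted_lfc = cfg$meta$planted_lfc,
                                 heterogeneity_sd = cfg$meta$heterogeneity_sd,
                                 seed = cfg$seed + 200L)
    meta_data <- generate_meta_studies(meta_spec)
    res$cohorts <- cohorts
    res$meta_data <- meta_data
    all_part <- do.call(rbind, lapply(cohorts, `[[`, "participants"))
    all_samp <- do.call(rbind, lapply(cohorts, function(co) {
      s <- co$samples
      s$cohort <- co$participants$cohort[1]
      s
    }))
    rownames(all_part) <- rownames(all_samp) <- NULL
    write_tsv_file(all_part, file.path(out_dir, "participants.tsv"))
    write_tsv_file(all_samp, file.path(out_dir, "samples.tsv"))
    manifest$stages$simulate <- list(participants = nrow(all_part),
                                     samples = nrow(all_samp),
                                     meta_studies = length(meta_data$studies))
  }

  if ("meta" %in% stages) {
    stop_if_not(!is.null(res$meta_data), "stage 'meta' needs 'simulate'")
    meta_res <- meta_analyze(res$meta_data$studies)
    cand <- filter_candidates(meta_res, min_abs_fc = th$fold_change,
                              max_p = th$meta_p)
    res$meta_results <- meta_res
    res$candidates <- cand
    write_tsv_file(meta_res, file.path(out_dir, "meta_results.tsv"))
    writeLines(cand$up, file.path(out_dir, "genes_up.txt"))
    writeLines(cand$down, file.path(out_dir, "genes_down.txt"))
    manifest$stages$meta <- list(genes = nrow(meta_res),
                                 up = length(cand$up),
                                 down = length(cand$down))
  }

  if ("proteomics" %in% stages) {
    stop_if_not(!is.null(res$cohorts), "stage 'proteomics' needs 'simulate'")
    disc <- cfg$discovery_cohort
    pep_disc <- generate_peptide_data(res$cohorts[[disc]],
                                      seed = cfg$seed + 300L)
    pep_val <- generate_peptide_data(res$cohorts[[cfg$elisa_cohort]],
                                     seed = cfg$seed + 301L)
    process <- function(pep) {
      filt <- filter_peptides(pep$pm, max_missing_fraction = th$max_missing,
                              max_replicate_cv = th$max_replicate_cv)
      norm <- normalize_peptides(filt$matrix)
      prot <- rollup_proteins(norm)
      # drop technical-replicate columns before testing
      keep <- !grepl("_rep$", colnames(prot))
      list(prot = prot[, keep, drop = FALSE],
           labels = pep$labels[colnames(prot)[keep]],
           report = filt$report)
    }
    d <- process(pep_disc); v <- process(pep_val)
    screen <- screen_candidates(d$prot, d$labels, alpha_fdr = th$fdr)
    screen <- concordance_check(screen, v$prot, v$labels)
    res$screen <- screen
    res$funnel <- c(targeted = nrow(screen),
                    significant = sum(screen$significant),
                    validated = sum(screen$significant &
                                      screen$concordant_in_validation))
    write_tsv_file(screen, file.path(out_dir, "protein_screen.tsv"))
    manifest$stages$proteomics <- as.list(res$funnel)
  }

  if ("normalize" %in% stages) {
    stop_if_not(!is.null(res$cohorts), "stage 'normalize' needs 'simulate'")
    res$normalized <- lapply(res$cohorts, function(co) {
      normalize_cohort(co$samples, co$participants,
                       reference = cfg$reference$set,
                       min_n = cfg$reference$min_n)
    })
    norm_all <- do.call(rbind, lapply(names(res$normalized), function(nm) {
      s <- res$normalized[[nm]]$samples
      s$cohort <- nm
      s
    }))
    rownames(norm_all) <- NULL
    write_tsv_file(norm_all, file.path(out_dir, "samples_normalized.tsv"))
    manifest$stages$normalize <- list(samples = nrow(norm_all))
  }

  if ("score" %in% stages) {
    stop_if_not(!is.null(res$normalized), "stage 'score' needs 'normalize'")
    res$scored <- lapply(names(res$normalized), function(nm) {
      s <- res$normalized[[nm]]$samples
      part <- res$cohorts[[nm]]$participants
      idx <- match(s$participant_id, part$participant_id)
      s$cohort <- nm
      s$group <- part$group[idx]
      s$pprom <- part$pprom[idx]
      s$ga_delivery_wk <- part$ga_delivery_wk[idx]
      s$panel_score <- panel_score(s$z_GPX3, s$z_NID1, s$z_PAPPA2)
      s$ratio_score <- ratio_score(s$mom_IBP4, s$mom_SHBG)
      s
    })
    names(res$scored) <- names(res$normalized)
    disc <- res$scored[[cfg$discovery_cohort]]
    dd <- disc[disc$platform == "msms" &
                 disc$ga_sample_wk <= th$ga_primary_max, ]
    res$panel_model <- derive_youden_threshold(
      dd$panel_score, dd$group, predictor = "three_protein",
      derivation_cohort = cfg$discovery_cohort)
    res$ratio_model <- derive_youden_threshold(
      dd$ratio_score, dd$group, predictor = "ibp4_shbg",
      derivation_cohort = cfg$discovery_cohort)
    write_threshold_model(res$panel_model,
                          file.path(out_dir, "threshold_panel.txt"))
    write_threshold_model(res$ratio_model,
                          file.path(out_dir, "threshold_ratio.txt"))
    manifest$stages$score <- list(panel_cutoff = res$panel_model$cutoff,
                                  ratio_cutoff = res$ratio_model$cutoff)
  }

  if ("evaluate" %in% stages) {
    stop_if_not(!is.null(res$scored), "stage 'evaluate' needs 'score'")
    B <- cfg$bootstrap$B
    perf_rows <- list()
    prev_rows <- list()
    for (nm in names(res$scored)) {
      s <- res$scored[[nm]]
      s <- s[s$platform == "msms" & s$ga_sample_wk <= th$ga_primary_max, ]
      for (pred in c("panel", "ratio")) {
        model <- if (pred == "panel") res$panel_model else res$ratio_model
        d <- data.frame(score = if (pred == "panel") s$panel_score else
                          s$ratio_score,
                        group = s$group, ga_sample_wk = s$ga_sample_wk,
                        pprom = s$pprom, ga_delivery_wk = s$ga_delivery_wk,
                        stringsAsFactors = FALSE)
        for (kind in c("none", "ga_bins", "trimester")) {
          sch <- strat_scheme(kind, min_stratum_n = th$min_stratum_n)
          perf_rows[[paste(nm, pred, kind)]] <-
            stratified_performance(d, sch, model, cohort = nm, B = B,
                                   seed = cfg$seed + 400L)
        }
        pw <- prevalence_weighted_bootstrap(
          d$score, d$group, model,
          prevalence = prevalence_for_cohort(nm, cfg$prevalence),
          B = B, seed = cfg$seed + 500L)
        prev_rows[[paste(nm, pred)]] <- data.frame(
          cohort = nm, predictor = model$predictor,
          prevalence = prevalence_for_cohort(nm, cfg$prevalence),
          ppv_mean = pw$ppv[["mean"]], ppv_lo = pw$ppv[["lo"]],
          ppv_hi = pw$ppv[["hi"]], npv_mean = pw$npv[["mean"]],
          npv_lo = pw$npv[["lo"]], npv_hi = pw$npv[["hi"]],
          stringsAsFactors = FALSE)
      }
    }
    res$performance <- do.call(rbind, perf_rows)
    res$prevalence_ppv <- do.call(rbind, prev_rows)
    rownames(res$performance) <- rownames(res$prevalence_ppv) <- NULL
    write_tsv_file(res$performance, file.path(out_dir, "performance.tsv"))
    write_tsv_file(res$prevalence_ppv,
                   file.path(out_dir, "prevalence_ppv.tsv"))

    el <- cfg$elisa_cohort
    if (!is.null(el) && el %in% names(res$scored)) {
      s <- res$scored[[el]]
      ms <- s[s$platform == "msms", ]
      elr <- s[s$platform == "elisa", ]
      elr$base_id <- sub("_E$", "", elr$sample_id)
      idx <- match(ms$sample_id, elr$base_id)
      agree <- lapply(panel_analytes(), function(a) {
        ag <- cross_platform_agreement(ms[[paste0("z_", a)]],
                                       elr[[paste0("z_", a)]][idx])
        data.frame(analyte = a, r = ag$r, bias = ag$bias,
                   loa_lo = ag$limits[1], loa_hi = ag$limits[2], n = ag$n,
                   stringsAsFactors = FALSE)
      })
      res$cross_platform <- do.call(rbind, agree)
      write_tsv_file(res$cross_platform,
                     file.path(out_dir, "cross_platform.tsv"))
    }
    demo <- lapply(names(res$cohorts), function(nm) {
      d <- cohort_table_stats(res$cohorts[[nm]]$participants)
      d$cohort <- nm
      d
    })
    res$demographics <- do.call(rbind, demo)
    rownames(res$demographics) <- NULL
    write_tsv_file(res$demographics, file.path(out_dir, "demographics.tsv"))
    manifest$stages$evaluate <- list(performance_rows = nrow(res$performance))
  }

  if ("survive" %in% stages) {
    stop_if_not(!is.null(res$scored), "stage 'survive' needs 'score'")
    surv_rows <- list()
    km_rows <- list()
    for (nm in names(res$scored)) {
      s <- res$scored[[nm]]
      s <- s[s$platform == "msms", ]
      s$score <- s$panel_score
      rg <- survival_risk_groups(s, res$cohorts[[nm]]$participants,
                                 res$panel_model,
                                 ga_max = th$ga_primary_max)
      if (length(unique(rg$risk_group)) < 2) next
      lr <- log_rank(rg$ga_delivery_wk, rg$risk_group)
      gap <- median_delivery_gap(rg$ga_delivery_wk, rg$risk_group)
      surv_rows[[nm]] <- data.frame(cohort = nm, predictor = "three_protein",
                                    n_high = sum(rg$risk_group == "high"),
                                    n_low = sum(rg$risk_group == "low"),
                                    logrank_chisq = lr$statistic,
                                    logrank_p = lr$p,
                                    median_gap_wk = gap,
                                    stringsAsFactors = FALSE)
      for (g in c("high", "low")) {
        km <- km_estimate(rg$ga_delivery_wk[rg$risk_group == g])
        km$cohort <- nm
        km$risk_group <- g
        km_rows[[paste(nm, g)]] <- km
      }
    }
    res$survival <- do.call(rbind, surv_rows)
    res$km_curves <- do.call(rbind, km_rows)
    rownames(res$survival) <- rownames(res$km_curves) <- NULL
    write_tsv_file(res$survival, file.path(out_dir, "survival.tsv"))
    write_tsv_file(res$km_curves, file.path(out_dir, "km_curves.tsv"))
    manifest$stages$survive <- list(cohorts = nrow(res$survival))
  }

  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  manifest$config_md5 <- unname(tools::md5sum(file.path(out_dir,
                                                        "config.yaml")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  res$out_dir <- out_dir

  if ("report" %in% stages) render_report(out_dir)
  invisible(res)
}

#' Render a plain-text summary report for a pipeline run
#'
#' Mirrors the structure of the published summaries: the candidate funnel,
#' per-cohort performance (with suppressed strata labelled), prevalence-
#' adjusted predictive values, cross-platform agreement, and survival
#' separation.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return Path of the report file, invisibly.
#' @export
render_report <- function(run_dir) {
  out <- file.path(run_dir, "report.txt")
  con <- file(out, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Spontaneous preterm birth biomarker pipeline - run summary")
  w("==========================================================")
  mf <- file.path(run_dir, "manifest.json")
  if (file.exists(mf)) {
    man <- jsonlite::read_json(mf)
    w("config md5: %s", man$config_md5 %||% "NA")
  }
  sf <- file.path(run_dir, "protein_screen.tsv")
  if (file.exists(sf)) {
    sc <- read_tsv_file(sf)
    w("")
    w("Candidate funnel: %d targeted -> %d significant (FDR) -> %d validated",
      nrow(sc), sum(sc$significant),
      sum(sc$significant & sc$concordant_in_validation))
  }
  pf <- file.path(run_dir, "performance.tsv")
  if (file.exists(pf)) {
    perf <- read_tsv_file(pf)
    w("")
    w("Stratified performance (AUC [95%% CI]):")
    for (i in seq_len(nrow(perf))) {
      r <- perf[i, ]
      if (nzchar(r$reason)) {
        w("  %-9s %-13s %-9s n=%d+%d  suppressed: %s (<%s)", r$cohort,
          r$predictor, r$stratum, r$n_case, r$n_control, r$reason,
          "15" )
      } else {
        w("  %-9s %-13s %-9s n=%d+%d  AUC %.3f [%.3f, %.3f]", r$cohort,
          r$predictor, r$stratum, r$n_case, r$n_control, r$auc, r$auc_lo,
          r$auc_hi)
      }
    }
  }
  vf <- file.path(run_dir, "prevalence_ppv.tsv")
  if (file.exists(vf)) {
    pv <- read_tsv_file(vf)
    w("")
    w("Prevalence-weighted predictive values:")
    for (i in seq_len(nrow(pv))) {
      r <- pv[i, ]
      w("  %-9s %-13s pi=%.3f  PPV %.3f [%.3f, %.3f]  NPV %.3f", r$cohort,
        r$predictor, r$prevalence, r$ppv_mean, r$ppv_lo, r$ppv_hi,
        r$npv_mean)
    }
  }
  cf <- file.path(run_dir, "cross_platform.tsv")
  if (file.exists(cf)) {
    cp <- read_tsv_file(cf)
    w("")
    w("Cross-platform agreement (z-scored, MS vs ELISA):")
    for (i in seq_len(nrow(cp))) {
      r <- cp[i, ]
      w("  %-7s r = %.2f  bias %.3f  LoA [%.3f, %.3f]  n=%d", r$analyte,
        r$r, r$bias, r$loa_lo, r$loa_hi, r$n)
    }
  }
  sv <- file.path(run_dir, "survival.tsv")
  if (file.exists(sv)) {
    su <- read_tsv_file(sv)
    w("")
    w("Time to delivery (three-protein risk groups):")
    for (i in seq_len(nrow(su))) {
      r <- su[i, ]
      w("  %-9s high n=%d low n=%d  log-rank chi2 %.2f (p %.2g)  gap %.1f wk",
        r$cohort, r$n_high, r$n_low, r$logrank_chisq, r$logrank_p,
        r$median_gap_wk)
    }
  }
  invisible(out)
}
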
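# Shared fixture builders for the test suite.

tiny_cohort_spec <- function(n_term = 20, n_sptb = 20, seed = 11L, ...) {
  cohort_spec("TEST", n_term = n_term, n_sptb = n_sptb, seed = seed, ...)
}

# Single-analyte models on a flat baseline, so the planted shift is the only
# systematic signal.
flat_analyte_model <- function(delta, analyte = "GPX3",
                               participant_sd = 0) {
  analyte_model(analyte, function(ga) rep(log(100), length(ga)),
                case_shift = delta, participant_sd = participant_sd,
                residual_sd = sqrt(1 - participant_sd^2))
}

# A small cohort generated with the default models; returns both tables.
small_default_cohort <- function(seed = 7L) {
  generate_cohort(cohort_spec("Asia1", 60, 40,
                              samples_per_participant = c(1L, 2L),
                              ga_sampling_window = c(5, 30), seed = seed))
}

# Risk-group table for a self-contained cohort: normalize, score, derive a
# threshold on the same cohort, classify by earliest qualifying draw.
risk_groups_for <- function(cohort, ga_max = 24) {
  norm <- normalize_cohort(cohort$samples, cohort$participants)
  s <- norm$samples
  part <- cohort$participants
  s$group <- part$group[match(s$participant_id, part$participant_id)]
  s$score <- panel_score(s$z_GPX3, s$z_NID1, s$z_PAPPA2)
  dd <- s[s$ga_sample_wk <= ga_max, ]
  model <- derive_youden_threshold(dd$score, dd$group,
                                   derivation_cohort = "self")
  survival_risk_groups(s, part, model, ga_max = ga_max)
}
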
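---
title: "Methods: serum biomarker panel analysis for spontaneous preterm birth"
author: "ptbpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serum biomarker panel analysis for spontaneous preterm birth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptbpanel)
```

# Overview

Spontaneous preterm birth (sPTB) — spontaneous labor or membrane rupture
leading to delivery before 37 completed weeks — is a leading cause of
neonatal morbidity, and serum biomarkers measured early in pregnancy are one
of the few routes to risk stratification while preventive interventions
(progesterone, cerclage, low-dose aspirin) are still effective. `ptbpanel`
implements an end-to-end analysis for validating a three-protein serum panel
(GPX3, NID1, PAPPA2) against the established IBP4/SHBG ratio comparator:

1. multi-study placental differential-expression meta-analysis
   (`meta_analyze()`, `filter_candidates()`);
2. targeted-proteomics quality control and candidate screening
   (`filter_peptides()`, `normalize_peptides()`, `rollup_proteins()`,
   `screen_candidates()`, `concordance_check()`);
3. gestational-age normalization by multiples of the median
   (`fit_reference_curve()`, `to_mom()`, `log_z_standardize()`);
4. composite risk scoring with Youden threshold transfer
   (`panel_score()`, `ratio_score()`, `derive_youden_threshold()`,
   `apply_threshold()`);
5. performance evaluation with bootstrap confidence intervals, stratified
   analyses and prevalence-weighted predictive values
   (`auc_mann_whitney()`, `bootstrap_ci()`, `stratified_performance()`,
   `prevalence_weighted_bootstrap()`, `cross_platform_agreement()`,
   `cohort_table_stats()`);
6. time-to-delivery survival comparison of predicted risk groups
   (`km_estimate()`, `log_rank()`, `median_delivery_gap()`).

Because the original cohort data are not redistributable, the package ships
a synthetic-cohort generator (`generate_cohort()`, `generate_meta_studies()`,
`generate_peptide_data()`) that reproduces the statistical structure the
analysis assumes, so every stage is exercised end to end by `run_pipeline()`
without any download.

# The synthetic study population

The generator emulates a four-site nested case–control design: a small
discovery cohort (11 term / 14 sPTB, single draws at 13–29 weeks), a
longitudinal validation cohort (19/31, one to four draws at 7–36 weeks), a
large Asian cohort (194/114, one to two draws at 5–30 weeks) and a second
Asian cohort (50/23, single draws at 5–28 weeks) — 456 participants in
total. Within each cohort:

* **Delivery timing.** Term deliveries are truncated-normal on [37, 42]
  weeks; sPTB deliveries are a two-component mixture of an early (< 34
  weeks) and a late (34 to < 37 weeks) component. Since no parametric form
  is published for these distributions, the component means, SDs and weights
  were set once to match the published per-cohort medians and interquartile
  ranges (e.g. term median 39 and sPTB median 35 weeks in the large Asian
  cohort) and are recorded in `default_cohort_specs()`.
* **Pre-outcome sampling.** Each participant contributes a uniform number of
  draws in the cohort's range, at sorted uniform gestational ages within the
  sampling window, truncated strictly below that participant's delivery
  week. This encodes the design guarantee that every specimen precedes labor
  or membrane rupture, and the suite asserts it row by row.
* **Analyte abundances.** Log-concentration = baseline curve(GA) + case
  shift + participant effect + draw noise, exponentiated. Baseline curves
  are low-order polynomials in gestational age (PAPPA2 rising strongly, the
  others varying gently); the curves themselves are nuisance structure that
  the MoM step is designed to remove. The default between-participant SD is
  0.5 and the residual SD `sqrt(1 - 0.25)`, so case shifts are standardized
  effects; the within-person correlation of repeated draws is not published,
  and 0.5 is a free choice recorded here, not a data-derived value.
* **Effect calibration.** Under the equal-variance binormal model a
  standardized shift delta gives AUC `pnorm(delta / sqrt(2))`;
  `calibrate_effect_size()` inverts this. Each of the three panel proteins
  receives `calibrate_effect_size(panel_auc) / sqrt(3)` per cohort, so that
  the equal-weight sum of three independent z-scores reaches the cohort's
  published panel AUC (0.74 / 0.93 / 0.80 / 0.83). IBP4 carries a small
  uniform positive shift (it is only mildly elevated in sPTB), and SHBG's
  per-cohort shifts are chosen so the log IBP4/SHBG ratio reaches the
  published comparator AUCs (0.68 / 0.77 / 0.59 / 0.61) — which makes the
  ratio markedly weaker in the Asian cohorts, reproducing its inconsistent
  behaviour outside its development population.
* **Demographics** (age, BMI, delivery mode, PPROM labels) are simulated
  from the published per-cohort summary statistics solely so
  `cohort_table_stats()` has realistic input; they never enter scoring.

What the generator does *not* emulate: assay-level artefacts (batch drift,
limits of quantification, hook effects), correlated analytes beyond the
shared participant effect, gestational-age-dependent effect sizes, and
informative sampling schedules. Passing recovery tests on this synthetic
population therefore demonstrates that the analysis machinery is correct
under its own assumptions, not that the panel performs as published on real
serum.

# Meta-analysis model

Per-study gene summaries are Welch statistics on log2 expression: effect
`y = mean(case) - mean(control)`, sampling variance `v = s1^2/n1 + s2^2/n2`,
and a Welch–Satterthwaite p-value. The published integration specifies the
framework but not the per-study test; Welch moments are the conventional
choice and the summaries are swappable (`meta_analyze(summaries = ...)`).

Three complementary statistics are pooled per gene:

* **Random-effects fold change** by the DerSimonian–Laird moment estimator:
  with fixed weights `w = 1/v` and Cochran's
  `Q = sum w (y - ybar_w)^2`, the between-study variance is
  `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))` and the pooled
  effect uses weights `1/(v + tau2)`. Tests cross-check against
  `metafor::rma(method = "DL")`.
* **Robust rank aggregation.** Per-study statistics are converted to
  normalized ranks `rank/n` (average ranks for ties); up- and
  down-regulation are aggregated as two separate one-directional lists.
  For one gene with order statistics `r_(1) <= ... <= r_(k)` the score is
  `rho = min_j P(Beta(j, k-j+1) <= r_(j))`, Bonferroni-corrected over the
  gene universe (the aggregation method's default correction; the
  publication does not specify one). A gene's reported score follows the
  direction of its pooled fold change.
* **Fisher's combined probability** `-2 sum log p` against chi-square with
  `2m` degrees of freedom.

Candidate filtering retains genes present in all studies with fold change
at least 1.2 on the *fold* scale (`2^|lfc| >= 1.2`; the published "absolute
fold-change >= 1.2" does not state the scale, and the fold scale is the
common reading) and meta p below 0.05. The filter's "meta p-value" is
likewise unspecified; Fisher's combined p is used, with the corrected RRA
score kept as a parallel column.

# Proteomics processing

Peptide-level peak areas pass a missingness filter (dropped when strictly
more than 20% missing) and, when technical replicates are annotated, a
reproducibility filter that reuses the assay's analytical bound: mean
replicate CV at or above 15% drops the peptide. Mapping "poor
reproducibility" to the 15% CV bound is a design decision, since the
published criterion names no statistic. Surviving peptides are
log2-transformed and median-centred per sample (idempotent by
construction), averaged into protein values over observed peptides, and
z-scored within cohort. Remaining missing cells stay missing and are
excluded pairwise from tests; no imputation model is invented.

The candidate screen is a two-sided Mann–Whitney U-test per protein — exact
enumeration when both groups have at most eight observations and no ties,
the tie-corrected normal approximation otherwise — with Benjamini–Hochberg
adjustment across the screened set (the 21 targeted proteins, not the wider
110-candidate list; the published FDR statement names no family, so the
family is configurable). Discovery hits must then hold up in the validation
cohort: same direction and at least half the discovery effect (the 0.5
fraction is configurable). On the synthetic funnel fixture (21 quantifiable
proteins, 3 carrying planted shifts) the screen reproduces the published
terminus of 3/21 validated candidates.

# Gestational-age normalization

Serum analytes change physiologically across pregnancy, so raw abundances
are expressed as multiples of the median (MoM): each measurement is divided
by the gestational-week-specific median of a reference population. The
reference set defaults to term-outcome samples of the same cohort and
platform — standard MoM practice in prenatal screening uses unaffected
pregnancies; whether the published reference pooled cohorts is not stated,
and cohort-specific is the default here (configurable to all samples).
Weeks with at least five reference samples anchor the curve; sparser weeks
are filled by linear interpolation between anchors and the edges extrapolate
as the nearest anchor. MoM values are then log-transformed (natural log; the
base is immaterial after z-scoring) and z-standardized within cohort and
platform with the n−1 SD. The chain is invariant to rescaling an analyte's
units and preserves within-week sample ranking, both asserted in the suite.

# Risk scores and threshold transfer

The panel score is the unweighted sum `z_GPX3 + z_NID1 + z_PAPPA2`; no
weighted or model-based combination is fitted (published sensitivity
analyses found no meaningful gain from flexible classifiers). The
comparator is the log ratio of MoM-adjusted IBP4 to SHBG; the published
comparator's exact scale is not specified, and the log-MoM ratio was chosen
because it is symmetric and unbounded like the panel score.

The classification threshold maximizes the Youden index
`J = sensitivity + specificity - 1` on the discovery cohort, scanning
midpoints between adjacent distinct scores plus the two trivial rules. Ties
in `J` break toward higher specificity, then the lower cutoff, making
derivation deterministic; classification is inclusive at the boundary
(`score >= cutoff` is high risk; the publication is silent on the
boundary). The threshold is then *frozen* and applied to every validation
cohort — the suite asserts that validation classifications cannot depend on
validation labels. Because within-cohort z-scoring centres scores with the
cohort's own case mix, a transferred cutoff can sit asymmetrically in a
validation cohort whose case enrichment differs from discovery; this is an
inherent property of cohort-wise standardization and is visible in the
synthetic runs as seed-to-seed variability of transferred sensitivity.

# Performance evaluation

AUC is the tie-corrected Mann–Whitney statistic (equal, by construction, to
the trapezoidal area under the empirical ROC curve; both identities are
asserted). Confidence intervals are percentile intervals from a stratified
nonparametric bootstrap (1000 replicates by default, resampling cases and
controls separately; percentile rather than BCa, as nothing in the
published description indicates otherwise). Confusion metrics report
undefined cells (e.g. PPV with no predicted positives) as missing with a
flag, never as zero.

Stratified analyses use the published a-priori windows: gestational-age
bins `< 16`, `16 to 20+6/7` and `> 20+6/7` weeks (the "16–20 weeks" label is
read as inclusive through 20 weeks 6 days), trimesters T1 through `13+6/7`
(boundary inclusive), T2 through `27+6/7`, T3 after, plus PPROM and
severity (< 34 weeks) case subtypes against all controls. Strata below 15
samples are emitted with metrics suppressed and an explicit reason. The
primary analysis restricts to draws at or before 24 weeks (configurable),
and analyses are per sample, matching how binned discrimination is
reported; a per-participant earliest-draw mode feeds the survival stage.

Because nested case–control sets are case-enriched by design, predictive
values are re-estimated under population prevalence priors (10.4% for the
US sites, 5.9% for the Asian sites): each of 1000 replicates resamples
`round(pi * N)` cases and `N - round(pi * N)` controls with replacement at
fixed analytic total `N` (fixed-N rather than binomial case counts — the
published description does not choose, and fixed-N keeps replicate sizes
constant), reclassifies at the frozen threshold, and recomputes PPV/NPV.
The replicate mean converges to the analytic Bayes value
`se * pi / (se * pi + (1 - sp)(1 - pi))`, asserted within three bootstrap
standard errors.

Cross-platform agreement between mass-spectrometry and immunoassay
measurements uses Pearson correlation of z-scored abundances and
Bland–Altman bias with 1.96-SD limits of agreement. Demographic tables use
the pooled two-sample t (equal variance), the two-sided rank-sum test,
Pearson chi-square *without* continuity correction, and the two-sided
Fisher exact test (point-probability method) for sparse 2×2 tables — the
uncorrected chi-square and point-probability conventions are evidenced by
exact reproduction of the published table statistics (8.36, 22.08, 50, 73;
Fisher p = 0.016) from the printed counts.

# Survival analysis

Each participant is classified once, by the risk class of their earliest
qualifying draw (at or before 24 weeks); the publication does not state how
multi-draw participants were classified, and the earliest draw is the
clinically relevant choice. Ongoing-pregnancy curves are Kaplan–Meier
product-limit estimates (through the survival package; with no censoring —
every pregnancy ends in an observed delivery — the curve equals one minus
the empirical CDF, and step heights must sum to one). Group differences use
the log-rank test, cross-checked in the suite against an independently
coded per-time hypergeometric accumulation, and the headline effect size is
the difference in median gestational age at delivery between predicted
low- and high-risk groups. On synthetic cohorts this gap increases
monotonically with the planted panel effect, which is the property the
suite asserts; its realized magnitude at a fixed seed is sensitive to where
the transferred cutoff lands relative to the validation score distribution
(see the threshold-transfer note above).

# Numerical and reproducibility choices

* Every stochastic operation takes an explicit integer seed, restores the
  caller's RNG state, and reproduces byte-identical output under the same
  seed; pipeline stage seeds are fixed offsets from the single master seed.
* Problem sizes in the shipped tests and pipeline defaults are the study's
  own design sizes (456 participants, six expression studies of 40 samples,
  1000 bootstrap replicates); the planted-gene recovery checks use 500-gene
  universes, large enough for stable recall/FPR estimates at the asserted
  tolerances.
* Degenerate inputs fail loudly and early: empty reference sets, zero
  cohort variance, single-class test inputs, nonpositive intensities and
  infeasible enrichment targets all raise errors that name the offending
  unit rather than propagating NaN.
* Ties: average ranks throughout (rank lists, Mann–Whitney, AUC); Youden
  ties break toward specificity then the lower cutoff; boundary cases are
  inclusive where stated (score at the cutoff is high risk, a peptide at
  exactly 20% missingness is retained, replicate CV at exactly 15% is
  dropped).

# Known limitations

* The synthetic population is the package's own construction; agreement
  with published cohort-level numbers demonstrates calibration of the
  generator plus correctness of the machinery, not external validity.
* The meta-analysis consumes already-normalized expression matrices;
  platform-specific preprocessing and batch correction are out of scope.
* No maternal-weight or smoking corrections are applied to MoM values, and
  no covariate-adjusted (e.g. Cox) survival modelling is provided.
* The publication reports both a ten-dataset and a six-dataset meta-analysis
  population; the study count here is simply an input, and the default
  synthetic configuration uses six.
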
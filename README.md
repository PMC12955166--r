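# ptbpanel

Validation analytics for a three-protein maternal-serum biomarker panel
(GPX3, NID1, PAPPA2) that predicts spontaneous preterm birth (sPTB —
spontaneous delivery before 37 completed weeks), benchmarked against the
established IBP4/SHBG ratio predictor.

The package is written for biostatisticians and translational researchers
who need the full analysis chain behind such a panel as tested, reusable
code:

* **Placental transcriptomic meta-analysis** — per-study Welch summaries on
  log2 expression, DerSimonian–Laird random-effects pooling of fold changes
  (τ² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw))), robust rank aggregation
  (ρ = min_j P(Beta(j, k−j+1) ≤ r₍ⱼ₎) over normalized ranks), Fisher's
  combined probability (−2Σln pᵢ ~ χ²₂ₘ), and candidate filtering
  (present in all studies, fold ≥ 1.2, meta p < 0.05).
* **Targeted proteomics processing** — peptide missingness (> 20%) and
  replicate-CV (≥ 15%) filters, log2 global-median normalization,
  peptide→protein roll-up, Mann–Whitney screening with Benjamini–Hochberg
  FDR, and discovery→validation concordance checks.
* **Gestational-age normalization** — multiples of the median (MoM) against
  per-week reference medians from term pregnancies, then log and
  within-cohort z-standardization.
* **Risk scoring** — composite score z_GPX3 + z_NID1 + z_PAPPA2, the
  log IBP4/SHBG MoM-ratio comparator, Youden-index threshold
  (J = se + sp − 1) derived on the discovery cohort and transferred frozen
  to validation cohorts.
* **Performance evaluation** — tie-corrected Mann–Whitney AUC, stratified
  bootstrap confidence intervals, gestational-age/trimester/PPROM/severity
  strata with an n ≥ 15 reporting rule, prevalence-weighted bootstrap
  PPV/NPV (π = 10.4% US, 5.9% Asia), Pearson/Bland–Altman cross-platform
  agreement, and demographic-table statistics (pooled t, rank-sum,
  uncorrected χ², point-probability Fisher exact).
* **Survival analysis** — Kaplan–Meier ongoing-pregnancy curves, log-rank
  test, and the median delivery-time gap between predicted risk groups.

Since the original cohorts are not redistributable, a synthetic-data module
reproduces the four-site nested case–control structure (456 participants,
1000+ serum draws, case effects calibrated through AUC = Φ(δ/√2)) and
planted-signal expression studies, so the whole pipeline runs and is tested
end to end offline. See the methods vignette
(`vignettes/ptbpanel-methods.Rmd`) for the models, assumptions and design
decisions.

## Worked example

```r
library(ptbpanel)
res <- run_pipeline(default_config(seed = 1), out_dir = "run")

res$funnel
#>    targeted significant   validated
#>          21           3           3

subset(res$performance, stratum == "all",
       c(cohort, predictor, n_case, n_control, auc, auc_lo, auc_hi))
#>    cohort     predictor n_case n_control   auc auc_lo auc_hi
#>       UAB three_protein     12         6 0.944  0.792  1.000
#>       UAB     ibp4_shbg     12         6 0.417  0.153  0.694
#>  Stanford three_protein     48        26 0.978  0.943  0.998
#>  Stanford     ibp4_shbg     48        26 0.922  0.857  0.975
#>     Asia1 three_protein    131       216 0.783  0.733  0.832
#>     Asia1     ibp4_shbg    131       216 0.569  0.507  0.632
#>     Asia2 three_protein     19        43 0.718  0.569  0.849
#>     Asia2     ibp4_shbg     19        43 0.608  0.454  0.760

res$survival
#>    cohort     predictor n_high n_low logrank_chisq logrank_p median_gap_wk
#>       UAB three_protein     11     7         11.37  7.46e-04          8.72
#>  Stanford three_protein     22    21         38.24  6.26e-10          6.94
#>     Asia1 three_protein    142   116         10.19  1.41e-03          3.22
#>     Asia2 three_protein     30    32          4.99  2.55e-02          1.07
```

Reading the output: the proteomics screen funnels 21 targeted proteins down
to the 3 planted markers (Mann–Whitney FDR < 0.05, concordant in
validation). Per-cohort AUCs of the three-protein composite exceed the
IBP4/SHBG comparator everywhere — most clearly in the Asian cohorts, where
the generator gives SHBG an unstable effect — and samples drawn at ≤ 24
weeks classify pregnancies into risk groups whose delivery times separate
(e.g. 3.2 weeks' difference in median gestational age at delivery in the
largest cohort, log-rank χ² = 10.2). Stage outputs (participant/sample
tables, meta-analysis results, screen, performance, prevalence-weighted
PPV, KM curves, a manifest and a plain-text report) are written as TSV/JSON
under `run/`.

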
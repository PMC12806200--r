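# tmasignal

Pharmacovigilance signal detection and risk modelling for thrombotic
microangiopathy (TMA) under VEGF/VEGFR-inhibitor therapy.

TMA — microvascular thrombosis with mechanical haemolysis and platelet
consumption, usually renal — is a rare, severe complication of
anti-angiogenic cancer drugs. `tmasignal` is an R package for
pharmacovigilance and clinical-epidemiology groups who want to quantify
that risk end to end:

* **Report handling** — validated individual-case-safety-report (ICSR)
  ingestion, exact-field deduplication, drug-name normalization against a
  bundled dictionary of 6 VEGF inhibitors and 16 VEGFR inhibitors, and
  cohort selection.
* **Disproportionality analysis** — 2×2 reporting odds ratios
  `ROR = ad/(bc)` with Woolf confidence intervals
  `exp(ln ROR ± z·√(1/a+1/b+1/c+1/d))`, the Haldane–Anscombe correction
  for zero cells, and the signal rule *n ≥ 3 reports and CI lower bound
  > 1*, with optional per-cancer stratified scans.
* **Covariate models** — univariate/multivariate logistic regression
  (IRLS) of TMA occurrence on gender, age band and drug class, with Wald
  odds-ratio tables and complete-separation diagnostics.
* **Time-to-onset** — median/IQR summaries (type-7 quartiles),
  Mann–Whitney comparisons (exact for small tie-free samples), and
  cumulative-onset curves.
* **Biomarker risk** — oriented Z-scores of platelet count, creatinine,
  indirect bilirubin, RBC and MCV; a composite score
  `Σ sign(z)·log2(1+|z|)`; quartile risk tiers; the French-criteria TTP
  rule (platelet < 30 ×10⁹/L and creatinine < 199 µmol/L); G-tests and
  Fisher tests on pre→post shifts.
* **Pathway enrichment** — ssGSEA per-sample scores (rank-weighted ECDF
  difference), two-group GSEA with a seeded gene-label permutation null
  and BH adjustment, and Spearman correlation of per-cancer pathway
  activity against per-cancer RORs.
* **Synthetic data** — seeded generators for every input (report
  universes with planted drug–event ratios, paired biochemistry panels,
  two-group expression experiments, pathway/ROR datasets) that record
  their planted ground truth for recovery testing.

## Worked example

```r
library(tmasignal)

out <- run_signal_scan(list(seed = 1, icsr = list(n_reports = 50000)))
out$signals[out$signals$exposure %in% c("All", "VEGFi", "VEGFRi"),
            c("exposure", "a", "ror", "ci_low", "ci_high", "is_signal")]
#>  exposure  a  ror ci_low ci_high is_signal
#>     VEGFi 19 4.95  3.023    8.09      TRUE
#>       All 29 2.87  1.886    4.36      TRUE
#>    VEGFRi 10 1.34  0.703    2.57     FALSE

out$tto_summary
#>   group median    q1    q3  n
#>   other   75.0  43.5 150.0 91
#>   VEGFi  225.0 137.0 589.0 19
#>  VEGFRi   38.5  20.0  70.8 10

out$tto_mann_whitney$p
#> [1] 0.000376
```

Reading this: in a 50,000-report synthetic oncology cohort (whose
generator plants a class-level reporting ratio of 5 for VEGF inhibitors
and 1.2 for VEGFR inhibitors against a 0.2% background TMA rate), the
scan recovers a VEGFi signal — 19 exposed TMA reports, ROR 4.95 with a
95% CI excluding 1 — while VEGFRi stays below the signal rule. Onset of
TMA is much later under VEGFi (median 225 days) than VEGFRi (median 38.5
days); the Mann–Whitney test calls that difference at p ≈ 4e-4.

The same orchestration exists for the biomarker stage
(`run_biomarker_assessment()`: composite scores, risk tiers, TTP flags,
pre→post tests) and the pathway stage (`run_pathway_correlation()`), all
driven by one config list or YAML file with explicit seeds. A thin CLI
wrapper is installed at `inst/scripts/tmasignal.R`.

See the methods vignette (`vignettes/tma-pharmacovigilance.Rmd`) for the
statistical conventions (quartile type, zero-cell correction, permutation
scheme, score transform) and the generator design.

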
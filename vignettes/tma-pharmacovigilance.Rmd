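---
title: "Methods: TMA signal detection and risk modelling for VEGF/VEGFR inhibitors"
author: "tmasignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TMA signal detection and risk modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Thrombotic microangiopathy (TMA) — microvascular thrombosis with mechanical
haemolysis and platelet consumption, typically renal — is a rare but severe
complication of anti-angiogenic cancer therapy. Two drug families are
implicated: VEGF inhibitors ("VEGFi": bevacizumab, aflibercept, and other
ligand-binding agents) and VEGFR inhibitors ("VEGFRi": sunitinib, sorafenib
and other receptor-targeting kinase inhibitors). `tmasignal` implements the
complete computational chain a pharmacovigilance group would run to
characterize this risk:

1. **Signal detection** on spontaneous-report databases: reporting odds
   ratios (ROR) for drug or drug-class exposure against a TMA-spectrum
   event set, with a count-gated signal rule.
2. **Covariate modelling**: univariate (ULR) and multivariate (MLR)
   logistic regression of TMA occurrence on gender, age band and drug
   class.
3. **Time-to-onset (TTO)**: median/IQR summaries, Mann-Whitney comparison
   between classes, cumulative-onset curves.
4. **Biochemical risk scoring** on paired pre/post patient panels:
   oriented Z-scores, a composite score, quartile risk tiers, and a TTP
   rule, with G-tests and Fisher tests on the pre-to-post shifts.
5. **Pathway enrichment**: ssGSEA per-sample scores, two-group permutation
   GSEA, and Spearman correlation of per-cancer pathway activity against
   per-cancer RORs.

Because real report universes (FAERS, Vigibase), hospital biochemistry and
pan-cancer expression archives are not redistributable, the package ships a
first-class synthetic-data module that generates each input with *known
planted structure*, so every stage can be validated by recovery tests.

# Disproportionality analysis

For a 2×2 table with cells $a$ (exposed, event), $b$ (exposed, no event),
$c$ (event, not exposed), $d$ (neither), the reporting odds ratio is

$$\mathrm{ROR} = \frac{a/b}{c/d} = \frac{ad}{bc},$$

with the Woolf (log-normal) interval
$\exp\!\left(\ln \mathrm{ROR} \pm z_{1-\alpha/2}\sqrt{1/a+1/b+1/c+1/d}\right)$.

Numerical choices:

* **Zero cells**: the Haldane–Anscombe correction adds 0.5 to all four
  cells, only when a zero occurs; `correction_applied` records it.
  Uncorrected counts are used otherwise, and `n_reports` is always the
  uncorrected $a$.
* **Signal rule**: a pair is a signal iff $a \ge 3$ *and* the 95% CI lower
  bound strictly exceeds 1. Both boundaries are strict and tested on a
  boundary grid.
* **Comparator**: the background is the full supplied (oncology) cohort,
  not an external universe — scans are run after restricting to the cohort
  of interest. The comparator therefore includes the other study class;
  this composition is a documented choice (the alternative, class-exclusive
  comparators, can be obtained by filtering with `select_cohort()` first).
* **Stratified scans** (e.g. per cancer type) still emit strata with
  $a < 3$, flagged `excluded`, mirroring the practice of dropping strata
  with fewer than three cases.
* No multiplicity adjustment is applied by default (raw RORs are the
  standard report); Benjamini–Hochberg flagging is available via
  `adjust = TRUE`.

A caution that the validation quantifies: for drugs whose *expected*
exposed-event count is near the gate (about 2–3 reports), conditioning on
$a \ge 3$ selects upward-fluctuating counts, so the false-positive rate
*among gate-passing drugs* exceeds the nominal one-sided level even under
the null. The unconditional fraction of null drugs flagged stays at or
below the nominal level; this distinction is inherent to count-gated
disproportionality rules.

# Report handling

* **Deduplication** keys on seven fields — gender, age, region, event
  date, the adverse-event term set, the medication set (suspect plus
  concomitant, order-insensitive), and indication — and deliberately *not*
  on the report id. Missing values participate as a distinct sentinel, so
  two reports both missing age can match. Event sets are compared by
  set-equality (an open choice; any-shared-term matching would merge more
  aggressively and is not implemented). The first record by input order
  survives; the operation is idempotent.
* **Drug normalization** maps brand names/synonyms to generic names via a
  bundled editable dictionary (6 VEGFi, 16 VEGFRi, common brands);
  matching is case- and whitespace-insensitive; unknown names survive
  verbatim tagged `unclassified`. Exposure uses suspect-role drugs only by
  default (standard ICSR practice; configurable).
* **Ages** are binned into half-open bands [0, 45), [45, 65), [65, 75),
  [75, ∞); only the outer bands are anchored by convention, the middle
  cuts are a documented choice.

# Covariate models

`fit_logistic()` fits maximum-likelihood logistic regression by IRLS
(`stats::glm`, convergence tolerance $10^{-12}$, ≤ 100 iterations), with
reference levels male / age 0–44 / VEGFRi by default. Wald intervals
($e^{\hat\beta \pm z\,\mathrm{SE}}$) match standard pharmacovigilance
reporting; profile-likelihood intervals are intentionally not used.
Complete separation is detected (boundary fits, runaway coefficients or
standard errors) and reported as a non-converged fit with a diagnostic —
`odds_ratio_table()` refuses non-converged fits rather than printing
garbage. Missing covariates are handled by complete-case analysis. The
multivariate model uses gender + age band + drug class only; region and
outcome are deliberately excluded from the default covariate set.

On any 2×2-reducible design the fitted odds ratio equals the contingency
cross-product ratio to at least 10 significant digits (verified in tests).

# Time to onset

TTO is whole days from therapy start to event onset; missing or
non-positive intervals are excluded with counts logged (same-day onsets are
treated as non-analyzable). Quartiles use the linear-interpolation
convention (`quantile` type 7) — IQRs depend on this convention, which is
why it is pinned. The Mann–Whitney test uses the exact null distribution
when $n_x + n_y \le 20$ with no ties and the tie/continuity-corrected
normal approximation otherwise; at the boundary the two agree within 0.01.
Reported central values are medians: onset-time distributions are strongly
right-skewed, so medians are the meaningful anchor even where summary
tables label central values loosely.

# Biomarker risk score

Five markers enter the score: platelet count (×10⁹/L), creatinine
(µmol/L), indirect bilirubin (µmol/L), RBC count (×10¹²/L), MCV (fL). Each
is standardized against the *pre-treatment* cohort baseline and multiplied
by a risk orientation (−1 for platelet and RBC, which fall in TMA; +1 for
the rest), so larger oriented Z always means higher risk. Orientation is a
package decision: scoring directionality has to be fixed somewhere, and
these are the clinically expected directions.

A log2-compressed sum defines the composite score. A plain
$\log_2$ of a Z-score is undefined at or below zero, so the package uses
the signed transform

$$\mathrm{score} = \sum_i \operatorname{sign}(z_i)\,\log_2(1 + |z_i|),$$

which is defined everywhere, odd, strictly monotone in each marker, and
behaves like $\log_2 |z_i|$ for large $|z_i|$. A raw (untransformed) sum
is available by `method = "raw"`. Risk tiers are quartiles of the
*baseline* score distribution (the tiers are not numerically defined
anywhere authoritative, so baseline quartiles are the package's
definition); intervals are half-open with ties going to the upper tier.

The TTP rule follows the French-score logic: platelet **< 30 ×10⁹/L and**
creatinine **< 199 µmol/L**, both strict — severe thrombocytopenia with
relatively preserved renal function favours TTP over HUS. Missing either
marker yields an undetermined (`NA`) flag, never `FALSE`. Note the
conjunction is implemented exactly as stated even though in the original
French score the creatinine criterion is *supporting* evidence rather than
a hard conjunct.

Pre/post comparisons use the unpaired two-sided Mann–Whitney test per
marker, matching the named test of standard reports despite the paired
design; a paired Wilcoxon signed-rank option exists. Tier shifts are
tested with a G-test ($G = 2\sum O \ln(O/E)$, no Williams correction) on
the **marginal** 2×k timepoint-by-tier table; the full 4×4 transition
matrix is also returned, since it is ambiguous which of the two a given
report intends. TTP-flag shifts use Fisher's exact test on the marginal
2×2.

# Enrichment scoring

**ssGSEA.** Per sample, genes are ranked by expression (average ranks for
ties) and traversed from highest to lowest; the score is the summed
difference between the weighted in-set ECDF (weights ∝ rank^α, α = 0.25 by
default) and the unweighted out-of-set ECDF. Scores are rank-based, hence
invariant under any strictly monotone per-sample transform. With
`normalize = TRUE` (default) the score matrix is divided by its overall
range, making scores comparable across samples. Sets are restricted to
genes present in the matrix; sets with fewer than two present genes are
skipped with a warning.

**Two-group GSEA.** Genes are ranked by the signal-to-noise ratio with an
SD floor of $0.2\,|\mathrm{mean}| + 0.2$ to avoid division blow-ups in
low-variance genes. The enrichment score is the maximum deviation of the
weighted Kolmogorov–Smirnov running sum (hit weights $|s|^p$, $p = 1$);
it always lies in [−1, 1]. The implementation evaluates the running-sum
extrema from hit positions only (between hits the sum changes linearly),
which tests verify against a full brute-force traversal. The null
distribution permutes **gene labels** — `n_perm` random same-size sets
drawn from the ranked list, shared across sets of equal size — because a
6-vs-6 design admits at most 924 distinct phenotype permutations, too few
for stable tail estimates. The permutation p-value uses the plus-one
estimator $(1 + \#\{|ES_0| \ge |ES|\})/(n_{\mathrm{perm}} + 1)$ (so it can
never be 0); NES divides ES by the mean magnitude of same-sign null
scores; BH adjustment runs across sets. A positive ES means enrichment in
`positive_class` (default: the last group label, i.e. `treated` for the
bundled generator).

**Pathway–ROR correlation.** Per-cancer pathway activity (mean ssGSEA
score across a cancer's samples; the mean rather than the median is the
default summary) is correlated with per-cancer RORs by Spearman's rank
correlation with average ranks and the two-sided t approximation; cancers
lacking an ROR (excluded strata) drop pairwise, with at least four pairs
required.

# The synthetic-data module

The generators define the study conditions; they are part of the tested
surface, not fixtures.

**Report cohorts** (`icsr_sim_config()`): 200,000 reports by default, one
suspect drug per report drawn from a catalog of the 22 study drugs plus
ten cytotoxic "other" drugs weighted so study drugs are ~10% of reports
(the order of magnitude of real oncology report universes). A drug with
planted relative reporting ratio $r$ produces a TMA-spectrum event with
probability $r \times$ `background_event_rate` (default 0.002, matching
the ~0.2% TMA incidence reported among users of these drugs); a
configuration whose capped probability would exceed 1 is rejected before
sampling. Default planted ratios are 5 for the VEGFi class and 1.2 for
VEGFRi, echoing the relative class signals in the large databases.
Onset times are log-normal per class — medians 201 d (VEGFi), 35 d
(VEGFRi), 60 d (other); log-SDs 1.3 / 0.9 / 1.0, chosen so that the
implied IQR ratios match the published IQR spans — and dates are emitted as
ISO-8601 with therapy start, onset, and a small reporting delay. A
configured fraction of records (default 2%) are exact copies of earlier
records across all seven deduplication key fields under fresh report ids;
the injected ids are recorded in the ground-truth sidecar. The generator
does not attempt to model reporting dynamics (stimulated reporting, the
Weber effect) or real co-medication structure (the co-medication rate is
zero by default).

**Biochemistry panels** (`biochem_sim_config()`): 1698 patients by
default, each marker bivariate normal across timepoints (correlation 0.6)
on the natural scale, truncated at a small positive physiologic floor.
Default means are the published cohort means (platelet 233.4 → 171.1,
creatinine 76.4 → 76.7, indirect bilirubin 6.9 → 7.9, RBC 3.9 → 3.8, MCV
90.19 → 91.3); dispersions are typical clinical SDs (75/70, 25, 4/4.5,
0.5, 5 in marker units). The TTP-region fractions (defaults 1.18% pre,
3.77% post) are *total* expected fractions: naturally-flagged panels in
excess of the target are displaced just above the platelet threshold and
shortfalls are planted into the region, so `ttp_fraction = 0` really
yields zero flags. Planting slightly perturbs the post-treatment platelet
tail; the mean-recovery contract is exact when the fractions are zero.
A deliberate limitation: markers are normal, so the generator reproduces
mean shifts but not shape-only changes. The real creatinine change is of
that kind (mean up 0.3 µmol/L while the median falls) — a rank test on
the synthetic cohort will *not* call creatinine significant, and the
validation suite only requires detection for the four markers with
substantive mean shifts.

**Expression experiments** (`expression_sim_config()`): 1000 genes, 6 vs
6 samples, log-normal expression with per-gene base levels, 20 gene sets
of 50 genes; planted sets get a mean log-scale shift in the treated group
(default: one `VEGF_SIGNALING` set shifted −1.5, emulating suppressed
VEGF signalling under a ligand-binding inhibitor). Gene-set membership is
drawn under the same seed, so the whole design is reproducible.

**Pathway/ROR datasets** (`generate_pathway_ror_dataset()`): 13 cancers;
the designated pathway couples to log-ROR through a Gaussian copula with
Pearson parameter $2\sin(\pi\rho_S/6)$, which yields population Spearman
correlation $\rho_S$; at $|\rho_S| = 1$ the coupling is exactly monotone
so the sample coefficient is exactly ±1. Other pathways are independent
noise.

All generators are byte-reproducible given seed + configuration and
record their planted truth in a sidecar (`ground_truth()`).

# What the validation does and does not show

The test suite validates the *statistics* against independent oracles
(closed forms, exhaustive enumeration, brute-force double loops,
`fgsea::calcGseaStat` as an external ES cross-check) and the *pipeline*
against planted truth: signal recovery at ratio 5 over 100 seeds with the
null-drug flag rate at or below the nominal level, Woolf CI coverage
within [93%, 97%] at true ROR 1/2/5, Wald CI coverage at true OR 4.5,
GSEA top-|NES| recovery of a +1.5-shifted 50-gene set in ≥90% of seeds
with BH control under the global null, marker-shift detection at the
published cohort means, and Spearman recovery of a planted 0.8 at n = 13
within 0.1 over 500 seeds. Problem sizes (200k reports × 100 seeds, 1698
patients × 100 seeds, 1000 permutations × 50 seeds, 500 correlation
seeds) were chosen to make these Monte-Carlo checks stable at the stated
bounds.

Passing on synthetic data shows the chain is *correct*, not that real
databases would give the same numbers: the generators deliberately omit
reporting biases, duplicate near-matches (only exact copies are
injected), real covariance between markers, and real expression
correlation structure. Conclusions about actual drugs still require the
real data sources.

# Worked example

```{r, eval = FALSE}
library(tmasignal)

# 1. simulate a report universe and scan it
cohort <- generate_icsr_cohort(icsr_sim_config(n_reports = 50000, seed = 1))
cohort <- normalize_drugs(deduplicate(ingest_reports(cohort)))
scan_signals(cohort, list(VEGFi = list(class = "VEGFi"),
                          VEGFRi = list(class = "VEGFRi")))

# 2. the full orchestrated analyses
out <- run_signal_scan(list(seed = 1, icsr = list(n_reports = 50000)))
bio <- run_biomarker_assessment(list(seed = 1))
pw  <- run_pathway_correlation(list(seed = 1))
```
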
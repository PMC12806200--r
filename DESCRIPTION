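Package: tmasignal
Title: Pharmacovigilance Signal Detection and Risk Modelling for
    VEGF/VEGFR-Inhibitor-Associated Thrombotic Microangiopathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mining spontaneous adverse-event reports for
    thrombotic microangiopathy (TMA) signals associated with VEGF and
    VEGFR inhibitors, and for the downstream analyses that put such
    signals in context.  Provides validated individual-case-safety-report
    (ICSR) handling (deduplication, drug-name normalization, cohort
    selection), reporting-odds-ratio disproportionality analysis with
    Woolf confidence intervals and the three-report signal rule,
    univariate and multivariate logistic covariate models, time-to-onset
    summaries with Mann-Whitney comparisons and cumulative-onset curves,
    a composite biochemical TMA/TTP risk score for paired patient panels,
    single-sample and two-group gene-set enrichment scoring, and Spearman
    correlation of per-cancer pathway activity against per-cancer
    reporting odds ratios.  A seeded synthetic-data module generates
    report cohorts, biochemistry panels, expression experiments and
    pathway/ROR datasets with known planted structure so every stage can
    be exercised and validated without access to proprietary
    pharmacovigilance or hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    fgsea,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
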
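#' Read a pipeline run configuration
#'
#' A single YAML (or R list) configuration drives the three end-to-end
#' analyses.  Recognized top-level keys: `seed`, `out_dir`, `alpha`, and
#' per-stage blocks `icsr`, `biochem`, `pathway` whose entries override the
#' corresponding simulator-config defaults (or give an `input_csv` path to
#' analyse an existing file instead of simulating).
#'
#' @param config path to a YAML file, or a list.
#' @return normalized config list.
#' @export
read_run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config$seed <- as.integer(config$seed %||% 1L)
  config$alpha <- config$alpha %||% 0.05
  config$out_dir <- config$out_dir %||% tempfile("tmasignal-run-")
  config
}

write_manifest <- function(out_dir, stage, manifest) {
  path <- file.path(out_dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Run the spontaneous-report signal-scan analysis end to end
#'
#' Fixed stage order: ingest -> deduplicate -> normalize -> cohort ->
#' disproportionality scan (overall classes and drugs, plus a per-cancer
#' scan) -> time-to-onset summaries, Mann-Whitney class comparison and
#' cumulative curves -> univariate and multivariate logistic covariate
#' models.  Every stage's report count is recorded in a JSON manifest so a
#' rerun with the same seed reproduces every artifact.
#'
#' @param config see [read_run_config()]; `config$icsr` parameterizes the
#'   report simulator, or supplies `input_csv`.
#' @return (invisibly) list with the signal table, TTO summaries, odds
#'   ratio table, curves, manifest and output paths.
#' @export
run_signal_scan <- function(config = list()) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  icsr_cfg <- cfg$icsr %||% list()
  if (!is.null(icsr_cfg$input_csv)) {
    raw <- read_icsr_csv(icsr_cfg$input_csv)
    truth <- NULL
  } else {
    sim_args <- icsr_cfg[intersect(names(icsr_cfg),
                                   names(formals(icsr_sim_config)))]
    sim_args$seed <- sim_args$seed %||% cfg$seed
    sim <- do.call(icsr_sim_config, sim_args)
    raw <- generate_icsr_cohort(sim)
    truth <- ground_truth(raw)
  }
  counts$raw <- nrow(raw)

  reports <- ingest_reports(raw)
  counts$ingested <- nrow(reports)
  counts$quarantined <- nrow(quarantine_log(reports))
  reports <- deduplicate(reports)
  counts$deduplicated <- nrow(reports)
  reports <- normalize_drugs(reports)
  counts$cohort <- nrow(reports)

  study_drugs <- unique(default_drug_dictionary()$generic)
  exposures <- c(
    list(All = list(class = c("VEGFi", "VEGFRi"), label = "All"),
         VEGFi = list(class = "VEGFi"), VEGFRi = list(class = "VEGFRi")),
    stats::setNames(lapply(study_drugs, function(d) list(drugs = d)),
                    study_drugs))
  signals <- scan_signals(reports, exposures, alpha = cfg$alpha)
  by_cancer <- scan_signals(reports,
                            list(All = list(class = c("VEGFi", "VEGFRi"),
                                            label = "All")),
                            stratify_by = "cancer_type", alpha = cfg$alpha)

  tma_reports <- reports[event_flags(reports, tma_event_set()), , drop = FALSE]
  tto <- extract_tto(tma_reports, group_by = "drug_class")
  tto_groups <- split(tto$days, tto$group)
  tto_tab <- do.call(rbind, lapply(names(tto_groups), function(g) {
    s <- tto_summary(tto_groups[[g]])
    data.frame(group = g, median = s$median, q1 = s$q1, q3 = s$q3,
               n = s$n, stringsAsFactors = FALSE)
  }))
  mw <- if (all(c("VEGFi", "VEGFRi") %in% names(tto_groups)))
    mann_whitney(tto_groups$VEGFi, tto_groups$VEGFRi) else NULL
  curves <- do.call(rbind, lapply(names(tto_groups), function(g)
    cbind(group = g, cumulative_curve(tto_groups[[g]]))))

  model_df <- reports[reports$suspect_classes %in% c("VEGFi", "VEGFRi"), ]
  model_df$drug_class <- model_df$suspect_classes
  outcome <- event_flags(model_df, tma_event_set())
  covs <- c("gender", "age_band", "drug_class")
  ulr <- fit_logistic(model_df, outcome, covs, "univariate")
  mlr <- fit_logistic(model_df, outcome, covs, "multivariate")
  # sparse outcomes can defeat individual fits; report what converged and
  # record the rest in the manifest rather than aborting the run
  skipped <- c(names(ulr)[!vapply(ulr, function(f) isTRUE(f$converged),
                                  logical(1))],
               if (!isTRUE(mlr$converged)) "MLR")
  or_parts <- list()
  ulr_ok <- ulr[vapply(ulr, function(f) isTRUE(f$converged), logical(1))]
  if (length(ulr_ok) > 0)
    or_parts$ulr <- odds_ratio_table(ulr_ok, cfg$alpha)
  if (isTRUE(mlr$converged))
    or_parts$mlr <- odds_ratio_table(mlr, cfg$alpha)
  or_tab <- do.call(rbind, or_parts) %||%
    data.frame(factor = character(), level = character(),
               model = character(), or = numeric(), ci_low = numeric(),
               ci_high = numeric(), p = numeric())
  rownames(or_tab) <- NULL

  utils::write.csv(signals, file.path(cfg$out_dir, "signals.csv"),
                   row.names = FALSE)
  utils::write.csv(by_cancer, file.path(cfg$out_dir, "signals_by_cancer.csv"),
                   row.names = FALSE)
  utils::write.csv(tto_tab, file.path(cfg$out_dir, "tto_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(curves, file.path(cfg$out_dir, "tto_curves.csv"),
                   row.names = FALSE)
  utils::write.csv(or_tab, file.path(cfg$out_dir, "odds_ratios.csv"),
                   row.names = FALSE)
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(cfg$out_dir, "icsr_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  manifest <- list(stage = "signal_scan", seed = cfg$seed, counts = counts,
                   alpha = cfg$alpha,
                   models_not_converged = skipped,
                   tto_mann_whitney_p = mw$p %||% NA)
  write_manifest(cfg$out_dir, "signal_scan", manifest)

  invisible(list(signals = signals, by_cancer = by_cancer,
                 tto_summary = tto_tab, tto_mann_whitney = mw,
                 curves = curves, odds_ratios = or_tab,
                 manifest = manifest, out_dir = cfg$out_dir))
}

#' Run the biomarker risk-assessment analysis end to end
#'
#' Generates (or reads) paired pre/post biochemistry panels, standardizes
#' them against the pre-treatment baseline, computes composite risk scores,
#' quartile-based risk tiers and TTP flags, and tests the pre -> post
#' changes: per-marker Mann-Whitney tests, a G-test on the marginal tier
#' distribution, and Fisher's exact test on the TTP flag margins.
#'
#' @param config see [read_run_config()]; `config$biochem` parameterizes
#'   the panel simulator, or supplies `input_csv`.
#' @return (invisibly) list with per-patient assessments, marker tests,
#'   tier and TTP shift analyses, manifest and paths.
#' @export
run_biomarker_assessment <- function(config = list()) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  bio_cfg <- cfg$biochem %||% list()
  if (!is.null(bio_cfg$input_csv)) {
    panels <- utils::read.csv(bio_cfg$input_csv, stringsAsFactors = FALSE)
  } else {
    sim_args <- bio_cfg[intersect(names(bio_cfg),
                                  names(formals(biochem_sim_config)))]
    sim_args$seed <- sim_args$seed %||% cfg$seed
    panels <- generate_biochem_cohort(do.call(biochem_sim_config, sim_args))
  }
  pre <- panels[panels$timepoint == "pre", , drop = FALSE]
  post <- panels[panels$timepoint == "post", , drop = FALSE]
  post <- post[match(pre$patient_id, post$patient_id), , drop = FALSE]
  if (anyNA(post$patient_id)) stopf("unmatched patient ids across timepoints")

  base <- baseline_stats(pre)
  z_pre <- zscore_panel(pre, base)
  z_post <- zscore_panel(post, base)
  score_pre <- composite_score(z_pre)
  score_post <- composite_score(z_post)
  cuts <- tier_cutpoints(score_pre)
  tier_pre <- assign_tier(score_pre, cuts)
  tier_post <- assign_tier(score_post, cuts)
  ttp_pre <- ttp_rule(pre$platelet, pre$creatinine)
  ttp_post <- ttp_rule(post$platelet, post$creatinine)

  marker_tests <- paired_marker_tests(pre, post)
  tier_shift <- tier_shift_analysis(tier_pre, tier_post)
  ttp_shift <- ttp_shift_analysis(ttp_pre, ttp_post)

  assessments <- data.frame(
    patient_id = pre$patient_id,
    score_pre = score_pre, score_post = score_post,
    tier_pre = as.character(tier_pre), tier_post = as.character(tier_post),
    ttp_pre = ttp_pre, ttp_post = ttp_post,
    stringsAsFactors = FALSE)
  utils::write.csv(assessments, file.path(cfg$out_dir, "assessments.csv"),
                   row.names = FALSE)
  utils::write.csv(marker_tests, file.path(cfg$out_dir, "marker_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(tier_shift$transition),
                   file.path(cfg$out_dir, "tier_transition.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(ttp_shift$transition),
                   file.path(cfg$out_dir, "ttp_transition.csv"),
                   row.names = FALSE)
  manifest <- list(stage = "biomarker_assessment", seed = cfg$seed,
                   counts = list(patients = nrow(pre)),
                   tier_cutpoints = cuts,
                   tier_g_test_p = tier_shift$test$p,
                   ttp_fisher_p = ttp_shift$test$p,
                   ttp_pct_pre = 100 * mean(ttp_pre, na.rm = TRUE),
                   ttp_pct_post = 100 * mean(ttp_post, na.rm = TRUE))
  write_manifest(cfg$out_dir, "biomarker", manifest)

  invisible(list(assessments = assessments, marker_tests = marker_tests,
                 tier_shift = tier_shift, ttp_shift = ttp_shift,
                 cutpoints = cuts, manifest = manifest,
                 out_dir = cfg$out_dir))
}

#' Run the pathway/ROR correlation analysis end to end
#'
#' Generates (or reads) a per-cancer pathway-score table and per-cancer
#' ROR vector and computes the per-pathway Spearman correlations.
#'
#' @param config see [read_run_config()]; `config$pathway` parameterizes
#'   [generate_pathway_ror_dataset()], or supplies `scores_csv`/`ror_csv`.
#' @return (invisibly) list with the score matrix, ROR vector, correlation
#'   table, manifest and paths.
#' @export
run_pathway_correlation <- function(config = list()) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  pw_cfg <- cfg$pathway %||% list()
  if (!is.null(pw_cfg$scores_csv)) {
    scores <- as.matrix(utils::read.csv(pw_cfg$scores_csv, row.names = 1,
                                        check.names = FALSE))
    ror_df <- utils::read.csv(pw_cfg$ror_csv, stringsAsFactors = FALSE)
    ror <- stats::setNames(ror_df$ror, ror_df$cancer)
    truth <- NULL
  } else {
    sim_args <- pw_cfg[intersect(names(pw_cfg),
                                 names(formals(generate_pathway_ror_dataset)))]
    sim_args$seed <- sim_args$seed %||% cfg$seed
    ds <- do.call(generate_pathway_ror_dataset, sim_args)
    scores <- ds$scores; ror <- ds$ror; truth <- ds$truth
  }
  rho_tab <- correlate_ror_pathways(scores, ror)

  utils::write.csv(data.frame(pathway = rownames(scores), scores,
                              check.names = FALSE),
                   file.path(cfg$out_dir, "pathway_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(cancer = names(ror), ror = unname(ror)),
                   file.path(cfg$out_dir, "ror_by_cancer.csv"),
                   row.names = FALSE)
  utils::write.csv(rho_tab, file.path(cfg$out_dir, "pathway_correlations.csv"),
                   row.names = FALSE)
  manifest <- list(stage = "pathway_correlation", seed = cfg$seed,
                   counts = list(cancers = ncol(scores),
                                 pathways = nrow(scores)))
  if (!is.null(truth)) manifest$truth <- truth
  write_manifest(cfg$out_dir, "pathway", manifest)

  invisible(list(scores = scores, ror = ror, correlations = rho_tab,
                 manifest = manifest, out_dir = cfg$out_dir))
}
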
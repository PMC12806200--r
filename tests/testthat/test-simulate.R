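test_that("generators are byte-identical under the same seed and config", {
  cfg <- icsr_sim_config(n_reports = 3000, seed = 77)
  expect_identical(generate_icsr_cohort(cfg), generate_icsr_cohort(cfg))
  bcfg <- biochem_sim_config(n_patients = 300, seed = 77)
  expect_identical(generate_biochem_cohort(bcfg),
                   generate_biochem_cohort(bcfg))
  ecfg <- expression_sim_config(n_genes = 200, n_samples_per_group = 3,
                                n_sets = 4, set_size = 20, seed = 77)
  expect_identical(generate_expression_experiment(ecfg),
                   generate_expression_experiment(ecfg))
  expect_identical(generate_pathway_ror_dataset(seed = 77),
                   generate_pathway_ror_dataset(seed = 77))
})

test_that("invalid simulator configurations are rejected before sampling", {
  expect_error(icsr_sim_config(background_event_rate = 0.5,
                               planted_associations = c(bevacizumab = 3)),
               "exceeds 1")
  expect_error(icsr_sim_config(duplicate_fraction = 1), "duplicate_fraction")
  expect_error(icsr_sim_config(planted_associations = c(notadrug = 2)),
               "not in catalog")
  expect_error(biochem_sim_config(pre_sds = c(platelet = -1, creatinine = 25,
                                              indirect_bilirubin = 4,
                                              rbc = 0.5, mcv = 5)),
               "positive")
  expect_error(expression_sim_config(gene_sets = list(A = character(0))),
               "non-empty")
  expect_error(expression_sim_config(
    gene_sets = list(A = "g0001"), planted_sets = c(B = 1)), "not in")
  expect_error(generate_pathway_ror_dataset(n_cancers = 3), ">= 4")
  expect_error(generate_pathway_ror_dataset(planted_rho = 1.5), "rho")
})

test_that("injected duplicates are recorded and removed by deduplication", {
  cfg <- icsr_sim_config(n_reports = 1000, duplicate_fraction = 0.1,
                         seed = 19)
  cohort <- generate_icsr_cohort(cfg)
  truth <- ground_truth(cohort)
  expect_equal(nrow(cohort), 1000)
  expect_equal(truth$n_duplicates, 100)
  dd <- deduplicate(cohort)
  expect_equal(attr(dd, "n_removed"), 100)
})

test_that("null associations yield mean ROR near 1 across seeds", {
  rors <- vapply(1:40, function(s) {
    cfg <- icsr_sim_config(
      n_reports = 20000, duplicate_fraction = 0,
      background_event_rate = 0.01,
      planted_associations = setNames(
        rep(1, nrow(default_drug_catalog())),
        default_drug_catalog()$drug),
      seed = 1000 + s)
    cohort <- normalize_drugs(generate_icsr_cohort(cfg))
    compute_ror(build_contingency(cohort, list(class = "VEGFi")))$ror
  }, numeric(1))
  expect_lt(abs(mean(rors) - 1), 0.1)
})

test_that("event probabilities equal planted ratio times background", {
  cfg <- icsr_sim_config(n_reports = 50000, duplicate_fraction = 0,
                         background_event_rate = 0.01,
                         planted_associations = c(bevacizumab = 5),
                         seed = 3)
  cohort <- generate_icsr_cohort(cfg)
  truth <- ground_truth(cohort)
  expect_equal(unname(truth$event_prob[["bevacizumab"]]), 0.05)
  bev <- cohort[cohort$suspect_drugs == "bevacizumab", ]
  tma_frac <- mean(grepl("thrombotic|haemolytic|microangiopath", bev$events))
  expect_equal(tma_frac, 0.05, tolerance = 0.35)  # binomial noise at ~2k
})

test_that("biochem marker means and pre/post correlation match the config", {
  cfg <- biochem_sim_config(n_patients = 1698, ttp_fraction_pre = 0,
                            ttp_fraction_post = 0, seed = 101)
  panels <- generate_biochem_cohort(cfg)
  pre <- panels[panels$timepoint == "pre", ]
  post <- panels[panels$timepoint == "post", ]
  for (k in marker_names()) {
    se_pre <- cfg$pre_sds[[k]] / sqrt(cfg$n_patients)
    expect_lt(abs(mean(pre[[k]]) - cfg$pre_means[[k]]), 3 * se_pre)
    # displaced TTP-region panels perturb the post platelet tail slightly
    se_post <- cfg$post_sds[[k]] / sqrt(cfg$n_patients)
    expect_lt(abs(mean(post[[k]]) - cfg$post_means[[k]]),
              3 * se_post + 0.01 * cfg$post_means[[k]])
    expect_gt(cor(pre[[k]], post[[k]]), 0.45)
    expect_lt(cor(pre[[k]], post[[k]]), 0.75)
  }
  expect_true(all(panels[, marker_names()] > 0))
})

test_that("ttp_fraction 0 flags nothing; configured fractions are recovered", {
  p0 <- generate_biochem_cohort(biochem_sim_config(
    n_patients = 2000, ttp_fraction_pre = 0, ttp_fraction_post = 0,
    seed = 7))
  expect_equal(sum(ttp_rule(p0$platelet, p0$creatinine)), 0)
  fr <- vapply(1:25, function(s) {
    p <- generate_biochem_cohort(biochem_sim_config(seed = s))
    post <- p[p$timepoint == "post", ]
    mean(ttp_rule(post$platelet, post$creatinine))
  }, numeric(1))
  expect_equal(mean(fr), 0.0377, tolerance = 0.1)
})

test_that("expression planting shifts exactly the member genes", {
  cfg <- expression_sim_config(n_genes = 400, n_samples_per_group = 5,
                               planted_sets = c(VEGF_SIGNALING = 1),
                               n_sets = 5, set_size = 50, dispersion = 0.5,
                               seed = 15)
  ex <- generate_expression_experiment(cfg)
  expect_true(all(ex$expr >= 0))
  truth <- ground_truth(ex$expr)
  planted_genes <- cfg$gene_sets$VEGF_SIGNALING
  lfc <- log(rowMeans(ex$expr[, ex$groups == "treated"]) /
               rowMeans(ex$expr[, ex$groups == "control"]))
  expect_gt(mean(lfc[planted_genes]), 0.6)
  expect_lt(abs(mean(lfc[setdiff(rownames(ex$expr), planted_genes)])), 0.15)
})

test_that("a negatively planted set yields a negative enrichment score", {
  cfg <- expression_sim_config(n_genes = 300, n_samples_per_group = 4,
                               planted_sets = c(VEGF_SIGNALING = -2),
                               n_sets = 4, set_size = 30, seed = 33)
  ex <- generate_expression_experiment(cfg)
  res <- gsea_two_group(ex$expr, ex$groups, ex$gene_sets, n_perm = 100,
                        seed = 2)
  expect_lt(res$es[res$set == "VEGF_SIGNALING"], 0)
})

test_that("a perfectly monotone copula gives sample Spearman exactly 1", {
  ds <- generate_pathway_ror_dataset(n_cancers = 13, planted_rho = 1,
                                     seed = 9)
  expect_equal(oracle_spearman(ds$scores[1, ], ds$ror), 1)
  ds_neg <- generate_pathway_ror_dataset(n_cancers = 13, planted_rho = -1,
                                         seed = 9)
  expect_equal(oracle_spearman(ds_neg$scores[1, ], ds_neg$ror), -1)
})

test_that("a null planted rho averages near zero across seeds", {
  rhos <- vapply(1:200, function(s) {
    ds <- generate_pathway_ror_dataset(n_cancers = 13, planted_rho = 0,
                                       seed = s)
    oracle_spearman(ds$scores[1, ], ds$ror)
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.05)
})
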
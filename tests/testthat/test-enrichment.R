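test_that("ssGSEA matches hand enumeration on the 5-gene example", {
  expr <- matrix(c(50, 40, 30, 20, 10), ncol = 1,
                 dimnames = list(paste0("g", 1:5), "s1"))
  sets <- list(top = c("g1", "g2"))
  # with {g1, g2}: positions 1,2 -> p_in = .5,1,1,1,1; p_out = 0,0,1/3,2/3,1
  s <- ssgsea_scores(expr, sets, alpha = 0, normalize = FALSE)
  expect_equal(unname(s[1, 1]), (0.5 - 0) + (1 - 0) + (1 - 1 / 3) +
                 (1 - 2 / 3) + 0)
  expect_equal(unname(s[1, 1]),
               oracle_ssgsea_sample(expr[, 1], rownames(expr),
                                    sets$top, alpha = 0))
  # top-gene-only running difference: 1 + 0.75 + 0.5 + 0.25 + 0 = 2.5
  expect_equal(oracle_ssgsea_sample(expr[, 1], rownames(expr), "g1", 0), 2.5)
})

test_that("ssGSEA equals the brute-force double loop on random matrices", {
  set.seed(17)
  for (i in 1:20) {
    expr <- matrix(rexp(40), nrow = 10, ncol = 4,
                   dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
    set <- sample(rownames(expr), sample(2:5, 1))
    s <- ssgsea_scores(expr, list(S = set), alpha = 0.25, normalize = FALSE)
    for (j in 1:4) {
      expect_equal(unname(s[1, j]),
                   oracle_ssgsea_sample(expr[, j], rownames(expr), set, 0.25),
                   tolerance = 1e-12)
    }
  }
})

test_that("ssGSEA is rank-based: invariant under monotone transforms", {
  set.seed(23)
  expr <- matrix(rexp(60) + 0.1, nrow = 15, ncol = 4,
                 dimnames = list(paste0("g", 1:15), paste0("s", 1:4)))
  sets <- list(A = sample(rownames(expr), 5), B = sample(rownames(expr), 4))
  s1 <- ssgsea_scores(expr, sets, normalize = FALSE)
  s2 <- ssgsea_scores(expr^3, sets, normalize = FALSE)
  s3 <- ssgsea_scores(log1p(expr) * 7, sets, normalize = FALSE)
  expect_equal(s1, s2, tolerance = 1e-12)
  expect_equal(s1, s3, tolerance = 1e-12)
})

test_that("ssGSEA score negates when the ranking is reversed (alpha = 0)", {
  expr <- matrix(c(5, 4, 3, 2, 1), ncol = 1,
                 dimnames = list(paste0("g", 1:5), "s"))
  rev_expr <- matrix(c(1, 2, 3, 4, 5), ncol = 1,
                     dimnames = list(paste0("g", 1:5), "s"))
  sets <- list(S = c("g1", "g2"))
  a <- ssgsea_scores(expr, sets, alpha = 0, normalize = FALSE)
  b <- ssgsea_scores(rev_expr, sets, alpha = 0, normalize = FALSE)
  expect_equal(unname(a[1, 1]), -unname(b[1, 1]), tolerance = 1e-12)
})

test_that("undersized sets are skipped with a warning", {
  expr <- matrix(rexp(20), 5, 4, dimnames = list(paste0("g", 1:5), NULL))
  expect_warning(s <- ssgsea_scores(expr, list(ok = c("g1", "g2"),
                                               tiny = "g3")), "skipping")
  expect_equal(rownames(s), "ok")
})

test_that("the fast KS enrichment score equals brute force and fgsea", {
  set.seed(29)
  for (i in 1:25) {
    n <- 200
    stat <- sort(rnorm(n), decreasing = TRUE)
    hits <- sort(sample(n, sample(3:30, 1)))
    fast <- tmasignal:::gsea_es(abs(stat), hits)
    expect_equal(fast, oracle_gsea_es(stat, hits), tolerance = 1e-12)
    ref <- fgsea::calcGseaStat(stat, selectedStats = hits, gseaParam = 1)
    expect_equal(fast, ref, tolerance = 1e-10)
  }
})

test_that("GSEA recovers a planted set with the right sign and is reproducible", {
  cfg <- expression_sim_config(n_genes = 600, n_samples_per_group = 6,
                               planted_sets = c(VEGF_SIGNALING = -1.5),
                               n_sets = 10, set_size = 40, seed = 41)
  ex <- generate_expression_experiment(cfg)
  res <- gsea_two_group(ex$expr, ex$groups, ex$gene_sets, n_perm = 500,
                        seed = 99)
  res2 <- gsea_two_group(ex$expr, ex$groups, ex$gene_sets, n_perm = 500,
                         seed = 99)
  expect_identical(res, res2)                     # seeded: bit-reproducible
  top <- res[which.max(abs(res$nes)), ]
  expect_equal(top$set, "VEGF_SIGNALING")
  expect_lt(top$es, 0)                            # down-shifted in treated
  expect_true(all(abs(res$es) <= 1))
  expect_true(all(res$p_adj >= res$p_perm))
  expect_true(all(res$p_perm >= 1 / 501))
})

test_that("the permutation p-value has the plus-one floor", {
  cfg <- expression_sim_config(n_genes = 300, n_samples_per_group = 3,
                               planted_sets = c(BIG = 3),
                               n_sets = 3, set_size = 30, seed = 53)
  ex <- generate_expression_experiment(cfg)
  res <- gsea_two_group(ex$expr, ex$groups, ex$gene_sets, n_perm = 99,
                        seed = 1)
  expect_equal(min(res$p_perm), 1 / 100)
})

test_that("BH adjustment is monotone in p and bounded by 1", {
  cfg <- expression_sim_config(n_genes = 400, n_samples_per_group = 4,
                               planted_sets = c(VEGF_SIGNALING = 0),
                               n_sets = 12, set_size = 25, seed = 61)
  ex <- generate_expression_experiment(cfg)
  res <- gsea_two_group(ex$expr, ex$groups, ex$gene_sets, n_perm = 200,
                        seed = 2)
  o <- order(res$p_perm)
  expect_true(!is.unsorted(res$p_adj[o]))
  expect_true(all(res$p_adj <= 1))
  expect_equal(res$p_adj, p.adjust(res$p_perm, "BH"))
})

test_that("Spearman correlation matches the rank formula", {
  scores <- matrix(c(1, 2, 3, 4, 5,
                     3, 1, 2, 5, 4), 2, 5, byrow = TRUE,
                   dimnames = list(c("mono", "perm"),
                                   paste0("C", 1:5)))
  ror <- setNames(c(10, 20, 30, 40, 50), paste0("C", 1:5))
  out <- correlate_ror_pathways(scores, ror)
  expect_equal(out$rho[out$pathway == "mono"], 1)
  expect_equal(out$rho[out$pathway == "perm"],
               oracle_spearman(c(3, 1, 2, 5, 4), c(10, 20, 30, 40, 50)))
  # the classic 3-point example: rho = 1 - 6*6/(3*8) = -0.5 (needs n >= 4
  # in the pipeline entry point, so check the formula via the oracle)
  expect_equal(oracle_spearman(c(1, 2, 3), c(3, 1, 2)), -0.5)
  expect_error(correlate_ror_pathways(scores[, 1:3], ror[1:3]), "4")
})

test_that("excluded cancers are dropped pairwise", {
  set.seed(5)
  scores <- matrix(rnorm(10), 2, 5,
                   dimnames = list(c("p1", "p2"), paste0("C", 1:5)))
  ror <- setNames(c(1, 2, NA, 3, 4), paste0("C", 1:5))
  out <- correlate_ror_pathways(scores, ror)
  expect_equal(unique(out$n), 4)
})

test_that("GMT round-trips through read and write", {
  sets <- list(SET_A = c("g1", "g2", "g3"), SET_B = c("g9", "g2"))
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back, sets)
})
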
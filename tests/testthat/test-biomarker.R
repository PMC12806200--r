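make_panels <- function(n = 400, seed = 2, shift = FALSE) {
  cfg <- if (shift) biochem_sim_config(n_patients = n, seed = seed)
         else biochem_sim_config(
           n_patients = n,
           post_means = c(platelet = 233.4, creatinine = 76.4,
                          indirect_bilirubin = 6.9, rbc = 3.9, mcv = 90.19),
           post_sds = c(platelet = 75, creatinine = 25,
                        indirect_bilirubin = 4, rbc = 0.5, mcv = 5),
           ttp_fraction_pre = 0, ttp_fraction_post = 0, seed = seed)
  generate_biochem_cohort(cfg)
}

test_that("Z-scores are zero at baseline mean and risk-oriented", {
  base <- data.frame(marker = marker_names(),
                     mean = c(200, 80, 7, 4, 90), sd = c(50, 20, 3, 0.5, 5))
  at_mean <- data.frame(platelet = 200, creatinine = 80,
                        indirect_bilirubin = 7, rbc = 4, mcv = 90)
  expect_equal(unname(zscore_panel(at_mean, base)[1, ]), rep(0, 5))
  low_plt <- at_mean; low_plt$platelet <- 150   # one SD below the mean
  expect_equal(unname(zscore_panel(low_plt, base)[1, "platelet"]), +1)
  high_mcv <- at_mean; high_mcv$mcv <- 95
  expect_equal(unname(zscore_panel(high_mcv, base)[1, "mcv"]), +1)
  base$sd[1] <- 0
  expect_error(zscore_panel(at_mean, base), "positive")
})

test_that("pre-timepoint Z-scores standardize to mean 0, SD 1", {
  panels <- make_panels(n = 1500)
  pre <- panels[panels$timepoint == "pre", ]
  z <- zscore_panel(pre, baseline_stats(pre))
  expect_equal(unname(colMeans(z)), rep(0, 5), tolerance = 1e-10)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 5), tolerance = 1e-10)
})

test_that("composite score is the signed-log2 sum with strict monotonicity", {
  z0 <- matrix(0, 1, 5, dimnames = list(NULL, marker_names()))
  expect_equal(composite_score(z0), 0)
  z1 <- z0; z1[1, 1] <- 1
  expect_equal(composite_score(z1), 1)   # log2(1 + 1)
  set.seed(9)
  for (i in 1:25) {
    z <- matrix(rnorm(5), 1, 5, dimnames = list(NULL, marker_names()))
    j <- sample(5, 1)
    z_up <- z; z_up[1, j] <- z_up[1, j] + runif(1, 0.01, 2)
    expect_gt(composite_score(z_up), composite_score(z))
  }
  z_na <- z0; z_na[1, 2] <- NA
  expect_error(composite_score(z_na), "missing")
  expect_equal(composite_score(z_na, na_action = "omit"), 0)
})

test_that("composite score depends only on Z-scores, not marker units", {
  panels <- make_panels(n = 300)
  pre <- panels[panels$timepoint == "pre", ]
  base <- baseline_stats(pre)
  s1 <- composite_score(zscore_panel(pre, base))
  rescaled <- pre
  rescaled$platelet <- pre$platelet * 1000   # change of units
  base2 <- baseline_stats(rescaled)
  s2 <- composite_score(zscore_panel(rescaled, base2))
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("tier assignment uses half-open intervals with upper-tier ties", {
  cuts <- c(-1, 0, 1)
  expect_equal(as.character(assign_tier(c(-2, -1, -0.5, 0, 0.5, 1, 3), cuts)),
               c("low", "medium-low", "medium-low", "medium-high",
                 "medium-high", "high", "high"))
  expect_error(assign_tier(0, c(1, 1, 2)), "increasing")
})

test_that("baseline quartile cutpoints put ~25% of the baseline in each tier", {
  panels <- make_panels(n = 2000)
  pre <- panels[panels$timepoint == "pre", ]
  score <- composite_score(zscore_panel(pre, baseline_stats(pre)))
  tiers <- assign_tier(score, tier_cutpoints(score))
  expect_equal(as.numeric(table(tiers)) / length(tiers), rep(0.25, 4),
               tolerance = 0.01)
})

test_that("the TTP rule is a strict lower-left orthant with NA for missing", {
  expect_true(ttp_rule(25, 150))
  expect_false(ttp_rule(25, 250))
  expect_false(ttp_rule(30, 150))     # strict inequality
  expect_false(ttp_rule(30, 199))
  expect_true(is.na(ttp_rule(NA, 150)))
  expect_true(is.na(ttp_rule(25, NA)))
  set.seed(4)
  for (i in 1:50) {
    p <- runif(1, 1, 60); c_ <- runif(1, 20, 400)
    if (isTRUE(ttp_rule(p, c_))) {
      expect_true(ttp_rule(p * 0.5, c_))     # risk region closed downward
      expect_true(ttp_rule(p, c_ * 0.5))
    }
  }
})

test_that("G statistic equals 2*sum(O*ln(O/E)) and approaches chi-square", {
  tab <- matrix(c(20, 10, 10, 20), 2, byrow = TRUE)
  g <- g_test(tab)
  expect_equal(g$G, oracle_g(tab), tolerance = 1e-12)
  expect_equal(g$df, 1)
  expect_equal(g$p, pchisq(oracle_g(tab), 1, lower.tail = FALSE))
  eq <- matrix(c(15, 15, 15, 15), 2)
  expect_equal(g_test(eq)$G, 0)
  expect_equal(g_test(eq)$p, 1)
  # asymptotic agreement with Pearson chi-square on large balanced tables
  big <- matrix(c(5200, 4800, 4900, 5100), 2, byrow = TRUE)
  pearson <- suppressWarnings(chisq.test(big, correct = FALSE)$statistic)
  expect_lt(abs(g_test(big)$G - pearson) / pearson, 0.01)
  # zero-margin rows are dropped with a warning
  expect_warning(g3 <- g_test(matrix(c(0, 0, 3, 4, 5, 6), 3, 2,
                                     byrow = TRUE)), "margin")
  expect_equal(g3$df, 1)
  expect_warning(gd <- g_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "margin")
  expect_equal(gd$p, 1)   # degenerate after dropping: no evidence
})

test_that("Fisher two-sided p equals hypergeometric enumeration", {
  tab <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  expect_equal(fisher_exact(tab), oracle_fisher_p(tab), tolerance = 1e-12)
  expect_equal(fisher_exact(tab), 0.4857143, tolerance = 1e-6)
  expect_equal(fisher_exact(matrix(c(0, 0, 2, 5), 2)), 1)  # zero margin
})

test_that("G-test and Fisher agree on significance for well-filled tables", {
  set.seed(12)
  agree <- vapply(1:200, function(i) {
    tab <- matrix(sample(20:120, 4, replace = TRUE), 2)
    (g_test(tab)$p < 0.05) == (fisher_exact(tab) < 0.05)
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})

test_that("per-marker tests are null when nothing changes and reject planted shifts", {
  panels <- make_panels(n = 1698, shift = TRUE, seed = 13)
  pre <- panels[panels$timepoint == "pre", ]
  post <- panels[panels$timepoint == "post", ]
  tests <- paired_marker_tests(pre, post)
  expect_lt(tests$p[tests$marker == "platelet"], 1e-6)
  expect_lt(tests$p[tests$marker == "indirect_bilirubin"], 1e-3)
  expect_error(paired_marker_tests(pre[1, ], post[1, ]), "2 patients")

  null_panels <- make_panels(n = 1698, seed = 14)
  tests0 <- paired_marker_tests(null_panels[null_panels$timepoint == "pre", ],
                                null_panels[null_panels$timepoint == "post", ])
  expect_gt(min(tests0$p), 0.001)   # no planted shift anywhere
})

test_that("transition matrices keep marginal bookkeeping", {
  pre <- factor(c("low", "low", "high", "medium-low"),
                levels = c("low", "medium-low", "medium-high", "high"))
  post <- factor(c("low", "medium-low", "high", "high"),
                 levels = levels(pre))
  # sparse toy tiers leave empty categories; the marginal G-test warns
  ts <- suppressWarnings(tier_shift_analysis(pre, post))
  expect_equal(as.numeric(rowSums(ts$transition)), c(2, 1, 0, 1))
  expect_equal(as.numeric(colSums(ts$transition)), c(1, 1, 0, 2))
  same <- suppressWarnings(tier_shift_analysis(pre, pre))
  expect_true(all(same$transition[row(same$transition) !=
                                    col(same$transition)] == 0))
  expect_equal(same$test$p, 1)

  tt <- ttp_shift_analysis(c(TRUE, FALSE, FALSE), c(TRUE, TRUE, FALSE))
  expect_equal(sum(tt$transition), 3)
  expect_equal(as.numeric(rowSums(tt$transition)), c(2, 1))
  expect_error(ttp_shift_analysis(c(TRUE), c(TRUE, FALSE)), "matched")
})
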
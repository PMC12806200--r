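#' The five study biomarkers and their risk orientation
#'
#' The composite TMA risk score is built from five routine biochemistry
#' markers.  Each marker carries a risk orientation so that a larger
#' oriented Z-score always means higher TMA risk: platelet count and RBC
#' count fall in TMA (orientation -1); creatinine, indirect bilirubin and
#' MCV rise (+1).
#'
#' @return named numeric vector of +/-1 orientations, names are the marker
#'   columns: `platelet` (x10^9/L), `creatinine` (umol/L),
#'   `indirect_bilirubin` (umol/L), `rbc` (x10^12/L), `mcv` (fL).
#' @export
marker_orientation <- function() {
  c(platelet = -1, creatinine = 1, indirect_bilirubin = 1,
    rbc = -1, mcv = 1)
}

marker_names <- function() names(marker_orientation())

check_panels <- function(panels) {
  miss <- setdiff(marker_names(), names(panels))
  if (length(miss) > 0)
    stopf("panel table lacks marker column(s): %s",
          paste(miss, collapse = ", "))
  invisible(panels)
}

#' Baseline (pre-treatment) marker statistics
#'
#' @param panels data.frame of pre-treatment panels (one row per patient)
#'   with the five marker columns.
#' @return data.frame with columns `marker`, `mean`, `sd`.
#' @export
baseline_stats <- function(panels) {
  check_panels(panels)
  m <- marker_names()
  data.frame(marker = m,
             mean = vapply(m, function(k) mean(panels[[k]], na.rm = TRUE),
                           numeric(1)),
             sd = vapply(m, function(k) stats::sd(panels[[k]], na.rm = TRUE),
                         numeric(1)),
             stringsAsFactors = FALSE)
}

#' Oriented per-marker Z-scores
#'
#' Standardizes each marker against the supplied baseline
#' (`z = (value - mean) / sd`) and multiplies by the marker's risk
#' orientation, so that a platelet count one SD *below* the baseline mean
#' yields an oriented z of +1.
#'
#' @param panels data.frame with the five marker columns.
#' @param baseline output of [baseline_stats()] (typically computed on the
#'   pre-treatment cohort).
#' @return numeric matrix, one row per panel, one column per marker.
#' @export
zscore_panel <- function(panels, baseline) {
  check_panels(panels)
  orient <- marker_orientation()
  if (any(baseline$sd <= 0 | !is.finite(baseline$sd)))
    stopf("baseline SDs must be positive")
  z <- sapply(marker_names(), function(k) {
    b <- baseline[baseline$marker == k, ]
    orient[[k]] * (panels[[k]] - b$mean) / b$sd
  })
  z <- matrix(z, ncol = length(marker_names()),
              dimnames = list(NULL, marker_names()))
  z
}

#' Composite TMA risk score
#'
#' Sums log2-compressed oriented Z-scores across the five markers.  Because
#' a plain log2 of a Z-score is undefined at or below zero, the signed
#' transform `sign(z) * log2(1 + |z|)` is used: defined everywhere, odd,
#' strictly monotone, and approximately `log2(|z|)` for large `|z|`.  A raw
#' sum of untransformed Z-scores is available via `method = "raw"`.
#'
#' @param oriented_z matrix from [zscore_panel()].
#' @param method `"signed_log2"` (default) or `"raw"`.
#' @param na_action `"error"` (default: any missing marker is an error) or
#'   `"omit"` to sum over observed markers.
#' @return numeric vector of scores, one per row.
#' @export
composite_score <- function(oriented_z, method = c("signed_log2", "raw"),
                            na_action = c("error", "omit")) {
  method <- match.arg(method)
  na_action <- match.arg(na_action)
  if (anyNA(oriented_z) && na_action == "error")
    stopf("missing marker Z-scores; set na_action='omit' to allow")
  tz <- switch(method,
               signed_log2 = sign(oriented_z) * log2(1 + abs(oriented_z)),
               raw = oriented_z)
  rowSums(tz, na.rm = (na_action == "omit"))
}

#' Tier cutpoints from a baseline score distribution
#'
#' @param baseline_scores composite scores of the pre-treatment cohort.
#' @return numeric vector of three cutpoints (the baseline quartiles).
#' @export
tier_cutpoints <- function(baseline_scores) {
  stats::quantile(baseline_scores, c(0.25, 0.5, 0.75), type = 7,
                  names = FALSE)
}

#' Assign risk tiers from composite scores
#'
#' Four tiers by half-open intervals against three increasing cutpoints
#' (default: baseline quartiles): `low` below the first cutpoint, then
#' `medium-low`, `medium-high`, and `high` at or above the third.  A score
#' exactly at a cutpoint falls in the upper tier.
#'
#' @param score numeric vector of composite scores.
#' @param cutpoints three strictly increasing numbers.
#' @return character vector of tiers (ordered factor levels low <
#'   medium-low < medium-high < high).
#' @export
assign_tier <- function(score, cutpoints) {
  if (length(cutpoints) != 3 || is.unsorted(cutpoints, strictly = TRUE))
    stopf("cutpoints must be three strictly increasing values")
  labs <- c("low", "medium-low", "medium-high", "high")
  idx <- findInterval(score, cutpoints, left.open = FALSE) + 1
  factor(labs[idx], levels = labs, ordered = TRUE)
}

#' TTP risk rule (French criteria)
#'
#' A panel is flagged at high risk of thrombotic thrombocytopenic purpura
#' when the platelet count is strictly below 30 x10^9/L *and* creatinine is
#' strictly below 199 umol/L (severe thrombocytopenia with relatively
#' preserved renal function favours TTP over HUS).  Missing either marker
#' yields `NA` (undetermined), never `FALSE`.
#'
#' @param platelet platelet counts (x10^9/L).
#' @param creatinine creatinine (umol/L).
#' @param platelet_max,creatinine_max rule thresholds (defaults 30, 199).
#' @return logical vector (with `NA` for undetermined).
#' @export
ttp_rule <- function(platelet, creatinine, platelet_max = 30,
                     creatinine_max = 199) {
  out <- platelet < platelet_max & creatinine < creatinine_max
  out[is.na(platelet) | is.na(creatinine)] <- NA  # undetermined, not FALSE
  out
}

#' Per-marker pre vs post comparisons
#'
#' Two-sided Mann-Whitney test per marker between the pre- and
#' post-treatment panels.  The unpaired rank test matches standard
#' pharmacovigilance reporting of such panels; a paired Wilcoxon
#' signed-rank alternative is available.
#'
#' @param pre,post data.frames of panels with the five marker columns,
#'   matched patients (same order).
#' @param paired use the Wilcoxon signed-rank test instead (default FALSE).
#' @return data.frame with columns `marker, statistic, p`.
#' @export
paired_marker_tests <- function(pre, post, paired = FALSE) {
  check_panels(pre); check_panels(post)
  if (nrow(pre) < 2 || nrow(post) < 2)
    stopf("need at least 2 patients per timepoint")
  rows <- lapply(marker_names(), function(k) {
    if (paired) {
      wt <- suppressWarnings(stats::wilcox.test(pre[[k]], post[[k]],
                                                paired = TRUE))
      data.frame(marker = k, statistic = unname(wt$statistic),
                 p = wt$p.value, stringsAsFactors = FALSE)
    } else {
      mw <- mann_whitney(pre[[k]], post[[k]])
      data.frame(marker = k, statistic = mw$U, p = mw$p,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Log-likelihood-ratio (G) test of independence
#'
#' `G = 2 * sum(O * ln(O/E))` over an r x c table with expected counts from
#' the margins; `df = (r-1)(c-1)`; p from the upper chi-square tail.  Cells
#' with observed zero contribute zero.  Rows/columns with zero margins are
#' dropped with a warning.  No Williams correction.
#'
#' @param tab matrix of non-negative counts.
#' @return list with `G`, `df`, `p`, `expected`.
#' @export
g_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stopf("counts must be non-negative")
  zr <- rowSums(tab) == 0
  zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("dropping zero-margin rows/columns from G-test table")
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    # degenerate after dropping margins: no evidence against independence
    return(list(G = 0, df = 0L, p = 1, expected = tab))
  }
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  terms <- ifelse(tab > 0, tab * log(tab / E), 0)
  G <- 2 * sum(terms)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(G = G, df = df,
       p = stats::pchisq(G, df, lower.tail = FALSE), expected = E)
}

#' Fisher's exact test, two-sided
#'
#' Two-sided p-value as the sum of hypergeometric probabilities (margins
#' fixed) of all tables no more probable than the observed one.  A table
#' with any zero margin is deterministic given its margins, so p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stopf("fisher_exact() expects a 2x2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Tier-shift and TTP-shift analyses
#'
#' Cross-tabulates matched pre -> post risk tiers (4x4) or TTP flags (2x2)
#' and tests whether the marginal pre vs post distribution changed: a
#' G-test on the 2 x k (timepoint x category) table for tiers, Fisher's
#' exact test for the TTP flags.  The transition matrix's row sums are the
#' pre counts and its column sums the post counts.
#'
#' @param pre,post vectors of tiers (from [assign_tier()]) or logical TTP
#'   flags, matched patients in the same order.
#' @return list with `transition` (contingency matrix), `marginal` (2 x k
#'   counts), and `test` (G-test result or Fisher p).
#' @export
tier_shift_analysis <- function(pre, post) {
  if (length(pre) != length(post))
    stopf("pre and post tiers must be matched (same length)")
  labs <- c("low", "medium-low", "medium-high", "high")
  pre <- factor(as.character(pre), levels = labs)
  post <- factor(as.character(post), levels = labs)
  transition <- table(pre = pre, post = post)
  marginal <- rbind(pre = table(pre), post = table(post))
  test <- g_test(marginal)
  list(transition = transition, marginal = marginal, test = test)
}

#' @rdname tier_shift_analysis
#' @export
ttp_shift_analysis <- function(pre, post) {
  if (length(pre) != length(post))
    stopf("pre and post TTP flags must be matched (same length)")
  pre <- factor(pre, levels = c(FALSE, TRUE),
                labels = c("not_at_risk", "at_risk"))
  post <- factor(post, levels = c(FALSE, TRUE),
                 labels = c("not_at_risk", "at_risk"))
  transition <- table(pre = pre, post = post)
  marginal <- rbind(pre = table(pre), post = table(post))
  list(transition = transition, marginal = marginal,
       test = list(p = fisher_exact(marginal)))
}
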
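#' Read / write gene-set collections in GMT format
#'
#' GMT is tab-separated: set name, description, then member genes.
#'
#' @param path file path.
#' @param gene_sets named list of character vectors.
#' @param descriptions optional character vector of descriptions.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], descriptions[i] %||% "na",
            gene_sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# restrict sets to genes present in the matrix; drop undersized sets
prepare_sets <- function(gene_sets, genes, min_size = 2) {
  if (length(gene_sets) == 0) stopf("empty gene-set collection")
  out <- lapply(gene_sets, function(s) intersect(unique(s), genes))
  dropped <- names(out)[lengths(out) < min_size]
  if (length(dropped) > 0)
    warning(sprintf("skipping %d gene set(s) with fewer than %d genes present: %s",
                    length(dropped), min_size,
                    paste(utils::head(dropped, 5), collapse = ", ")))
  out[lengths(out) >= min_size]
}

#' Single-sample gene-set enrichment scores (ssGSEA)
#'
#' For each sample, genes are ranked by expression (average ranks for
#' ties) and ordered from highest to lowest.  The set score is the sum,
#' over all positions of the ordered list, of the difference between the
#' weighted in-set empirical CDF (weights proportional to rank^alpha) and
#' the unweighted out-of-set ECDF.  With `normalize = TRUE` (default) the
#' whole score matrix is divided by its range across samples and sets, so
#' scores are comparable across samples.
#'
#' @param expr non-negative numeric matrix, genes x samples, with rownames.
#' @param gene_sets named list of character vectors of gene ids; members
#'   absent from `expr` are dropped (sets with fewer than 2 present genes
#'   are skipped with a warning).
#' @param alpha rank weighting exponent (default 0.25).
#' @param normalize divide the score matrix by its overall range (default
#'   TRUE).
#' @return numeric matrix, sets x samples.
#' @export
ssgsea_scores <- function(expr, gene_sets, alpha = 0.25, normalize = TRUE) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stopf("expression matrix needs gene rownames")
  if (any(expr < 0)) stopf("expression matrix must be non-negative")
  sets <- prepare_sets(gene_sets, rownames(expr), min_size = 2)
  if (length(sets) == 0) stopf("no usable gene sets")
  n_genes <- nrow(expr)
  scores <- matrix(NA_real_, nrow = length(sets), ncol = ncol(expr),
                   dimnames = list(names(sets), colnames(expr)))
  set_idx <- lapply(sets, function(s) match(s, rownames(expr)))
  for (j in seq_len(ncol(expr))) {
    r <- rank(expr[, j])               # average ranks for ties
    ord <- order(r, decreasing = TRUE) # highest expression first
    w <- r[ord]^alpha
    for (k in seq_along(sets)) {
      member <- logical(n_genes)
      member[set_idx[[k]]] <- TRUE
      member <- member[ord]
      wk <- w * member
      p_in <- cumsum(wk) / sum(wk)
      p_out <- cumsum(!member) / (n_genes - length(set_idx[[k]]))
      scores[k, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  scores
}

# signal-to-noise ranking metric with an SD floor to avoid blowups;
# positive values mean higher expression in `positive_class`
signal_to_noise <- function(expr, groups, positive_class = NULL,
                            sd_floor = function(m) 0.2 * abs(m) + 0.2) {
  g <- unique(groups)
  if (length(g) != 2) stopf("need exactly two groups")
  positive_class <- positive_class %||% g[length(g)]
  if (!positive_class %in% g) stopf("positive_class not among group labels")
  x1 <- expr[, groups == positive_class, drop = FALSE]
  x2 <- expr[, groups != positive_class, drop = FALSE]
  if (ncol(x1) < 2 || ncol(x2) < 2) stopf("need >= 2 samples per group")
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  s1 <- pmax(apply(x1, 1, stats::sd), sd_floor(m1))
  s2 <- pmax(apply(x2, 1, stats::sd), sd_floor(m2))
  (m1 - m2) / (s1 + s2)
}

# weighted Kolmogorov-Smirnov enrichment score from sorted stats.
# Only positions of set members matter: between hits the running sum
# decreases linearly, so the extrema lie at (or just before) hit positions.
gsea_es <- function(abs_stat_sorted, hit_pos) {
  N <- length(abs_stat_sorted)
  k <- length(hit_pos)
  hit_pos <- sort(hit_pos)
  w <- abs_stat_sorted[hit_pos]
  tot <- sum(w)
  p_hit <- if (tot > 0) cumsum(w) / tot else seq_len(k) / k
  denom <- N - k
  p_miss_at <- (hit_pos - seq_len(k)) / denom
  p_miss_before <- (hit_pos - seq_len(k)) / denom  # just before hit j
  top <- max(p_hit - p_miss_at)
  bottom <- min(c(0, c(0, p_hit[-k]) - p_miss_before))
  if (top >= abs(bottom)) top else bottom
}

#' Two-group GSEA with a gene-label permutation null
#'
#' Genes are ranked by the signal-to-noise ratio between the two groups
#' (SD floored at `0.2*|mean| + 0.2`), and each set's enrichment score (ES)
#' is the maximum deviation of the weighted Kolmogorov-Smirnov running sum
#' (hit weights `|stat|^p`).  The null distribution permutes gene labels:
#' `n_perm` random sets of the same size are drawn from the ranked list
#' (the null is shared across sets of equal size).  The permutation p-value
#' uses the plus-one estimator `(1 + #(|ES_null| >= |ES|)) / (n_perm + 1)`;
#' NES divides ES by the mean magnitude of same-sign null scores; p-values
#' are Benjamini-Hochberg adjusted across sets.
#'
#' @param expr numeric matrix, genes x samples, with rownames.
#' @param groups vector of two group labels, one per column.
#' @param gene_sets named list of gene-id vectors.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutation draws.
#' @param weight_p hit-weight exponent (default 1).
#' @param positive_class group label treated as the "up" phenotype: a
#'   positive ES means enrichment among genes higher in this group.
#'   Defaults to the last distinct group label (`"treated"` for the
#'   bundled generator's `control`/`treated` labels).
#' @return data.frame with columns `set, size, es, nes, p_perm, p_adj,
#'   direction`, sorted by `p_perm`.
#' @export
gsea_two_group <- function(expr, groups, gene_sets, n_perm = 1000,
                           seed = NULL, weight_p = 1,
                           positive_class = NULL) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stopf("expression matrix needs gene rownames")
  stat <- signal_to_noise(expr, groups, positive_class)
  if (all(stat == stat[1]))
    stopf("degenerate ranking: no between-group variation")
  ord <- order(stat, decreasing = TRUE)
  abs_sorted <- abs(stat[ord])^weight_p
  gene_rank_pos <- match(rownames(expr), rownames(expr)[ord])

  sets <- prepare_sets(gene_sets, rownames(expr), min_size = 2)
  if (length(sets) == 0) stopf("no usable gene sets")
  sizes <- lengths(sets)
  N <- nrow(expr)

  if (!is.null(seed)) set.seed(seed)
  null_by_size <- new.env(parent = emptyenv())
  null_for <- function(k) {
    key <- as.character(k)
    if (is.null(null_by_size[[key]])) {
      null_by_size[[key]] <- vapply(seq_len(n_perm), function(i)
        gsea_es(abs_sorted, sample.int(N, k)), numeric(1))
    }
    null_by_size[[key]]
  }

  rows <- lapply(names(sets), function(nm) {
    pos <- gene_rank_pos[match(sets[[nm]], rownames(expr))]
    es <- gsea_es(abs_sorted, pos)
    nulls <- null_for(length(pos))
    p_perm <- (1 + sum(abs(nulls) >= abs(es))) / (n_perm + 1)
    same_sign <- nulls[sign(nulls) == sign(es)]
    nes <- if (length(same_sign) > 0) es / mean(abs(same_sign)) else NA_real_
    data.frame(set = nm, size = length(pos), es = es, nes = nes,
               p_perm = p_perm, direction = sign(es),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_perm, method = "BH")
  out <- out[order(out$p_perm, -abs(out$nes)), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("set", "size", "es", "nes", "p_perm", "p_adj", "direction")]
}

#' Correlate per-cancer pathway activity with per-cancer RORs
#'
#' Spearman rank correlation (average ranks for ties; two-sided p via the
#' t approximation) between each pathway's per-cancer summary score and the
#' per-cancer reporting odds ratio.  Cancers lacking an ROR (for example
#' strata excluded for fewer than three cases) are dropped pairwise; at
#' least four complete pairs are required.
#'
#' @param scores numeric matrix, pathways x cancers (e.g. mean ssGSEA score
#'   across each cancer's samples), with dimnames.
#' @param ror named numeric vector of per-cancer RORs (names matching the
#'   score columns).
#' @return data.frame with columns `pathway, rho, p, n`.
#' @export
correlate_ror_pathways <- function(scores, ror) {
  scores <- as.matrix(scores)
  common <- intersect(colnames(scores), names(ror))
  if (length(common) == 0) stopf("no cancers shared between scores and ROR")
  rows <- lapply(rownames(scores), function(pw) {
    x <- scores[pw, common]
    y <- ror[common]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 4)
      stopf("fewer than 4 complete cancer pairs for pathway '%s'", pw)
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    data.frame(pathway = pw, rho = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
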
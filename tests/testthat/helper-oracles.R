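# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals.

# direct Woolf evaluation of the reporting odds ratio
oracle_ror <- function(a, b, c, d, alpha = 0.05) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - alpha / 2)
  list(ror = ror, ci_low = exp(log(ror) - z * se),
       ci_high = exp(log(ror) + z * se))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_p <- function(x, y) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  vals <- c(x, y)
  u_of <- function(xi) {
    xs <- vals[xi]; ys <- vals[-xi]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  splits <- combn(n, nx)
  u_null <- apply(splits, 2, u_of)
  p <- min(mean(u_null <= u_obs), mean(u_null >= u_obs)) * 2
  min(1, p)
}

# two-sided Fisher p by hypergeometric enumeration (fixed margins)
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(ks, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# direct G statistic
oracle_g <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  2 * sum(ifelse(tab > 0, tab * log(tab / E), 0))
}

# double-loop ssGSEA score for one sample (no normalization)
oracle_ssgsea_sample <- function(values, genes, set, alpha) {
  r <- rank(values)
  ord <- order(r, decreasing = TRUE)
  genes_ord <- genes[ord]
  w_ord <- r[ord]^alpha
  in_set <- genes_ord %in% set
  w_tot <- sum(w_ord[in_set])
  n <- length(genes)
  n_out <- n - sum(in_set)
  score <- 0
  for (i in seq_len(n)) {
    p_in <- sum(w_ord[seq_len(i)][in_set[seq_len(i)]]) / w_tot
    p_out <- sum(!in_set[seq_len(i)]) / n_out
    score <- score + (p_in - p_out)
  }
  score
}

# brute-force weighted KS enrichment score over the full running sum
oracle_gsea_es <- function(stat_sorted, hit_pos, p = 1) {
  n <- length(stat_sorted)
  hits <- logical(n); hits[hit_pos] <- TRUE
  w <- abs(stat_sorted)^p
  w_tot <- sum(w[hits])
  run <- 0; best <- 0
  p_in <- 0; p_out <- 0
  n_out <- n - length(hit_pos)
  for (i in seq_len(n)) {
    if (hits[i]) p_in <- p_in + w[i] / w_tot else p_out <- p_out + 1 / n_out
    run <- p_in - p_out
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Spearman rho by the rank formula with average ties
oracle_spearman <- function(x, y) {
  cor(rank(x), rank(y))
}

# small well-formed raw ICSR table used across tests
make_raw_reports <- function() {
  data.frame(
    report_id = c("r1", "r2", "r3"),
    gender = c("female", "male", "unknown"),
    age_years = c(44.9, 45.0, 70),
    region = c("Americas", "Europe", "Asia"),
    event_date = c("2020-03-01", "2021-07-15", "2022-01-10"),
    suspect_drugs = c("AVASTIN", "sunitinib ", "cisplatin"),
    concomitant_drugs = c("", "", ""),
    indication = c("renal cell carcinoma", "colon adenocarcinoma",
                   "breast cancer"),
    events = c("thrombotic microangiopathy", "nausea",
               "Haemolytic Uraemic Syndrome;rash"),
    outcome = c("nonfatal", "fatal", "unknown"),
    therapy_start = c("2020-01-01", "2021-01-01", "2021-12-01"),
    event_onset = c("2020-02-05", "2021-07-01", "2022-01-05"),
    stringsAsFactors = FALSE)
}
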
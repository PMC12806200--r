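#' Build a 2x2 exposure-by-event contingency table
#'
#' Cross-classifies a deduplicated, normalized report cohort by exposure to
#' a drug (or drug class) and occurrence of any term of an event set.  The
#' background comparator is the full supplied cohort: each report is counted
#' exactly once, in one of the four cells
#' \describe{
#'   \item{a}{exposed, with event}
#'   \item{b}{exposed, no event}
#'   \item{c}{not exposed, with event}
#'   \item{d}{neither}
#' }
#'
#' @param reports ICSR data.frame (deduplicated, drug-normalized).
#' @param exposure a list with either `drugs` (character vector of generic
#'   names) or `class` (`"VEGFi"`, `"VEGFRi"`, or both for a pooled "All"
#'   exposure); optional `label`.
#' @param events an [event_set()] (or character vector of terms).
#' @param suspect_only count a report as exposed only via suspect drugs
#'   (default `TRUE`).
#' @return object of class `contingency_table`.
#' @export
build_contingency <- function(reports, exposure, events = tma_event_set(),
                              suspect_only = TRUE) {
  if (nrow(reports) == 0) stopf("empty cohort: no reports to tabulate")
  if (is.character(events)) events <- event_set("events", events)

  exposed <- exposure_flags(reports, exposure, suspect_only)
  has_event <- event_flags(reports, events)

  a <- sum(exposed & has_event)
  b <- sum(exposed & !has_event)
  c_ <- sum(!exposed & has_event)
  d <- sum(!exposed & !has_event)
  structure(list(a = a, b = b, c = c_, d = d,
                 exposure_label = exposure$label %||%
                   paste(exposure$drugs %||% exposure$class, collapse = "+"),
                 event_label = events$name,
                 n = nrow(reports)),
            class = "contingency_table")
}

exposure_flags <- function(reports, exposure, suspect_only = TRUE) {
  if (!is.null(exposure$drugs)) {
    hit <- has_any_term(reports$suspect_drugs, exposure$drugs)
    if (!suspect_only)
      hit <- hit | has_any_term(reports$concomitant_drugs, exposure$drugs)
    hit
  } else if (!is.null(exposure$class)) {
    if (is.null(reports$suspect_classes))
      stopf("class-level exposure needs normalize_drugs() first")
    has_any_term(reports$suspect_classes, exposure$class, lower = FALSE)
  } else {
    stopf("exposure spec needs either $drugs or $class")
  }
}

event_flags <- function(reports, events) {
  if (is.character(events)) events <- event_set("events", events)
  has_any_term(reports$events, events$terms)
}

#' Reporting odds ratio with Woolf 95% confidence interval
#'
#' Computes `ROR = (a/b)/(c/d) = ad/(bc)` with the Woolf (log-normal)
#' interval `exp(log(ROR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.  If any
#' cell is zero, the Haldane-Anscombe correction adds 0.5 to all four cells
#' before computing (flagged via `correction_applied`); otherwise counts are
#' used as-is.  `n_reports` is always the uncorrected `a` cell, the number
#' of exposed reports with the event.
#'
#' @param table a `contingency_table` (or list with fields `a,b,c,d`).
#' @param alpha two-sided level for the CI (default 0.05).
#' @param min_reports minimum report count of the signal rule (default 3).
#' @return object of class `signal_result`: fields `ror`, `ci_low`,
#'   `ci_high`, `n_reports`, `alpha`, `is_signal`, `correction_applied`.
#' @export
#' @examples
#' compute_ror(list(a = 10, b = 90, c = 100, d = 9900))
compute_ror <- function(table, alpha = 0.05, min_reports = 3) {
  cells <- c(table$a, table$b, table$c, table$d)
  if (any(cells < 0) || any(cells != floor(cells)))
    stopf("contingency cells must be non-negative integers")
  if (all(cells == 0)) stopf("all-zero contingency table")
  correction <- any(cells == 0)
  cc <- if (correction) cells + 0.5 else cells
  ror <- (cc[1] * cc[4]) / (cc[2] * cc[3])
  se <- sqrt(sum(1 / cc))
  z <- stats::qnorm(1 - alpha / 2)
  res <- structure(list(
    ror = ror,
    ci_low = exp(log(ror) - z * se),
    ci_high = exp(log(ror) + z * se),
    n_reports = as.integer(table$a),
    alpha = alpha,
    is_signal = NA,
    correction_applied = correction,
    exposure_label = table$exposure_label %||% NA_character_,
    event_label = table$event_label %||% NA_character_
  ), class = "signal_result")
  res$is_signal <- classify_signal(res, min_reports)
  res
}

#' Apply the signal-detection rule
#'
#' A drug/event pair is a signal when the number of exposed reports with the
#' event is at least `min_reports` (default three) *and* the lower bound of
#' the 95% CI of the ROR strictly exceeds one.
#'
#' @param result a `signal_result`.
#' @param min_reports minimum report count (default 3).
#' @return logical.
#' @export
classify_signal <- function(result, min_reports = 3) {
  isTRUE(result$n_reports >= min_reports && result$ci_low > 1)
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("ROR %s vs %s: %.3f [%.3f, %.3f], n=%d%s -> %s\n",
              x$exposure_label, x$event_label, x$ror, x$ci_low, x$ci_high,
              x$n_reports,
              if (x$correction_applied) " (0.5 correction)" else "",
              if (isTRUE(x$is_signal)) "SIGNAL" else "no signal"))
  invisible(x)
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 [%s x %s]: a=%d b=%d c=%d d=%d (n=%d)\n",
              x$exposure_label, x$event_label, x$a, x$b, x$c, x$d, x$n))
  invisible(x)
}

#' Scan many drug/event pairs for disproportionality signals
#'
#' Computes one ROR row per (exposure, event set, stratum) combination.
#' Strata (for example per-cancer scans) with fewer than `min_reports`
#' exposed-event reports are still emitted, flagged `excluded = TRUE` and
#' `is_signal = FALSE`, mirroring the practice of dropping strata with
#' fewer than three cases.  Results are sorted by ROR, descending.
#'
#' @param reports deduplicated, normalized ICSR data.frame.
#' @param exposures named list of exposure specs (see [build_contingency()]).
#' @param event_sets named list of [event_set()]s (default: the bundled TMA
#'   set).
#' @param stratify_by optional column name (e.g. `"cancer_type"`); when set,
#'   the 2x2 is built within each stratum.
#' @param min_reports,alpha signal rule parameters.
#' @param adjust apply Benjamini-Hochberg flagging across the scan's
#'   one-sided Woolf z-tests (off by default; raw RORs are reported either
#'   way).
#' @return data.frame with columns `exposure, event_set, stratum, a, b, c,
#'   d, ror, ci_low, ci_high, n, is_signal, excluded` (plus `p_adj` when
#'   `adjust = TRUE`).
#' @export
scan_signals <- function(reports, exposures, event_sets = NULL,
                         stratify_by = NULL, min_reports = 3, alpha = 0.05,
                         adjust = FALSE) {
  if (is.null(event_sets)) event_sets <- list(TMA = tma_event_set())
  if (inherits(event_sets, "event_set")) event_sets <- list(event_sets)
  if (!is.null(stratify_by) && is.null(reports[[stratify_by]]))
    stopf("stratification column '%s' not found in reports", stratify_by)
  strata <- if (is.null(stratify_by)) list(all = seq_len(nrow(reports)))
            else split(seq_len(nrow(reports)), reports[[stratify_by]])
  # exposure and event flags are computed once on the full cohort (the
  # padded canonical strings are shared across exposures) and subset per
  # stratum, so a scan over many drugs stays O(drugs + strata)
  pad_sus <- pad_multi(reports$suspect_drugs)
  pad_cls <- if (!is.null(reports$suspect_classes))
    pad_multi(reports$suspect_classes, lower = FALSE) else NULL
  pad_ev <- pad_multi(reports$events)
  exp_flags <- lapply(exposures, function(x) {
    if (!is.null(x$drugs)) match_pad(pad_sus, x$drugs)
    else if (!is.null(x$class)) {
      if (is.null(pad_cls)) stopf("class-level exposure needs normalize_drugs() first")
      match_pad(pad_cls, x$class, lower = FALSE)
    } else stopf("exposure spec needs either $drugs or $class")
  })
  ev_flags <- lapply(event_sets, function(e) match_pad(pad_ev, e$terms))
  rows <- list()
  for (s_name in names(strata)) {
    idx <- strata[[s_name]]
    if (length(idx) == 0) next
    for (e_name in names(event_sets)) {
      ev <- ev_flags[[e_name]][idx]
      for (x_name in names(exposures)) {
        ex <- exp_flags[[x_name]][idx]
        a <- sum(ex & ev); b <- sum(ex & !ev)
        c_ <- sum(!ex & ev); d <- sum(!ex & !ev)
        excluded <- a < min_reports
        res <- if (a + b + c_ + d == 0) NULL
               else compute_ror(list(a = a, b = b, c = c_, d = d),
                                alpha, min_reports)
        rows[[length(rows) + 1]] <- data.frame(
          exposure = x_name, event_set = e_name,
          stratum = if (is.null(stratify_by)) NA_character_ else s_name,
          a = a, b = b, c = c_, d = d,
          ror = res$ror %||% NA_real_,
          ci_low = res$ci_low %||% NA_real_,
          ci_high = res$ci_high %||% NA_real_,
          n = a,
          is_signal = !excluded && isTRUE(res$is_signal),
          excluded = excluded,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (adjust && nrow(out) > 0) {
    # one-sided p from the Woolf z statistic for ROR > 1
    z <- log(out$ror) / ((log(out$ci_high) - log(out$ci_low)) /
                           (2 * stats::qnorm(1 - alpha / 2)))
    out$p_adj <- stats::p.adjust(stats::pnorm(z, lower.tail = FALSE), "BH")
  }
  out <- out[order(-out$ror, out$exposure), , drop = FALSE]
  rownames(out) <- NULL
  out
}
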
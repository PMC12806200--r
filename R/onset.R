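#' Extract time-to-onset samples from a report cohort
#'
#' Time to onset (TTO) is the number of whole days from therapy start to
#' adverse-event onset.  Reports lacking either date, or with a
#' non-positive interval, are excluded and counted in the `"excluded"`
#' attribute.  Grouping is by drug class (reports whose suspect drugs span
#' both study classes are labelled `"mixed"`), by gender, or by individual
#' suspect drug (a report with several suspect drugs contributes to each).
#'
#' @param reports ICSR data.frame with parsed dates (and, for
#'   `"drug_class"`, a `suspect_classes` column from [normalize_drugs()]).
#' @param group_by `"drug_class"`, `"gender"` or `"drug"`.
#' @return data.frame with columns `group` and `days`; attribute
#'   `"excluded"` holds counts of missing-date and non-positive intervals.
#' @export
extract_tto <- function(reports, group_by = c("drug_class", "gender", "drug")) {
  group_by <- match.arg(group_by)
  days <- as.numeric(reports$event_onset - reports$therapy_start)
  missing <- is.na(days)
  nonpos <- !missing & days <= 0
  keep <- !missing & !nonpos

  group <- switch(group_by,
    gender = reports$gender,
    drug_class = {
      cls <- split_terms(reports$suspect_classes)
      vapply(cls, function(v) {
        v <- unique(v[v %in% c("VEGFi", "VEGFRi")])
        if (length(v) == 1) v else if (length(v) > 1) "mixed" else "other"
      }, character(1))
    },
    drug = NA  # handled below (one row per suspect drug)
  )

  if (group_by == "drug") {
    sus <- split_terms(reports$suspect_drugs)
    reps <- lengths(sus)
    out <- data.frame(group = unlist(sus),
                      days = rep(days, reps),
                      stringsAsFactors = FALSE)
    out <- out[!is.na(out$days) & out$days > 0, , drop = FALSE]
  } else {
    out <- data.frame(group = group[keep], days = days[keep],
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "excluded") <- c(missing_dates = sum(missing),
                             nonpositive = sum(nonpos))
  out
}

#' Median and interquartile range of a TTO sample
#'
#' Quartiles use the linear-interpolation convention between order
#' statistics ([stats::quantile()] type 7); reported IQRs depend on this
#' choice, so it is fixed and documented.
#'
#' @param days positive numeric vector.
#' @return list with `median`, `q1`, `q3`, `n`.
#' @export
tto_summary <- function(days) {
  if (length(days) == 0) stopf("empty TTO sample")
  q <- stats::quantile(days, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3], n = length(days))
}

#' Mann-Whitney U test
#'
#' Two-sample rank test.  When the combined sample size is at most 20 and
#' there are no ties, the exact p-value is used (full null enumeration of
#' rank assignments); otherwise the normal approximation with tie and
#' continuity corrections.  The returned `U` is the number of (x, y) pairs
#' with x > y (ties count 1/2), so `U_x + U_y = n_x * n_y`.
#'
#' @param x,y non-empty numeric vectors.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exact_max combined size up to which the exact p is used (20).
#' @return list with `U`, `p`, `method`.
#' @export
mann_whitney <- function(x, y, alternative = "two.sided", exact_max = 20) {
  if (length(x) == 0 || length(y) == 0)
    stopf("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y)) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative,
                       exact = use_exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (use_exact) "exact" else "normal approximation")
}

#' Cumulative-onset curve
#'
#' Right-continuous empirical step function of onset times, in percent; the
#' last step reaches 100%.  Curve values at the sample quartiles agree with
#' [tto_summary()] in the sense that at least 25/50/75% of onsets have
#' occurred by q1/median/q3.
#'
#' @param days positive numeric vector.
#' @return data.frame with columns `day` (sorted unique values) and
#'   `cum_pct`.
#' @export
cumulative_curve <- function(days) {
  if (length(days) == 0) stopf("empty TTO sample")
  d <- sort(unique(days))
  cum <- stats::ecdf(days)(d) * 100
  data.frame(day = d, cum_pct = cum)
}
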
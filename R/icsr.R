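#' Required columns of a raw ICSR table
#' @keywords internal
icsr_required_columns <- function() {
  c("report_id", "gender", "age_years", "region", "event_date",
    "suspect_drugs", "indication", "events", "therapy_start", "event_onset")
}

parse_iso_date <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
  suppressWarnings(as.Date(x, format = "%Y-%m-%d"))
}

#' Ingest and validate raw individual case safety reports
#'
#' Reads a raw ICSR table (one row per report; multi-valued fields
#' semicolon-separated), validates it, parses ISO-8601 dates, normalizes
#' gender/region/outcome categories and bins ages into half-open bands.
#' Malformed rows (unparseable dates, no adverse-event term, no suspect
#' drug) are quarantined rather than silently dropped: the returned table
#' carries the quarantined rows and reasons in the `"quarantine"` attribute
#' (see [quarantine_log()]).
#'
#' @param raw data.frame with at least the columns named by
#'   `icsr_required_columns()`; `concomitant_drugs` and `outcome` are
#'   optional.
#' @param age_breaks,age_labels age-band definition; bands are `[lo, hi)`.
#' @param cancer_lookup indication-to-cancer-code lookup, see
#'   [default_cancer_lookup()].
#' @return validated ICSR data.frame with parsed `Date` columns, an
#'   `age_band` column and a `cancer_type` column.
#' @export
ingest_reports <- function(raw,
                           age_breaks = default_age_breaks(),
                           age_labels = default_age_labels(),
                           cancer_lookup = default_cancer_lookup()) {
  need <- icsr_required_columns()
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0)
    stopf("missing required ICSR column(s): %s",
          paste(missing_cols, collapse = ", "))
  df <- as.data.frame(raw, stringsAsFactors = FALSE)
  if (!"concomitant_drugs" %in% names(df)) df$concomitant_drugs <- ""
  if (!"outcome" %in% names(df)) df$outcome <- "unknown"

  n <- nrow(df)
  reasons <- character(n)
  add_reason <- function(bad, why) {
    reasons[bad] <<- ifelse(nzchar(reasons[bad]),
                            paste(reasons[bad], why, sep = "; "), why)
  }

  df$report_id <- as.character(df$report_id)
  df$gender <- ifelse(norm_key(df$gender) %in% c("female", "male"),
                      norm_key(df$gender), "unknown")
  reg <- df$region
  known_reg <- c("Americas", "Europe", "Asia", "other")
  idx <- match(norm_key(reg), norm_key(known_reg))
  df$region <- ifelse(is.na(idx), "unknown", known_reg[idx])
  df$outcome <- ifelse(norm_key(df$outcome) %in% c("fatal", "nonfatal"),
                       norm_key(df$outcome), "unknown")

  df$age_years <- suppressWarnings(as.numeric(df$age_years))
  bad_age <- !is.na(df$age_years) & df$age_years < 0
  add_reason(bad_age, "negative age")
  df$age_band <- age_band(df$age_years, age_breaks, age_labels)

  for (col in c("event_date", "therapy_start", "event_onset")) {
    raw_col <- as.character(df[[col]])
    parsed <- parse_iso_date(raw_col)
    nonempty <- !is.na(raw_col) & nzchar(trimws(raw_col))
    add_reason(nonempty & is.na(parsed), sprintf("unparseable %s", col))
    df[[col]] <- parsed
  }

  add_reason(field_empty(df$events), "no adverse-event term")
  add_reason(field_empty(df$suspect_drugs), "no suspect drug")

  df$cancer_type <- map_cancer_type(df$indication, cancer_lookup)

  bad <- nzchar(reasons)
  quarantine <- data.frame(row = which(bad),
                           report_id = df$report_id[bad],
                           reason = reasons[bad],
                           stringsAsFactors = FALSE)
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "quarantine") <- quarantine
  out
}

#' Quarantine log of an ingested cohort
#' @param reports output of [ingest_reports()].
#' @return data.frame of quarantined rows with reasons.
#' @export
quarantine_log <- function(reports) {
  attr(reports, "quarantine") %||%
    data.frame(row = integer(), report_id = character(),
               reason = character(), stringsAsFactors = FALSE)
}

dedup_key <- function(reports) {
  con <- canon_multi(reports$concomitant_drugs)
  drugs <- ifelse(nzchar(con),
                  paste(canon_multi(reports$suspect_drugs), con, sep = ";"),
                  canon_multi(reports$suspect_drugs))
  drugs_all <- canon_sorted(drugs)
  events_all <- canon_sorted(reports$events)
  paste(na_sentinel(reports$gender),
        na_sentinel(reports$age_years),
        na_sentinel(reports$region),
        na_sentinel(as.character(reports$event_date)),
        events_all,
        drugs_all,
        na_sentinel(norm_key(reports$indication)),
        sep = "\x1f")
}

#' Remove duplicate reports
#'
#' Spontaneous-reporting databases contain duplicate submissions of the same
#' case.  Reports are considered duplicates when they match exactly on seven
#' key fields: gender, age, region, event date, the adverse-event term set,
#' the full medication set (suspect plus concomitant, order-insensitive) and
#' the indication.  The report id is deliberately *not* part of the key.
#' Missing values participate as a distinct sentinel, so two reports that
#' both lack an age can still match.  Among duplicates, the first by input
#' order survives.  The operation is idempotent.
#'
#' @param reports validated ICSR data.frame.
#' @return the deduplicated data.frame; the number of removed rows is in
#'   attribute `"n_removed"`.
#' @export
deduplicate <- function(reports) {
  if (nrow(reports) == 0) {
    attr(reports, "n_removed") <- 0L
    return(reports)
  }
  keep <- !duplicated(dedup_key(reports))
  out <- reports[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "quarantine") <- attr(reports, "quarantine")
  attr(out, "n_removed") <- sum(!keep)
  out
}

normalize_drug_vector <- function(drugs, dictionary) {
  idx <- match(norm_key(drugs), norm_key(dictionary$synonym))
  out <- ifelse(is.na(idx), trimws(drugs), dictionary$generic[idx])
  cls <- ifelse(is.na(idx), "unclassified", dictionary$class[idx])
  list(names = out, classes = cls)
}

# vectorized field-level normalization: single-token rows (the common
# case) are mapped directly; only rows with ";" are split
normalize_drug_field <- function(x, dictionary) {
  x <- ifelse(is.na(x), "", x)
  names_out <- character(length(x))
  class_out <- character(length(x))
  multi <- grepl(";", x, fixed = TRUE)
  if (any(!multi)) {
    m <- normalize_drug_vector(x[!multi], dictionary)
    names_out[!multi] <- m$names
    class_out[!multi] <- m$classes
  }
  if (any(multi)) {
    toks <- strsplit(x[multi], ";", fixed = TRUE)
    mapped <- lapply(toks, function(v) {
      v <- trimws(v); v <- v[nzchar(v)]
      normalize_drug_vector(v, dictionary)
    })
    names_out[multi] <- vapply(mapped, function(m)
      paste(m$names, collapse = ";"), character(1))
    class_out[multi] <- vapply(mapped, function(m)
      paste(m$classes, collapse = ";"), character(1))
  }
  empty <- field_empty(x)
  names_out[empty] <- ""
  class_out[empty] <- ""
  list(names = names_out, classes = class_out)
}

#' Normalize drug names against a dictionary
#'
#' Replaces every recognized brand name or synonym by its generic name and
#' tags it with its drug class; unrecognized names are kept verbatim and
#' tagged `unclassified`.  Matching is case- and whitespace-insensitive.
#' Adds/overwrites a `suspect_classes` column (semicolon-separated, parallel
#' to `suspect_drugs`).  Never changes the report count.
#'
#' @param reports validated ICSR data.frame.
#' @param dictionary drug dictionary, see [default_drug_dictionary()].
#' @return the data.frame with normalized drug names and class tags.
#' @export
normalize_drugs <- function(reports, dictionary = default_drug_dictionary()) {
  dictionary <- validate_drug_dictionary(dictionary)
  sus <- normalize_drug_field(reports$suspect_drugs, dictionary)
  con <- normalize_drug_field(reports$concomitant_drugs, dictionary)
  reports$suspect_drugs <- sus$names
  reports$suspect_classes <- sus$classes
  reports$concomitant_drugs <- con$names
  reports
}

#' Select an analysis cohort by filters
#'
#' Returns exactly the reports satisfying the conjunction of the supplied
#' filters.  Supported filter keys: `cancer_type`, `drug` (generic name),
#' `class` (`"VEGFi"`/`"VEGFRi"`), `date_range` (length-2 Date vector on
#' `event_date`), `suspect_only` (logical; default `TRUE`, requiring the
#' target drug/class to appear among *suspect* drugs).  Unknown keys are
#' rejected.
#'
#' @param reports validated (normalized) ICSR data.frame.
#' @param ... named filters.
#' @return subset of `reports`.
#' @export
select_cohort <- function(reports, ...) {
  filters <- list(...)
  allowed <- c("cancer_type", "drug", "class", "date_range", "suspect_only")
  unknown <- setdiff(names(filters), allowed)
  if (length(unknown) > 0)
    stopf("unknown cohort filter key(s): %s", paste(unknown, collapse = ", "))
  suspect_only <- filters$suspect_only %||% TRUE

  keep <- rep(TRUE, nrow(reports))
  if (!is.null(filters$cancer_type))
    keep <- keep & reports$cancer_type %in% filters$cancer_type
  if (!is.null(filters$date_range)) {
    dr <- as.Date(filters$date_range)
    keep <- keep & !is.na(reports$event_date) &
      reports$event_date >= dr[1] & reports$event_date <= dr[2]
  }
  if (!is.null(filters$drug)) {
    hit <- has_any_term(reports$suspect_drugs, filters$drug)
    if (!suspect_only)
      hit <- hit | has_any_term(reports$concomitant_drugs, filters$drug)
    keep <- keep & hit
  }
  if (!is.null(filters$class)) {
    if (is.null(reports$suspect_classes))
      stopf("run normalize_drugs() before class filters")
    keep <- keep & has_any_term(reports$suspect_classes, filters$class,
                                lower = FALSE)
  }
  out <- reports[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write ICSR cohorts as CSV
#'
#' UTF-8 CSV with a header row and ISO-8601 dates; multi-valued fields are
#' semicolon-separated.
#'
#' @param path file path.
#' @param reports ICSR data.frame.
#' @return `read_icsr_csv` returns a raw data.frame ready for
#'   [ingest_reports()]; `write_icsr_csv` returns `path` invisibly.
#' @export
read_icsr_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  fileEncoding = "UTF-8")
}

#' @rdname read_icsr_csv
#' @export
write_icsr_csv <- function(reports, path) {
  df <- reports
  for (col in c("event_date", "therapy_start", "event_onset"))
    if (col %in% names(df)) df[[col]] <- as.character(df[[col]])
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
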
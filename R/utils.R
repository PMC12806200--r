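`%||%` <- function(x, y) if (is.null(x)) y else x

#' Split a delimited multi-value field into a character vector
#'
#' ICSR tables store multi-valued fields (drugs, adverse-event terms) as a
#' single semicolon-separated string so that cohorts round-trip through CSV.
#'
#' @param x character vector of delimited strings.
#' @param sep field separator, default `";"`.
#' @return list of character vectors (empty strings drop out).
#' @keywords internal
split_terms <- function(x, sep = ";") {
  out <- strsplit(ifelse(is.na(x), "", x), sep, fixed = TRUE)
  lapply(out, function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

join_terms <- function(x, sep = ";") {
  vapply(x, function(v) paste(v, collapse = sep), character(1))
}

# canonical form used for case/whitespace-insensitive matching
norm_key <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

# canonicalize a ";"-joined multi-value field without splitting it
canon_multi <- function(x, lower = TRUE) {
  x <- ifelse(is.na(x), "", x)
  if (lower) x <- tolower(x)
  x <- gsub("[[:space:]]+", " ", trimws(x))
  gsub(" *; *", ";", x)
}

# does any token of the ";"-joined field equal any of `terms`? (vectorized)
pad_multi <- function(x, lower = TRUE) paste0(";", canon_multi(x, lower), ";")

match_pad <- function(pad, terms, lower = TRUE) {
  if (lower) terms <- norm_key(terms)
  hit <- rep(FALSE, length(pad))
  for (t in terms)
    hit <- hit | grepl(paste0(";", t, ";"), pad, fixed = TRUE)
  hit
}

has_any_term <- function(x, terms, lower = TRUE) {
  match_pad(pad_multi(x, lower), terms, lower)
}

# TRUE where the multi-value field has no tokens at all
field_empty <- function(x) {
  !grepl("[^;[:space:]]", ifelse(is.na(x), "", x))
}

# sorted canonical multiset form of a multi-value field (for dedup keys);
# one- and two-token rows (the overwhelmingly common cases) avoid the
# per-row split/sort
canon_sorted <- function(x, lower = TRUE) {
  out <- canon_multi(x, lower)
  nsep <- nchar(out) - nchar(gsub(";", "", out, fixed = TRUE))
  two <- nsep == 1
  if (any(two)) {
    first <- sub(";.*", "", out[two])
    second <- sub(".*;", "", out[two])
    swap <- first > second
    out[two] <- ifelse(swap, paste(second, first, sep = ";"), out[two])
  }
  many <- nsep > 1
  if (any(many)) {
    out[many] <- vapply(strsplit(out[many], ";", fixed = TRUE),
                        function(v) paste(sort(v), collapse = ";"),
                        character(1))
  }
  out
}

# missing values participate in dedup keys as a distinct sentinel
na_sentinel <- function(x, sentinel = "\x01NA") {
  x <- as.character(x)
  x[is.na(x)] <- sentinel
  x
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}
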
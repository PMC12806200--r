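#' Bundled VEGF/VEGFR-inhibitor drug dictionary
#'
#' Maps brand names and synonyms to generic drug names and to the two study
#' drug classes: `VEGFi` (ligand-binding VEGF inhibitors) and `VEGFRi`
#' (receptor tyrosine-kinase / receptor-targeting inhibitors).  The default
#' dictionary covers the six VEGF inhibitors (bevacizumab, ranibizumab,
#' brolucizumab, aflibercept, conbercept, pegaptanib) and sixteen VEGFR
#' inhibitors (ramucirumab, nintedanib, apatinib, axitinib, sunitinib,
#' sorafenib, regorafenib, vandetanib, cabozantinib, pazopanib, lenvatinib,
#' anlotinib, fruquintinib, tivozanib, cediranib, brivanib) together with
#' common brand names.  Matching is case- and whitespace-insensitive.
#'
#' @return data.frame with columns `synonym`, `generic`, `class`.
#' @seealso [normalize_drugs()], [drug_class()]
#' @export
#' @examples
#' dict <- default_drug_dictionary()
#' subset(dict, generic == "bevacizumab")
default_drug_dictionary <- function() {
  vegfi <- c("bevacizumab", "ranibizumab", "brolucizumab", "aflibercept",
             "conbercept", "pegaptanib")
  vegfri <- c("ramucirumab", "nintedanib", "apatinib", "axitinib",
              "sunitinib", "sorafenib", "regorafenib", "vandetanib",
              "cabozantinib", "pazopanib", "lenvatinib", "anlotinib",
              "fruquintinib", "tivozanib", "cediranib", "brivanib")
  brands <- c(
    avastin    = "bevacizumab",
    lucentis   = "ranibizumab",
    beovu      = "brolucizumab",
    eylea      = "aflibercept",
    zaltrap    = "aflibercept",
    macugen    = "pegaptanib",
    cyramza    = "ramucirumab",
    ofev       = "nintedanib",
    vargatef   = "nintedanib",
    inlyta     = "axitinib",
    sutent     = "sunitinib",
    nexavar    = "sorafenib",
    stivarga   = "regorafenib",
    caprelsa   = "vandetanib",
    cabometyx  = "cabozantinib",
    cometriq   = "cabozantinib",
    votrient   = "pazopanib",
    lenvima    = "lenvatinib",
    fotivda    = "tivozanib"
  )
  generic <- c(vegfi, vegfri, unname(brands))
  synonym <- c(vegfi, vegfri, names(brands))
  cls <- ifelse(generic %in% vegfi, "VEGFi", "VEGFRi")
  data.frame(synonym = synonym, generic = generic, class = cls,
             stringsAsFactors = FALSE)
}

validate_drug_dictionary <- function(dictionary) {
  need <- c("synonym", "generic", "class")
  if (!is.data.frame(dictionary) || !all(need %in% names(dictionary)))
    stopf("drug dictionary needs columns: %s", paste(need, collapse = ", "))
  if (!all(dictionary$class %in% c("VEGFi", "VEGFRi")))
    stopf("drug dictionary classes must be 'VEGFi' or 'VEGFRi'")
  key <- norm_key(dictionary$synonym)
  if (anyDuplicated(key))
    stopf("drug dictionary synonyms must be unique (case-insensitive)")
  dictionary
}

#' Look up the study class of drug names
#'
#' @param drugs character vector of drug names (generic or brand).
#' @param dictionary a drug dictionary, see [default_drug_dictionary()].
#' @return character vector: `"VEGFi"`, `"VEGFRi"` or `"unclassified"`.
#' @export
drug_class <- function(drugs, dictionary = default_drug_dictionary()) {
  dictionary <- validate_drug_dictionary(dictionary)
  idx <- match(norm_key(drugs), norm_key(dictionary$synonym))
  out <- dictionary$class[idx]
  out[is.na(out)] <- "unclassified"
  out
}

#' Construct an adverse-event set
#'
#' An event set is a named collection of preferred terms; matching against
#' report event lists is case-insensitive.
#'
#' @param name label for the set.
#' @param terms non-empty character vector of preferred terms.
#' @return object of class `event_set`.
#' @export
event_set <- function(name, terms) {
  terms <- unique(trimws(as.character(terms)))
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0) stopf("event set '%s' has no terms", name)
  structure(list(name = name, terms = terms), class = "event_set")
}

#' The bundled TMA event set
#'
#' The six preferred terms on the thrombotic-microangiopathy spectrum used
#' throughout the package: TMA itself, thrombotic thrombocytopenic purpura,
#' haemolytic uraemic syndrome and its atypical form, microangiopathic
#' haemolytic anaemia, and renal-limited TMA.
#'
#' @return an [event_set()].
#' @export
tma_event_set <- function() {
  event_set("TMA", c(
    "thrombotic microangiopathy",
    "thrombotic thrombocytopenic purpura",
    "haemolytic uraemic syndrome",
    "atypical haemolytic uraemic syndrome",
    "microangiopathic haemolytic anaemia",
    "renal thrombotic microangiopathy"
  ))
}

#' Bundled indication-to-cancer-type lookup
#'
#' Maps free-text cancer indications to the thirteen per-cancer strata used
#' in stratified scans (TCGA-style codes).  Unmapped indications fall into
#' `"other"`.  The table is an ordinary data.frame and can be edited or
#' replaced by the caller.
#'
#' @return data.frame with columns `pattern` (lower-case substring matched
#'   against the indication) and `code`.
#' @export
default_cancer_lookup <- function() {
  data.frame(
    pattern = c("endometrial", "ovarian", "gastric", "glioblastoma",
                "breast", "renal cell", "colon", "rectal", "hepatocellular",
                "lung squamous", "lung adeno", "sarcoma", "thyroid"),
    code = c("UCEC", "OV", "STAD", "GBM", "BRCA", "KIRC", "COAD", "READ",
             "LIHC", "LUSC", "LUAD", "SARC", "THCA"),
    stringsAsFactors = FALSE
  )
}

map_cancer_type <- function(indication, lookup = default_cancer_lookup()) {
  ind <- norm_key(indication)
  out <- rep("other", length(ind))
  for (i in seq_len(nrow(lookup))) {
    hit <- grepl(lookup$pattern[i], ind, fixed = TRUE)
    out[hit & out == "other"] <- lookup$code[i]
  }
  out[is.na(indication) | !nzchar(trimws(ifelse(is.na(indication), "",
                                                indication)))] <- "other"
  out
}

#' Default age bands
#'
#' Half-open bands `[lo, hi)`: 0-44, 45-64, 65-74, 75+.
#' @return numeric vector of left endpoints plus Inf, with band labels.
#' @keywords internal
default_age_breaks <- function() c(0, 45, 65, 75, Inf)

default_age_labels <- function() c("0-44", "45-64", "65-74", "75+")

age_band <- function(age_years, breaks = default_age_breaks(),
                     labels = default_age_labels()) {
  as.character(cut(age_years, breaks = breaks, labels = labels,
                   right = FALSE, include.lowest = TRUE))
}
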
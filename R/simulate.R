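#' Default drug catalog for the report simulator
#'
#' The 22 study drugs (6 VEGFi, 16 VEGFRi) plus ten common cytotoxic
#' oncology drugs as the `other` background, with sampling weights chosen
#' so that roughly 10% of reports involve a study drug — the order of
#' magnitude seen in large oncology report universes.
#'
#' @return data.frame with columns `drug`, `class`, `weight`.
#' @export
default_drug_catalog <- function() {
  dict <- default_drug_dictionary()
  study <- unique(dict[, c("generic", "class")])
  names(study) <- c("drug", "class")
  study$weight <- ifelse(study$class == "VEGFi", 0.6, 0.4)
  other <- data.frame(
    drug = c("cisplatin", "carboplatin", "oxaliplatin", "paclitaxel",
             "docetaxel", "doxorubicin", "gemcitabine", "capecitabine",
             "etoposide", "irinotecan"),
    class = "other", weight = 9, stringsAsFactors = FALSE)
  rbind(study, other)
}

default_demographic_mix <- function() {
  list(
    gender = c(female = 0.525, male = 0.398, unknown = 0.077),
    age_band = c("0-44" = 0.20, "45-64" = 0.40, "65-74" = 0.25,
                 "75+" = 0.15),
    region = c(Americas = 0.55, Europe = 0.25, Asia = 0.12, other = 0.05,
               unknown = 0.03),
    cancer = c(KIRC = 0.15, COAD = 0.15, OV = 0.12, BRCA = 0.10,
               LUAD = 0.08, STAD = 0.06, LUSC = 0.05, READ = 0.05,
               LIHC = 0.05, GBM = 0.04, UCEC = 0.04, THCA = 0.03,
               SARC = 0.03, other = 0.05),
    outcome = c(fatal = 0.1, nonfatal = 0.7, unknown = 0.2)
  )
}

#' Configuration for the synthetic ICSR cohort generator
#'
#' Defines a report universe with planted drug/event association strengths.
#' For a drug with planted relative reporting ratio `r`, the probability
#' that one of its reports carries a TMA-spectrum event is
#' `r * background_event_rate` (an error is raised if any such probability
#' exceeds one).  Default planted ratios put the VEGF-inhibitor class at
#' ratio 5 and the VEGFR-inhibitor class at 1.2, echoing the relative
#' signal strengths reported for the two classes in large pharmacovigilance
#' databases; time-to-onset is log-normal per class with medians 201 days
#' (VEGFi), 35 days (VEGFRi) and 60 days (other).
#'
#' @param n_reports number of reports (including injected duplicates).
#' @param drug_catalog data.frame `drug, class, weight`.
#' @param background_event_rate baseline per-report TMA probability.
#' @param planted_associations named numeric vector of relative reporting
#'   ratios per drug; drugs absent default to 1 for `other` drugs and to
#'   the class default (`VEGFi` 5, `VEGFRi` 1.2).  Pass ratios explicitly
#'   (including `1`) to override.
#' @param tto_days named list per class: `c(median = ..., sdlog = ...)`.
#' @param demographic_mix category probabilities, see
#'   `default_demographic_mix()`.
#' @param duplicate_fraction fraction of records that are exact copies of
#'   earlier records on all deduplication key fields (must be < 1).
#' @param seed integer seed.
#' @return object of class `icsr_sim_config`.
#' @export
icsr_sim_config <- function(n_reports = 200000,
                            drug_catalog = default_drug_catalog(),
                            background_event_rate = 0.002,
                            planted_associations = NULL,
                            tto_days = list(
                              VEGFi = c(median = 201, sdlog = 1.3),
                              VEGFRi = c(median = 35, sdlog = 0.9),
                              other = c(median = 60, sdlog = 1.0)),
                            demographic_mix = default_demographic_mix(),
                            duplicate_fraction = 0.02,
                            seed = 1L) {
  if (!is_count(n_reports)) stopf("n_reports must be a positive integer")
  if (!is_prob(background_event_rate) || background_event_rate <= 0 ||
      background_event_rate >= 1)
    stopf("background_event_rate must be in (0, 1)")
  if (!is_prob(duplicate_fraction) || duplicate_fraction >= 1)
    stopf("duplicate_fraction must be in [0, 1)")
  if (!all(c("drug", "class", "weight") %in% names(drug_catalog)))
    stopf("drug_catalog needs columns drug, class, weight")

  ratios <- stats::setNames(
    ifelse(drug_catalog$class == "VEGFi", 5,
           ifelse(drug_catalog$class == "VEGFRi", 1.2, 1)),
    drug_catalog$drug)
  if (!is.null(planted_associations)) {
    if (is.null(names(planted_associations)))
      stopf("planted_associations must be named by drug")
    unknown <- setdiff(names(planted_associations), drug_catalog$drug)
    if (length(unknown) > 0)
      stopf("planted drugs not in catalog: %s",
            paste(unknown, collapse = ", "))
    if (any(!is.finite(planted_associations) | planted_associations < 0))
      stopf("planted ratios must be finite and >= 0")
    ratios[names(planted_associations)] <- planted_associations
  }
  p_event <- ratios * background_event_rate
  if (any(p_event > 1))
    stopf("planted ratio x background rate exceeds 1 for: %s",
          paste(names(p_event)[p_event > 1], collapse = ", "))

  structure(list(n_reports = as.integer(n_reports),
                 drug_catalog = drug_catalog,
                 background_event_rate = background_event_rate,
                 planted_associations = ratios,
                 event_prob = p_event,
                 tto_days = tto_days,
                 demographic_mix = demographic_mix,
                 duplicate_fraction = duplicate_fraction,
                 seed = as.integer(seed)),
            class = "icsr_sim_config")
}

sample_cat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

band_to_age <- function(band) {
  lo <- c("0-44" = 18, "45-64" = 45, "65-74" = 65, "75+" = 75)
  hi <- c("0-44" = 44.999, "45-64" = 64.999, "65-74" = 74.999, "75+" = 90)
  stats::runif(length(band), lo[band], hi[band])
}

#' Generate a synthetic ICSR cohort
#'
#' Draws `n_reports` spontaneous reports from the configured report
#' universe: one suspect drug per report, demographics from the configured
#' mix, a TMA-spectrum event with probability `ratio x background rate`
#' given the drug, therapy-start and onset dates consistent with the
#' drug class's log-normal time-to-onset distribution, and a configured
#' fraction of exact duplicate records (copies of earlier records on all
#' seven deduplication key fields, under fresh report ids).  Identical seed
#' and config give byte-identical output.  Ground truth (planted ratios,
#' per-drug event probabilities, injected duplicate ids) is recorded in the
#' `"ground_truth"` attribute for recovery tests (see [ground_truth()]).
#'
#' @param config an [icsr_sim_config()].
#' @return raw ICSR data.frame ready for [ingest_reports()].
#' @export
generate_icsr_cohort <- function(config) {
  stopifnot(inherits(config, "icsr_sim_config"))
  set.seed(config$seed)
  n_dup <- round(config$duplicate_fraction * config$n_reports)
  n <- config$n_reports - n_dup
  cat <- config$drug_catalog
  mix <- config$demographic_mix

  di <- sample.int(nrow(cat), n, replace = TRUE, prob = cat$weight)
  drug <- cat$drug[di]
  cls <- cat$class[di]
  p_event <- unname(config$event_prob[drug])
  has_event <- stats::runif(n) < p_event

  tma_terms <- tma_event_set()$terms
  generic_terms <- c("nausea", "hypertension", "proteinuria", "fatigue",
                     "diarrhoea", "rash", "anaemia", "pyrexia", "headache",
                     "vomiting")
  events <- sample(generic_terms, n, replace = TRUE)
  extra <- stats::runif(n) < 0.25
  events[extra] <- paste(events[extra],
                         sample(generic_terms, sum(extra), replace = TRUE),
                         sep = ";")
  events[has_event] <- sample(tma_terms, sum(has_event), replace = TRUE)

  band <- sample_cat(n, mix$age_band)
  cancer_code <- sample_cat(n, mix$cancer)
  indication_text <- c(
    UCEC = "endometrial carcinoma", OV = "ovarian cancer",
    STAD = "gastric adenocarcinoma", GBM = "glioblastoma multiforme",
    BRCA = "invasive breast cancer", KIRC = "renal cell carcinoma",
    COAD = "colon adenocarcinoma", READ = "rectal adenocarcinoma",
    LIHC = "hepatocellular carcinoma", LUSC = "lung squamous cell carcinoma",
    LUAD = "lung adenocarcinoma", SARC = "soft tissue sarcoma",
    THCA = "thyroid cancer", other = "malignant neoplasm")

  start <- as.Date("2013-01-01") +
    sample.int(3650, n, replace = TRUE) - 1
  tto_par <- config$tto_days
  med <- vapply(cls, function(k) tto_par[[k]][["median"]], numeric(1))
  sdl <- vapply(cls, function(k) tto_par[[k]][["sdlog"]], numeric(1))
  tto <- pmax(1, round(stats::rlnorm(n, meanlog = log(med), sdlog = sdl)))
  tto[!has_event] <- pmax(1, round(stats::rlnorm(
    sum(!has_event), meanlog = log(45), sdlog = 1)))
  onset <- start + tto
  report_date <- onset + sample.int(31, n, replace = TRUE) - 1

  df <- data.frame(
    report_id = sprintf("R%07d", seq_len(n)),
    gender = sample_cat(n, mix$gender),
    age_years = round(band_to_age(band), 1),
    region = sample_cat(n, mix$region),
    event_date = report_date,
    suspect_drugs = drug,
    concomitant_drugs = "",
    indication = unname(indication_text[cancer_code]),
    events = events,
    outcome = sample_cat(n, mix$outcome),
    therapy_start = start,
    event_onset = onset,
    stringsAsFactors = FALSE)

  dup_ids <- character(0)
  if (n_dup > 0) {
    src <- sample.int(n, n_dup, replace = TRUE)
    dup <- df[src, , drop = FALSE]
    dup$report_id <- sprintf("D%07d", seq_len(n_dup))
    dup_ids <- dup$report_id
    df <- rbind(df, dup)
    rownames(df) <- NULL
  }
  attr(df, "ground_truth") <- list(
    planted_associations = config$planted_associations,
    event_prob = config$event_prob,
    background_event_rate = config$background_event_rate,
    duplicate_report_ids = dup_ids,
    n_duplicates = n_dup,
    seed = config$seed)
  df
}

#' Configuration for the synthetic biochemistry cohort
#'
#' Paired pre/post panels of the five study markers.  Default means are the
#' published pre/post means from a 1698-patient VEGF(R)i-treated cohort
#' (platelet 233.4 -> 171.1 x10^9/L, creatinine 76.4 -> 76.7 umol/L,
#' indirect bilirubin 6.9 -> 7.9 umol/L, RBC 3.9 -> 3.8 x10^12/L, MCV
#' 90.19 -> 91.3 fL); dispersions are typical clinical SDs.  Each marker is
#' bivariate normal across timepoints on the natural scale (correlation
#' `pre_post_correlation`), truncated at a small positive physiologic
#' floor.  On top of this, a configurable fraction of patients at each
#' timepoint is drawn from the TTP region (platelet < 30 x10^9/L,
#' creatinine < 199 umol/L), defaults 1.18% pre and 3.77% post.
#'
#' @param n_patients number of patients (default 1698).
#' @param pre_means,pre_sds,post_means,post_sds named numeric vectors over
#'   the five markers.
#' @param pre_post_correlation within-marker correlation across timepoints.
#' @param ttp_fraction_pre,ttp_fraction_post expected fraction of panels in
#'   the TTP region at each timepoint.
#' @param seed integer seed.
#' @return object of class `biochem_sim_config`.
#' @export
biochem_sim_config <- function(n_patients = 1698,
                               pre_means = c(platelet = 233.4,
                                             creatinine = 76.4,
                                             indirect_bilirubin = 6.9,
                                             rbc = 3.9, mcv = 90.19),
                               pre_sds = c(platelet = 75, creatinine = 25,
                                           indirect_bilirubin = 4,
                                           rbc = 0.5, mcv = 5),
                               post_means = c(platelet = 171.1,
                                              creatinine = 76.7,
                                              indirect_bilirubin = 7.9,
                                              rbc = 3.8, mcv = 91.3),
                               post_sds = c(platelet = 70, creatinine = 25,
                                            indirect_bilirubin = 4.5,
                                            rbc = 0.5, mcv = 5),
                               pre_post_correlation = 0.6,
                               ttp_fraction_pre = 0.0118,
                               ttp_fraction_post = 0.0377,
                               seed = 1L) {
  m <- marker_names()
  for (v in list(pre_means, pre_sds, post_means, post_sds))
    if (!identical(sort(names(v)), sort(m)))
      stopf("marker vectors must be named exactly: %s",
            paste(m, collapse = ", "))
  if (any(pre_sds <= 0) || any(post_sds <= 0))
    stopf("marker SDs must be positive")
  if (!is_prob(pre_post_correlation) || pre_post_correlation >= 1)
    stopf("pre_post_correlation must be in [0, 1)")
  if (!is_prob(ttp_fraction_pre) || !is_prob(ttp_fraction_post))
    stopf("TTP fractions must be probabilities")
  if (!is_count(n_patients)) stopf("n_patients must be a positive integer")
  structure(list(n_patients = as.integer(n_patients),
                 pre_means = pre_means[m], pre_sds = pre_sds[m],
                 post_means = post_means[m], post_sds = post_sds[m],
                 pre_post_correlation = pre_post_correlation,
                 ttp_fraction_pre = ttp_fraction_pre,
                 ttp_fraction_post = ttp_fraction_post,
                 seed = as.integer(seed)),
            class = "biochem_sim_config")
}

#' Generate a synthetic paired biochemistry cohort
#'
#' @param config a [biochem_sim_config()].
#' @return long data.frame, one row per patient-timepoint: `patient_id`,
#'   `timepoint` (`pre`/`post`) and the five marker columns, with planted
#'   TTP patient indices in the `"ground_truth"` attribute.
#' @export
generate_biochem_cohort <- function(config) {
  stopifnot(inherits(config, "biochem_sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  rho <- config$pre_post_correlation
  m <- marker_names()
  pre <- post <- matrix(NA_real_, n, length(m), dimnames = list(NULL, m))
  for (k in m) {
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    pre[, k] <- config$pre_means[[k]] + config$pre_sds[[k]] * z1
    post[, k] <- config$post_means[[k]] +
      config$post_sds[[k]] * (rho * z1 + sqrt(1 - rho^2) * z2)
    floor_k <- 0.02 * config$pre_means[[k]]
    pre[, k] <- pmax(pre[, k], floor_k)
    post[, k] <- pmax(post[, k], floor_k)
  }
  # the configured fraction is the *total* expected fraction of panels in
  # the TTP region: naturally-flagged panels in excess of the target are
  # displaced just above the platelet threshold (mirrored), and any
  # shortfall is planted into the region
  plant <- function(mat, frac) {
    nat <- which(mat[, "platelet"] < 30 & mat[, "creatinine"] < 199)
    k_target <- stats::rbinom(1, n, frac)
    if (length(nat) > k_target) {
      out_idx <- sample(nat, length(nat) - k_target)
      mat[out_idx, "platelet"] <- 60 - mat[out_idx, "platelet"]
      idx <- setdiff(nat, out_idx)
    } else {
      k_extra <- k_target - length(nat)
      pool <- setdiff(seq_len(n), nat)
      add <- if (k_extra > 0) sample(pool, k_extra) else integer(0)
      mat[add, "platelet"] <- stats::runif(length(add), 8, 29.5)
      mat[add, "creatinine"] <- stats::runif(length(add), 40, 190)
      idx <- c(nat, add)
    }
    list(mat = mat, idx = sort(idx))
  }
  pp <- plant(pre, config$ttp_fraction_pre)
  qq <- plant(post, config$ttp_fraction_post)
  pre <- pp$mat; post <- qq$mat

  ids <- sprintf("P%05d", seq_len(n))
  out <- rbind(
    data.frame(patient_id = ids, timepoint = "pre", pre,
               stringsAsFactors = FALSE),
    data.frame(patient_id = ids, timepoint = "post", post,
               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "ground_truth") <- list(
    ttp_planted_pre = pp$idx, ttp_planted_post = qq$idx,
    seed = config$seed)
  out
}

#' Configuration for the synthetic two-group expression experiment
#'
#' Emulates a small two-group RNA-seq design (defaults: 6 treated vs 6
#' control samples, 1000 genes, 20 gene sets of 50 genes) with log-normal
#' expression and planted mean log-scale shifts on selected sets in the
#' treated group.  The default plants a single down-shifted
#' `VEGF_SIGNALING` set (shift -1.5), mirroring suppressed VEGF signalling
#' under a ligand-binding inhibitor.
#'
#' @param n_genes,n_samples_per_group positive integers.
#' @param gene_sets named list of gene-id vectors, or `NULL` to draw
#'   `n_sets` random sets of `set_size` genes.
#' @param planted_sets named numeric vector: mean log-scale shift applied
#'   to member genes in the treated group.  Names must be gene-set names.
#' @param dispersion log-scale SD of expression noise.
#' @param n_sets,set_size used only when `gene_sets` is `NULL`.
#' @param seed integer seed.
#' @return object of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_genes = 1000, n_samples_per_group = 6,
                                  gene_sets = NULL,
                                  planted_sets = c(VEGF_SIGNALING = -1.5),
                                  dispersion = 1, n_sets = 20,
                                  set_size = 50, seed = 1L) {
  if (!is_count(n_genes) || !is_count(n_samples_per_group))
    stopf("n_genes and n_samples_per_group must be positive integers")
  if (dispersion <= 0) stopf("dispersion must be positive")
  genes <- sprintf("g%04d", seq_len(n_genes))
  if (is.null(gene_sets)) {
    set.seed(seed)  # set membership is part of the design, hence seeded too
    nm <- c(names(planted_sets),
            sprintf("RANDOM_SET_%02d",
                    seq_len(max(0, n_sets - length(planted_sets)))))
    gene_sets <- stats::setNames(
      lapply(nm, function(i) sample(genes, min(set_size, n_genes))), nm)
  }
  if (any(lengths(gene_sets) == 0)) stopf("gene sets must be non-empty")
  bad <- setdiff(names(planted_sets), names(gene_sets))
  if (length(bad) > 0)
    stopf("planted sets not in collection: %s", paste(bad, collapse = ", "))
  structure(list(n_genes = as.integer(n_genes),
                 n_samples_per_group = as.integer(n_samples_per_group),
                 genes = genes, gene_sets = gene_sets,
                 planted_sets = planted_sets, dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' Generate a synthetic two-group expression experiment
#'
#' @param config an [expression_sim_config()].
#' @return list with `expr` (non-negative genes x samples matrix),
#'   `groups` (`control`/`treated`), `gene_sets`, and planted truth in the
#'   `"ground_truth"` attribute of `expr`.
#' @export
generate_expression_experiment <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  m <- config$n_samples_per_group
  mu <- stats::runif(n, log(10), log(1000))
  shift <- numeric(n)
  for (nm in names(config$planted_sets)) {
    idx <- match(config$gene_sets[[nm]], config$genes)
    shift[idx] <- shift[idx] + config$planted_sets[[nm]]
  }
  groups <- rep(c("control", "treated"), each = m)
  expr <- matrix(NA_real_, n, 2 * m,
                 dimnames = list(config$genes,
                                 paste0(rep(c("ctrl_", "trt_"), each = m),
                                        seq_len(m))))
  for (j in seq_len(2 * m)) {
    mlog <- if (groups[j] == "treated") mu + shift else mu
    expr[, j] <- stats::rlnorm(n, meanlog = mlog, sdlog = config$dispersion)
  }
  attr(expr, "ground_truth") <- list(
    planted_sets = config$planted_sets, shift_per_gene = shift,
    seed = config$seed)
  list(expr = expr, groups = groups, gene_sets = config$gene_sets)
}

#' Generate a per-cancer pathway-score / ROR dataset with planted rank
#' correlation
#'
#' Stands in for pairing per-cancer pathway activity summaries with
#' per-cancer reporting odds ratios.  The designated pathway is coupled to
#' the (log) ROR through a Gaussian copula whose Pearson parameter
#' `2*sin(pi*rho/6)` yields population Spearman correlation `rho`; at
#' `|rho| = 1` the coupling is exactly monotone, so the sample Spearman
#' correlation is exactly +/-1.  All other pathways are independent noise.
#'
#' @param n_cancers number of cancer types (>= 4; default 13).
#' @param n_pathways number of pathways (default 5; the first is planted).
#' @param planted_rho target Spearman correlation, in `[-1, 1]`.
#' @param seed integer seed.
#' @param planted_pathway name of the coupled pathway.
#' @return list with `scores` (pathways x cancers), `ror` (named vector)
#'   and `truth`.
#' @export
generate_pathway_ror_dataset <- function(n_cancers = 13, n_pathways = 5,
                                         planted_rho = 0.8, seed = 1L,
                                         planted_pathway = "PLATELET_ACTIVATION") {
  if (!is_count(n_cancers) || n_cancers < 4) stopf("n_cancers must be >= 4")
  if (!is.finite(planted_rho) || abs(planted_rho) > 1)
    stopf("|planted_rho| must be <= 1")
  set.seed(seed)
  cancers <- c("UCEC", "OV", "STAD", "GBM", "BRCA", "KIRC", "COAD", "READ",
               "LIHC", "LUSC", "LUAD", "SARC", "THCA")
  if (n_cancers <= length(cancers)) cancers <- cancers[seq_len(n_cancers)]
  else cancers <- c(cancers, sprintf("C%02d",
                                     seq_len(n_cancers - length(cancers))))
  u <- stats::rnorm(n_cancers)
  ror <- stats::setNames(exp(0.5 * u), cancers)
  if (abs(planted_rho) == 1) {
    v <- sign(planted_rho) * u
  } else {
    r <- 2 * sin(pi * planted_rho / 6)
    v <- r * u + sqrt(1 - r^2) * stats::rnorm(n_cancers)
  }
  pw <- c(planted_pathway,
          sprintf("NULL_PATHWAY_%02d", seq_len(max(0, n_pathways - 1))))
  scores <- matrix(stats::rnorm(n_pathways * n_cancers, 0.5, 0.1),
                   n_pathways, n_cancers, dimnames = list(pw, cancers))
  scores[1, ] <- 0.5 + 0.1 * v
  list(scores = scores, ror = ror,
       truth = list(planted_pathway = planted_pathway,
                    planted_rho = planted_rho, seed = seed))
}

#' Ground truth recorded by a synthetic generator
#'
#' @param x object returned by a generator (or its `expr` element).
#' @return the recorded ground-truth list, or `NULL`.
#' @export
ground_truth <- function(x) attr(x, "ground_truth", exact = TRUE)
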
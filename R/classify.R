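#' Genes in which causal variants define monogenic FH
#' @return Character vector `c("LDLR", "APOB", "PCSK9")`.
#' @export
fh_genes <- function() c("LDLR", "APOB", "PCSK9")

#' The 24-gene lipid-disorder sequencing panel
#' @return Character vector of gene symbols.
#' @export
panel_genes_24 <- function() {
  c("ABCA1", "ABCG5", "ABCG8", "ANGPTL3", "APOA1", "APOA5", "APOB",
    "APOC2", "APOC3", "APOE", "CETP", "GPD1", "GPIHBP1", "LCAT", "LDLR",
    "LDLRAP1", "LIPC", "LIPI", "LMF1", "LPL", "PCSK9", "SAR1B", "STAP1",
    "USF1")
}

.split_field <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ",")[[1]]
}

#' Harmonize lipid measurements for classification
#'
#' Adds three columns to a participant table: `atorva_equiv` (equivalent
#' atorvastatin dose, 0 for non-users), `statin_user` (the duration-based
#' predicate) and `ldl_pretreat` (LDL-C back-corrected to the estimated
#' pretreatment level for statin users; identical to `ldl_c` otherwise).
#' HDL-C and TG are never recalculated.
#'
#' @param participants Participant data.frame (see [generate_cohort()] for
#'   the column contract).
#' @param equivalence,reduction Statin tables (defaults shipped).
#' @return The input with the harmonization columns appended.
#' @export
harmonize_lipids <- function(participants,
                             equivalence = statin_equivalence_table(),
                             reduction = statin_reduction_table()) {
  n <- nrow(participants)
  usr <- statin_user(participants$statin_months_pre_us,
                     participants$statin_months_hist)
  eq <- numeric(n)
  for (i in seq_len(n)) {
    if (usr[i] && !is.na(participants$statin_drug[i])) {
      eq[i] <- atorvastatin_equivalent(participants$statin_drug[i],
                                       participants$statin_dose[i],
                                       equivalence)
    }
  }
  participants$statin_user <- usr
  participants$atorva_equiv <- eq
  participants$ldl_pretreat <- pretreatment_ldl(participants$ldl_c, eq,
                                                reduction)
  participants
}

#' Assign one participant to a study group
#'
#' Applies the rule cascade, exclusions first:
#' \enumerate{
#'   \item `EXCLUDED` -- a pathogenic/likely-pathogenic (P/LP) variant in a
#'     panel gene outside LDLR/APOB/PCSK9/APOE; or an FH-gene P/LP variant
#'     co-occurring with the e2e2 haplotype; or two or more P/LP variants
#'     across LDLR/APOB/PCSK9/APOE.
#'   \item `FD` -- e2e2 haplotype and TG >= 1.5 mmol/L.
#'   \item `FH` -- P/LP variant in LDLR/APOB/PCSK9 and DLCN score >= 9.
#'   \item `POLY_HCL` -- pretreatment LDL-C > 4.9 mmol/L, HIGH LDL-C PRS
#'     band, no tendon xanthomas.
#'   \item `SEVERE_HCL` -- pretreatment LDL-C > 4.9 mmol/L, LOW band, no
#'     tendon xanthomas.
#'   \item `CONTROL` -- no causal panel variant, LOW band, LDL-C < 3.0 and
#'     TG < 1.5 mmol/L.
#'   \item `UNCLASSIFIED` otherwise (or when required inputs are missing).
#' }
#' TG is always the measured value (never back-corrected); LDL-C is the
#' harmonized pretreatment value.
#'
#' @param p One participant: a one-row data.frame or named list carrying at
#'   least `apoe`, `tg`, `ldl_pretreat`, `prs_ldl_band`,
#'   `tendon_xanthomas`, `causal_genes`, `causal_classes`, and the DLCN
#'   inputs (`sex`, `chd`, `chd_onset_age`).
#' @param thresholds [class_thresholds()].
#' @param criteria DLCN table, default [dlcn_criteria_table()].
#' @return List with `group`, `reasons` (character vector of evaluated
#'   predicates on the winning rule) and `dlcn` (points, NA if not
#'   computed).
#' @export
assign_group <- function(p, thresholds = class_thresholds(),
                         criteria = dlcn_criteria_table()) {
  if (is.data.frame(p)) {
    stopifnot(nrow(p) == 1L)
    p <- as.list(p)
  }
  need <- c("apoe", "tg", "ldl_pretreat", "prs_ldl_band",
            "tendon_xanthomas", "causal_genes", "causal_classes")
  absent <- setdiff(need, names(p))
  if (length(absent)) {
    return(list(group = "UNCLASSIFIED",
                reasons = paste0("insufficient data: missing ",
                                 paste(absent, collapse = ",")),
                dlcn = NA_integer_))
  }

  genes <- .split_field(p$causal_genes)
  classes <- .split_field(p$causal_classes)
  if (length(genes) != length(classes)) {
    stop("causal_genes and causal_classes must be parallel lists")
  }
  plp_genes <- genes[classes %in% c("P", "LP")]
  fh_set <- fh_genes()
  combo_set <- c(fh_set, "APOE")

  # (1) exclusions
  if (length(setdiff(plp_genes, combo_set))) {
    return(list(group = "EXCLUDED",
                reasons = paste0("plp_outside_fh_genes:",
                                 paste(setdiff(plp_genes, combo_set),
                                       collapse = ",")),
                dlcn = NA_integer_))
  }
  is_e2e2 <- identical(p$apoe, "e2e2")
  if (any(plp_genes %in% fh_set) && isTRUE(is_e2e2)) {
    return(list(group = "EXCLUDED",
                reasons = "fh_gene_plp_with_e2e2", dlcn = NA_integer_))
  }
  if (sum(plp_genes %in% combo_set) >= 2) {
    return(list(group = "EXCLUDED",
                reasons = "multiple_fh_gene_plp", dlcn = NA_integer_))
  }

  miss <- function(x) is.null(x) || is.na(x)
  if (miss(p$apoe) || miss(p$tg)) {
    return(list(group = "UNCLASSIFIED",
                reasons = "insufficient data: apoe or tg missing",
                dlcn = NA_integer_))
  }

  # (2) FD
  if (is_e2e2 && p$tg >= thresholds$fd_tg_min) {
    return(list(group = "FD",
                reasons = sprintf("apoe=e2e2; tg=%.2f>=%.1f", p$tg,
                                  thresholds$fd_tg_min),
                dlcn = NA_integer_))
  }

  # (3) FH
  dlcn <- NA_integer_
  if (any(plp_genes %in% fh_set)) {
    premature <- isTRUE(p$chd) && !miss(p$chd_onset_age) &&
      ((identical(p$sex, "M") && p$chd_onset_age < 55) ||
       (identical(p$sex, "F") && p$chd_onset_age < 60))
    dlcn <- dlcn_score(
      ldl_c = p$ldl_pretreat, causal_mutation = TRUE,
      tendon_xanthomas = isTRUE(p$tendon_xanthomas),
      premature_chd = premature, criteria = criteria)
    if (dlcn >= thresholds$dlcn_definite_min) {
      return(list(group = "FH",
                  reasons = sprintf("fh_gene_plp:%s; dlcn=%d>=%d",
                                    paste(intersect(plp_genes, fh_set),
                                          collapse = ","), dlcn,
                                    thresholds$dlcn_definite_min),
                  dlcn = dlcn))
    }
  }

  if (miss(p$ldl_pretreat) || miss(p$prs_ldl_band)) {
    return(list(group = "UNCLASSIFIED",
                reasons = "insufficient data: ldl or prs band missing",
                dlcn = dlcn))
  }
  high_ldl <- p$ldl_pretreat > thresholds$hcl_ldl_min
  no_xanth <- !isTRUE(p$tendon_xanthomas)

  # (4) polygenic HCL
  if (high_ldl && identical(p$prs_ldl_band, "HIGH") && no_xanth) {
    return(list(group = "POLY_HCL",
                reasons = sprintf("ldl=%.2f>%.1f; band=HIGH; no_xanthomas",
                                  p$ldl_pretreat, thresholds$hcl_ldl_min),
                dlcn = dlcn))
  }
  # (5) severe HCL
  if (high_ldl && identical(p$prs_ldl_band, "LOW") && no_xanth) {
    return(list(group = "SEVERE_HCL",
                reasons = sprintf("ldl=%.2f>%.1f; band=LOW; no_xanthomas",
                                  p$ldl_pretreat, thresholds$hcl_ldl_min),
                dlcn = dlcn))
  }
  # (6) control
  if (!length(plp_genes) && identical(p$prs_ldl_band, "LOW") &&
      p$ldl_pretreat < thresholds$control_ldl_max &&
      p$tg < thresholds$control_tg_max) {
    reasons <- sprintf("no_causal_variant; band=LOW; ldl=%.2f<%.1f; tg=%.2f<%.1f",
                       p$ldl_pretreat, thresholds$control_ldl_max,
                       p$tg, thresholds$control_tg_max)
    if (identical(p$panel, "GENES_6")) {
      reasons <- paste0(reasons, "; reduced_panel")
    }
    return(list(group = "CONTROL", reasons = reasons, dlcn = dlcn))
  }

  list(group = "UNCLASSIFIED", reasons = "no rule satisfied", dlcn = dlcn)
}

#' Classify every participant in a cohort
#'
#' Vectorized wrapper around [assign_group()]. The table must already be
#' harmonized ([harmonize_lipids()]) and carry PRS bands.
#'
#' @inheritParams harmonize_lipids
#' @param thresholds [class_thresholds()].
#' @param criteria DLCN table.
#' @return data.frame with `id`, `group`, `reasons`, `dlcn`.
#' @export
classify_cohort <- function(participants, thresholds = class_thresholds(),
                            criteria = dlcn_criteria_table()) {
  if (!"ldl_pretreat" %in% names(participants)) {
    stop("participants must be harmonized first (harmonize_lipids)")
  }
  res <- lapply(seq_len(nrow(participants)), function(i) {
    assign_group(participants[i, , drop = FALSE], thresholds, criteria)
  })
  data.frame(
    id = participants$id,
    group = vapply(res, `[[`, character(1), "group"),
    reasons = vapply(res, function(r) paste(r$reasons, collapse = "; "),
                     character(1)),
    dlcn = vapply(res, `[[`, integer(1), "dlcn"),
    stringsAsFactors = FALSE
  )
}
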
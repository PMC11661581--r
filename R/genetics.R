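#' Call the APOE epsilon haplotype from rs7412 and rs429358 genotypes
#'
#' The APOE isoform system is determined by two SNPs: the alternate allele
#' of rs7412 tags epsilon-2 and the alternate allele of rs429358 tags
#' epsilon-4; chromosomes carrying neither are epsilon-3. Genotypes are
#' given as alternate-allele counts (0, 1 or 2) or as GT strings such as
#' `"0/1"`.
#'
#' The double-heterozygote (rs7412 0/1 and rs429358 0/1) is genuinely
#' phase-ambiguous (e2e4 vs the essentially absent e1e3); it is assigned
#' `e2e4` with a warning, matching standard practice.
#'
#' @param gt_rs7412,gt_rs429358 Alternate-allele count (0/1/2) or a
#'   VCF-style GT string (`"0/0"`, `"0|1"`, ...). `NA` is an error.
#' @return One of `"e2e2"`, `"e2e3"`, `"e2e4"`, `"e3e3"`, `"e3e4"`,
#'   `"e4e4"`.
#' @export
call_apoe_haplotype <- function(gt_rs7412, gt_rs429358) {
  n2 <- .alt_count(gt_rs7412, "rs7412")
  n4 <- .alt_count(gt_rs429358, "rs429358")
  if (n2 + n4 > 2L) {
    stop("inconsistent APOE genotypes: e2 + e4 allele counts exceed 2")
  }
  if (n2 == 1L && n4 == 1L) {
    warning("rs7412/rs429358 double heterozygote is phase-ambiguous; ",
            "assigning e2e4")
  }
  n3 <- 2L - n2 - n4
  alleles <- c(rep("2", n2), rep("3", n3), rep("4", n4))
  alleles <- sort(alleles)
  paste0("e", alleles[1], "e", alleles[2])
}

.alt_count <- function(gt, label) {
  if (length(gt) != 1L || is.na(gt)) {
    stop("APOE haplotype undetermined: missing genotype at ", label)
  }
  if (is.numeric(gt)) {
    if (!gt %in% 0:2) stop("genotype at ", label, " must be 0, 1 or 2")
    return(as.integer(gt))
  }
  alleles <- strsplit(as.character(gt), "[/|]")[[1]]
  if (length(alleles) != 2L || any(!alleles %in% c("0", "1"))) {
    stop("APOE haplotype undetermined: unparseable genotype '", gt,
         "' at ", label)
  }
  sum(alleles == "1")
}

#' Weighted polygenic score from effect-allele dosages
#'
#' Returns the weighted allele sum `sum(beta_i * dosage_i)` over the
#' model's variants. Dosages must be aligned to `model$variants` order
#' (or carry names matching the rsids, in which case they are realigned).
#' Missing dosages are refused by default; with
#' `missing_policy = "impute_mean"` they are replaced by the
#' Hardy-Weinberg expectation `2 * effect_allele_freq`.
#'
#' @param dosages Numeric vector of effect-allele dosages in {0, 1, 2}.
#' @param model A [prs_model()].
#' @param missing_policy `"error"` (default) or `"impute_mean"`.
#' @return The raw weighted score (before any APOE adjustment).
#' @export
compute_weighted_prs <- function(dosages, model,
                                 missing_policy = c("error", "impute_mean")) {
  stopifnot(inherits(model, "prs_model"))
  missing_policy <- match.arg(missing_policy)
  v <- model$variants
  if (!is.null(names(dosages))) {
    dosages <- dosages[v$rsid]
  }
  if (length(dosages) != nrow(v)) {
    stop("dosage vector length ", length(dosages),
         " does not match model with ", nrow(v), " variants")
  }
  miss <- is.na(dosages)
  if (any(miss)) {
    if (missing_policy == "error") {
      stop("missing dosage for ", sum(miss), " variant(s); set ",
           "missing_policy = \"impute_mean\" to impute 2*freq")
    }
    dosages[miss] <- 2 * v$effect_allele_freq[miss]
  }
  if (any(dosages < 0 | dosages > 2)) stop("dosages must lie in [0, 2]")
  sum(v$beta * dosages)
}

#' Final LDL-C genetic score with APOE haplotype adjustment
#'
#' @param raw Raw weighted PRS from [compute_weighted_prs()].
#' @param hap APOE haplotype string (see [apoe_haplotypes()]).
#' @param model An LDL-C [prs_model()] carrying the adjustment map.
#' @return `raw + adjustment[hap]`.
#' @export
final_ldl_score <- function(raw, hap, model) {
  stopifnot(inherits(model, "prs_model"))
  if (model$trait != "LDL_C") {
    stop("APOE adjustment applies to the LDL_C score only")
  }
  if (any(!hap %in% apoe_haplotypes())) {
    stop("unknown APOE haplotype: ", paste(setdiff(hap, apoe_haplotypes()),
                                           collapse = ", "))
  }
  raw + unname(model$apoe_adjustment[hap])
}

#' Reference-population stratification bands
#'
#' @param reference_scores Non-empty numeric vector of scores from the
#'   reference population.
#' @param high,low Percentile thresholds; scores strictly above the
#'   `high`-th percentile are HIGH, strictly below the `low`-th are LOW.
#' @return An object of class `strat_bands`.
#' @export
strat_bands <- function(reference_scores, high = 80, low = 50) {
  reference_scores <- reference_scores[!is.na(reference_scores)]
  if (!length(reference_scores)) stop("reference scores must be non-empty")
  if (!(0 < low && low < high && high < 100)) {
    stop("need 0 < low < high < 100")
  }
  structure(list(reference = as.numeric(reference_scores),
                 high = high, low = low),
            class = "strat_bands")
}

#' Empirical percentile of a score in a reference population
#'
#' Uses the mid-distribution convention: the percentile of `x` is
#' `100 * (#\{ref < x\} + 0.5 * #\{ref == x\}) / n`. This makes band
#' membership reproducible and symmetric under ties: within the reference
#' sample itself, exactly 20% exceed the 80th-percentile threshold and
#' 50% fall below the 50th (up to ties).
#'
#' @param score Numeric vector of scores.
#' @param bands A [strat_bands()] object.
#' @return Percentiles in \[0, 100\], vectorized over `score`.
#' @export
percentile_rank <- function(score, bands) {
  stopifnot(inherits(bands, "strat_bands"))
  ref <- bands$reference
  n <- length(ref)
  vapply(score, function(s) {
    if (is.na(s)) return(NA_real_)
    100 * (sum(ref < s) + 0.5 * sum(ref == s)) / n
  }, numeric(1))
}

#' Stratify a percentile into HIGH / LOW / INTERMEDIATE bands
#'
#' HIGH iff strictly above the high threshold (default 80th percentile),
#' LOW iff strictly below the low threshold (default 50th), otherwise
#' INTERMEDIATE.
#'
#' @param percentile Numeric vector in \[0, 100\].
#' @param bands A [strat_bands()] (only the thresholds are used).
#' @return Character vector in `c("HIGH", "LOW", "INTERMEDIATE")`.
#' @export
stratify <- function(percentile, bands = NULL) {
  high <- if (is.null(bands)) 80 else bands$high
  low <- if (is.null(bands)) 50 else bands$low
  if (any(percentile < 0 | percentile > 100, na.rm = TRUE)) {
    stop("percentiles must lie in [0, 100]")
  }
  out <- rep("INTERMEDIATE", length(percentile))
  out[percentile > high] <- "HIGH"
  out[percentile < low] <- "LOW"
  out[is.na(percentile)] <- NA_character_
  out
}

#' Rare-variant filter for candidate causal variants
#'
#' Keeps annotations that are non-synonymous AND either absent from
#' gnomAD or with gnomAD allele frequency below the rarity threshold
#' (default 0.01%).
#'
#' @param annotations data.frame with columns `gnomad_af` (fraction, `NA`
#'   for absent) and `synonymous` (logical).
#' @param af_max Rarity threshold on gnomAD AF (default `1e-4`).
#' @return The kept subset of `annotations`.
#' @export
rare_variant_filter <- function(annotations, af_max = 1e-4) {
  stopifnot(is.data.frame(annotations),
            all(c("gnomad_af", "synonymous") %in% names(annotations)))
  af <- annotations$gnomad_af
  if (any(af < 0 | af > 1, na.rm = TRUE)) stop("gnomad_af outside [0, 1]")
  keep <- !annotations$synonymous & (is.na(af) | af < af_max)
  annotations[keep, , drop = FALSE]
}
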
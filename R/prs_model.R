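#' Polygenic risk score models
#'
#' A `prs_model` bundles the variant/effect-allele/weight table defining a
#' weighted polygenic score for one lipid trait, plus (for LDL-C only) the
#' APOE haplotype adjustment applied on top of the weighted allele sum.
#'
#' @param trait One of `"LDL_C"` or `"TG"`.
#' @param variants data.frame with columns `rsid`, `effect_allele`
#'   (single base A/C/G/T), `effect_allele_freq` (in \[0, 1\]) and `beta`
#'   (finite score weight per effect allele).
#' @param apoe_adjustment Named numeric vector mapping the six APOE
#'   haplotypes (`e2e2` ... `e4e4`) to a score increment. Required for
#'   `trait = "LDL_C"`, must be absent for `"TG"`.
#'
#' @return An object of class `prs_model`.
#' @export
prs_model <- function(trait = c("LDL_C", "TG"), variants,
                      apoe_adjustment = NULL) {
  trait <- match.arg(trait)
  stopifnot(is.data.frame(variants))
  req <- c("rsid", "effect_allele", "effect_allele_freq", "beta")
  missing_cols <- setdiff(req, names(variants))
  if (length(missing_cols)) {
    stop("variant table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(variants) == 0L) stop("variant table must be non-empty")
  if (any(!variants$effect_allele %in% c("A", "C", "G", "T"))) {
    stop("effect_allele must be one of A/C/G/T")
  }
  f <- variants$effect_allele_freq
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1)) {
    stop("effect_allele_freq must lie in [0, 1]")
  }
  if (any(!is.finite(variants$beta))) stop("beta must be finite")
  if (anyDuplicated(variants$rsid)) stop("duplicated rsid in variant table")

  if (trait == "LDL_C") {
    if (is.null(apoe_adjustment)) {
      apoe_adjustment <- apoe_ldl_adjustment()
    }
    if (!setequal(names(apoe_adjustment), apoe_haplotypes())) {
      stop("apoe_adjustment must cover exactly the six APOE haplotypes")
    }
    apoe_adjustment <- apoe_adjustment[apoe_haplotypes()]
  } else if (!is.null(apoe_adjustment)) {
    stop("apoe_adjustment is only meaningful for the LDL_C trait")
  }

  structure(
    list(trait = trait,
         variants = variants[, req],
         apoe_adjustment = apoe_adjustment),
    class = "prs_model"
  )
}

#' @export
print.prs_model <- function(x, ...) {
  cat(sprintf("<prs_model> trait=%s, %d variants%s\n", x$trait,
              nrow(x$variants),
              if (!is.null(x$apoe_adjustment)) ", APOE-adjusted" else ""))
  invisible(x)
}

#' The six APOE epsilon haplotypes
#' @return Character vector `c("e2e2","e2e3","e2e4","e3e3","e3e4","e4e4")`.
#' @export
apoe_haplotypes <- function() {
  c("e2e2", "e2e3", "e2e4", "e3e3", "e3e4", "e4e4")
}

#' APOE haplotype increments for the final LDL-C genetic score
#'
#' Score increments added to the weighted allele sum to form the final
#' LDL-C genetic score: -0.9 (e2e2), -0.4 (e2e3), -0.2 (e2e4), 0 (e3e3),
#' 0.1 (e3e4), 0.2 (e4e4).
#' @return Named numeric vector over the six haplotypes.
#' @export
apoe_ldl_adjustment <- function() {
  c(e2e2 = -0.9, e2e3 = -0.4, e2e4 = -0.2,
    e3e3 = 0, e3e4 = 0.1, e4e4 = 0.2)
}

#' Read a PRS coefficient table from CSV
#'
#' Expects columns `rsid,effect_allele,effect_allele_freq,beta`.
#'
#' @param path CSV file path.
#' @inheritParams prs_model
#' @return A `prs_model`.
#' @export
read_prs_model <- function(path, trait = c("LDL_C", "TG"),
                           apoe_adjustment = NULL) {
  trait <- match.arg(trait)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  prs_model(trait, tab, apoe_adjustment)
}

#' Default synthetic PRS models
#'
#' The per-allele weights of the published 57-variant LDL-C and 40-variant
#' TG scores are not redistributable; the package ships clearly synthetic
#' stand-in tables (plausible allele frequencies and effect sizes) so the
#' scoring and stratification machinery is fully exercisable. Replace with
#' [read_prs_model()] for real analyses.
#'
#' @param trait `"LDL_C"` (57 variants) or `"TG"` (40 variants).
#' @return A `prs_model`.
#' @export
default_prs_model <- function(trait = c("LDL_C", "TG")) {
  trait <- match.arg(trait)
  file <- if (trait == "LDL_C") "prs_ldl_synthetic.csv" else "prs_tg_synthetic.csv"
  path <- system.file("extdata", file, package = "atherolip", mustWork = TRUE)
  read_prs_model(path, trait)
}
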
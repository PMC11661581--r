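#' Classification thresholds
#'
#' Cut-offs used by the lipid harmonization and group-assignment rules:
#' TG >= 1.5 mmol/L for dysbetalipoproteinemia, LDL-C > 4.9 mmol/L for the
#' hypercholesterolemia groups, control limits LDL-C < 3.0 and TG < 1.5
#' mmol/L, DLCN "definite" at >= 9 points, the Friedewald validity limit
#' TG <= 4.5 mmol/L, and the Lp(a) bands at 30 / 50 / 180 mg/dL.
#'
#' @param fd_tg_min,hcl_ldl_min,control_ldl_max,control_tg_max,dlcn_definite_min,friedewald_tg_max
#'   Scalar thresholds (mmol/L except DLCN points).
#' @param lpa_bands Increasing numeric vector of the three Lp(a) cut-offs
#'   in mg/dL.
#' @return A list of class `class_thresholds`.
#' @export
class_thresholds <- function(fd_tg_min = 1.5, hcl_ldl_min = 4.9,
                             control_ldl_max = 3.0, control_tg_max = 1.5,
                             dlcn_definite_min = 9, friedewald_tg_max = 4.5,
                             lpa_bands = c(30, 50, 180)) {
  stopifnot(fd_tg_min > 0, hcl_ldl_min > 0, control_ldl_max > 0,
            control_tg_max > 0, dlcn_definite_min > 0,
            friedewald_tg_max > 0, length(lpa_bands) == 3,
            all(diff(lpa_bands) > 0), all(lpa_bands > 0))
  structure(list(fd_tg_min = fd_tg_min, hcl_ldl_min = hcl_ldl_min,
                 control_ldl_max = control_ldl_max,
                 control_tg_max = control_tg_max,
                 dlcn_definite_min = dlcn_definite_min,
                 friedewald_tg_max = friedewald_tg_max,
                 lpa_bands = lpa_bands),
            class = "class_thresholds")
}

#' Friedewald LDL-C estimate (mmol/L)
#'
#' `LDL-C = TC - HDL-C - TG / 2.2`, valid only for TG <= 4.5 mmol/L;
#' above that a direct measurement is required and the function errors.
#'
#' @param tc,hdl,tg Total, HDL cholesterol and triglycerides, mmol/L.
#' @param thresholds [class_thresholds()].
#' @return Estimated LDL-C in mmol/L (vectorized).
#' @export
friedewald_ldl <- function(tc, hdl, tg, thresholds = class_thresholds()) {
  if (any(c(tc, hdl, tg) < 0, na.rm = TRUE)) {
    stop("lipid concentrations must be non-negative")
  }
  if (any(tg > thresholds$friedewald_tg_max, na.rm = TRUE)) {
    stop("TG > ", thresholds$friedewald_tg_max,
         " mmol/L: direct LDL-C measurement required")
  }
  tc - hdl - tg / 2.2
}

.read_extdata_csv <- function(file) {
  utils::read.csv(system.file("extdata", file, package = "atherolip",
                              mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Default statin dose tables
#'
#' `statin_equivalence_table()` maps named statin doses to the equivalent
#' atorvastatin dose; `statin_reduction_table()` maps atorvastatin dose to
#' the average relative LDL-C reduction. Shipped values follow standard
#' published dose-equivalence and dose-response charts and are editable
#' (pass your own data.frame to the consumers).
#' @return data.frame.
#' @export
statin_equivalence_table <- function() .read_extdata_csv("statin_equivalence.csv")

#' @rdname statin_equivalence_table
#' @export
statin_reduction_table <- function() .read_extdata_csv("statin_ldl_reduction.csv")

#' Convert a statin dose to its atorvastatin-equivalent dose
#'
#' Looks the drug up in the equivalence table and interpolates linearly
#' between listed doses (constant extrapolation beyond the listed range).
#'
#' @param drug Statin name (lowercase, e.g. `"rosuvastatin"`).
#' @param dose Daily dose in mg.
#' @param table Equivalence table, default [statin_equivalence_table()].
#' @return Equivalent atorvastatin dose in mg/day.
#' @export
atorvastatin_equivalent <- function(drug, dose,
                                    table = statin_equivalence_table()) {
  rows <- table[table$drug == drug, , drop = FALSE]
  if (!nrow(rows)) stop("unknown statin drug: ", drug)
  if (!is.finite(dose) || dose <= 0) stop("dose must be positive")
  rows <- rows[order(rows$dose), ]
  stats::approx(rows$dose, rows$atorvastatin_equivalent, xout = dose,
                rule = 2)$y
}

#' Back-correct a measured LDL-C to its estimated pretreatment level
#'
#' Divides the on-treatment measurement by `1 - r(dose)`, where `r` is the
#' average relative LDL-C reduction at the given atorvastatin-equivalent
#' dose, interpolated from the reduction table. Only LDL-C is corrected;
#' HDL-C and TG are never recalculated.
#'
#' @param measured_ldl Measured LDL-C, mmol/L.
#' @param atorva_dose Atorvastatin-equivalent dose, mg/day (0 for none).
#' @param table Reduction table, default [statin_reduction_table()].
#' @return Estimated untreated LDL-C, mmol/L.
#' @export
pretreatment_ldl <- function(measured_ldl, atorva_dose,
                             table = statin_reduction_table()) {
  if (any(measured_ldl < 0, na.rm = TRUE)) stop("measured LDL-C must be >= 0")
  tab <- table[order(table$atorvastatin_dose), ]
  r <- stats::approx(tab$atorvastatin_dose, tab$ldl_reduction,
                     xout = atorva_dose, rule = 2)$y
  if (any(r >= 1)) stop("LDL reduction fraction must be < 1")
  measured_ldl / (1 - r)
}

#' Statin-use predicate
#'
#' A participant counts as a statin user when taking statins for more than
#' 1 month before the arterial ultrasound, or for 3 months or longer
#' historically.
#'
#' @param months_before_ultrasound,months_historical Durations in months;
#'   `NA` is treated as 0 (no therapy).
#' @return Logical (vectorized).
#' @export
statin_user <- function(months_before_ultrasound, months_historical = 0) {
  pre <- ifelse(is.na(months_before_ultrasound), 0, months_before_ultrasound)
  hist <- ifelse(is.na(months_historical), 0, months_historical)
  pre > 1 | hist >= 3
}

#' Lp(a) concentration band
#'
#' `NORMAL` below 30 mg/dL, `BORDERLINE` in \[30, 50), `ELEVATED` at
#' >= 50, and `VERY_HIGH` strictly above 180 mg/dL (a subset of the
#' elevated range flagged separately).
#'
#' @param lpa Lp(a), mg/dL.
#' @param thresholds [class_thresholds()].
#' @return Character vector.
#' @export
lpa_band <- function(lpa, thresholds = class_thresholds()) {
  if (any(lpa < 0, na.rm = TRUE)) stop("Lp(a) must be >= 0")
  b <- thresholds$lpa_bands
  out <- rep(NA_character_, length(lpa))
  out[lpa < b[1]] <- "NORMAL"
  out[lpa >= b[1] & lpa < b[2]] <- "BORDERLINE"
  out[lpa >= b[2]] <- "ELEVATED"
  out[lpa > b[3]] <- "VERY_HIGH"
  out
}

#' Default Dutch Lipid Clinic Network criteria table
#' @return data.frame with columns `category`, `item`, `points`.
#' @export
dlcn_criteria_table <- function() .read_extdata_csv("dlcn_criteria.csv")

#' Dutch Lipid Clinic Network (DLCN) score
#'
#' Sums, over the five DLCN categories (family history, clinical history,
#' physical examination, LDL-C level, DNA), the highest-scoring satisfied
#' item in each category. LDL-C must be the untreated (back-corrected)
#' level. A score >= 9 is a "definite" FH diagnosis.
#'
#' @param ldl_c Untreated LDL-C, mmol/L.
#' @param causal_mutation Logical: pathogenic/likely-pathogenic variant in
#'   LDLR/APOB/PCSK9.
#' @param tendon_xanthomas,arcus_cornealis_under_45 Logical physical signs.
#' @param premature_chd,premature_cerebral_peripheral Logical clinical
#'   history items.
#' @param family_premature_cvd_or_high_ldl,family_xanthoma_or_child_high_ldl
#'   Logical family-history items.
#' @param criteria DLCN point table, default [dlcn_criteria_table()].
#' @return Integer point total.
#' @export
dlcn_score <- function(ldl_c, causal_mutation = FALSE,
                       tendon_xanthomas = FALSE,
                       arcus_cornealis_under_45 = FALSE,
                       premature_chd = FALSE,
                       premature_cerebral_peripheral = FALSE,
                       family_premature_cvd_or_high_ldl = FALSE,
                       family_xanthoma_or_child_high_ldl = FALSE,
                       criteria = dlcn_criteria_table()) {
  req <- c("category", "item", "points")
  if (!is.data.frame(criteria) || !all(req %in% names(criteria))) {
    stop("malformed DLCN criteria table")
  }
  ldl <- if (is.na(ldl_c)) -Inf else ldl_c
  sat <- c(
    family_premature_cvd_or_high_ldl = isTRUE(family_premature_cvd_or_high_ldl),
    family_xanthoma_or_child_high_ldl = isTRUE(family_xanthoma_or_child_high_ldl),
    premature_chd = isTRUE(premature_chd),
    premature_cerebral_peripheral = isTRUE(premature_cerebral_peripheral),
    tendon_xanthomas = isTRUE(tendon_xanthomas),
    arcus_cornealis_under_45 = isTRUE(arcus_cornealis_under_45),
    ldl_ge_8p5 = ldl >= 8.5,
    ldl_6p5_to_8p4 = ldl >= 6.5 && ldl < 8.5,
    ldl_5p0_to_6p4 = ldl >= 5.0 && ldl < 6.5,
    ldl_4p0_to_4p9 = ldl >= 4.0 && ldl < 5.0,
    causal_mutation = isTRUE(causal_mutation)
  )
  hit <- criteria[criteria$item %in% names(sat)[sat], , drop = FALSE]
  if (!nrow(hit)) return(0L)
  as.integer(sum(tapply(hit$points, hit$category, max)))
}
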
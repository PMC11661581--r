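#' Plaque definition rule
#'
#' A focal structure is a plaque when it encroaches into the lumen by at
#' least 0.5 mm, or by at least 50% of the surrounding intima-media
#' thickness, or has a thickness >= 1.5 mm.
#'
#' @param encroachment_min mm, default 0.5.
#' @param imt_ratio_min Fraction of surrounding IMT, default 0.5.
#' @param thickness_min mm, default 1.5.
#' @return List of class `plaque_rule`.
#' @export
plaque_rule <- function(encroachment_min = 0.5, imt_ratio_min = 0.5,
                        thickness_min = 1.5) {
  stopifnot(encroachment_min > 0, imt_ratio_min > 0, thickness_min > 0)
  structure(list(encroachment_min = encroachment_min,
                 imt_ratio_min = imt_ratio_min,
                 thickness_min = thickness_min),
            class = "plaque_rule")
}

#' Does a measurement qualify as a plaque?
#'
#' @param height Plaque thickness, mm.
#' @param encroachment Luminal encroachment, mm.
#' @param surrounding_imt Surrounding intima-media thickness, mm.
#' @param rule [plaque_rule()].
#' @return Logical (vectorized); `FALSE` for missing measurements.
#' @export
is_plaque <- function(height, encroachment, surrounding_imt,
                      rule = plaque_rule()) {
  out <- (encroachment >= rule$encroachment_min) |
    (encroachment >= rule$imt_ratio_min * surrounding_imt) |
    (height >= rule$thickness_min)
  out & !is.na(out)
}

#' Percent stenosis per the European Carotid Surgery Trial convention
#'
#' `(1 - residual_lumen_area / original_lumen_area) * 100`.
#'
#' @param residual_lumen_area,original_lumen_area Areas, mm^2.
#' @return Percent stenosis in \[0, 100\] (vectorized).
#' @export
ecst_stenosis <- function(residual_lumen_area, original_lumen_area) {
  if (any(original_lumen_area <= 0, na.rm = TRUE)) {
    stop("original lumen area must be positive")
  }
  if (any(residual_lumen_area < 0 |
          residual_lumen_area > original_lumen_area, na.rm = TRUE)) {
    stop("residual lumen area must lie in [0, original]")
  }
  (1 - residual_lumen_area / original_lumen_area) * 100
}

.territory_sites <- list(
  CAROTID = c("CCA", "BIFURCATION", "ICA"),
  FEMORAL = c("CFA", "BIFURCATION", "SFA")
)
.territory_segments <- list(
  CAROTID = c("ICA", "BULB", "CCA_1", "CCA_2"),
  FEMORAL = c("SFA", "BIF", "CFA_1", "CFA_2")
)

#' Valid sites / scoring segments per territory
#' @param territory `"CAROTID"` or `"FEMORAL"`.
#' @return Character vector.
#' @export
territory_sites <- function(territory) {
  .territory_sites[[match.arg(territory, names(.territory_sites))]]
}

#' @rdname territory_sites
#' @export
territory_segments <- function(territory) {
  .territory_segments[[match.arg(territory, names(.territory_segments))]]
}

.check_records <- function(records) {
  req <- c("participant_id", "territory", "side", "site", "segment",
           "surrounding_imt", "height", "encroachment",
           "residual_lumen_area", "original_lumen_area")
  absent <- setdiff(req, names(records))
  if (length(absent)) {
    stop("ultrasound records lack columns: ", paste(absent, collapse = ", "))
  }
  for (terr in unique(records$territory)) {
    rows <- records[records$territory == terr, ]
    bad <- setdiff(unique(rows$site), territory_sites(terr))
    if (length(bad)) stop("invalid site(s) for ", terr, ": ",
                          paste(bad, collapse = ", "))
    badseg <- setdiff(unique(rows$segment[!is.na(rows$segment)]),
                      territory_segments(terr))
    if (length(badseg)) stop("invalid segment label(s) for ", terr, ": ",
                             paste(badseg, collapse = ", "))
  }
  invisible(records)
}

#' Aggregate plaque-level records into per-territory metrics
#'
#' Input rows are one per plaque (sites free of plaque may appear with
#' missing plaque fields). All rows must belong to one participant and one
#' territory. Measurements failing [is_plaque()] are excluded from every
#' metric. The five aggregates are: plaque number (count of qualifying
#' plaques over the six sites); maximum stenosis (largest per-artery
#' stenosis, an artery being a side/site pair, its stenosis taken at the
#' site of maximum obstruction); total stenosis (sum of per-artery maxima,
#' may exceed 100%); maximum plaque height; and the plaque score from
#' [plaque_score()].
#'
#' @param records data.frame of plaque rows (see column contract above).
#' @param rule [plaque_rule()].
#' @return One-row data.frame with `plaque_number`, `max_stenosis`,
#'   `total_stenosis`, `max_plaque_height`, `plaque_score`.
#' @export
aggregate_territory <- function(records, rule = plaque_rule()) {
  .check_records(records)
  if (length(unique(records$participant_id)) > 1L ||
      length(unique(records$territory)) > 1L) {
    stop("records must come from a single participant and territory")
  }
  keep <- is_plaque(records$height, records$encroachment,
                    records$surrounding_imt, rule)
  pl <- records[keep, , drop = FALSE]
  if (!nrow(pl)) {
    return(data.frame(plaque_number = 0L, max_stenosis = 0,
                      total_stenosis = 0, max_plaque_height = 0,
                      plaque_score = 0))
  }
  sten <- ecst_stenosis(pl$residual_lumen_area, pl$original_lumen_area)
  artery <- paste(pl$side, pl$site, sep = ":")
  per_artery_max <- tapply(sten, artery, max)
  data.frame(
    plaque_number = nrow(pl),
    max_stenosis = max(per_artery_max),
    total_stenosis = sum(per_artery_max),
    max_plaque_height = max(pl$height),
    plaque_score = plaque_score(records, rule)
  )
}

#' Plaque score: summed per-segment maximum plaque thickness
#'
#' Each territory is divided into four scoring segments per side (eight in
#' total); the score is the sum over segments of the maximum qualifying
#' plaque thickness, zero for plaque-free segments.
#'
#' @inheritParams aggregate_territory
#' @return Score in mm.
#' @export
plaque_score <- function(records, rule = plaque_rule()) {
  .check_records(records)
  keep <- is_plaque(records$height, records$encroachment,
                    records$surrounding_imt, rule)
  pl <- records[keep, , drop = FALSE]
  if (!nrow(pl)) return(0)
  seg <- paste(pl$side, pl$segment, sep = ":")
  if (anyNA(pl$segment)) stop("qualifying plaque without a segment label")
  sum(tapply(pl$height, seg, max))
}

#' Per-participant, per-territory plaque metrics for a whole cohort
#'
#' @param records Ultrasound record table for many participants.
#' @param rule [plaque_rule()].
#' @return data.frame keyed by `participant_id` and `territory` with the
#'   five metric columns of [aggregate_territory()].
#' @export
plaque_metrics <- function(records, rule = plaque_rule()) {
  .check_records(records)
  parts <- split(records,
                 list(records$participant_id, records$territory),
                 drop = TRUE)
  out <- lapply(parts, function(sub) {
    cbind(data.frame(participant_id = sub$participant_id[1],
                     territory = sub$territory[1],
                     stringsAsFactors = FALSE),
          aggregate_territory(sub, rule))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
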
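# Shared builders for small in-code fixtures.

tiny_ldl_model <- function(n = 3, betas = c(-0.1, 0.2, 0.05),
                           freqs = c(0.3, 0.5, 0.1)) {
  prs_model("LDL_C", data.frame(
    rsid = sprintf("rsT%03d", seq_len(n)),
    effect_allele = rep(c("A", "C", "G", "T"), length.out = n),
    effect_allele_freq = rep(freqs, length.out = n),
    beta = rep(betas, length.out = n)))
}

tiny_tg_model <- function(n = 2, betas = c(0.08, -0.03)) {
  prs_model("TG", data.frame(
    rsid = sprintf("rsU%03d", seq_len(n)),
    effect_allele = rep(c("A", "C"), length.out = n),
    effect_allele_freq = rep(0.4, n),
    beta = rep(betas, length.out = n)))
}

# A minimal harmonized participant row satisfying the classifier contract;
# override fields as needed.
base_participant <- function(...) {
  p <- list(
    id = "P1", sex = "F", age = 50, bmi = 27, smoking = "never",
    hypertension = FALSE, diabetes = FALSE, tendon_xanthomas = FALSE,
    tc = 5, ldl_c = 3.2, hdl_c = 1.4, tg = 1.2, ldl_direct = FALSE,
    lpa = 10, statin_drug = NA_character_, statin_dose = NA_real_,
    statin_months_pre_us = NA_real_, statin_months_hist = NA_real_,
    causal_genes = "", causal_classes = "", apoe = "e3e3",
    prs_ldl_band = "INTERMEDIATE", prs_tg_band = "INTERMEDIATE",
    chd = FALSE, chd_onset_age = NA_real_, panel = "GENES_24",
    ldl_pretreat = 3.2)
  mods <- list(...)
  p[names(mods)] <- mods
  p
}

# A random one-participant one-territory fixture: 0-6 plaque rows plus one
# plaque-free site row.
random_territory_fixture <- function(pid, territory) {
  segs <- territory_segments(territory)
  k <- sample(0:6, 1)
  rows <- if (k > 0) {
    do.call(rbind, lapply(seq_len(k), function(i) {
      us_record(pid = pid, territory = territory,
                side = sample(c("LEFT", "RIGHT"), 1),
                segment = sample(segs, 1),
                imt = runif(1, 0.5, 1.2),
                height = runif(1, 0.3, 4),
                encroachment = runif(1, 0.1, 3),
                stenosis = runif(1, 5, 90))
    }))
  } else NULL
  rbind(rows, us_record(pid = pid, territory = territory))
}

# One-participant ultrasound record builder (carotid by default).
us_record <- function(pid = "P1", territory = "CAROTID", side = "LEFT",
                      segment = NULL, imt = 0.7, height = NA_real_,
                      encroachment = NA_real_, stenosis = NA_real_,
                      original = 30) {
  if (is.null(segment)) {
    segment <- if (is.na(height)) NA_character_ else
      territory_segments(territory)[2]   # bulb / bifurcation segment
  }
  site <- if (is.na(segment)) {
    territory_sites(territory)[1]        # plaque-free row: record the CCA/CFA
  } else if (territory == "CAROTID") {
    c(ICA = "ICA", BULB = "BIFURCATION", CCA_1 = "CCA", CCA_2 = "CCA")[segment]
  } else {
    c(SFA = "SFA", BIF = "BIFURCATION", CFA_1 = "CFA", CFA_2 = "CFA")[segment]
  }
  data.frame(participant_id = pid, territory = territory, side = side,
             site = unname(site), segment = segment, surrounding_imt = imt,
             height = height, encroachment = encroachment,
             residual_lumen_area = if (is.na(stenosis)) NA_real_ else
               original * (1 - stenosis / 100),
             original_lumen_area = if (is.na(stenosis)) NA_real_ else original,
             stringsAsFactors = FALSE)
}
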
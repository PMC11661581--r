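# Group-assignment cascade and lipid harmonization pipeline.

test_that("rule cascade assigns the five labels per the inclusion criteria", {
  # FD: e2e2 + TG >= 1.5, even with high TG
  r <- assign_group(base_participant(apoe = "e2e2", tg = 4.1))
  expect_identical(r$group, "FD")

  # FH: FH-gene P/LP + definite DLCN
  r <- assign_group(base_participant(causal_genes = "LDLR",
                                     causal_classes = "P",
                                     ldl_pretreat = 9.0))
  expect_identical(r$group, "FH")
  expect_gte(r$dlcn, 9)

  # polygenic HCL: LDL > 4.9, HIGH band, no xanthomas
  r <- assign_group(base_participant(ldl_pretreat = 5.5,
                                     prs_ldl_band = "HIGH"))
  expect_identical(r$group, "POLY_HCL")

  # severe HCL: LDL > 4.9, LOW band
  r <- assign_group(base_participant(ldl_pretreat = 5.5,
                                     prs_ldl_band = "LOW"))
  expect_identical(r$group, "SEVERE_HCL")

  # control: variant-free, LOW band, low lipids
  r <- assign_group(base_participant(ldl_pretreat = 2.5, tg = 1.0,
                                     prs_ldl_band = "LOW"))
  expect_identical(r$group, "CONTROL")
})

test_that("exclusion rules override inclusion", {
  # P/LP outside the FH genes
  r <- assign_group(base_participant(causal_genes = "LPL",
                                     causal_classes = "P", apoe = "e2e2",
                                     tg = 4))
  expect_identical(r$group, "EXCLUDED")

  # FH-gene P/LP combined with e2e2
  r <- assign_group(base_participant(causal_genes = "LDLR",
                                     causal_classes = "LP", apoe = "e2e2",
                                     tg = 4))
  expect_identical(r$group, "EXCLUDED")

  # two FH-gene P/LP variants
  r <- assign_group(base_participant(causal_genes = "LDLR,APOB",
                                     causal_classes = "P,P",
                                     ldl_pretreat = 9))
  expect_identical(r$group, "EXCLUDED")

  # a VUS is not a causal variant: neither excludes nor blocks control
  r <- assign_group(base_participant(causal_genes = "LPL",
                                     causal_classes = "VUS",
                                     ldl_pretreat = 2.5, tg = 1.0,
                                     prs_ldl_band = "LOW"))
  expect_identical(r$group, "CONTROL")
})

test_that("boundary and fallthrough behaviour", {
  # e2e2 but TG below 1.5: not FD; xanthomas block the polygenic label
  r <- assign_group(base_participant(apoe = "e2e2", tg = 1.49,
                                     ldl_pretreat = 5.5,
                                     prs_ldl_band = "HIGH",
                                     tendon_xanthomas = TRUE))
  expect_identical(r$group, "UNCLASSIFIED")
  # TG exactly at threshold is FD (inclusive)
  r <- assign_group(base_participant(apoe = "e2e2", tg = 1.5))
  expect_identical(r$group, "FD")
  # LDL exactly 4.9 is not "> 4.9"
  r <- assign_group(base_participant(ldl_pretreat = 4.9,
                                     prs_ldl_band = "HIGH"))
  expect_identical(r$group, "UNCLASSIFIED")
  # FH-gene variant with indefinite DLCN is not FH
  r <- assign_group(base_participant(causal_genes = "PCSK9",
                                     causal_classes = "LP",
                                     ldl_pretreat = 3.5))
  expect_identical(r$group, "UNCLASSIFIED")
  expect_lt(r$dlcn, 9)
})

test_that("missing required inputs yield UNCLASSIFIED with a reason", {
  p <- base_participant()
  p$prs_ldl_band <- NA_character_
  r <- assign_group(p)
  expect_identical(r$group, "UNCLASSIFIED")
  expect_match(r$reasons, "insufficient data")
  p <- base_participant()
  p$apoe <- NULL
  r <- assign_group(p)
  expect_match(r$reasons, "insufficient data")
})

test_that("reduced-panel controls are flagged", {
  r <- assign_group(base_participant(ldl_pretreat = 2.5, tg = 1.0,
                                     prs_ldl_band = "LOW", panel = "GENES_6"))
  expect_identical(r$group, "CONTROL")
  expect_match(r$reasons, "reduced_panel")
})

test_that("harmonization is the identity for non-users and inverts the
           treatment effect for users", {
  df <- do.call(rbind, lapply(list(
    base_participant(id = "A"),
    base_participant(id = "B", statin_drug = "atorvastatin",
                     statin_dose = 40, statin_months_pre_us = 12,
                     ldl_c = 4.0)),
    function(p) as.data.frame(p, stringsAsFactors = FALSE)))
  h <- harmonize_lipids(df)
  expect_false(h$statin_user[1])
  expect_equal(h$ldl_pretreat[1], h$ldl_c[1])
  expect_true(h$statin_user[2])
  expect_equal(h$ldl_pretreat[2], 4.0 / (1 - 0.49))
  # short therapy does not trigger correction
  df$statin_months_pre_us[2] <- 0.5
  h <- harmonize_lipids(df)
  expect_false(h$statin_user[2])
  expect_equal(h$ldl_pretreat[2], h$ldl_c[2])
})

test_that("classification is a partition: exactly one label each", {
  set.seed(21)
  ref <- generate_reference_population(300, tiny_ldl_model(8), tiny_tg_model(5),
                                       seed = 5)
  spec <- cohort_spec(n_per_group = c(FD = 10, FH = 10, POLY_HCL = 10,
                                      SEVERE_HCL = 10, CONTROL = 10),
                      seed = 9)
  coh <- generate_cohort(spec, ref)
  cl <- classify_cohort(harmonize_lipids(coh))
  expect_equal(nrow(cl), 50)
  expect_true(all(cl$group %in% c("FD", "FH", "POLY_HCL", "SEVERE_HCL",
                                  "CONTROL", "EXCLUDED", "UNCLASSIFIED")))
  expect_false(any(duplicated(cl$id)))
  # POLY and SEVERE mutually exclusive by disjoint bands
  poly <- coh$prs_ldl_band[cl$group == "POLY_HCL"]
  sev <- coh$prs_ldl_band[cl$group == "SEVERE_HCL"]
  expect_true(all(poly == "HIGH") && all(sev == "LOW"))
})
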
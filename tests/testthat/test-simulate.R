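# Synthetic cohort generator: determinism, HWE, criterion-consistency,
# fixture round-trips.

test_that("reference population: determinism, HWE, self-stratification", {
  ldl <- tiny_ldl_model(6); tg <- tiny_tg_model(4)
  r1 <- generate_reference_population(400, ldl, tg, seed = 3)
  r2 <- generate_reference_population(400, ldl, tg, seed = 3)
  expect_identical(r1$dosages, r2$dosages)
  expect_identical(r1$apoe, r2$apoe)
  expect_true(all(r1$dosages %in% 0:2))

  # HWE: per-variant dosage mean within 3 SE of 2*freq at large n
  big <- generate_reference_population(
    1e5, default_prs_model("LDL_C"), default_prs_model("TG"), seed = 4)
  freqs <- c(default_prs_model("LDL_C")$variants$effect_allele_freq,
             default_prs_model("TG")$variants$effect_allele_freq)
  means <- colMeans(big$dosages)
  se <- sqrt(2 * freqs * (1 - freqs) / 1e5)
  expect_true(all(abs(means - 2 * freqs) <= 3.5 * se))

  # ~20% of members exceed their own 80th percentile (near-continuous
  # scores; heavy score ties in few-variant models legitimately lower this)
  lab <- stratify(percentile_rank(big$ldl_final, big$ldl_bands),
                  big$ldl_bands)
  expect_equal(mean(lab == "HIGH"), 0.2, tolerance = 0.01)
  expect_equal(mean(lab == "LOW"), 0.5, tolerance = 0.01)
  expect_error(generate_reference_population(1, ldl, tg), ">= 2")
})

test_that("zero allele frequencies give all-zero dosages and raw scores", {
  m <- prs_model("LDL_C", data.frame(
    rsid = c("a", "b"), effect_allele = c("A", "C"),
    effect_allele_freq = c(0, 0), beta = c(0.5, -0.5)))
  ref <- generate_reference_population(50, m, tiny_tg_model(), seed = 1)
  expect_true(all(ref$dosages[, c("a", "b")] == 0))
  expect_true(all(ref$ldl_raw == 0))
})

test_that("cohort generation: exact counts, determinism, intended criteria", {
  ref <- generate_reference_population(500, tiny_ldl_model(10), tiny_tg_model(6),
                                       seed = 2)
  spec <- cohort_spec(n_per_group = c(FD = 12, FH = 15, POLY_HCL = 10,
                                      SEVERE_HCL = 9, CONTROL = 20),
                      seed = 6)
  coh <- generate_cohort(spec, ref)
  expect_equal(nrow(coh), 66)
  expect_equal(as.vector(table(coh$group_intended)[c("FD", "FH", "POLY_HCL",
                                                     "SEVERE_HCL", "CONTROL")]),
               c(12, 15, 10, 9, 20))
  coh2 <- generate_cohort(spec, ref)
  expect_identical(coh, coh2)

  # group-defining predicates hold by construction
  expect_true(all(coh$apoe[coh$group_intended == "FD"] == "e2e2"))
  expect_true(all(coh$tg[coh$group_intended == "FD"] >= 1.5))
  expect_true(all(coh$apoe[coh$group_intended != "FD"] != "e2e2"))
  expect_true(all(coh$prs_ldl_band[coh$group_intended == "POLY_HCL"] == "HIGH"))
  expect_true(all(coh$prs_ldl_band[coh$group_intended %in%
                                     c("SEVERE_HCL", "CONTROL")] == "LOW"))
  expect_true(all(coh$causal_genes[coh$group_intended == "FH"] %in%
                    c("LDLR", "APOB", "PCSK9")))

  # classifier recovers every intended label
  cl <- classify_cohort(harmonize_lipids(coh))
  expect_identical(cl$group, coh$group_intended)
})

test_that("ultrasound generator: determinism, site coverage, severity zero", {
  ref <- generate_reference_population(300, tiny_ldl_model(5), tiny_tg_model(3),
                                       seed = 2)
  params <- default_group_params()
  params$CONTROL$us_carotid_lambda <- 0
  params$CONTROL$us_femoral_lambda <- 0
  spec <- cohort_spec(n_per_group = c(FH = 5, CONTROL = 5), seed = 8,
                      group_params = params)
  coh <- generate_cohort(spec, ref)
  us1 <- generate_ultrasound(coh, spec)
  us2 <- generate_ultrasound(coh, spec)
  expect_identical(us1, us2)

  # severity 0: no plaques, but all six sites per territory recorded
  ctrl <- us1[us1$participant_id %in% coh$id[coh$group_intended == "CONTROL"], ]
  expect_true(all(is.na(ctrl$height)))
  one <- ctrl[ctrl$participant_id == ctrl$participant_id[1], ]
  expect_equal(nrow(one), 12)
  expect_setequal(paste(one$territory, one$side, one$site),
                  c(t(outer(c("CAROTID LEFT", "CAROTID RIGHT"),
                            territory_sites("CAROTID"), paste)),
                    t(outer(c("FEMORAL LEFT", "FEMORAL RIGHT"),
                            territory_sites("FEMORAL"), paste))))
  expect_error(generate_ultrasound(transform(coh, group_intended = "XX"), spec),
               "unknown group")
})

test_that("fixtures round-trip losslessly through the readers", {
  ldl <- default_prs_model("LDL_C"); tg <- default_prs_model("TG")
  ref <- generate_reference_population(200, ldl, tg, seed = 5)
  spec <- cohort_spec(n_per_group = c(FD = 2, FH = 2, CONTROL = 1), seed = 10)
  coh <- generate_cohort(spec, ref)
  us <- generate_ultrasound(coh, spec)
  out <- file.path(tempdir(), "fixt")
  paths <- write_fixtures(ref, coh, us, out)

  # VCF: 57 + 40 score variants plus the two APOE SNPs, 5 sample columns
  lines <- readLines(paths["vcf"])
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 57 + 40 + 2)
  header <- strsplit(lines[startsWith(lines, "#CHROM")], "\t")[[1]]
  expect_equal(length(header), 9 + 5)

  geno <- read_genotypes(paths["vcf"], ldl, tg)
  expect_equal(geno$dosages[coh$id, colnames(attr(coh, "dosages"))],
               attr(coh, "dosages"))
  expect_identical(unname(geno$apoe[match(coh$id, rownames(geno$dosages))]),
                   coh$apoe)

  ph <- read_phenotypes(paths["phenotypes"])
  expect_equal(ph$ldl_c, coh$ldl_c, tolerance = 1e-12)
  expect_identical(ph$apoe, coh$apoe)
  us2 <- read_ultrasound(paths["ultrasound"])
  expect_equal(us2$height, us$height, tolerance = 1e-12)

  # empty cohort: headers-only files, no error
  empty_spec <- cohort_spec(n_per_group = c(FD = 0), seed = 1)
  empty <- generate_cohort(empty_spec, ref)
  expect_equal(nrow(empty), 0)
  p2 <- write_fixtures(ref, empty, NULL, file.path(tempdir(), "fixt0"))
  expect_equal(nrow(read_phenotypes(p2["phenotypes"])), 0)
  vlines <- readLines(p2["vcf"])
  expect_equal(sum(!startsWith(vlines, "#")), 57 + 40 + 2)
})

test_that("effect-allele orientation flip is applied when effect = REF", {
  ldl <- tiny_ldl_model(2); tg <- tiny_tg_model(2)
  ref <- generate_reference_population(50, ldl, tg, seed = 5)
  spec <- cohort_spec(n_per_group = c(CONTROL = 3), seed = 3)
  coh <- generate_cohort(spec, ref)
  out <- file.path(tempdir(), "flip")
  paths <- write_fixtures(ref, coh, NULL, out)
  # swap REF/ALT of the first score variant and complement the GTs
  lines <- readLines(paths["vcf"])
  i <- which(!startsWith(lines, "#"))[1]
  f <- strsplit(lines[i], "\t")[[1]]
  gts <- f[10:length(f)]
  flip <- c("0/0" = "1/1", "0/1" = "0/1", "1/1" = "0/0")
  lines[i] <- paste(c(f[1:2], f[3], f[5], f[4], f[6:9], flip[gts]),
                    collapse = "\t")
  writeLines(lines, paths["vcf"])
  geno <- read_genotypes(paths["vcf"], ldl, tg)
  expect_equal(geno$dosages[coh$id, ], attr(coh, "dosages"))
})
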
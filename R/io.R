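.other_base <- function(allele) {
  c(A = "G", C = "T", G = "A", T = "C")[allele]
}

.variant_table <- function(ldl_model, tg_model) {
  # synthetic score variants on chr1 at deterministic positions; the two
  # APOE SNPs at their GRCh37 coordinates (ALT = e2 / e4 tagging allele)
  v <- rbind(ldl_model$variants[, c("rsid", "effect_allele")],
             tg_model$variants[, c("rsid", "effect_allele")])
  v <- v[!duplicated(v$rsid), ]
  tab <- data.frame(
    chrom = "1", pos = 1000000L + 1000L * seq_len(nrow(v)), rsid = v$rsid,
    ref = unname(.other_base(v$effect_allele)), alt = v$effect_allele,
    stringsAsFactors = FALSE)
  rbind(tab,
        data.frame(chrom = "19", pos = 45412079L, rsid = "rs7412",
                   ref = "C", alt = "T", stringsAsFactors = FALSE),
        data.frame(chrom = "19", pos = 45411941L, rsid = "rs429358",
                   ref = "T", alt = "C", stringsAsFactors = FALSE))
}

.gt_string <- function(dosage) {
  c("0/0", "0/1", "1/1")[dosage + 1L]
}

#' Write cohort genotypes as a VCF v4.2 file
#'
#' Emits one biallelic record per score variant (ALT = effect allele) plus
#' rs7412 and rs429358 (ALT = the e2 / e4 tagging alleles), with a GT
#' column per participant. Dosages are ALT-allele counts.
#'
#' @param dosages Subjects x variants matrix of effect-allele dosages
#'   (columns named by rsid).
#' @param apoe APOE haplotype per subject (used to derive the rs7412 and
#'   rs429358 genotypes).
#' @param ldl_model,tg_model The [prs_model()]s defining the variants.
#' @param path Output file path.
#' @param sample_ids Sample column names, default rownames of `dosages`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(dosages, apoe, ldl_model, tg_model, path,
                      sample_ids = rownames(dosages)) {
  tab <- .variant_table(ldl_model, tg_model)
  n <- nrow(dosages)
  stopifnot(length(apoe) == n, !is.null(sample_ids))
  e2 <- vapply(strsplit(apoe, "e"), function(a) sum(a == "2"), integer(1))
  e4 <- vapply(strsplit(apoe, "e"), function(a) sum(a == "4"), integer(1))
  gmat <- matrix(character(0), nrow(tab), n)
  if (n > 0) {
    for (j in seq_len(nrow(tab))) {
      rs <- tab$rsid[j]
      d <- if (rs == "rs7412") e2 else if (rs == "rs429358") e4 else
        as.integer(round(dosages[, rs]))
      gmat[j, ] <- .gt_string(d)
    }
  }
  header <- c("##fileformat=VCFv4.2",
              "##source=atherolip",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(tab)), function(j) {
    paste(c(tab$chrom[j], tab$pos[j], tab$rsid[j], tab$ref[j], tab$alt[j],
            ".", "PASS", ".", "GT", gmat[j, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read effect-allele dosages from a VCF
#'
#' Parses the VCF with `VariantAnnotation::readVcf` and returns the
#' subjects x variants dosage matrix oriented to the model effect alleles:
#' when a model's effect allele is the REF allele of the record, the
#' ALT-allele dosage is flipped to `2 - d` (the standard PRS orientation
#' pitfall). Variants whose alleles match neither orientation are an
#' error.
#'
#' @param path VCF file.
#' @param ldl_model,tg_model [prs_model()]s whose rsids are looked up.
#' @return List with `dosages` (subjects x model variants, effect-allele
#'   oriented) and `apoe` (haplotype per subject called from
#'   rs7412/rs429358).
#' @export
read_genotypes <- function(path, ldl_model, tg_model) {
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF carries no GT field: ", path)
  rsids <- rownames(gt)
  alt_count <- function(g) {
    vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), integer(1))
  }
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- vapply(VariantAnnotation::alt(vcf), function(a)
    as.character(a)[1], character(1))
  model_tab <- rbind(ldl_model$variants, tg_model$variants)
  model_tab <- model_tab[!duplicated(model_tab$rsid), ]
  missing_rs <- setdiff(model_tab$rsid, rsids)
  if (length(missing_rs)) {
    stop("VCF is missing score variants: ",
         paste(utils::head(missing_rs, 5), collapse = ", "))
  }
  n_samp <- ncol(gt)
  dos <- matrix(NA_real_, n_samp, nrow(model_tab),
                dimnames = list(colnames(gt), model_tab$rsid))
  for (k in seq_len(nrow(model_tab))) {
    rs <- model_tab$rsid[k]
    j <- match(rs, rsids)
    d <- alt_count(gt[j, ])
    if (model_tab$effect_allele[k] == alt[j]) {
      dos[, k] <- d
    } else if (model_tab$effect_allele[k] == ref[j]) {
      dos[, k] <- 2 - d
    } else {
      stop("effect allele of ", rs, " matches neither REF nor ALT")
    }
  }
  apoe <- rep(NA_character_, n_samp)
  j2 <- match("rs7412", rsids); j4 <- match("rs429358", rsids)
  if (!is.na(j2) && !is.na(j4)) {
    c2 <- alt_count(gt[j2, ]); c4 <- alt_count(gt[j4, ])
    apoe <- vapply(seq_len(n_samp), function(i)
      suppressWarnings(call_apoe_haplotype(c2[i], c4[i])), character(1))
  }
  list(dosages = dos, apoe = apoe)
}

#' Write a complete synthetic fixture set
#'
#' Writes `genotypes.vcf`, `phenotypes.csv`, `ultrasound.csv` and the two
#' coefficient tables (`prs_ldl.csv`, `prs_tg.csv`) into `out_dir`. The
#' files round-trip losslessly through [read_genotypes()],
#' [read_phenotypes()] and [read_ultrasound()].
#'
#' @param reference A [generate_reference_population()] result.
#' @param cohort Output of [generate_cohort()] (dosages attached).
#' @param records Output of [generate_ultrasound()] (may be NULL).
#' @param out_dir Output directory, created if needed.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(reference, cohort, records, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- c(vcf = file.path(out_dir, "genotypes.vcf"),
             phenotypes = file.path(out_dir, "phenotypes.csv"),
             ultrasound = file.path(out_dir, "ultrasound.csv"),
             prs_ldl = file.path(out_dir, "prs_ldl.csv"),
             prs_tg = file.path(out_dir, "prs_tg.csv"))
  dos <- attr(cohort, "dosages")
  if (nrow(cohort)) {
    write_vcf(dos, cohort$apoe, reference$ldl_model, reference$tg_model,
              paths["vcf"], sample_ids = cohort$id)
  } else {
    write_vcf(matrix(numeric(0), 0, 0), character(0), reference$ldl_model,
              reference$tg_model, paths["vcf"], sample_ids = character(0))
  }
  utils::write.csv(as.data.frame(cohort), paths["phenotypes"],
                   row.names = FALSE, na = "")
  if (is.null(records)) {
    records <- data.frame(participant_id = character(0), territory = character(0),
                          side = character(0), site = character(0),
                          segment = character(0), surrounding_imt = numeric(0),
                          height = numeric(0), encroachment = numeric(0),
                          residual_lumen_area = numeric(0),
                          original_lumen_area = numeric(0))
  }
  utils::write.csv(records, paths["ultrasound"], row.names = FALSE, na = "")
  utils::write.csv(reference$ldl_model$variants, paths["prs_ldl"],
                   row.names = FALSE)
  utils::write.csv(reference$tg_model$variants, paths["prs_tg"],
                   row.names = FALSE)
  invisible(paths)
}

#' Read a phenotype table written by [write_fixtures()]
#' @param path CSV path.
#' @return data.frame with typed columns (logical flags, numeric lipids).
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (col in c("hypertension", "diabetes", "tendon_xanthomas", "ldl_direct",
                "chd")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' Read an ultrasound record table written by [write_fixtures()]
#' @param path CSV path.
#' @return data.frame of plaque/site rows.
#' @export
read_ultrasound <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}
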
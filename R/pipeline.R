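#' Run configuration for the end-to-end pipeline
#'
#' @param vcf,phenotypes Paths to the genotype VCF and phenotype CSV
#'   (required).
#' @param ultrasound Path to the ultrasound CSV, or NULL to skip the
#'   plaque stage.
#' @param prs_ldl,prs_tg Coefficient CSV paths; NULL uses the shipped
#'   synthetic defaults.
#' @param reference_n,reference_seed Size and seed of the simulated
#'   reference population used for percentile stratification when no
#'   measured reference is available.
#' @param seed Analysis seed (Monte-Carlo stages).
#' @param thresholds [class_thresholds()].
#' @return List of class `run_config`.
#' @export
run_config <- function(vcf, phenotypes, ultrasound = NULL,
                       prs_ldl = NULL, prs_tg = NULL,
                       reference_n = 1858, reference_seed = 1, seed = 1,
                       thresholds = class_thresholds()) {
  for (p in c(vcf, phenotypes, ultrasound, prs_ldl, prs_tg)) {
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  }
  structure(list(vcf = vcf, phenotypes = phenotypes, ultrasound = ultrasound,
                 prs_ldl = prs_ldl, prs_tg = prs_tg,
                 reference_n = reference_n, reference_seed = reference_seed,
                 seed = seed, thresholds = thresholds),
            class = "run_config")
}

.hyperlipidemia_groups <- c("FD", "FH", "POLY_HCL", "SEVERE_HCL")

#' Run the full analysis pipeline
#'
#' Stages: read inputs, score genotypes and call APOE haplotypes, rank
#' against a (simulated) reference population, harmonize lipids, classify
#' participants, aggregate ultrasound metrics, and run the comparison
#' battery (Kruskal-Wallis omnibus across the hyperlipidemia groups,
#' covariate-adjusted pairwise contrasts, and single-factor comparisons
#' against the control group). Deterministic for a fixed config.
#'
#' @param config A [run_config()].
#' @return List of class `study_report` with elements `participants`,
#'   `classification`, `plaque_metrics`, `group_summaries`, `comparisons`
#'   and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ldl_model <- if (is.null(config$prs_ldl)) default_prs_model("LDL_C") else
    read_prs_model(config$prs_ldl, "LDL_C")
  tg_model <- if (is.null(config$prs_tg)) default_prs_model("TG") else
    read_prs_model(config$prs_tg, "TG")

  geno <- read_genotypes(config$vcf, ldl_model, tg_model)
  pheno <- read_phenotypes(config$phenotypes)
  if (!all(pheno$id %in% rownames(geno$dosages))) {
    stop("phenotype ids missing from VCF: ",
         paste(utils::head(setdiff(pheno$id, rownames(geno$dosages)), 5),
               collapse = ", "))
  }
  dos <- geno$dosages[pheno$id, , drop = FALSE]

  reference <- generate_reference_population(
    n = config$reference_n, ldl_model = ldl_model, tg_model = tg_model,
    seed = config$reference_seed)

  ldl_raw <- as.numeric(dos[, ldl_model$variants$rsid, drop = FALSE] %*%
                          ldl_model$variants$beta)
  apoe <- geno$apoe[match(pheno$id, rownames(geno$dosages))]
  pheno$apoe <- apoe
  pheno$prs_ldl_score <- final_ldl_score(ldl_raw, apoe, ldl_model)
  pheno$prs_tg_score <- as.numeric(dos[, tg_model$variants$rsid, drop = FALSE] %*%
                                     tg_model$variants$beta)
  pheno$prs_ldl_band <- stratify(percentile_rank(pheno$prs_ldl_score,
                                                 reference$ldl_bands),
                                 reference$ldl_bands)
  pheno$prs_tg_band <- stratify(percentile_rank(pheno$prs_tg_score,
                                                reference$tg_bands),
                                reference$tg_bands)

  pheno <- harmonize_lipids(pheno)
  classification <- classify_cohort(pheno, config$thresholds)
  pheno$group <- classification$group

  metrics <- NULL
  if (!is.null(config$ultrasound)) {
    records <- read_ultrasound(config$ultrasound)
    if (nrow(records)) metrics <- plaque_metrics(records)
  }

  grp <- pheno$group
  in_study <- grp %in% .hyperlipidemia_groups
  summaries <- lapply(split(pheno, grp), function(g) {
    list(n = nrow(g),
         age = summarize_values(g$age), bmi = summarize_values(g$bmi),
         ldl_pretreat = summarize_values(g$ldl_pretreat),
         hdl = summarize_values(g$hdl_c), tg = summarize_values(g$tg),
         lpa = if (any(!is.na(g$lpa))) summarize_values(g$lpa) else NULL,
         male = sum(g$sex == "M"), statin = sum(g$statin_user),
         chd = sum(g$chd), hypertension = sum(g$hypertension),
         diabetes = sum(g$diabetes),
         smoking_current = sum(g$smoking == "current"),
         smoking_ex = sum(g$smoking == "ex"),
         high_ldl_prs = sum(g$prs_ldl_band == "HIGH", na.rm = TRUE),
         high_tg_prs = sum(g$prs_tg_band == "HIGH", na.rm = TRUE))
  })

  comparisons <- list()
  study_groups <- intersect(.hyperlipidemia_groups, unique(grp))
  if (length(study_groups) >= 2) {
    sg <- pheno[in_study, ]
    covars_lipid <- data.frame(sex = as.integer(sg$sex == "M"), age = sg$age)
    for (var in c("ldl_pretreat", "hdl_c", "tg")) {
      comparisons[[paste0(var, "_omnibus")]] <-
        kruskal_wallis(split(sg[[var]], sg$group))
      comparisons[[paste0(var, "_pairwise")]] <-
        adjusted_pairwise_contrasts(sg[[var]], sg$group, covars_lipid)
    }
    comparisons$lpa_pairwise <- tryCatch(
      adjusted_pairwise_contrasts(sg$lpa, sg$group, NULL),
      error = function(e) NULL)
    covars_full <- data.frame(sex = as.integer(sg$sex == "M"), age = sg$age,
                              bmi = sg$bmi,
                              hypertension = as.integer(sg$hypertension),
                              diabetes = as.integer(sg$diabetes),
                              smoking = as.integer(sg$smoking != "never"),
                              statin_months = ifelse(is.na(sg$statin_months_pre_us),
                                                     0, sg$statin_months_pre_us))
    comparisons$chd_pairwise <- adjusted_pairwise_contrasts(
      sg$chd, sg$group, covars_full)
    if (!is.null(metrics)) {
      m <- metrics[metrics$territory == "CAROTID", ]
      m <- m[match(sg$id, m$participant_id), ]
      for (var in c("plaque_number", "total_stenosis", "plaque_score")) {
        ok <- !is.na(m[[var]])
        comparisons[[paste0("carotid_", var, "_pairwise")]] <-
          adjusted_pairwise_contrasts(m[[var]][ok], sg$group[ok],
                                      covars_full[ok, , drop = FALSE])
      }
    }
  }
  if ("CONTROL" %in% grp && length(study_groups)) {
    keep <- grp %in% c(study_groups, "CONTROL")
    comparisons$ldl_vs_control <- single_factor_comparison(
      pheno$ldl_pretreat[keep], grp[keep])
    comparisons$chd_vs_control <- single_factor_comparison(
      factor(pheno$chd[keep]), grp[keep])
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("atherolip")),
    seed = config$seed, reference_seed = config$reference_seed,
    reference_n = config$reference_n,
    inputs = unlist(config[c("vcf", "phenotypes", "ultrasound")]))

  structure(list(participants = pheno, classification = classification,
                 plaque_metrics = metrics, group_summaries = summaries,
                 comparisons = comparisons, provenance = provenance),
            class = "study_report")
}

#' Format a clinical-characteristics table from a study report
#'
#' One row per clinical variable, one column per group plus an "All"
#' column pooling the four hyperlipidemia groups; counts as
#' `"n (percent)"`, continuous variables as `"median (Q1; Q3)"`. Groups
#' with no members are omitted with a warning.
#'
#' @param report A [run_pipeline()] result.
#' @return data.frame of formatted strings.
#' @export
make_clinical_table <- function(report) {
  s <- report$group_summaries
  groups <- intersect(c(.hyperlipidemia_groups, "CONTROL"), names(s))
  absent <- setdiff(c(.hyperlipidemia_groups, "CONTROL"), groups)
  if (length(absent)) {
    warning("omitting empty group column(s): ", paste(absent, collapse = ", "))
  }
  study <- intersect(.hyperlipidemia_groups, groups)
  pool <- report$participants[report$participants$group %in% study, ]
  n_all <- nrow(pool)
  fmt_med <- function(sv) sprintf("%.1f (%.1f; %.1f)", sv$median, sv$q1, sv$q3)
  col_for <- function(g) {
    x <- s[[g]]
    c(n = as.character(x$n),
      male = count_percent(x$male, x$n),
      age = fmt_med(x$age), bmi = fmt_med(x$bmi),
      smoking_current = count_percent(x$smoking_current, x$n),
      smoking_ex = count_percent(x$smoking_ex, x$n),
      hypertension = count_percent(x$hypertension, x$n),
      diabetes = count_percent(x$diabetes, x$n),
      statins = count_percent(x$statin, x$n),
      high_ldl_prs = count_percent(x$high_ldl_prs, x$n),
      high_tg_prs = count_percent(x$high_tg_prs, x$n))
  }
  all_col <- c(n = as.character(n_all),
               male = count_percent(sum(pool$sex == "M"), n_all),
               age = fmt_med(summarize_values(pool$age)),
               bmi = fmt_med(summarize_values(pool$bmi)),
               smoking_current = count_percent(sum(pool$smoking == "current"), n_all),
               smoking_ex = count_percent(sum(pool$smoking == "ex"), n_all),
               hypertension = count_percent(sum(pool$hypertension), n_all),
               diabetes = count_percent(sum(pool$diabetes), n_all),
               statins = count_percent(sum(pool$statin_user), n_all),
               high_ldl_prs = count_percent(sum(pool$prs_ldl_band == "HIGH",
                                                na.rm = TRUE), n_all),
               high_tg_prs = count_percent(sum(pool$prs_tg_band == "HIGH",
                                               na.rm = TRUE), n_all))
  cols <- c(list(All = all_col), lapply(stats::setNames(groups, groups), col_for))
  out <- as.data.frame(cols, stringsAsFactors = FALSE)
  out <- cbind(parameter = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Detectable-effect power table
#'
#' One [detectable_difference()] evaluation per row of `params`.
#'
#' @param params data.frame with columns `parameter`, `n1`, `n2`, `sd`
#'   (standard deviations must be supplied by the user).
#' @param alpha,power Test size and target power.
#' @return `params` with a `detectable_difference` column appended.
#' @export
power_report <- function(params, alpha = 0.05, power = 0.80) {
  if (!nrow(params)) {
    params$detectable_difference <- numeric(0)
    return(params)
  }
  stopifnot(all(c("parameter", "n1", "n2", "sd") %in% names(params)))
  if (any(is.na(params$sd))) stop("sd must be supplied for every parameter")
  params$detectable_difference <- mapply(
    detectable_difference, n1 = params$n1, n2 = params$n2, sd = params$sd,
    MoreArgs = list(alpha = alpha, power = power))
  params
}
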
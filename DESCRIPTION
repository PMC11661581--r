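Package: atherolip
Title: Genetic Atherogenic Hyperlipidemia Classification and Comparison
Version: 0.1.0
Authors@R: person("Pipeline", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the comparative analysis of genetically based
    atherogenic hyperlipidemias. Computes weighted polygenic risk scores
    (PRS) for LDL cholesterol and triglycerides with APOE haplotype
    adjustment, calls APOE epsilon haplotypes from rs7412/rs429358
    genotypes, harmonizes lipid panels (Friedewald LDL-C, statin
    back-correction to pretreatment levels, Lp(a) banding, Dutch Lipid
    Clinic Network scoring), classifies participants into familial
    dysbetalipoproteinemia, familial hypercholesterolemia, polygenic,
    severe hypercholesterolemia and control groups, quantifies carotid
    and femoral atherosclerosis from plaque-level ultrasound records,
    and runs the nonparametric group-comparison battery (exact
    Mann-Whitney and Fisher tests, Kruskal-Wallis, Holm step-down,
    covariate-adjusted median-split logistic contrasts, noncentral-t
    power analysis). Includes a seeded synthetic cohort generator so the
    whole pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
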
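---
title: "Models and methods behind atherolip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind atherolip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atherolip)
```

# Scope

`atherolip` implements a comparative-analysis pipeline for genetically
based atherogenic hyperlipidemias: familial dysbetalipoproteinemia (FD),
familial hypercholesterolemia (FH), polygenic hypercholesterolemia
(HCL), severe HCL, and lipid-normal controls. The pipeline covers
genotype-derived polygenic risk scores (PRS) with APOE haplotype
adjustment, rule-based participant classification, lipid harmonization,
carotid/femoral plaque quantification, a nonparametric comparison
battery, and a seeded synthetic-cohort generator that makes every stage
testable without patient data.

# Genetic scores and stratification

The weighted PRS for a trait is the allele-dosage sum
$S = \sum_i \beta_i d_i$ over the score variants, $d_i \in \{0,1,2\}$
counted on the effect allele. For LDL-C the final genetic score adds an
APOE haplotype increment: $-0.9$ (e2e2), $-0.4$ (e2e3), $-0.2$ (e2e4),
$0$ (e3e3), $+0.1$ (e3e4), $+0.2$ (e4e4). APOE haplotypes are called
from two SNPs: the rs7412 alternate allele tags epsilon-2 and the
rs429358 alternate allele tags epsilon-4; remaining chromosomes are
epsilon-3. The rs7412/rs429358 double heterozygote is phase-ambiguous
(e2e4 versus the essentially absent e1e3 configuration) and is assigned
e2e4 with a warning, matching standard practice.

Stratification is relative to a reference population: HIGH means
strictly above the 80th percentile of the reference score distribution,
LOW strictly below the 50th. Because band membership must be exactly
reproducible, the percentile convention is fixed: the percentile of $x$
is $100\,(\#\{r < x\} + \tfrac12\#\{r = x\})/n$ (mid-distribution rank).
Applied to a tie-free reference sample itself this flags exactly 20%
HIGH and 50% LOW, which is what the acceptance suite asserts.

The published 57-variant LDL-C and 40-variant TG weight tables are not
redistributable from the source material; the package ships clearly
synthetic coefficient tables (`prs_*_synthetic.csv`: uniform allele
frequencies in 0.05--0.95, log-normal effect magnitudes around 0.06--0.07
per allele, random sign). They exercise the machinery with a realistic
score spread relative to the ±0.9 APOE increments; real analyses should
supply their own tables via `read_prs_model()`.

Effect-allele orientation against a VCF is resolved by allele matching:
if the model's effect allele is the record's REF, the ALT dosage is
flipped to $2-d$. Missing dosages are refused by default; optional
imputation uses the Hardy-Weinberg mean $2f$ because silent imputation
would shift percentile bands.

# Lipid harmonization and classification

LDL-C is computed by the Friedewald formula in mmol/L
($\mathrm{LDL} = \mathrm{TC} - \mathrm{HDL} - \mathrm{TG}/2.2$), valid
only for TG $\le 4.5$ mmol/L; above that a direct measurement is
required and the function refuses. For statin users (therapy for more
than 1 month before the ultrasound, or 3 months or longer historically)
the measured LDL-C is back-corrected to a pretreatment estimate by
dividing by $1-r$, where $r$ is the average relative reduction at the
atorvastatin-equivalent dose. The equivalence and dose-response tables
are editable CSVs shipped with standard published values (atorvastatin
10/20/40/80 mg $\to$ 37/43/49/55% LDL-C reduction; rosuvastatin twice,
simvastatin half the atorvastatin potency, linear interpolation between
listed doses). HDL-C and TG are never recalculated.

The Dutch Lipid Clinic Network (DLCN) score sums the highest-scoring
satisfied item per category (family history, clinical history, physical
signs, LDL-C band, causal mutation), with "definite" FH at $\ge 9$
points. The point table is a versioned CSV fixture, not hard-coded.

Classification is a fixed-order rule cascade with exclusions first:

1. **EXCLUDED** -- pathogenic/likely-pathogenic (P/LP) variant in a panel
   gene outside LDLR/APOB/PCSK9/APOE; an FH-gene P/LP variant together
   with the e2e2 haplotype; or two or more P/LP variants across those
   genes.
2. **FD** -- e2e2 and measured TG $\ge 1.5$ mmol/L (TG is never
   back-corrected).
3. **FH** -- FH-gene P/LP variant and DLCN $\ge 9$ (on pretreatment
   LDL-C).
4. **POLY_HCL** -- pretreatment LDL-C $> 4.9$ mmol/L, HIGH PRS band, no
   tendon xanthomas.
5. **SEVERE_HCL** -- same but LOW band.
6. **CONTROL** -- no causal variant, LOW band, LDL-C $< 3.0$ and TG
   $< 1.5$ mmol/L.
7. **UNCLASSIFIED** otherwise; missing required inputs always yield
   UNCLASSIFIED with an explicit reason, never a silent label.

Design choices worth noting: the precedence (FD before FH before the
polygenic/severe split) mirrors the inclusion-list order with exclusions
overriding everything, since the exclusion criteria are stated as
absolute. A variant of uncertain significance is *not* treated as
causal: it neither excludes a participant nor blocks the control label.
Participants sequenced on the reduced 6-gene panel can still be labelled
CONTROL but the label carries a `reduced_panel` flag, because a 6-gene
screen cannot establish the full no-causal-variant criterion; the
package records the provenance rather than guessing. The panel gene list
itself is configuration (`panel_genes_24()`), since the source material
is internally inconsistent about its size.

# Ultrasound quantification

A measurement is a plaque when it encroaches $\ge 0.5$ mm into the
lumen, or $\ge 50\%$ of the surrounding intima-media thickness, or is
$\ge 1.5$ mm thick. Stenosis follows the European Carotid Surgery Trial
area convention, $(1 - A_{res}/A_{orig}) \times 100$; although the
narrative around the measurement speaks of "diameter" stenosis, the
stated formula uses areas and the area form is implemented.

Per territory (carotid or femoral, six sites each: CCA/bifurcation/ICA
and CFA/bifurcation/SFA, both sides) five aggregates are computed over
qualifying plaques only: plaque number (count), per-artery maximum
stenosis taken at the site of maximum obstruction with the overall
maximum and the **sum of per-artery maxima** as total stenosis (which
can therefore exceed 100%), maximum plaque height, and the plaque score
-- the sum over the eight scoring segments (ICA segment, bulb, two
distal CCA segments, per side) of the per-segment maximum plaque
thickness. Reading "sum of all maximum stenoses" as per-artery rather
than per-plaque maxima is the interpretation consistent with a median
total of ~106% arising from a handful of diseased arteries. The
bifurcation site maps to the bulb scoring segment.

# The synthetic cohort generator

The generator's defaults are the stated world of the analysis: group
sizes 29/61/49/41/144; lipid log-normals matched to the printed medians
(FD TG 4.10, FD LDL-C 3.57, FD HDL-C 1.03, FH pretreatment LDL-C 8.03
mmol/L), right-skew being evident from the printed quartile asymmetry;
CHD Bernoulli frequencies 31.0/29.5/6.1/7.3/2.8% with onset medians 40
and 44 years for FD and FH; the printed demographic frequencies; statin-use
frequencies per group with measured LDL-C derated through the same
dose-response table the harmonizer inverts. Where no value is printed
(e.g. polygenic-group LDL-C median, HDL-C for non-FD groups, Lp(a)
spreads) a single clinically plausible choice was made once (polygenic
5.6, severe 5.3, control 2.5 mmol/L LDL-C; HDL-C 1.20-1.45 rising from
FH to control; log-normal Lp(a) with sdlog 1) and not revisited.

Every generated participant satisfies its intended group's defining
predicates *by construction*: FD members get e2e2 and TG truncated at
1.54; FH members one P/LP FH-gene variant and LDL-C $\ge 4$ (so causal
mutation + LDL band always reach DLCN 9); polygenic and severe members
have genotype vectors rejection-sampled into the HIGH/LOW band of the
reference score; controls are variant-free, LOW-band, with LDL-C and TG
truncated below their cut-offs. The truncations shift medians by well
under the 10% Monte-Carlo tolerance (the largest, polygenic LDL-C, has
no printed target). Label recovery by the classifier is therefore exact,
and the acceptance suite asserts 100% concordance.

Ultrasound severity is a per-group Poisson plaque rate per territory
with log-normal heights (encroachment set equal to height so every drawn
plaque passes the plaque rule) and log-normal per-plaque stenoses capped
at 95%. The FH carotid constants (rate 4, height median 1.76 mm,
stenosis median 33%) were fixed by one-time moment matching against the
printed FH carotid medians (4 plaques, 106% total stenosis, 5.93 mm
plaque score); other groups use rate 2 (study groups) and 0.3--0.4
(controls), preserving the printed ordering FH > other study groups >
control on carotid burden.

What the generator does **not** emulate: linkage disequilibrium between
score variants, the enrichment of high TG-PRS carriers within FD,
secondary causes of dysbetalipoproteinemia, longitudinal lipid
trajectories, or measurement error correlated across sites. A green
calibration test therefore establishes that the pipeline arithmetic and
the distributional calibration are right, not that the generator is a
faithful epidemiological model.

Reproducibility: one master seed per `cohort_spec`; each generator stage
derives a sub-stream (`seed*1009 + offset mod 2^31-1`), so fixtures are
byte-identical across runs and independent across stages.

# Statistical engine

All tests are two-sided. The Mann-Whitney U uses pooled midranks; for
combined $n \le 20$ the exact permutation p-value is computed by
enumeration (fraction of label assignments with $|U - n_1 n_2/2|$ at
least the observed), otherwise the tie-corrected normal approximation
without continuity correction. Kruskal-Wallis uses the tie-corrected
$H$ with a $\chi^2_{k-1}$ p-value; an all-tied input degenerates to
$p = 1$ with a warning. Fisher's exact test uses the point-probability
("sum of no-more-likely tables") two-sided convention -- the dominant
convention, fixed so enumeration oracles match. For r x c tables the
same rule is applied by exhaustive enumeration when a cheap composition
bound on the table space is below $10^6$, otherwise by seeded
Monte-Carlo (Patefield sampling) with a reported standard error. Holm's
step-down is $\tilde p_{(i)} = \max_{j\le i}\min(1,(m-j+1)p_{(j)})$
returned in input order.

The covariate-adjusted contrasts mirror the source design: a continuous
outcome is discretized at the whole-sample median, and for each group
pair a logistic model of the indicator on the pair dummy plus covariates
yields a Wald p-value, Holm-adjusted over the family. The model is
abandoned for the unadjusted Mann-Whitney (flagged `fallback_used`) on
non-convergence, separation (fitted probability within $10^{-8}$ of 0/1
or a coefficient beyond 15), or fewer than 5 events/non-events in either
group -- the "low event count" fallback. The statin-duration covariate
is encoded as continuous months (the user can substitute the binary
user flag). Control-group comparisons use single-factor tests only
(Mann-Whitney / Fisher), reflecting the sparse-event situation there.

Quantiles everywhere (medians, quartiles, the discretization median) use
linear interpolation (R type 7), fixed and documented.

Power analysis inverts the noncentral-t power function: the detectable
difference is the root of
$\mathrm{power}(\Delta) = 1 - F_{t,\nu,\lambda}(t_c) +
F_{t,\nu,\lambda}(-t_c) = 0.8$ with
$\lambda = \Delta/(s\sqrt{1/n_1+1/n_2})$, $\nu = n_1+n_2-2$, solved by
`uniroot` to $10^{-10}$; inverse-consistency to $10^{-6}$ is asserted.
Group standard deviations are user inputs -- the source reports only the
resulting detectable effects, not the SDs behind them, so those numbers
are not reproducible and are not targets.

A note on type-I calibration: Fisher's exact test is intrinsically
conservative on discrete tables (its true size is below the nominal
level). The null-calibration acceptance test therefore uses large
balanced tables (1000 per arm, success probability 0.5), a design chosen
so the discreteness is small enough for the test's true size to sit
inside the $\alpha \pm 2\mathrm{SE}$ acceptance band at 2000
replicates. The residual gap to 0.05 is a property of the test, not an
implementation artefact.

# Numerical and degenerate-input choices

* Exact-vs-approximate Mann-Whitney cutoff: combined $n \le 20$
  (enumeration of at most $\binom{20}{10} \approx 1.8\times10^5$
  assignments).
* Fisher point-probability comparisons use a $1+10^{-7}$ relative
  tolerance, like the reference implementations, to absorb float noise.
* Logistic fits: IRLS with at most 50 iterations; diagnostics logged via
  the `fallback_used` flag rather than silent p-values.
* `pretreatment_ldl` refuses reduction fractions $\ge 1$; dose lookup
  extrapolates flat beyond the table range.
* Zero-variance rank tests return $p = 1$ with a warning rather than
  NaN.

# Known limitations

* The shipped PRS weights are synthetic; percentile thresholds computed
  from them are internally consistent but not transferable to real
  cohorts.
* FD is defined genetically plus a TG threshold; no
  ultracentrifugation/electrophoresis phenotype confirmation is
  modelled.
* The generator draws TG-score genotypes under Hardy-Weinberg
  independence, so the observed enrichment of high TG-PRS among FD
  patients is not reproduced.
* Partial retrospective ultrasound protocols (number/max/total stenosis
  only) propagate missing fields; the policy of including such
  participants is left to the caller.
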
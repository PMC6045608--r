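---
title: "Validating serum microRNA biomarkers of NAFLD severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating serum microRNA biomarkers of NAFLD severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seromir)
```

## The problem

Nonalcoholic fatty liver disease (NAFLD) spans a spectrum from simple
steatosis (NAFL) to steatohepatitis (NASH) and advanced fibrosis. Telling the
severe forms apart currently requires a liver biopsy, which is invasive and
error-prone; circulating microRNAs have repeatedly been proposed as
non-invasive alternatives, with limited agreement across studies. This
package implements the complete statistical workflow needed to validate such
serum miRNA biomarkers against biopsy-proven severity: qPCR quantification
and quality control, histological severity scoring, univariate group
comparisons, single-marker diagnostic evaluation, and cross-validated
multivariate classification. Because patient-level data of this kind are
rarely shared, the package also ships a synthetic cohort generator that
reproduces the statistical structure such a study assumes, so every stage is
testable end to end.

## Quantification model

Raw measurements are qPCR threshold cycles (Ct): the cycle at which the
amplification signal crosses detection, with one cycle equal to one doubling
of template, so lower Ct means more abundant miRNA. The pipeline applies the
standard relative-quantification model with an assumed amplification
efficiency of 2 (perfect doubling; no efficiency correction is attempted):

* **Detection QC.** A measurement is *detected* when Ct < 38 cycles. Assays
  detected in fewer than 90% of subjects are excluded — in the default
  synthetic panel this removes two assays whose baseline abundance sits at
  the detection limit, mirroring the fate of assays that fail to amplify in
  real serum panels. Undetected values are treated as missing, not imputed at
  the threshold: censoring-as-value would bias fold-changes toward the null.
  An `impute` mode exists for sensitivity analysis. Both thresholds are
  arguments of `detection_qc()`.
* **Reference normalization.** Each subject's target Ct is referenced to the
  arithmetic mean of two reference-miRNA Cts, which equals the log2 of the
  geometric mean of the reference abundances. Reference stability is
  checked with the geNorm measure: for assay $i$,
  $M_i = \mathrm{mean}_{j \ne i}\, \mathrm{sd}_s(Ct_{s,j} - Ct_{s,i})$,
  the average standard deviation of pairwise log-ratios across subjects;
  lower is more stable, and a stepwise trace removes the least stable assay
  down to the final pair. Missing values are handled pairwise-complete.
* **Relative levels.** $\Delta Ct_{s,a} = Ct_{s,a} - \overline{Ct}_{s,\mathrm{refs}}$,
  $\Delta\Delta Ct_{s,a} = \Delta Ct_{s,a} - \overline{\Delta Ct}_{\mathrm{control},a}$,
  $\mathrm{level}_{s,a} = 2^{-\Delta\Delta Ct_{s,a}}$. Levels are
  fold-changes against the control group's geometric mean, which is exactly
  1 by construction. The control reference uses the arithmetic mean of
  control $\Delta Ct$ (standard practice; the mean-vs-median choice is not
  prescribed by the underlying model).

## Severity scoring

Histology is scored on the two standard systems: NAS (steatosis 0–3 +
lobular inflammation 0–2 + ballooning 0–2, with 0–2 / 3–4 / 5–8 categories
and NAS ≥ 5 as definite NASH) and SAF activity (ballooning + inflammation,
with A ≥ 2 marking significant disease). Fibrosis stages F3–F4 define
advanced fibrosis. Lobular inflammation is stored on the 0–2 scale; a grade
of 3 (used by some NAS conventions) is accepted with a warning.

The serum comparator algorithms use their standard published formulas —
FIB-4 = age·AST/(platelets·√ALT), APRI = 100·(AST/ULN)/platelets (ULN
default 40 IU/L, configurable), BARD = [BMI ≥ 28] + 2·[AST/ALT ≥ 0.8] +
[diabetes], the NAFLD fibrosis score with its published coefficients, and
HOMA-IR = glucose·insulin/405. Category boundaries follow the printed
inequality conventions (1.30 for FIB-4, 1 for APRI, ≥ 2 for BARD, and
−1.455/−0.675/0.676 for NFS, taking −1.455 as the published cut-off where
printings disagree); a score exactly at a strict cut-off falls in the lower
bin.

## Univariate statistics

Two-group comparisons follow an adaptive policy: pooled-variance Student t
when both samples pass a Shapiro–Wilk normality screen and an F-test of
variance equality (both at 0.05, configurable), otherwise Mann–Whitney U.
Welch's t would be the usual remedy for normal-but-heteroscedastic data, but
the adaptive policy deliberately routes that case to the rank test; both
branches can be forced. Every result records the branch actually taken.
Fold-change testing is performed on the log2 level scale: $2^{-\Delta\Delta Ct}$
levels are log-normal by construction, so the normal-theory branch is valid
on the $\Delta\Delta Ct$ scale and would essentially never be selected on
the raw-ratio scale. The reported fold-change itself is the ratio of
arithmetic mean levels. p-values are reported raw across the panel (an
optional Benjamini–Hochberg adjustment is available but is not part of the
default workflow). Multi-group comparisons use one-way ANOVA with Tukey HSD;
categorical tables use Pearson's chi-square without continuity correction;
correlation switches between Pearson and Spearman on the same normality
screen.

## Diagnostic evaluation

Because some miRNAs rise with severity and others fall, ratios of induced
over repressed markers are first-class features: the default set crosses the
six induced (miR-34a, -27b, -22, -122, -192, -21) with the three repressed
(miR-30c, -16, -197) markers, 18 ratios named like `miR-34a/197`.

Single markers are evaluated with an empirical ROC at the observed values
(no midpoint interpolation — published cut-offs are on the observed scale
and this keeps them reproducible), ties stepped simultaneously, AUROC by the
trapezoidal rule (provably equal to the Mann–Whitney U statistic over
$n_1 n_0$ with ties counted one half). Marker orientation is auto-resolved
so AUROC ≥ 0.5 and recorded. The operating cut-off maximizes the Youden
index J = sensitivity + specificity − 1 over observed thresholds; ties break
toward higher sensitivity, then the lower cut-off. The metric panel
(sensitivity, specificity, PPV, NPV, PLR, NLR, accuracy) is computed from
the confusion counts with Clopper–Pearson exact intervals for proportions,
Simel log-method intervals for likelihood ratios (Haldane 0.5 correction at
zero cells), and Hanley–McNeil (default) or DeLong intervals for the AUROC.
The interval methods are stated choices: diagnostic-panel publications
rarely name theirs, and these are the standard defaults. Degenerate margins
return flagged missing metrics rather than errors, and a perfect
specificity reports PLR = ∞ explicitly.

## Multivariate classification

`plsda()` implements PLS1 discriminant analysis by NIPALS on autoscaled
predictors with the class coded 0/1 and called at the 0.5 midpoint (the
coding and threshold are symmetric defaults; a Youden-threshold mode on the
cross-validated scores exists because published sensitivity/specificity
pairs may derive from either). The fit is deterministic, successive score
vectors are orthogonal, and with as many latent variables as the predictor
rank it reproduces ordinary least squares — both properties are asserted in
the test suite, along with agreement to 1e-8 with an independent PLS
implementation.

Model complexity is chosen by leave-one-out cross-validation: the latent
variable count minimizing total misclassifications, ties to the smallest
count. Generalization is assessed on the pooled out-of-fold continuous
scores. Two leakage guards matter here: autoscaling *and* median imputation
are recomputed inside every training fold, and the ROC over CV scores uses
a fixed orientation (higher score = positive), since auto-orientation would
bias a null model's AUROC above 0.5.

One estimator property deserves note: pooled LOO scores carry a small
pessimistic bias of order $1/(n-1)$, because each held-out subject is
predicted with a training class-mean that tilts away from its own class. At
this study's dimensions (92 subjects, 33-variable panel) the measured null
AUROC is ≈ 0.496; at much smaller problems (say 30 × 8) it can reach ≈
0.45. The null-calibration test therefore runs at the study dimensions, and
CV AUROCs from small panels should be read with this bias in mind.

The default variable panels mirror a three-model comparison: 16 serum-based
clinical variables (age, BMI, glucose, triglycerides, total/HDL/LDL
cholesterol, bilirubin, albumin, platelets, ALT, AST, ɣ-GT, ALP, ferritin,
hemoglobin), 33 miRNA variables (16 detected assays + 17 ratios), and their
49-variable union. The 17-ratio set is the 18-ratio cross minus miR-21/16
— both members of that pair are general liver-injury responders also
altered in drug-induced liver injury, making it the least disease-specific
ratio; the panel composition is configuration, not inference, and can be
changed freely.

## The synthetic cohort generator

`default_cohort_spec()` encodes the study conditions: three groups of 17
normal-liver controls, 25 NAFL and 50 NASH subjects; group-wise clinical
means and standard deviations on their clinical units; histology grade
frequencies per group; and a 20-assay qPCR panel (18 targets + 2
references) with baseline Cts spanning the 24–39.5 cycle range so that the
serum band 28–37 (≈ 500-fold abundance span) is realistic, the references
are abundant and low-noise, and two assays sit beyond the detection limit.

Generation draws clinical variables independently from truncated normals
(redrawing at the physiologic floor of zero), sex as Bernoulli from the
group's female fraction, and histology grades independently per feature
from the group marginals with resampling until the group's defining
constraints hold: NASH requires steatosis, ballooning and inflammation all
≥ 1 (so SAF activity ≥ 2 for every NASH subject), NAFL requires activity
< 2 and NAS < 5. The joint histology distribution is not identifiable from
published marginals, so constrained independent sampling is a modeling
choice that preserves the marginals approximately while guaranteeing label
consistency. Ct values follow
$Ct = \mathrm{base} - \mathrm{log2\ effect(group)} + N(0, \sigma)$, censored
to missing at 38 cycles. Default effects are +1 log2 unit in NASH and +0.3
in NAFL for induced markers (negated for repressed ones) with 1 cycle of
target noise and 0.3 cycles of reference noise: the magnitudes are free
parameters (significance, not effect size, is what such studies report),
chosen once so that single-marker AUROCs land in the 0.7–0.85 range
typical of this literature. A DILI (drug-induced liver injury) comparator
spec provides 17 patients with liver-injury direction effects and no
histology. Identical `(spec, seed)` pairs reproduce cohorts bit for bit.

Deliberate simplifications, and what they imply for the tests:

* Clinical variables are mutually independent within group and independent
  of the histology grades. Real cohorts correlate AST with fibrosis stage
  within the diseased group, which is exactly what makes FIB-4 a strong
  within-NAFLD fibrosis predictor; the generator therefore *understates*
  the performance of composite clinical scores for within-group contrasts
  (FIB-4's AUROC for F > 2 comes out near 0.6 here versus ~0.85 in real
  data). A correlation hook would be the natural extension.
* Independent sampling of group marginals also understates between-subject
  overlap, so cross-validated AUROCs on the synthetic default (≈ 0.9) are
  optimistic relative to real cohorts (≈ 0.75–0.85). Passing tests
  demonstrate correctness of the machinery and qualitative orderings
  (combined ≥ miRNA-only panels), not real-data effect sizes.
* Missing NL insulin (not measured in such controls) is filled with a
  normal fasting value of 8 ± 4 µU/mL; diabetes/impaired fasting glucose is
  derived deterministically as fasting glucose ≥ 100 mg/dL rather than
  sampled, so the flag is consistent with the glucose draw.

## Simulation sizes and numerical choices

The test suite checks the direction-recovery property — each of the nine
validated miRNAs recovered with the correct sign at p < 0.05 in at least
95% of cohorts — with 10,000 replicates. The true per-marker rate under the
default conditions is ≈ 0.955–0.966 (calibrated once at 6,000 replicates),
close enough to the 0.95 bound that smaller designs would fail by
Monte-Carlo noise alone; at 10,000 replicates the estimator's standard
error (≈ 0.002) resolves the bound. Other simulation checks use 200
replicates (geNorm reference ranking, null CV calibration, binormal AUROC
agreement) or 25–30 (panel-ordering comparisons), sizes at which the
asserted margins are several Monte-Carlo standard errors wide.

Numerical conventions worth knowing: Ct values are validated to (0, 45);
all tie-breaks are deterministic (Youden: higher sensitivity then lower
cut-off; latent variables: smallest count); NIPALS stops early if the
residual class covariance is numerically zero and reports the components it
extracted; zero-variance predictors are an error in a direct `plsda()` fit
but are tolerated (unit scale, zero contribution) inside cross-validation
folds where a constant training column can arise by resampling; constant
samples route to the rank branch of the adaptive test rather than erroring.

## Limitations

Beyond the generator simplifications above: no PCR efficiency estimation or
inter-plate calibration; no smoothed/binormal ROC fitting; no sparse or
orthogonal PLS variants and no permutation p-values for model significance;
the DILI comparator reuses the two-group machinery and makes no causality
assessment. The multiple-testing default (raw p across a 16-assay panel)
follows the field's reporting convention and should be tightened for larger
panels.

## A minimal run

```{r pipeline, eval = FALSE}
sim <- generate_cohort(default_cohort_spec(), seed = 7)
res <- run_pipeline(sim$cohort, sim$ct,
                    config = default_pipeline_config(seed = 7))
res
res$fold_changes$saf_activity
res$markers$saf_activity[["miR-34a/197"]]
res$plsda$saf_activity$combined
```
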
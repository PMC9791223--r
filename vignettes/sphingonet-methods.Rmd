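---
title: "Methods: sphingolipid network analysis of metabolic syndrome"
author: "sphingonet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sphingolipid network analysis of metabolic syndrome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sphingonet)
```

# Scope and model

`sphingonet` analyzes a subjects × species serum sphingolipid abundance
matrix alongside a clinical table. Five lipid classes are distinguished:
dihydroceramides (DCER), ceramides (CER), sphingomyelins (SM),
hexosylceramides (HCER) and lactosylceramides (LCER). The analytical thread
is: classify metabolic syndrome (MetS), screen species for MetS-associated
abundance shifts, quantify covariate-adjusted associations, and compare the
*correlation structure* of the sphingolipidome across clinically defined
strata via distance networks.

## MetS classification

The updated ATPIII rule is used: a subject is MetS-positive when at least 3
of 5 components are abnormal — waist circumference > 102 cm (men) / > 88 cm
(women); triglycerides ≥ 150 mg/dL; HDL-c < 40 mg/dL (men) / < 50 mg/dL
(women); blood pressure ≥ 130 mmHg systolic or ≥ 85 mmHg diastolic; fasting
glucose ≥ 100 mg/dL. Each of the last four is alternatively satisfied by a
medication flag (for blood pressure, treatment with a hypertension
history). Strictness of each inequality follows the clinical definitions
above; all thresholds are overridable through `metsCriteria()`. The
classifier is monotone: worsening a component value can never remove a
diagnosis. Impaired glucoregulation is flagged when glucose > 100 mg/dL
*and* insulin ≥ 25 mIU/L; the inflammation stratification splits subjects
at the overall sample median of CRP, ties assigned to "low" (the definition
speaks of "below or above" the median; a deterministic convention is
required, and assigning the measure-zero tie set to "low" is the
conservative choice).

## Preprocessing

Species with 20% or more missing values are removed — the retention rule is
*strictly* less than 20%, so a species with exactly 20% missing is dropped.
Retained abundances are natural-log transformed (the transform base is
immaterial downstream: z-scoring absorbs it, and the network stage is
rank-based) and z-scored per species over non-missing entries; z-scoring
uses the full sample rather than analysis subgroups, which leaves the
Spearman-based networks untouched (any strictly monotone per-species
transform does). The two ratio biomarkers, CER/LCER and
(DCER + CER)/(HCER + LCER), are computed on **raw** class totals before any
transformation; class totals sum the non-missing species only — no
imputation is attempted, and the < 20% missingness filter bounds the
resulting bias.

## Volcano screening

Species are screened between MetS groups on untransformed abundances: a
two-sided Wilcoxon rank-sum test and a fold-change threshold of 1.15 in
either direction (FC > 1.15 or FC < 1/1.15), flagged when both criteria
hold at p < 0.05. The Wilcoxon p-value is exact (from the null distribution
of U) whenever the smaller sample has ≤ 8 observations and there are no
ties, otherwise a tie-corrected, continuity-corrected normal approximation
is used. Fold change is the ratio of group *means* by default — the
standard volcano convention; a median variant is available via
`fcStat = "median"` and the choice is recorded in the output's metadata,
since the convention is not uniquely determined by the display.

## Association models

Linear models relate z-scored lipid exposures to z-scored, log-transformed
health biomarkers; logistic models relate them to MetS and its components,
reported as odds ratios per 1-SD increase with Wald 95% CIs (the default
inferential summary of standard GLM fits). Adjustment covariates are sex,
age, race and education (plus, optionally, MetS diagnosis in the linear
models); categorical covariates are dummy-coded against fixed reference
levels (sex "female", race "White", education "high school or less"), age
enters linearly in years. Complete-case analysis is used throughout — no
covariate imputation. Coefficient matrices mask cells with p ≥ 0.05 to 0,
the display convention for regression matrix plots. Logistic fitting is
IRLS to tolerance 1e-8 with at most 100 iterations; perfect or
quasi-separation is reported as an explicit error rather than returned as a
divergent estimate.

## Distance networks

Within each stratum, pairwise Spearman correlations (midrank ties,
pairwise-complete observations) are computed over the volcano-selected
species. Two-sided p-values come from the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df; an exact
permutation-enumeration p is available for pairs with ≤ 10 complete
observations. p-values are Benjamini–Hochberg adjusted over the
strictly-upper-triangle family *within* each stratum's matrix (each network
is built and interpreted per subgroup, so the family is per matrix, not
pooled). Coefficients with adjusted p ≥ 0.05 are set to 0; the distance is
$d = 1 - |\rho|$, so non-significant pairs sit at distance 1 and carry no
edge, and edge weights are $|\rho|$ — the only monotone weight consistent
with "shorter distance = stronger association".

Clustering is agglomerative greedy modularity optimization
(Clauset–Newman–Moore) on the weighted significant-edge graph: start from
singletons, repeatedly merge the connected cluster pair with the largest
modularity gain, and report the partition at the maximum modularity along
the merge path. Ties in the gain are broken toward the lexicographically
smallest cluster-index pair, which makes the procedure fully deterministic;
isolated nodes remain singletons. Modularity is the weighted Newman score
$Q = \frac{1}{2m}\sum_{ij}\left(w_{ij} - \frac{k_ik_j}{2m}\right)
\delta(c_i, c_j)$.

The distance between two lipid classes is the arithmetic mean of $d$ over
all cross-class species pairs. Differences in an interclass distance
between two strata are tested by permutation: subjects are pooled and
randomly reassigned to pseudo-strata of the original sizes, the full
pipeline (Spearman → BH → distance → mean) is recomputed each repetition
(1,000 by default), and the two-sided p-value uses add-one smoothing,
$p = (1 + \#\{|\Delta_{perm}| \ge |\Delta_{obs}|\})/(1 + n_{perm})$, so it
is never exactly 0. Plain label permutation preserving stratum sizes is
used; no covariate structure is preserved in the reassignment. Whole
networks are compared with a Steiger-type statistic: Fisher-z transform
each off-diagonal coefficient and form
$\chi^2 = \sum_{i<j} (z^{(1)}_{ij} - z^{(2)}_{ij})^2 /
(\tfrac{1}{n_1-3} + \tfrac{1}{n_2-3})$ on $k(k-1)/2$ df. Among the several
matrix-comparison variants in circulation, this Fisher-z χ² form is
implemented because it is exactly reconstructible from its definition,
reduces to the classical two-sample correlation z-test at $k = 2$, and is
calibrated under the null in simulation.

# The synthetic cohort generator

`generateCohort()` emulates a midlife US biomarker cohort so the pipeline
is fully testable. Its defaults are fixed study conditions, not tuning
knobs.

**Clinical variables.** The five ATPIII component scores are a one-factor
Gaussian model: $z_i = \sqrt{\lambda}f + \sqrt{1-\lambda}\,\varepsilon_i$
with shared-variance $\lambda = 0.5$, thresholded at a common latent
cut-off $\tau$. $\tau$ is calibrated by 1-D numerical integration so that
$P(\ge 3\text{ of }5) $ equals the target prevalence (default 0.375, the
published prevalence of the cohort this emulates); measured values are
monotone (exponential) transforms of the latent scores anchored exactly at
the clinical thresholds, so the *classifier*, not the generator, decides
the diagnosis — avoiding circularity — and sex-specific cut-offs are
honored by construction. Diastolic pressure is a deterministic linear
function of systolic so the blood-pressure component has a single latent
driver and the analytic calibration stays exact. Medication flags are
drawn only among subjects whose latent component is abnormal (30%), and
half of the medicated are "treated to target" with measured values pulled
below threshold — the override path of the classifier is exercised without
shifting prevalence. Inflammatory biomarkers (CRP, IL-6, fibrinogen,
sICAM) are lognormal with additive log-scale shifts in MetS subjects
(defaults +0.4, +0.3, +0.15, +0.1); sociodemographics are drawn
independently of disease status (age ~ N(55.7, 12.5²) truncated to 25–85,
sex 55% female, race 74.8% White, three education levels).

**Lipids.** Log-abundances are multivariate normal with within-class
correlation blocks (Spearman 0.6) and stratum-specific interclass targets,
then exponentiated (lognormal abundances, SD 0.5 on the log scale).
Correlation targets are specified on the *Spearman* scale — the scale the
downstream analysis measures — and converted to latent Pearson via
$\rho_P = 2\sin(\pi\rho_S/6)$; since exponentiation is monotone, rank
correlations survive to the abundance scale. The resulting latent
correlation matrix is validated positive-semidefinite at configuration
time, with the error naming an offending class pair when one is
identifiable from its two-block submatrix. MetS subjects' class means are
shifted on the log scale (defaults: DCER +0.2, CER +0.2, HCER −0.2, LCER
−0.25, SM 0), sized so that fold changes clear the 1.15 volcano threshold
for the ceramide-pathway classes while sphingomyelins stay null — the
qualitative signature the analysis is designed to recover. The default
stratum-specific interclass targets encode the qualitative differences the
stratified comparison should detect: a healthy reference stratum with
tight within-pathway coupling (DCER–CER and HCER–LCER at 0.5, cross pairs
0.1–0.15); high CRP without MetS strengthening the precursor→HCER link and
weakening HCER–LCER; MetS with low CRP strengthening DCER–CER only; and
MetS with high CRP tightening all four classes together. Missingness is
injected completely at random (default 5%) as a stand-in for
below-detection-limit losses; left-censoring at a detection limit is
deliberately *not* modeled — MCAR suffices to exercise the missingness
filter and the pairwise-complete correlation path, and a censoring
mechanism would distort the planted rank correlations that the tests rely
on.

**What passing tests do and do not show.** The generator produces clean
lognormal abundances with exchangeable subjects inside each stratum. Real
lipidomic data add batch effects, heavy tails, detection-limit censoring
(informative missingness), and covariate-correlated sampling, none of
which are emulated; passing tests demonstrate the *statistical machinery*
is correct and calibrated under the stated model, not that the pipeline is
robust to those artifacts.

# Numerical conventions and degenerate inputs

- Constant species make a Spearman coefficient undefined: a hard error
  naming the species, not a silent NA.
- Zero or negative abundances cannot be log-transformed: hard error; a
  constant species cannot be z-scored: hard error naming it.
- A species with fewer than 2 observations per group is skipped by the
  volcano screen with a warning.
- Strata smaller than 20 subjects are skipped by the pipeline with a
  warning rather than failing the run (correlation matrices at such sizes
  are noise); strata below 4 subjects are an error at the function level.
- The permutation p-value is two-sided via $|\Delta|$ with add-one
  smoothing; comparisons with the observed statistic use a 1e-12 tolerance
  so that exact ties (e.g. identical strata) count as "at least as
  extreme" and yield p = 1.
- All random draws go through seeded private RNG streams that restore the
  caller's RNG state; identical configuration and seed reproduce outputs
  bit-for-bit.

# Problem sizes used in the shipped studies

The packaged simulation studies use: prevalence calibration at
n = 10,000; planted-correlation recovery at n = 5,000; permutation-test
type-I calibration over 500 null cohorts of 200 subjects per stratum with
200 permutations each (the add-one smoothed p at 200 permutations rejects
at rate 10/201 ≈ 0.0497 under the null); power against interclass Spearman
0.6 vs 0.3 over 100 runs at 500 subjects per stratum; cluster-structure
recovery over 50 runs at n = 1,000; and greedy-vs-exhaustive modularity
on 200 random graphs of up to 8 nodes (4,140 partitions enumerated per
graph). These sizes give Monte-Carlo standard errors comfortably inside
the asserted bands.

# Known limitations

- Fold-change convention (means vs medians) is not uniquely determined by
  the exploratory display it feeds; both are offered and the choice is
  recorded.
- The Steiger comparison assumes independent strata and all
  $|\rho| < 1$; it tests equality of full correlation matrices, not of
  the thresholded networks derived from them.
- Complete-case association models can bias estimates when covariate
  missingness is informative.
- The generator's MCAR missingness understates the structure of real
  detection-limit censoring (see above).
- The normal-approximation Wilcoxon tail is accurate to ~0.02 only for
  samples of 5 or more per group; below that the exact enumeration path is
  always used in analysis.
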
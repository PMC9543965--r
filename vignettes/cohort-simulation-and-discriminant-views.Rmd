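---
title: "Simulating fibro-inflammatory cohorts and building discriminant views"
author: "fibrolens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating fibro-inflammatory cohorts and building discriminant views}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrolens)
```

## The scientific setting

People with type 2 diabetes (T2D) carry an excess heart-failure risk
long before symptoms appear, plausibly through inflammation-driven
interstitial myocardial fibrosis. A natural study design pairs a
case–control comparison (people with T2D vs matched healthy controls,
each phenotyped with cardiovascular MRI and a multiplexed plasma panel
of fibro-inflammatory biomarkers) with a three-arm randomised trial in
the cases (standard care, a low-energy meal-replacement plan, supervised
exercise; measurements before and after 12 weeks). The analysis then
asks two questions: do cases and controls separate in the joint
biomarker–phenotype space, and does an intervention move the treated
group back towards the healthy region?

`fibrolens` implements that analysis as a reusable, fully tested
pipeline. Because subject-level data from such trials are rarely
shareable, the package's first module is a *generator*: it simulates
cohorts whose distributional structure matches the per-group summary
statistics that publications do print, so every downstream stage can be
exercised, validated, and taught without any data access.

## The synthetic-cohort model

Each variable is described declaratively (`variable_spec`) by a role
(demographic, clinical, anthropometric, MRI, glycaemic, biomarker,
categorical), a family, and per-group parameters *on the modelled
scale*:

* **Biomarkers** are log10-normal: publications report them as
  log10 mean ± SD together with the back-transformed geometric
  mean (10^μ) and geometric SD (10^σ). The default panel holds the 23
  markers with published per-group values (units pg/ml).
* **Approximately normal clinical and MRI variables** (age, HbA1c,
  glucose, weight, BMI, blood pressures, LV volumes/strain, etc.) are
  Gaussian with the published mean ± SD per group.
* **Skewed variables reported as median (IQR)** (eGFR, LV
  mass:volume, left-atrial volume, aortic distensibility, E/e′) are
  modelled log10-normal with location `log10(median)` and scale solved
  in closed form from `IQR = median · (10^{zσ} − 10^{−zσ})`,
  `z = qnorm(0.75)` (`solve_log10normal_quartiles()`). This preserves
  the reported skew without inventing a new family.
* **Binary demographics** (sex, ethnicity, smoking history,
  hypertension) are Bernoulli at the published group proportions.

Two published rows are deliberately *not* defaulted: diabetes duration
(undefined for controls, so it cannot satisfy the rule that every group
has parameters) and late gadolinium enhancement (its printed format
does not identify a distribution). The published analysis used 75
variables in total; only the parameters above are printed, so the
default schema has 51 columns and the remainder are out of reach by
construction.

Design defaults are the published ones: 36 controls vs 83 cases, and
30/24/22 completers in the standard-care/MRP/exercise arms (76
completers, two rows each).

### Pre/post dependence and intervention effects

Within-subject dependence is a bivariate Gaussian per variable on the
modelled scale: follow-up = location + ρ·(baseline − location) +
√(1−ρ²)·scale·ε + arm effect. ρ defaults to 0.7 — trials of this kind
rarely report within-subject correlations, and 0.7 is a typical
repeat-measurement correlation for anthropometric and biochemical
variables over 12 weeks. With ρ = 1 and zero effects the follow-up
reproduces the baseline exactly, which the tests assert.

Default arm effects combine the published completer changes (MRP:
weight −13.6 kg, fasting glucose −1.9 mmol/L, systolic blood pressure
−13 mmHg; exercise: weight −1.6 kg, glucose −0.8 mmol/L) with a
*declared assumption* for the biomarker response, since per-arm
biomarker changes are not printed: the ten MRP-responsive markers that
have per-group parameters (leptin, adiponectin, FABP4, NGAL,
pentraxin 3, MMP2, MMP8, PAI1, VEGFR1, NTproANP) move 60% of the way
from the case location towards the healthy location on the log10 scale
— a marked shift that stops short of full normalisation, matching the
qualitative published finding; the exercise arm moves only MMP8. BMI
accompanies the MRP weight loss (−4.8 kg/m², i.e. −13.6 kg at the
cohort's implied height). These choices were made once, before any
testing, and are not tuning knobs.

Variables are mutually independent by default; `cohort_config(cor_matrix = )`
offers a Gaussian-copula hook for stress tests, because the published
cross-correlation matrices are not available to parameterise a default.
Missingness is MCAR only (`inject_missingness()`), masking each eligible
continuous cell independently and returning a mask so imputation error
can be scored; the publication states nothing about its missingness
mechanism, so MAR/MNAR are out of scope.

What the generator does *not* emulate: cross-variable correlation
structure (by default), assay floor/ceiling effects, batch effects, and
informative dropout. Tests passing on these cohorts therefore validate
the *statistical machinery*, not claims about real patients.

## Panel preparation

Biomarkers are analysed on the log10 scale (`log10_transform()`, which
refuses non-positive values by position) and summarised on both scales:
`back_transform(μ, σ)` returns the geometric mean 10^μ and geometric SD
10^σ. Standardisation (`fit_standardizer()` / `apply_standardizer()`)
subtracts the column mean and divides by the sample (n−1) SD — the
convention that standard statistics packages print, hence the one the
published summaries reflect — ignoring missing entries during fitting
and reporting (rather than silently dividing by) zero-variance columns.

`knn_impute()` fills each missing cell with the unweighted mean of the
target column among the k nearest rows. The distance between two rows is
the mean squared difference over the columns observed in both, which
keeps rows with different missingness patterns comparable; neighbours
must have the target column observed; ties break at the lower row index;
with no eligible neighbour the observed column mean is used and counted
as a fallback. k defaults to 5 and the neighbour mean is unweighted —
the reference implementation behind the published analysis is not
specified in its text, so these are explicit, documented substitutes.
Imputation operates on the standardised matrix (Euclidean-type distances
are meaningless across raw mixed units), and the suite checks the
implementation cell-for-cell against an exhaustive neighbour-search
oracle and verifies it beats column-mean imputation under correlated
structure.

## Group statistics

Case–control comparisons use Welch's t-test for parametric continuous
variables (the published text says only "independent t-tests";
recomputation from rounded summaries cannot distinguish pooled from
Welch, so the safer unequal-variance form is the default and the pooled
form a switch), Mann–Whitney otherwise, and Pearson chi-square for
categorical variables. Normality flagging is a Shapiro–Wilk test at
α = 0.05 on within-group-centred residuals — a deterministic surrogate
for visual histogram/Q–Q assessment — and can be overridden per
variable. Bonferroni correction is the plain `min(1, p·m)` with `m`
defaulting to the panel size actually tested.

Pre/post analysis is a change-score regression per arm: Δy on an
intercept plus nothing (Model 1), Δweight and baseline weight
(Model 2), or ΔHbA1c and baseline HbA1c (Model 3), reporting the
intercept's two-sided test. With two occasions this is the natural
single-arm operationalisation of a repeated-measures ANOVA with
covariates, and Model 1 reduces *exactly* to the paired t-test — an
identity the tests assert on every simulated arm. A degenerate fit with
zero residual variance reports statistic 0 and p = 1 when the intercept
is zero rather than NaN.

`classify_remission()` encodes remission as fasting glucose
< 7.0 mmol/L *or* HbA1c < 6.5% without glucose-lowering medication;
`convert_hba1c()` is the IFCC→NGSP master equation
(% = 0.09148 × mmol/mol + 2.152), which reproduces the paired
printed reporting of HbA1c in both unit systems.

## Latent views

**PCA.** Standardised variables are mean-centred and decomposed by SVD;
covariance eigenvalues are d²/(n−1), variance-explained fractions are
eigenvalue/trace, and subject scores are projections onto the leading
right singular vectors (three by default; more are available). Axis
signs are fixed deterministically (largest-magnitude loading positive).
The 3-D scores get a least-squares best-fit plane: through the
centroid, spanned by the two leading principal directions of the
scores, with a degeneracy flag for collinear input. Invariants under
test: orthonormal axes, non-increasing eigenvalues, fractions summing
to one, diagonal score covariance, rotation invariance of the spectrum.

**Fisher plane.** The horizontal axis is Fisher's linear discriminant
between pre- and post-intervention rows, `w ∝ (S_w + λI)⁻¹(m₂ − m₁)`
with S_w the pooled within-class scatter, normalised so the post class
projects larger. The ridge λ defaults to 10⁻³·trace(S_w)/p because the
variable count (~50) exceeds the per-arm sample size (22–30), making
S_w singular; λ = 0 on a singular system raises an error that names the
remedy. The vertical axis is the vector from the healthy-control centre
to the pre-intervention centre minus its projection onto the horizontal
axis, normalised — so "up" means "towards where the treated group
started relative to healthy", and the healthy/pre/post centres can be
read off one plot. Classification thresholds the horizontal coordinate
at the midpoint of the two projected class means (ties to the
nearer-mean class), and accuracy is resubstitution — no cross-validation,
matching how single per-group accuracies are conventionally reported
with this construction.

Two numerical caveats are worth stating plainly. First, the Fisher
direction is validated against a brute-force grid search over 10⁴
angles of the Fisher criterion on 2-D toys — the implementation must
match the maximiser to 0.1°. Second, resubstitution accuracy in the
p ≳ n regime is optimistic: with ~50 variables and ~24 subjects per
phase, even label-permuted data can be separated well. The permutation
null test therefore lives in a low-dimensional setting where chance
behaviour is identifiable, and the reported per-arm accuracies on
simulated cohorts should be read as descriptive of the view, not as
out-of-sample error.

## Problem sizes and determinism

Everything is seeded through `withr::with_seed`, so identical
configurations give bit-identical tables and byte-identical report
bundles (`run_report()` stamps every artifact with the seed and a
configuration hash). The test suite's Monte-Carlo checks use sizes
chosen to make their tolerances sharp but cheap: parameter recovery at
5,000–10,000 subjects per group (4 standard errors), arm-effect
recovery at 5,000 pairs, and 100-seed sweeps for the separation and
shift properties at the published cohort sizes.

## Known limitations

* Default parameters cover exactly the published values; the ~25
  unprinted panel variables of the original 75-variable analysis cannot
  be defaulted and are out of scope.
* The remission prevalence of a simulated MRP arm is an emergent
  property of the configured glucose shift (roughly 60% of subjects
  cross the threshold), not a calibration target; the published 83%
  arises from the rule's arithmetic on an arm where 20 of 24 subjects
  qualify, which is how the package reproduces it.
* Imputation is single-pass kNN; no multiple imputation or EM/MICE.
* No more than three groups per Fisher plane, and no inferential claims
  attach to the visualisations.
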
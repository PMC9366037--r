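---
title: "Methods: PET quantification and prognostic modeling in follicular lymphoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PET quantification and prognostic modeling in follicular lymphoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the scientific choices behind `flpet`: what each
stage computes, the exact conventions used where the literature leaves
room, and what the synthetic generators do and do not emulate.

## 1. SUV and lesion quantification

PET voxel values are converted to standardized uptake values by body
weight:

$$\mathrm{SUV} = \frac{\text{activity (Bq/mL)}}{\text{injected dose (Bq)} / \text{body weight (g)}}$$

`to_suv()` implements this directly; `pet_volume()` carries the voxel
grid, spacing (mm) and optional organ labels (liver, spleen, bone
marrow).

**Detection.** Candidate lesions are voxels with SUV at or above a
detection threshold (default 2.5, a common fixed absolute threshold for
lymphoma), grouped into 3D connected components under **26-connectivity**
(all face, edge and corner neighbors). 26-connectivity is the most
permissive standard choice and avoids splitting a diagonal lesion bridge
into two lesions.

**Delineation.** Each component is delineated with the fixed-threshold
isocontour at **41% of that component's SUVmax**, the threshold
historically validated for sphere volume recovery on phantoms. The mask
is the closed set `SUV >= 0.41 * SUVmax`, restricted to the connected
piece containing the component's peak voxel. Per lesion:

- MTV (cm³) = voxel count × voxel volume,
- SUVmean over the delineated voxels,
- TLG = MTV × SUVmean.

**Tie-break.** If several voxels share the component maximum, the peak
voxel is the first in column-major scan order. This makes the pipeline,
and the Dmax below, fully deterministic.

**Patient summary.** TMTV and patient TLG are sums over lesions; patient
SUVmax the maximum; **Dmax** is the largest pairwise Euclidean distance
between lesion peak voxels, in cm, defined as 0 when fewer than two
lesions exist. Lesion *centroids* may be used instead via
`compute_dmax(position = "centroid")`.

**Organ rules.** The spleen counts as involved if any detected lesion
peak lies in the spleen mask (focal) or if the spleen's mean SUV exceeds
150% of the liver's mean SUV (diffuse). Bone-marrow uptake contributes to
the volume metrics only when focal; `bone_marrow_filter()` drops diffuse
marrow components. Absent masks make these calls `NA` with a warning
rather than silently negative.

## 2. Optimal cutpoints for continuous features

`optimal_cutoff()` scans every midpoint between adjacent distinct feature
values, subject to both groups containing at least `floor(min_frac * n)`
patients (default `min_frac = 0.1`), and keeps the split maximizing the
two-group log-rank statistic. Because the maximum over many candidate
splits inflates the nominal log-rank p-value, the reported
`p_corrected` applies the Miller–Siegmund approximation for maximally
selected statistics,

$$p \approx \varphi(b)\left(b - \tfrac{1}{b}\right)
  \log\!\frac{\varepsilon_2(1-\varepsilon_1)}{\varepsilon_1(1-\varepsilon_2)}
  + \frac{4\varphi(b)}{b},$$

with $b$ the observed maximal statistic and
$(\varepsilon_1, \varepsilon_2)$ the scanned quantile range; the result
is clamped to lie between the uncorrected p-value and 1. Under a null
simulation (independent feature, n = 126, 500 replicates) the corrected
test holds its 5% size.

Published cutoffs for the four PET features (SUVmax 17.60, TMTV
408.72 cm³, TLG 1446.98, Dmax 56.73 cm) ship as the `fl_cutoffs()`
preset; dichotomization is **strict** (`value > cutoff` is "high"), so a
value exactly at a cutoff is low.

## 3. Survival machinery

Progression-free survival is computed from diagnosis and event/censor
dates, converted to months at 30.44 days/month. Kaplan–Meier estimates
are right-continuous step functions; log-rank tests and Cox models wrap
the `survival` package with **Efron** handling of tied event times (the
default because it is less biased than Breslow when ties are common, as
they are with monthly follow-up granularity). `tidy()` returns
coefficients with hazard ratios and Wald confidence intervals; constant
covariates and non-converged fits are errors, near-separation is a
warning.

## 4. Risk scores

The three-factor score counts adverse factors — TLG above cutoff, Dmax
above cutoff, elevated LDH — and maps 0–1 → low, 2 → intermediate,
3 → high. Comparators:

- **FLIPI**: age ≥ 60, Ann Arbor III–IV, Hb < 12 g/dL, > 4 nodal sites,
  elevated LDH; 0–1 low, 2 intermediate, ≥ 3 high.
- **FLIPI2**: age > 60, elevated β2-microglobulin, Hb < 12 g/dL, longest
  diameter of largest involved node > 6 cm, bone-marrow involvement;
  0 low, 1–2 intermediate, 3–5 high.
- **PRIMA-PI**: elevated β2-microglobulin → high; otherwise bone-marrow
  involvement → intermediate; otherwise low.

All return ordered factors so that monotonicity properties are testable.

## 5. Model evaluation

- **Harrell's C-index**: over usable pairs (the earlier time is an
  event, or tied times with exactly one event), concordant pairs plus
  half of risk ties, divided by usable pairs. Computed by an explicit
  vectorized O(n²) pair count; the standard error comes from
  `survival::concordance`.
- **Paired bootstrap comparison** (`compare_c()`): both models'
  C-indices are recomputed on the same bootstrap resamples (default
  2000), giving a percentile CI and two-sided p for the difference.
- **Time-dependent ROC** (`td_auc()`): cumulative/dynamic AUC at horizon
  τ with inverse-probability-of-censoring weights from the censoring
  Kaplan–Meier ($1/\hat G(t^-)$ for cases, $1/\hat G(\tau)$ for
  controls).
- **Decision curves**: net benefit
  $\mathrm{TP}/n - \mathrm{FP}/n \cdot p_t/(1-p_t)$ across threshold
  probabilities, with event probabilities under censoring taken from the
  Kaplan–Meier within the treated subset; treat-all and treat-none
  references included.
- **Calibration**: predicted survival grouped into quantile bins,
  compared to each bin's Kaplan–Meier estimate at the horizon.

## 6. Pathologic-grade statistics

Grade 3A vs low-grade comparisons use Pearson's chi-square **without**
continuity correction when all expected counts are ≥ 5, Fisher's exact
test otherwise (`contingency_test()` routes automatically and reports
which test ran). Continuous features use the Mann–Whitney test, exact by
complete enumeration for small untied samples, otherwise the
tie-corrected normal approximation without continuity correction.
`roc_binary()` builds the empirical ROC (rank-sum AUC, Hanley–McNeil
standard error for the test against 0.5) and picks the Youden-optimal
cutoff, breaking ties toward higher specificity. `ppv_npv_from_sens_spec()`
reconstructs the confusion matrix from rounded sensitivity/specificity
and class sizes, mirroring how such tables are reported.

## 7. Synthetic generators and their ground truth

**Phantoms** (`phantom_spec()` / `gen_phantom()`): uniform-uptake
ellipsoids on a constant background, optional liver/spleen regions,
optional Gaussian noise (truncated at SUV 0) and edge blur. True volumes
are obtained by *voxel-center counting*, not the continuous ellipsoid
volume, so that a correct delineation recovers MTV, TLG and SUVmax
bit-exactly in the noiseless case; the truth also records the
deterministic peak voxels, the pairwise distance matrix and Dmax.
Uniform uptake is deliberately idealized: it makes the 41% isocontour
recover the whole lesion exactly, which turns segmentation into a
testable proposition. Blur and noise are provided for stress testing,
where recovery is approximate, as it is clinically.

**Cohorts** (`cohort_spec()` / `gen_cohort()`): clinical factors are
Bernoulli draws at prevalences matching a 126-patient FL population
(e.g. stage III–IV 0.825, bone-marrow involvement 0.484, elevated LDH
0.214, elevated β2-MG 0.325), optionally correlated through a Gaussian
copula. PET features are log-normal with medians near the published
cohort (SUVmax 12, TMTV 215 cm³, TLG 1020, Dmax 60 cm). Event times
follow a proportional-hazards exponential model with baseline rate
0.0022/month — calibrated so that a cohort with the default planted
hazard ratios (LDH 2.287, high TLG 3.612, high Dmax 2.877) shows roughly
a 52% five-year event-free fraction — and censoring is uniform on 12–96
months (median follow-up ≈ 41 months). Every generated cohort carries a
`truth` attribute with the linear predictor and planted log hazard
ratios.

What the simulator does *not* emulate: competing risks, time-varying
hazards, measurement error in the PET features, or correlation between
the PET features and the clinical factors beyond what the copula option
induces. Conclusions about comparator indices on synthetic data reflect
the planted hazard structure (only LDH, TLG and Dmax are prognostic by
default), not the clinical performance of FLIPI/FLIPI2/PRIMA-PI.

## 8. Reproducibility

All generator randomness flows through explicit seeds; `with_seed()`
evaluates code under a temporary seed and restores the caller's RNG
state. `scripts/acceptance.R` re-derives the package's headline
quantities from a single `--seed` argument and writes them as JSON.
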
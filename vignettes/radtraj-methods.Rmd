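---
title: "Methods: longitudinal radiomic trajectory biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal radiomic trajectory biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(radtraj)
```

# Overview

`radtraj` implements a delta-radiomics workflow for serial CT measurements
of tumour lesions. The pipeline has four stages:

1. **Feature extraction** from voxel data: volume, surface area, and
   first-order intensity statistics per lesion, aggregated over up to five
   target lesions per patient.
2. **Longitudinal summaries**: each feature's trajectory over repeated
   scans is condensed into three numbers (AUC1, beta, AUC2), and the
   volume trajectory is classified into one of six response patterns.
3. **Survival modelling**: each summary is dichotomized at an optimal
   log-rank cutpoint, screened by univariate Cox regression and variance
   inflation, and combined into a multivariate Cox model by bidirectional
   stepwise AIC.
4. **Evaluation**: the linear risk score from the final model is assessed
   with censoring-weighted time-dependent ROC curves and Kaplan-Meier
   curves of the dichotomized score.

A synthetic cohort generator with known trajectory patterns and
proportional-hazards outcomes exercises the whole pipeline end to end.

# Trajectory summaries

Let a feature be observed at times $t_1 < \dots < t_k$ (months from
baseline) with values $v_1, \dots, v_k$, normalized to $v_1 = 1$ when the
feature is strictly positive at baseline. The three summaries are:

* **AUC1** — total trapezoidal area,
  $\mathrm{AUC1} = \sum_{i=1}^{k-1} \tfrac{1}{2}(v_i + v_{i+1})(t_{i+1} - t_i).$
* **beta** — ordinary least-squares slope of $v$ on $t$,
  $\beta = \sum_i (t_i - \bar t)(v_i - \bar v) \big/ \sum_i (t_i - \bar t)^2.$
* **AUC2** — signed trapezoidal area in which a segment's area is *added*
  when the feature increases over the segment and *subtracted* otherwise:
  $\mathrm{AUC2} = \sum_{i=1}^{k-1} s_i \, \tfrac{1}{2}(v_i + v_{i+1})(t_{i+1} - t_i),
  \quad s_i = \begin{cases} +1 & v_{i+1} > v_i \\ -1 & v_{i+1} \le v_i. \end{cases}$

AUC2 rewards sustained growth and penalizes sustained shrinkage, so it
orders trajectories from durable response (large negative) through mixed
response to continuous progression (large positive). `|AUC2| = AUC1`
exactly when the trajectory is monotone; this invariant is tested. Flat
segments subtract by default; `zero_increment = "drop"` excludes them.

# Volume trajectory patterns

Normalized volume trajectories are labelled 1-6 by `classify_pattern()`
using two statistics: the nadir depth $d = 1 - \min_i v_i$ and the
post-nadir regrowth slope $m = (v_k - v_{\min}) / (t_k - t_{\min})$.

| Pattern | Description | Rule |
|---|---|---|
| 1 | reduction only | nadir at last scan, or $m \le 0$ |
| 2 | deep nadir, slow regrowth | $d \ge 0.3$, $m \le 0.1$ |
| 3 | deep nadir, fast regrowth | $d \ge 0.3$, $m > 0.1$ |
| 4 | shallow nadir, slow regrowth | $d < 0.3$, $m \le 0.1$ |
| 5 | shallow nadir, fast regrowth | $d < 0.3$, $m > 0.1$ |
| 6 | progression only | no volume below baseline |

The depth threshold 0.3 mirrors the conventional response boundary for
volumetric shrinkage, and 0.1 per month separates indolent from rapid
regrowth; both are arguments (`d_deep`, `m_fast`) rather than constants.
The labels are ordered by aggressiveness, and on synthetic cohorts the
rank correlation between the generating label and volume AUC2 is checked
to exceed 0.8.

# Voxel-level features

`roi_features()` computes, per lesion:

* **volume** — voxel count times voxel volume (mm^3^).
* **surface area** — an isosurface at level 0.5 of the binary mask after
  Gaussian smoothing (sigma 0.8 voxels), triangulated by marching
  tetrahedra. Smoothing removes the voxelization staircase; on a
  digitized sphere of radius 20 mm the area is within 3% of $4\pi r^2$.
  Masks under 27 voxels fall back to exact face counting, which is the
  honest answer when there is no resolvable curvature.
* **density** — mean attenuation (HU) inside the mask.
* **skewness_pos / kurtosis_pos** — third and fourth standardized moments
  of the voxels with positive HU (soft-tissue component). Kurtosis is
  reported non-excess (normal = 3). Fewer than 3 positive voxels yields
  `NA` with a warning.
* **entropy** — Shannon entropy (bits) of the HU histogram with fixed
  10-HU bins anchored at -1000 HU, so values are comparable across scans.
* **entropy_inner** — the same entropy after eroding the mask by a
  physical margin (default 2 mm, ellipsoidal structuring element in
  voxel space), isolating the lesion core from partial-volume boundary
  voxels. If erosion empties the mask the un-eroded value is returned
  and flagged.

`aggregate_lesions()` combines 1-5 lesions per scan: volumes add; every
other feature is volume-weighted. `make_phantom()` builds spheres with
constant, Gaussian, or core-rim textures and attaches analytic ground
truth, which the test-suite uses as an oracle.

# Survival modelling

**Optimal cutpoint.** For each candidate marker, `optimal_cutpoint()`
scans the midpoints between consecutive distinct values, skipping splits
that leave less than `min_group_frac` (default 10%) of patients on either
side, and keeps the cutoff with the smallest two-group log-rank p-value
(ties resolved toward the smaller cutoff). The log-rank statistic is
computed from first principles over the risk sets and matches
`survival::survdiff()` to numerical precision in the tests.

Minimum-p selection is *anticonservative*: on pure-noise markers the
selected cutpoint reaches nominal significance far more often than 5%,
which the test-suite demonstrates directly. `n_perm` requests a
permutation-adjusted p-value that restores approximately nominal
behaviour; downstream modelling still treats the dichotomized markers as
candidates to be screened, not as confirmed effects.

**Screening and selection.** `univariate_screen()` fits one Cox model per
dichotomized marker and keeps those with Wald p < `alpha` (default 0.05).
`vif_screen()` removes markers whose variance inflation factor
$1/(1-R^2)$ exceeds 10. `stepwise_aic()` then performs bidirectional
stepwise selection starting from the full candidate set, accepting only
strict AIC improvements and logging every step. Cox fits use
`survival::coxph()` with Efron tie handling; fits with fewer events than
coefficients, constant columns, or signs of monotone separation are
rejected or flagged.

**Time-dependent ROC.** For a horizon $\tau$, cases are patients with an
event by $\tau$ and controls are patients still at risk after $\tau$.
`time_dependent_auroc()` computes the cumulative-case/dynamic-control
AUROC with inverse-probability-of-censoring weights $1/\hat G(T_i^-)$,
where $\hat G$ is the Kaplan-Meier estimate of the censoring
distribution. Without censoring this reduces exactly to the proportion
of concordant case-control pairs, which is the oracle used in testing.

# Synthetic cohort generator

`generate_cohort()` draws, per patient: a pattern label from
`pattern_mix`; a scan grid of `n_timepoints_range` visits (default 5-8)
spaced `timepoint_spacing` months apart (default 2); a normalized volume
trajectory equal to the pattern's piecewise-exponential template times
lognormal multiplicative noise (default CV 0.10), re-normalized to 1 at
baseline; secondary features as linear transforms of the volume ratio
plus independent lognormal noise; and an exponential survival time with
hazard $\lambda_0 \exp(\mathbf{c}^\top \mathbf{z})$, where $\mathbf{z}$
are the patient's *realized* trajectory summaries and the default
coefficient vector is `c(volume_auc2 = 0.12)` with
$\lambda_0 = 0.02$/month. Censoring is uniform on 6-54 months.

The default grid of 5-8 scans reflects that the three summaries of a
trajectory are poorly determined from very short follow-up: AUC-type
summaries scale with follow-up length, so cohorts dominated by 2-3-scan
patients mix follow-up duration into the marker and the link between
pattern label and AUC2 degrades. The template parameters (nadir at 35%
of follow-up, rise rates 0.05-0.19 log-units/month) were fixed by
computing each template's AUC2 in closed form and choosing bands that
keep the six labels ordered by AUC2 before noise is added.

What the generator emulates: ordered response patterns, multiplicative
measurement noise, volume-linked secondary features, proportional-hazards
outcomes with realistic censoring. What it does not: scan-to-scan
correlation of noise, informative censoring, missing visits,
inter-feature correlation beyond the shared volume signal, or any claim
of matching a specific clinical population.

# Worked example

```{r example}
spec <- cohort_spec(n_patients = 120, seed = 42)
cohort <- generate_cohort(spec)
res <- analyze_cohort(cohort$trajectories, cohort$outcomes,
                      run_config(write_plots = FALSE))
res$pattern_correlations$auc2$rho
subset(res$cutpoints, marker == "volume_auc2")
res$stepwise$selected
res$td_auroc
```

The file-based entry point `run_pipeline(run_config(...))` writes every
intermediate table as CSV plus a plain-text log, and reruns with the same
seed are byte-identical. A command-line wrapper is installed at
`system.file("cli", "radtraj-pipeline.R", package = "radtraj")`.

# Numerical choices and limitations

* Trapezoidal areas and the OLS slope are closed-form; no iterative
  numerics are involved in the summaries.
* The cutpoint scan is exhaustive over midpoints, so it is exact by
  construction; it is compared against brute-force enumeration with
  `survival::survdiff()` in the tests.
* Surface area depends on the smoothing sigma: too little leaves
  staircase bias (overestimation), too much erodes thin structures. The
  default 0.8 voxels was chosen on digitized spheres of radius 8-20 mm
  before being frozen.
* The stepwise search is greedy and can miss the AIC-optimal subset;
  tests compare it against exhaustive best-subset enumeration on small
  candidate sets and require it to come within 2 AIC units.
* All p-values downstream of cutpoint optimization inherit the
  minimum-p selection bias discussed above and should be treated as
  exploratory.
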
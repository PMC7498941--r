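---
title: "Methods: template-based connectivity, amyloid burden, and longitudinal cortical thinning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: template-based connectivity, amyloid burden, and longitudinal cortical thinning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netthin)
```

## The scientific question

In clinically normal older adults, does low baseline functional integrity of
the default-mode network (DMN), in combination with elevated amyloid burden,
presage faster cortical thinning within the DMN's own cortical territory?
`netthin` implements the full measurement-and-modelling chain needed to ask
that question — resting-state connectivity extraction, amyloid-PET
quantification, network cortical composites, and longitudinal mixed-effects
modelling — and exercises it end to end on synthetic cohorts whose generative
parameters are known, so that every stage's fidelity can be quantified.

## The model at the core

For subject $i$ at visit time $t_{ij}$ (years from first scan), DMN composite
thickness is modelled as

$$y_{ij} = \beta_0 + b_{0i} + \mathbf{x}_i^\top\boldsymbol\beta +
  \left(\beta_t + \beta_{F t}F_i + \beta_{A t}A_i + \beta_{FAt}F_iA_i +
  \mathbf{c}_i^\top\boldsymbol\beta_{ct} + b_{1i}\right) t_{ij} +
  \varepsilon_{ij},$$

where $F_i$ is baseline DMN connectivity (adjusted and demeaned), $A_i$ is
the continuous amyloid measure (PiB FLR DVR, demeaned), $\mathbf{c}_i$ are
age, sex and education, and $(b_{0i}, b_{1i})$ is a correlated random
intercept/slope pair — `(time | subject)` in lme4 notation. The three-way
coefficient $\beta_{FAt}$ is the primary quantity: whether connectivity and
amyloid *interact* in modulating the rate of thinning.

`fit_thinning_lme()` fits this family (primary, amyloid-stratified without
the DVR terms, and augmented variants with control-network connectivity,
time-varying control-network thickness, or inferior-temporal tau) via
`lme4::lmer`, REML by default.

### Inference conventions

* **Degrees of freedom.** Reported as residual df $= n_\text{rows} -
  p_\text{fixed}$. The 14-term fixed design (main effects *and*
  covariate-by-time interactions) is used throughout; it is the unique design
  for which the df bookkeeping of all model variants is mutually consistent
  (the full model loses 14, a stratified model 10, each added
  connectivity/tau covariate 2, a time-varying thickness covariate 1).
  Satterthwaite df via lmerTest are available with
  `df_method = "satterthwaite"`; they are smaller for between-subject slope
  terms and are the better choice when visit counts are low.
* **Effect sizes.** Cohen's $d = 2t/\sqrt{df}$, sign-preserving
  (`effect_size_from_t()`).
* **Demeaning.** Continuous predictors are demeaned over the *full* table
  before any stratification, with subject-constant columns averaged across
  subjects (one value per subject) so that variable visit counts do not
  weight the mean. Sex enters as a 0/1 indicator.
* **No multiplicity correction** is applied: the stratified and augmented
  fits are post-hoc decompositions of one primary interaction.

## Connectivity by template-based rotation (TBR)

Given fixed spatial templates $IC$ (voxels × components) and a session
$X$ (voxels × volumes), TBR computes $M = X^{+} IC$: each column of $M$ is
the least-squares time course whose template-weighted combination of volumes
best reproduces that template's spatial pattern. No per-subject ICA is
required, and nuisance sources not spanned by the templates are implicitly
separated.

Numerically, `tbr_timecourses()` uses an SVD: by default only
machine-precision singular values are truncated (the exact pseudo-inverse,
which is the algebraic contract the tests verify against an independent
oracle). Band-limited, nuisance-cleaned sessions, however, have trailing
singular directions that are filter-attenuated noise; the exact inverse
weights them by $1/\sigma$ and the unmixing degrades — paradoxically more at
*lower* noise. The `var_keep` argument therefore projects the data onto the
minimal leading principal subspace holding a set fraction of variance before
inversion; the pipeline uses `var_keep = 0.99`, and the dimensionality
actually used is recorded. The whole-network measure is the arithmetic mean
of the Pearson correlations between each in-mask voxel (map value strictly
above 40% of the map maximum) and the network's own TBR time course;
Fisher-z averaging is available as `average = "fisher"`. Between-subject
variance associated with motion (mean framewise displacement) and data
dimensionality (retained nuisance PCs) is removed by linear residualization
across subjects.

## Nuisance model

Per session, in order: zero-phase fourth-order Butterworth bandpass of every
voxel; 15 tissue regressors (top-5 temporal PCs of the voxels whose maximum
tissue probability is WM, CSF or bone, ties broken WM > CSF > bone > GM);
18 motion regressors (6 parameters, first differences backfilled with 0,
squares); the 33 columns filtered identically; z-scored; reduced by PCA to
the minimal set reaching 90% cumulative variance; removed from every voxel
by OLS projection with an intercept. Residuals are orthogonal to every
retained component by construction.

**On the passband.** Two presets ship. The narrow `c(0.08, 0.1)` Hz band is
kept as the documented default of the filtering functions, but it deserves a
warning that the package's own simulations make concrete: at TR 3 s over 120
volumes, a 0.02 Hz-wide band holds only about 14 real signal dimensions.
Thirty-three identically filtered nuisance regressors then span essentially
the whole in-band space, and removing the PCs that explain 90% of their
variance removes *all* in-band signal — cleaned connectivity collapses to
exactly zero. The conventional wide band `c(0.008, 0.1)` Hz (about 66
dimensions, of which the reduction removes a small minority) is therefore
the pipeline default, and the narrow band should be treated as unusable with
this nuisance model at these run lengths.

PCA components use a fixed sign convention (largest-magnitude loading
positive) so results are identical across linear-algebra backends. The
zero-phase filter demeans each series first (a bandpass has no DC gain, and
this makes DC removal exact on finite series) and uses odd-reflection
padding scaled to the filter's settle time, because plain forward-backward
filtering without padding leaves large edge transients.

## Amyloid and tau quantification

The continuous amyloid measure is the FLR DVR: the unweighted mean uptake of
16 Desikan–Killiany regions (precuneus, rostral anterior cingulate, medial
orbitofrontal, superior frontal, rostral middle frontal, inferior parietal,
inferior temporal, middle temporal; both hemispheres) divided by cerebellar
gray. Tau is summarized as the bilateral inferior-temporal SUVR with the
same reference. Group assignment uses the fixed published threshold
DVR > 1.186 by default (`classify_amyloid()`), with strict inequality
(boundary values are "low").

`gmm_cutoff()` alternatively derives a threshold from the sample: a
two-component univariate Gaussian mixture is fit by EM (k-means
initialization, 10 restarts, log-likelihood tolerance $10^{-8}$, at most 500
iterations) and the equal-posterior crossing between the component means is
returned. A caveat worth stating explicitly: if the mixture is parameterized
from *post-dichotomization group summaries* (group means 1.08/1.46, group
SDs 0.1/0.1, weights 87:33), the crossing lands near
$\bar\mu + \sigma^2\log(w_1/w_2)/\Delta\mu \approx 1.30$ — not at 1.186.
Dichotomized group SDs understate how tight the true amyloid-negative
component is; a sample-derived cutoff should be fit on the raw DVR values of
a real sample, not on group-level summaries.

## Cortical composites

Functional node masks are carried to thickness space in four steps:
per-voxel modal labels across replicate label volumes (ties: smallest label
id, with "undefined" never beating a defined label); cubic resampling of
each node mask to a finer grid (separable natural splines; default target
1.5 mm for the synthetic 3 mm grids — the 0.5 mm production target is
configurable but pointless at toy scale; the 0.25 inclusion threshold is
kept, with overlaps resolved by the highest interpolated value and a
gray-matter partition gating inclusion); vertex labelling by the modal label
of all voxel centers within 2 mm of each vertex (Euclidean, world
coordinates, 0-based voxel-center convention); and per-visit unweighted mean
thickness over a network's vertices.

## The synthetic cohort and what it does (and does not) emulate

`generate_cohort()` reproduces the target study's design margins: 120
subjects; 2–8 visits with the published visit-count distribution; total
follow-up span drawn from N(5.04, 0.8²) years clipped to [3.69, 6.96]
(per-interval scheduling cannot reproduce those margins — two visits spaced
2–3 years apart cannot span 3.7+ years); age N(73.35, 6²), 70/120 female,
education N(16.0, 2.9²); amyloid from the two-component mixture above;
baseline connectivity Gaussian with SD 0.1 (the study does not report its FC
distribution; Gaussian-demeaned is a modelling choice). Default generative
coefficients plant a *negative* FC × DVR × time interaction of study-like
magnitude (single-fit |t| ≈ 2.5 at n = 120), thinning −0.010 mm/year,
random intercept/slope SDs 0.12 mm and 0.012 mm/year (correlation −0.2),
residual SD 0.05 mm.

`generate_session()` builds 120-volume TR-3 sessions on a 12³ grid of 3 mm
voxels: a shell head geometry (bone/CSF shells, WM core, GM between);
smooth non-negative network maps supported only on the GM shell — cortical
networks must not place signal inside the tissue-nuisance masks, or the
tissue PCs absorb the planted sources, exactly as aCompCor on real data
degrades when masks leak into cortex; planted source time courses that are
band-limited (0.02–0.09 Hz) and orthogonalized over the session (narrowband
sinusoid sources are otherwise mutually correlated, and least-squares
unmixing then recovers the dual basis rather than the sources); a
motion-correlated global nuisance component; shared WM/CSF fluctuations; and
white noise. A subject's "true connectivity" is the amplitude coupling
between a network's map and its time course.

What passing tests therefore demonstrate: the *chain* is correct — filtering
preserves in-band signal, the nuisance model removes what it should and
nothing it should not, TBR recovers planted time courses, the connectivity
measure orders subjects by their planted coupling (rank correlation > 0.9 at
n = 60), the composites machinery reproduces vertex means, and the mixed
model recovers planted coefficients with < 10% bias and ≈5% type-I error.
What they do not demonstrate: behavior under real-data features the
generator omits — spatially structured physiological noise, motion-by-space
image artifacts, registration error, non-Gaussian thickness measurement
error, hemodynamic variability, or template mismatch with the subject's true
functional topography.

## Numerical choices and edge cases

* Pseudo-inverse truncation: singular values below
  $\max(\dim)\,\epsilon\,\sigma_1$; optional variance-based dimensionality
  (`var_keep`) as above.
* Framewise displacement: sum of absolute parameter differences, rotations
  converted at a 50 mm radius (configurable).
* Mask thresholds are strict inequalities (a voxel exactly at 40% of the map
  maximum, or a mask value exactly 0.25, is excluded; a DVR exactly at the
  cutoff is "low").
* Zero-variance voxels are excluded from connectivity averages with a count;
  an all-zero session, an empty mask, a rank-deficient nuisance design, a
  degenerate EM component, and missing ROI rows are hard errors naming the
  offender.
* Demo problem sizes: the shipped pipeline configuration uses 24 subjects on
  a 12³ grid (a complete run fits comfortably in a few tens of seconds);
  simulation studies in the test suite use 200 replicates at n = 120 for
  bias and 500 replicates at 60 subjects × 4 visits for test size — sizes at
  which Monte-Carlo error is small relative to the properties being
  checked.

## Known limitations

* The pipeline's measured connectivity is a bounded correlation average;
  its mapping from the planted coupling is monotone but nonlinear, so fitted
  interaction coefficients are on the measured scale, not the generative
  one (sign and ordering are preserved; magnitudes are not comparable).
* The sample-derived GMM cutoff is only meaningful on raw DVR samples, as
  discussed above.
* The composites stage works on synthetic vertex clouds, not real surface
  meshes; FreeSurfer-style reconstruction, annotation files and longitudinal
  template building are out of scope, as are scanner physics, realignment,
  spatial normalization, PET reconstruction and partial-volume correction —
  their outputs are this package's inputs.
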
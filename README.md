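# netthin

Longitudinal cortical thinning in the default-mode network (DMN) as a joint
function of baseline network connectivity and amyloid burden — the full
analysis chain, implemented as a tested R package and exercised end to end
on synthetic cohorts with known ground truth.

The package is for researchers working on preclinical Alzheimer's disease
neuroimaging who want a reusable, verifiable implementation of this
measurement-and-modelling chain:

1. **Template-based rotation (TBR) connectivity.** With fixed spatial
   network templates `IC` (voxels × components) and a BOLD session `X`
   (voxels × volumes), network time courses are the least-squares unmixing
   `M = X⁺ · IC`. The whole-network measure is the mean Pearson correlation
   between in-mask voxels (map value > 40% of the map maximum) and the
   network's time course, adjusted across subjects for head motion (mean
   framewise displacement) and data dimensionality.
2. **Nuisance preprocessing.** Zero-phase 4th-order Butterworth bandpass;
   33 nuisance regressors (top-5 temporal PCs per WM/CSF/bone tissue class +
   6 motion parameters with derivatives and squares), filtered identically,
   z-scored, PCA-reduced to 90% variance, and removed by OLS projection.
3. **Amyloid/tau PET.** FLR DVR (mean of 16 bilateral frontal, lateral and
   retrosplenial ROI uptakes over cerebellar gray), inferior-temporal tau
   SUVR, and amyloid positivity (fixed cutoff DVR > 1.186, or a
   two-component Gaussian-mixture crossing fit by EM).
4. **Network cortical composites.** Modal label atlas → cubic resampling
   with a 0.25 inclusion threshold inside a gray-matter partition → vertex
   labelling by 2 mm modal neighborhoods → per-visit mean thickness.
5. **Longitudinal mixed models.** For thickness `y` of subject `i` at time
   `t` (years from first scan):

   `y ~ FC * DVR * time + (age + sex + edu) * time + (time | subject)`

   fit by REML (lme4), with residual-df inference (`df = rows − fixed
   effects`), Cohen's `d = 2t/√df`, amyloid-stratified variants without the
   DVR terms, and augmented variants (control-network FC, time-varying
   control-network thickness, inferior-temporal tau). The three-way
   `FC:DVR:time` term is the primary effect.
6. **Synthetic data with ground truth** for every input above, plus a
   `run_pipeline()` orchestrator and manifest.

## Worked example

A complete run on the default demonstration cohort (24 subjects, 12³ voxel
grid, 120 volumes at TR 3 s, a planted *negative* connectivity × amyloid ×
time interaction):

```r
library(netthin)
run <- run_pipeline(pipeline_config(seed = 42))
print(run)
#> <pipeline_run> 24 subjects, seed 42
#>   components: cohort, qc, connectivity, composites, pet, table, fits
#>   primary fc:pib:time: est -1.119, t(108) = -4.04, p = 0.000101
summary(run$fits$primary)
#> Longitudinal thinning LME — primary model
#>   122 observations, 24 subjects; REML, df = n - p = 108
#>         term   estimate       se     t  df         p     d
#>  (Intercept)  2.511e+00 0.029120 86.23 108 2.01e-101 16.59
#>           fc -1.637e-01 0.256800 -0.64 108  5.25e-01 -0.12
#>          pib  3.288e-01 0.130500  2.52 108  1.32e-02  0.48
#>         time -4.078e-03 0.006649 -0.61 108  5.41e-01 -0.12
#>          ...
#>  fc:pib:time -1.119e+00 0.277200 -4.04 108  1.01e-04 -0.78  <-- primary
#> Random effects: intercept SD 0.0826, slope SD 0.01833; residual SD 0.02945
#> Primary term fc:pib:time: t(108) = -4.04, p = 0.000101, d = -0.78
```

The fitted primary coefficient is negative — subjects generated with *lower*
baseline DMN connectivity and *higher* amyloid thin faster — recovering the
sign of the planted interaction from raw simulated images through filtering,
nuisance removal, TBR, composite construction, PET quantification and the
mixed model. `run$connectivity`, `run$composites`, `run$pet` and
`run$table` hold each stage's outputs; `make_report(run$fits)` collates the
primary and stratified fits into one term-by-model table.

The summary-statistic utilities work directly on published group tables:

```r
pooled_two_sample_t(1.08, 0.1, 87, 1.46, 0.1, 33)
#> <group_comparison> t(118) = 18.587, p = 7.47e-37
effect_size_from_t(2.43, 421)
#> [1] 0.2368619
```

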
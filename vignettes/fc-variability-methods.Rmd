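---
title: "Mapping intersubject variability of seed-based functional connectivity"
author: "fcvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping intersubject variability of seed-based functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcvar)
```

## The question and the estimand

Most group fMRI analyses compare *mean* connectivity between groups. This
package targets a complementary question: does group membership change how
much individuals *differ from each other*? The motivating setting is
sensory deprivation — e.g. congenital deafness — where the deprived
cortex's connectivity may not simply shift in one direction but become
more heterogeneous across individuals, because no shared sensory
experience anchors its organization.

The estimand is therefore the across-subject spread of seed-based
functional connectivity (FC) at each voxel, compared between groups. FC is
measured as the Pearson correlation between a seed region's mean BOLD
time course and every gray-matter voxel's time course, Fisher transformed
(`z = atanh(r)`) so that spread is comparable across the correlation
scale.

## The pipeline

### Denoising: one projection, confounds and band-pass together

Each run's voxel series are replaced by their least-squares residuals
against a single regressor matrix holding (i) an intercept, (ii) the
run's confound columns (motion-like series, drift, task regressor,
tissue signals — whatever the confound table supplies), and (iii) a
discrete-cosine basis spanning every frequency *outside* the pass band
(default 0.01–0.1 Hz at TR = 2 s). Doing both in one projection matters:
filtering first and regressing unfiltered confounds afterwards
reintroduces out-of-band variance, a well-documented artifact of
sequential pipelines. Because the operation is an orthogonal projection it
is idempotent and can only shrink per-voxel variance — both properties
are unit-tested.

The seed course is the mean of the z-scored seed-voxel series; series are
standardized per run before concatenation so that run-level scale
differences cannot masquerade as connectivity. Correlations are clamped
at `|r| = 1 - 1e-7` before `atanh` so degenerate voxels stay finite.

A deliberate simplification: connectivity is plain Pearson correlation on
the run-standardized concatenated residuals. Condition-weighted GLM
variants of seed connectivity exist in common toolboxes, but their
weighting scheme is tool-specific; with task predictors already removed
as confounds, the residual series is treated as continuous.

### Variance testing: Brown-Forsythe at every voxel

At each voxel the across-subject values `y_ij` (subject i, group j) are
reduced to absolute deviations from their **group median**,
`d_ij = |y_ij - med_j|`, and a one-way ANOVA F across groups on `d` gives
the test statistic with df `(k - 1, N - k)`. Median centering (the
Brown-Forsythe variant of Levene's test) is what keeps the false-positive
rate near nominal under skewed data; the mean-centered variant is
available via `center = "mean"` but is not the default. Even-sized groups
use the midpoint median; no randomness anywhere. The vectorized map
implementation is tested against a scalar per-voxel reference to 1e-10
and the type-I error is verified by simulation at n = 16/33 for Gaussian
and log-normal nulls.

Nuisance covariates (age, task accuracy, reaction time) are removed
before the variance test by `residualize()`: per voxel, `y ~ group
intercepts + centered covariates` is fit jointly and only the covariate
component is subtracted. Fitting jointly matters because covariates can
differ by group (the hearing group is younger in the design this package
emulates); a pooled fit would alias the group difference into the
covariate beta.

Where variance differs significantly, the effect direction is summarized
by the **variability ratio**: SD(group 1) / SD(group 2) of the
residualized Fisher-z values per voxel. The ratio is reported on the SD
scale by default — "twice as variable" then means what it says — with a
variance-scale option (`spread = "var"`), since either convention exists
in the literature.

### Cluster-extent correction

Voxel-wise maps are thresholded at voxel p < 0.05 and corrected for
multiple comparisons by cluster extent within the analysis mask, in the
Monte-Carlo (AlphaSim-style) tradition: fill the mask with white Gaussian
noise, convolve to the data's estimated smoothness, re-standardize,
threshold at the two-tailed z quantile, record the maximum cluster size,
and repeat (default 1000 iterations; the threshold is stable well before
that at these mask sizes, and 100,000 is supported). The extent threshold
is the smallest size whose exceedance probability is at most the
corrected alpha.

Smoothness is estimated from the group-median-centered FC residuals — the
maps that carry the null spatial correlation — by the residual
first-difference estimator: per axis,
`FWHM = voxel_size * sqrt(-2 ln 2 / ln(1 - var(diff) / (2 var)))`,
averaged over maps with an estimable ratio. For white noise convolved
with a Gaussian kernel this recovers the kernel FWHM in expectation,
which the tests verify for a 6 mm kernel on a 2 mm grid.

Default connectivity is face adjacency (6-neighborhood), the conservative
choice; 18 and 26 are available. One caveat is documented rather than
hidden: the absolute-deviation transform roughens the F map relative to
the residual maps whose smoothness feeds the null, so the correction runs
conservative for the Brown-Forsythe map (measured family-wise error on
null cohorts is well below the nominal 5%; the acceptance suite bounds it
at 9%).

### Group means: covariate-adjusted F, not ANOVA-on-residuals

Group differences in mean FC use the partial F for the group factor in
the joint model `fc ~ group + centered covariates`, df `(k-1, N-k-q)`,
with model-based post hoc t maps per pair. A subtlety forced this choice:
running a plain one-way ANOVA on covariate-residualized values is
anticonservative whenever covariates separate the groups (task accuracy
differs by ~2.5 within-group SDs in the emulated design), because the
subtracted covariate component carries estimation noise that is itself
group-patterned. The partial F prices that in. Since residualized and raw
FC differ only within the covariate span, `group_mean_map()` returns
identical maps for either input, and `F = t^2` still holds for two
groups. The flip side, also real, is that strongly group-separated
covariates inflate the adjusted contrast's standard error — power is
genuinely lower in confounded designs, and the tests exercise power in
the unconfounded configuration.

### Spatial association of two maps

Whether the regions of increased variability are the regions of mean
reorganization is asked by correlating the two unthresholded statistic
maps within the mask. Significance cannot come from treating voxels as
independent — both maps are spatially smooth — so the null shuffles the
variability map's in-mask values and re-smooths each permuted volume to
the data's estimated FWHM (re-standardized to the original mean/SD)
before correlating. The unsmoothed variant is also reported as a
diagnostic; on smooth maps its null is several times too narrow, which is
precisely the artifact the matched null avoids. p-values are two-sided on
|r| with the add-one rule (never exactly zero), and only one side is
permuted — a single exchangeable side suffices for the null of no spatial
association. Calibration is verified by simulation: on independent smooth
maps the matched-null p is uniform (KS test), while the naive null is
visibly anticonservative.

### Factors and ROIs

Continuous subject factors (e.g. age of first hearing-aid use, duration
of use, hearing threshold) are related to FC by partial Pearson
correlation — both sides residualized on any covariates — with p from the
t transform at df `n - 2 - q` and listwise deletion of missing factor
values (hearing threshold is typically observed only on a subset).
ROI-level analysis averages FC over each cluster-derived ROI and runs the
same correlation for every ROI x factor cell, reporting uncorrected p
together with Benjamini-Hochberg q across the whole family; single-voxel
ROIs reproduce the voxel-wise map exactly, which is tested.

## The synthetic cohort

No raw data from the motivating study are public, so the package carries
a generator whose defaults *are* the emulated design: groups of 16
(native-signing deaf), 23 (delayed-signing deaf) and 33 (hearing)
subjects; 10 runs of 360 s at TR = 2 s with the first volumes' discard
handled at load time; 2 mm voxels; 6 mm spatial smoothness; covariates
age (deaf group older by ~2.5 y), task accuracy (0.74 vs 0.89, SD 0.06)
and reaction time (1.083 vs 1.147 s), echoing the emulated cohort table.

Ground truth is planted on the Fisher-z scale, the scale the variance
test operates on: each subject carries a trait `z_s ~ N(mu_g, sigma_g^2)`
per effect region, with defaults `sigma = 0.4` (deaf) vs `0.2` (hearing)
— the "twice the variability" regime at a typical intersubject spread —
and region means `0.2 vs 0.5` (large temporal-like region, 343 voxels at
24³) and `0.65 vs 0.5` (smaller frontal-like region, 216 voxels), so that
mean reorganization and variability increase co-occur spatially as the
motivating findings describe. Region sizes are chosen to clear plausible
extent thresholds, as any reported cluster by definition does.

Two generation routes share this truth model:

* **Time-series route** (`generate_cohort()`): seed voxels carry a
  unit-variance white latent signal `g(t)` plus smoothed noise; an effect
  voxel carries `w_s g(t)` plus noise, with `w_s` solved in closed form so
  the ideal-seed correlation equals `tanh(z_s)`. With white seed noise the
  solution is `expected_correlation()`'s textbook formula; with smoothed
  noise the generator uses the exact variance of the seed-mean noise
  derived from the kernel autocorrelation over the seed geometry. The
  latent signal is white by design: the band-pass stage then affects
  signal and noise spectra identically, keeping the planted correlation
  the recovery target. Drift, a block task regressor, and standardized
  random-walk motion series are mixed in with recorded weights and listed
  in the per-run confound tables.
* **Map-level route** (`simulate_fc_cohort()`): per-subject Fisher-z maps
  drawn directly — a spatially smooth background field with equal
  across-subject SD (0.2) in every group, the regional trait `z_s`, and a
  small smooth measurement-noise field (SD 0.04, matching the residual
  estimation error of roughly half an hour of band-passed data). This is
  the input contract of the variance-mapping stage, and it is what the
  cohort-scale calibration studies (family-wise error over hundreds of
  cohorts, ratio recovery over dozens) use; re-simulating full BOLD time
  series for those studies would only re-test what the time-series route's
  own calibration tests already establish.

Everything is a pure function of the configuration and one integer seed;
per-subject substreams are derived deterministically so that adding a
subject or toggling a stage never shifts anyone else's noise.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: hemodynamic autocorrelation
and HRF structure, physiological noise and spikes, registration error,
distance-dependent motion artifacts, non-Gaussian FC distributions, and
truth whose variance effects have soft spatial boundaries. Within a
region the trait is constant across voxels (the region succeeds or fails
as a unit), which is the planted-truth contract but makes detection
counts across regions binomial rather than voxel-wise.

## Numerical choices and edge cases

* Grids must match exactly (1e-4 on voxel size and affine); nothing is
  ever resampled silently.
* Statistic maps write 0 outside the mask; p-value maps write 1, so
  downstream thresholding can never pick up background voxels.
* Zero-variance voxel series yield z = 0 with a warning; a zero-variance
  seed is an error. All-zero deviation voxels in the variance test are
  flagged degenerate with p = 1.
* Rank-deficient designs fail loudly, naming the collinear columns; the
  projection basis deduplicates regressors deterministically (later
  duplicates dropped).
* Cluster ids order by size, then peak coordinate; mask voxel order is
  lexicographic by coordinate — both pure functions of the input.
* Masked storage (time x in-mask-voxel matrices) everywhere: whole-brain
  loops dominate cost, and the compiled inner loops (connected
  components, column medians) keep the Monte-Carlo and calibration
  studies inside minutes.

## Problem sizes used by the test and acceptance suites

Cohort-scale claims are checked at sizes chosen to make the relevant
sampling error small while keeping a laptop-scale run: ratio recovery on
50 cohorts (24³ grid, n = 16 vs 33, 500 Monte-Carlo iterations each),
family-wise error on 200 null cohorts (20³ grid), permutation calibration
on 200 repeats of 199 permutations (16³), FC recovery on 100 subjects of
1760 volumes (white-noise configuration, where the closed-form coupling
is exact and the Fisher `1/sqrt(T-3)` standard error applies — band-pass
filtering reduces effective degrees of freedom by the bandwidth fraction
and is therefore checked for unbiasedness, not for that SE). The
acceptance script reruns the same computations at comparable sizes from a
single seed.

## Known limitations

* The Monte-Carlo extent correction is conservative for the
  Brown-Forsythe map (see above); a permutation-based maximal-statistic
  correction would be exact but is out of scope.
* The weighted-GLM connectivity variant and surface-based analysis are
  not implemented.
* The smoothness estimator assumes approximately stationary Gaussian
  autocorrelation; heavy nonstationarity (e.g. mixed tissue classes in
  the mask) will bias the extent threshold in either direction.
* ROI factor correlations inherit the usual caveats of averaging over
  cluster-derived ROIs selected on the same cohort; the package reports
  them with q-values but leaves circularity control to the analyst.
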
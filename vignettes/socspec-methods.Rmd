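---
title: "Predicting soil organic carbon from Vis-NIR spectra: models, conventions and design choices"
author: "socspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting soil organic carbon from Vis-NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(socspec)
```

## The problem

Monitoring soil organic carbon (SOC) across a field over time requires far
more measurements than conventional laboratory analysis can affordably
provide. Visible--near-infrared (Vis-NIR, 400--2500 nm) reflectance
spectroscopy offers a fast proxy: organic matter, water and mineral
constituents produce overlapping absorption features, and a multivariate
calibration can map a spectrum to an SOC concentration in g kg^-1^.

The practical complications this package addresses are the ones that
dominate proximal soil sensing in the field:

* two instruments with different spectral resolutions (a 1 nm full-range
  point spectrometer and a 5 nm two-sensor instrument that also records
  an on-the-go stream from a tractor-drawn shank);
* laboratory spectra of dried, sieved samples versus field spectra taken
  on moist, rough soil;
* the need to correct field spectra using the corresponding laboratory
  measurements before a field-capable model becomes acceptably accurate;
* model interpretation: which wavelengths carry the SOC signal, and
  whether they are stable across instruments, conditions and
  preprocessing.

Everything is exercised end-to-end on a synthetic scene generator, so the
full pipeline is testable without any proprietary measurement files.

## Partial least squares regression

The calibration engine is univariate-response PLSR fit by sequential
NIPALS on mean-centered (never variance-scaled) data. Centering without
scaling is the standard convention for spectra because all channels share
units; it also keeps regression-coefficient magnitudes comparable across
wavelengths, which the importance analysis relies on.

Per component $a$ the algorithm extracts a unit-norm weight vector
$w_a \propto X_a^\top y_a$, scores $t_a = X_a w_a$, x-loadings
$p_a = X_a^\top t_a / t_a^\top t_a$ and a y-loading
$q_a = y_a^\top t_a / t_a^\top t_a$, then deflates $X$ and $y$. The
response sum of squares explained by component $a$ is

$$SS_a = q_a^2 \, t_a^\top t_a,$$

and the variable importance in projection of wavelength $j$ is

$$\mathrm{VIP}_j = \sqrt{\frac{p \sum_{a=1}^{A} SS_a \,
  (w_{aj} / \lVert w_a \rVert)^2}{\sum_{a=1}^{A} SS_a}},$$

the standard definition under which $\sum_j \mathrm{VIP}_j^2 = p$ holds
exactly; the package asserts that identity to 1e-8 in its tests. NIPALS
was chosen over SIMPLS so the extracted weights are precisely the $w_a$
this formula needs. Regression coefficients on the centered reflectance
scale are accumulated per component count via
$R = W (P^\top W)^{-1}$, so one fit serves every candidate component
count during tuning. The per-wavelength inner loops (thousands of small
local fits during transfer tuning) run in compiled code
(`src/pls_core.cpp`).

## Preprocessing conventions

Four operators are provided, applied after a fixed preparation order:
splice correction, trimming to the common 400--2200 nm modelling range,
robust replicate outlier removal, replicate averaging.

* **SG** -- Savitzky--Golay first derivative, window 11 points,
  polynomial order 2. The order and derivative are conventions (the
  operator family does not prescribe them); both are arguments of
  `savitzky_golay()`. Edges where the window does not fit are dropped, so
  a 1 nm grid yields 405--2195 nm.
* **SGCR** -- Savitzky--Golay *smoothing* (derivative order 0) followed by
  continuum removal, i.e. division by the upper convex hull of each
  spectrum. Output lies in (0, 1] with hull support points exactly 1.
* **gapDer** -- gap-segment first derivative with gap w = 11 points and
  averaging segments of s = 10 points: the difference of trailing and
  leading segment means divided by the (w + s) x step center distance.
  Exact on affine spectra; edge support trims the grid to 415--2185 nm.
* **MSC** -- multiplicative scatter correction: each spectrum is
  regressed on a reference (the set mean by default), and
  $(x - a)/b$ is returned. The reference is stored with the result so new
  data can be corrected against the same reference.

Derivative operators and the hull never bridge a dead band: each
contiguous grid segment is processed independently.

Splice correction removes the additive steps at the junctions of a
multi-sensor spectrometer: each segment beyond a splice point is shifted
so its first value equals the linear extrapolation from the last two
points of the preceding segment, the lowest-wavelength segment being the
anchor.

Replicate outlier removal is a functional implementation of the
adjusted-quantile idea: per sample, spectra are projected onto principal
components keeping >= 99% variance (capped at n - 2), robust distances
are computed by a deterministic MCD-style reweighting (median/MAD start,
iterated 0.975 chi-square reweighting; groups too small for a stable full
covariance, n < 2k + 2, keep a diagonal robust scale), and spectra are
flagged beyond a chi-square 0.975 cutoff that is *raised* whenever the
empirical distance tail is lighter than chi-square -- so clean replicate
groups lose nothing. Determinism was preferred over a resampling MCD so
that the whole study is bit-reproducible from one seed.

## Cross-validation design

Evaluation and every tuning decision use a stratified 5-fold nested
cross-validation with 5 repetitions (25 models per dataset):

* **Spatial grouping.** Samples within 8 m are joined by single-linkage
  connected components and always share a fold, preventing spatial
  autocorrelation from leaking between training and test data.
* **Stratification.** Groups are sorted by group-mean SOC and dealt into
  folds in blocks of k consecutive groups with a random permutation of
  fold labels inside each block -- a randomized round-robin. A plain
  rotation would admit only k distinct partitions; the block permutation
  keeps the SOC balance while making repetitions genuinely random.
* **Shared subdivisions.** Folds are a function of the sample table and
  the scheme seed only, so all 16 dataset variants (and all corrected
  variants) are compared on identical splits.
* **Inner tuning.** The inner 5-fold CV scores every component count
  1..20 from a single deflation path per fold; ties go to the smallest
  count. The inner fold count is a convention (the outer design does not
  determine it) and is configurable.

## Lab-to-field correction

Three corrections map field spectra toward the laboratory domain, each
fit strictly on training samples:

* **LT** -- per-wavelength ordinary least squares of lab on field values.
* **PDS** -- per lab wavelength, a local PLS from the field window
  $[i-w, i+w]$ (clipped at segment boundaries, never padded) onto lab
  channel i; the coefficients form a banded transform matrix, exactly
  zero outside the band. Tuning grid: ncomp 1--10 x window 1--20.
* **EPO** -- the column-centered, per-location lab-minus-field difference
  matrix D is decomposed by SVD; its first c right singular vectors span
  the disturbance subspace and spectra are projected onto the orthogonal
  complement $P = I - VV^\top$. Centering D before the SVD is a
  convention adopted here. Grid: c 1--10.

The downstream model is trained on corrected field spectra (the corrected
path of the study design). When an EPO-corrected model is meant to score
laboratory spectra too, those are projected with the same P -- standard
EPO usage; in this pipeline the predictive model never mixes domains, so
the projection of lab data only arises in the transfer fit itself.

Parameter selection minimizes the pooled inner-CV RMSE of the
corrected-field model, with the transfer refit inside every inner
training fold. The inner refit matters: fitting the transform once per
outer fold lets a heavily parameterized PDS (ncomp 10, window 20) score
near-perfectly in the inner CV -- its transform has already seen the
inner test rows -- and the selection then favors overfit transforms that
fail on the outer test data. Both the per-fold selections and their mode
are reported, since a single "optimal" parameter per dataset is a
summary, not the estimator.

## Wavelength importance

Per variant, the 25 CV models contribute their regression coefficients
and VIP scores at their own tuned component counts; the per-wavelength
median forms the importance profile. Peaks are strict extrema within a
centered window (span 100 nm for RC, both maxima and minima; 50 nm for
VIP, maxima only), computed per contiguous segment with endpoints
excluded and dead bands never bridged -- "span" is read as the full
window width. Derivative-preprocessed profiles are matched on the
derivative grid; no back-mapping of derivative features to absorption
centers is attempted. Matching against the reference variant
(high-resolution lab MSC) uses +-10 nm for the 1 nm instrument and
+-20 nm for the 5 nm instrument, and match totals are monotone in the
tolerance by construction.

A VIP > 1 selection rule is provided (`vip_selection()`); note that in a
single-component model with equal weights every VIP is exactly 1, so the
strict inequality deliberately selects nothing in that degenerate case.

## Performance metrics

RMSE; R^2 computed as $1 - SSE/SST$ about the observed mean on held-out
predictions (which can be negative -- it is not a squared correlation);
RPD as the n-1 standard deviation of the observations divided by RMSE,
so rpd x rmse recovers sd(observed) exactly and a perfect fit reports
RPD = Inf with a flag; and Lin's concordance correlation coefficient with
n-denominator moments. One metric set per repetition is computed on the
pooled outer-fold predictions (five values per boxplot-style summary),
with median and IQR across repetitions.

## The synthetic scene and what it emulates

`scene_params()` fixes the study conditions: 50 sampling locations, SOC
drawn from a truncated normal with mean 19.6 g kg^-1^ on 14--25 g kg^-1^
(the standard deviation, 2.5 g kg^-1^, is a package default -- only the
mean and range are stated quantities), and volumetric moisture 15--25% at
field acquisition. The 1 nm device spans 350--2500 nm with splice steps
at 1000/1800 nm and 18 lab / 15 field replicates; the 5 nm device spans
350--2200 nm with a 1000--1100 nm dead band, 18 lab replicates and an
on-the-go stream of ~12 georeferenced scans within 3 m of each location.

The forward model is deliberately phenomenological -- additive Gaussian
absorption bands on a smooth decreasing baseline, not radiative transfer
-- because the pipeline only needs realistic band, scatter and moisture
structure. Its components:

* SOC bands at 560, 1330, 1412, 1720 and 2008 nm (widths 55, 25, 20, 35,
  45 nm), depths proportional to SOC. The 1330/1412 widths keep the two
  neighboring features separable under continuum removal.
* A smooth per-location nuisance (six random broad Gaussian bumps per
  location, amplitude 0.004) standing in for mineralogy and texture
  variation. Replicate averaging cannot remove it, and it is what holds
  laboratory models near R^2 ~ 0.9 rather than 0.999 -- the calibration
  target for the generator defaults.
* Replicate-level multiplicative/additive scatter and instrument noise;
  the 5 nm device additionally carries a per-sample inter-sensor
  offset/tilt error (its two sensors respond slightly differently to
  each sample presentation), which is why its laboratory models trail
  the 1 nm device.
* Field disturbance: water absorption at 1400/1900 nm whose depth grows
  with moisture and whose center and width also change with moisture (a
  curved manifold -- a linear model cannot fully absorb it, which is
  precisely what makes subspace-removal corrections worthwhile); overall
  darkening of wet soil; a weak masking of the SOC bands by water; a
  per-location baseline distortion (offset/slope/curvature) and a
  band-like structured disturbance on a fixed 8-dimensional smooth basis
  (patchy moisture films, surface condition); extra field noise. The
  on-the-go stream doubles the scatter/tilt/noise disturbance to reflect
  varying soil contact of a moving below-ground sensor.

All draws derive from one master seed through fixed stream offsets, so
every dataset regenerates bit-identically; the per-location nuisance uses
a device-independent stream because the same soil must look the same to
both instruments (this also makes the 5 nm spectra exactly the
block-mean resample of the 1 nm spectra when noise is switched off).

What passing on this generator does **not** show: performance on real
soils with correlated mineralogy--SOC structure, carbonate interference,
nonlinear particle-size effects, or instrument drift over a season. The
generator validates the *pipeline logic* -- leakage-free evaluation,
correction behavior, importance recovery -- not field-readiness of any
particular calibration.

## Numerical choices and degenerate inputs

* Reflectance is clipped to (0, 1) at generation (epsilon 1e-6);
  continuum removal refuses non-positive reflectance; MSC refuses
  |slope| < 1e-12.
* NIPALS stops early when the residual covariance or score norm falls
  below 1e-12; requested components beyond that are truncated (with a
  warning at the user-facing surface, silently inside the inner CV where
  truncation is routine).
* Tuning ties break toward the simpler model: smallest component count,
  then smallest window. Peak ties resolve to the lowest wavelength via
  the strict-extremum rule.
* Zero field variance at a wavelength gives an LT slope of 0 and
  intercept mean(lab); an EPO component count above rank(D) is truncated
  with a warning.
* Nearest-stream selection uses planar Euclidean distance with ties
  broken by stream record order; the "same plot" constraint of the
  original design is generalized to a 3 m maximum radius, since plot
  polygons are out of scope.

## Problem sizes used by the tests and the acceptance script

The test suite runs the full study conditions (50 locations, all 16
variants, 25 models each) for the ordering and correction checks, with
the EPO correction standing in for "best correction" (if EPO improves a
variant, the best of the three corrections improves it a fortiori); the
complete three-method comparison, including the full PDS grid, lives in
`analysis/04_transfer.R`. Module tests use 12--30 location scenes with
reduced replicate counts. `scripts/acceptance.R` re-runs the 16-variant
study with LT and EPO corrections and the peak-match analysis at the full
50-location scale.

## Known limitations

* Single-response PLSR only; no sparse or kernel variants.
* The outlier rule assumes roughly elliptical replicate scatter after
  projection; heavy-tailed but symmetric replicate noise may be
  over-trimmed.
* EPO assumes the disturbance is (locally) additive in the preprocessed
  space; after strongly nonlinear preprocessing the projection is only an
  approximation, which is visible in the study replica as smaller EPO
  gains on MSC-preprocessed variants.
* The stream selector assigns every scan within the radius to the nearest
  sampling point independently; a scan may serve two nearby points.
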
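---
title: "Speckle-variance OCT angiography of radial peripapillary capillaries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{svOCT RPC methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The radial peripapillary capillaries (RPCs) are a plexus of long, nearly
parallel capillaries inside the retinal nerve fibre layer (RNFL) around
the optic disc; they supply the retinal ganglion cell axons whose loss
defines diseases such as glaucoma. Speckle-variance optical coherence
tomography (svOCT) images this bed label-free: at each slow-axis location
the scanner acquires N repeat B-scans, and the per-voxel intensity
variance across the repeats is high where moving blood decorrelates the
speckle and low in static tissue. From the en-face projection of that
variance over the RNFL slab one measures capillary density (crossings of
a perpendicular sampling line per 100 um), its inverse the inter-capillary
distance (ICD = line length / crossings), and per-vessel diameters; the
ICD is then regressed on RNFL thickness with a linear mixed model.

Because no public svOCT volumes of this kind exist, the package pairs the
analysis pipeline with a synthetic phantom whose every voxel has a known
ground truth, so each stage is validated quantitatively rather than by
eye.

## The speckle phantom

`generate_network()` builds the morphological truth: `n` parallel
polylines with perpendicular spacing `spacing_um` (exact when
`waviness = 0`), a region-dependent radial orientation (temporal and
nasal sectors horizontal, superior/inferior vertical, arcuate sectors
diagonal), diameters in micrometres, and a depth inside the RNFL band.

`render_oct_volume()` turns a network plus a layered retina
(`retina_layers()`: ILM, RNFL/GCL, RPE/BM depth maps and per-layer
reflectivities) into a repeat-frame intensity volume indexed
`[repeat, slow, depth, fast]`. Speckle is synthesized *coherently*: each
voxel carries a circular complex Gaussian scattering field with variance
equal to the local reflectivity, so the detected amplitude is Rayleigh
and the intensity is fully developed speckle with unit contrast. Static
tissue reuses one field realization across repeats; a voxel whose flow
fraction is `f` (partial tube volume) mixes in a fresh field per repeat,

    E_t = sqrt(1 - f w) E_static + sqrt(f w) E_t,fresh ,

giving a repeat-to-repeat field correlation `1 - f w`, where
`w = flow_decorrelation`. The point-spread function is applied to the
*field* - laterally at the beam FWHM (8.6 um) and axially at the
coherence length (6 um) - and the intensity is detected afterwards. Two
modelling points deserve emphasis:

* Blurring the field rather than the intensity is essential. An
  intensity-level mixture of independent per-voxel draws loses its
  across-repeat variance once the sampling is finer than the PSF (the
  blur averages independent draws), whereas physical speckle keeps unit
  contrast with PSF-sized grains at any sampling density. The coherent
  model reproduces that, including the beaded "varicosity" appearance of
  capillaries in the sv image.
* The per-voxel flow *fraction* (overlap of the 5 um tube with the 3 um
  depth voxels) matters: with a binary in/out mask, capillaries lying
  between depth-voxel centers would vanish entirely.

Optional bulk-motion events laterally shift one repeat of a whole
B-scan, producing the bright streak rows the en-face filter must remove.
`render_histology()` rasterizes the same truth at sub-micron pixels with
a small PSF (0.5 um), standing in for confocal images of perfusion-
labelled flat mounts; rendering the same network at the OCT PSF instead
reproduces, in silico, the direction of the svOCT-vs-histology diameter
bias (a rect profile convolved with an 8.6 um FWHM Gaussian measures
~9.3 um FWHM for a 5 um vessel).

Default study conditions: a 1060 nm source with 61.5 nm bandwidth
(coherence length ~6 um in tissue at n = 1.33), focal waist ~7.3-7.5 um
(lateral FWHM ~8.6 um), three repeats, six peripapillary regions with
spacings 31-40 um (arcuate sectors densest), capillary diameter 5 um, a
90 um RNFL, and a 636.5 x 636.5 um analysis crop. The desk-scale grids
are 160 x 160 lateral samples over a 700 um field (4.4 um pixels,
matching the clinical ~3.3 um pitch in spirit) and 96 depth pixels over
288 um (3 um axial pitch); the clinical 300 x 300 grid over ~1 mm is a
constructor default that any study can request. The depth range and
sampling are package choices - the corresponding clinical values are not
public - and any depth grid covering the layers is equivalent.

## The angiography pipeline

`speckle_variance()` uses the population (1/N) normalization; none of
its invariants (repeat permutation, additive shift, quadratic scaling)
depend on that choice. `threshold_sv()` zeroes values strictly below a
percentile of the *nonzero* values (default 75th), a deterministic
surrogate for the interactive brightness/contrast suppression used on
clinical displays; ties at the threshold are kept so a constant image is
unchanged.

`remove_streaks()` flags en-face rows whose median exceeds the global
row-median by more than `k = 3` MADs *and* twice the 90th-percentile row
median, then reconstructs the flagged band (plus two neighbour rows
reached by the slow-axis PSF) by linear interpolation across clean rows.
Two design points: the amplitude floor prevents capillaries that run
along the fast axis (whole-row vessels, as in the temporal sector) from
being mistaken for streaks - they elevate a row only by the slab-diluted
vessel signal, an order of magnitude less than whole-frame
decorrelation; and interpolation rather than attenuation is used because
a bulk-motion B-scan retains no in-place vessel information, while the
vessels *crossing* the band continue smoothly through it. The published
streak filters for this kind of device are not described in detail
anywhere we can implement from, so this component is a declared
stand-in validated against the phantom (vessel-pixel recall within two
percentage points of an artifact-free run at a 5% streak rate).

`enface_project()` reduces sv between two named boundaries (default ILM
to RNFL/GCL, mean reducer; max available) and `crop_enface()` takes the
centered `floor(crop/pixel)` window, idempotently.

## Layer segmentation

The ILM and the RPE/BM complex are extracted per B-scan as connected
minimum-cost paths by dynamic programming across the fast axis
(|depth step| <= 5 px per column) - the same single-boundary objective
that graph-based OCT segmenters optimize, which is sufficient at phantom
complexity. The ILM path runs on the negated positive vertical gradient,
clipped at its upper decile so that every strong edge saturates to zero
cost, with a small linear anterior bias selecting the anterior-most
strong edge; the RPE path runs on negated brightness smoothed *laterally
only* (sigma 4 px), because the bright band is only a few depth pixels
thick and axial smoothing would dilute it below the RNFL's brightness.
Intensity scale invariance comes from normalizing by the volume median.
The RNFL/GCL boundary has no usable edge at this resolution and is
derived by a fixed anterior offset from the RPE (`derive_rnfl_gcl()`,
clipped at the ILM with a warning); `fit_rnfl_offset()` calibrates the
offset against a known boundary, emulating the manual offset choice.
RNFL thickness is the lateral mean of `rnfl_gcl - ilm` averaged over 10
evenly spaced B-scans; "10 evenly spaced" and "lateral mean" are
declared defaults where the original protocol says only "10 selected
B-scans".

## Morphometry

The measurement protocol mirrors the manual one: a straight line through
the image center, perpendicular to the capillaries, counting crossings.
All estimators are algorithmic surrogates with declared defaults,
validated against phantom truth:

* `binarize()`: Otsu's threshold on the nonzero pixels after 1 px
  Gaussian smoothing; a foreground fraction above one half warns of
  inverted contrast.
* `dominant_orientation()`: structure-tensor orientation (gradient outer
  products) of the smoothed image, vessel direction perpendicular to the
  dominant gradient; images whose tensor coherence falls below 0.2 are
  rejected as isotropic with a suggestion to pass the angle explicitly.
  The pipeline falls back to the region's canonical radial orientation
  in that case - exactly the prior a human reader uses.
* `smooth_along()`: 1-D Gaussian smoothing along the vessel direction (a
  matched filter, sigma 30 um). svOCT capillaries are beaded; a reader
  counting crossings joins the beads by eye, and directional averaging
  is the algorithmic equivalent. `close_vessel_mask()` (morphological
  closing with a line element along the vessels, 30 um) removes residual
  gaps without merging adjacent parallel capillaries.
* `count_crossings()`: bilinear sampling at quarter-pixel steps; maximal
  foreground runs at least one pixel long are crossings. The line length
  is capped at the image width so oblique (arcuate-sector) lines do not
  reach the corners, where a radial network is clipped by the square
  field.
* `density_and_icd()`: density = 100 n / L, ICD = L / n, so
  density x ICD = 100 identically; zero crossings flag the ICD as
  undefined rather than dividing by zero.
* `capillary_diameter()`: per connected vessel, the profile
  perpendicular to the local orientation through the widest point
  (distance-transform maximum; the operational reading of "widest
  perpendicular chord"), measured as full width at half maximum on the
  grayscale image (binary run length as fallback); non-unimodal profiles
  are skipped and counted. FWHM on grayscale is used because it is
  robust to the binarization threshold; whether the original manual
  measurements used grayscale or thresholded images is not stated.

## Statistics

Measurements arrive in multiples per eye and subject, so all comparisons
use linear mixed models with random intercepts for eye nested within
subject (`lme4`), dropping a grouping level when it has as many levels
as observations (single-region subsets have one measurement per eye).
ICD is log-transformed before technique comparisons; the ICD-RNFL
regression is reported on the raw scale by default with the log fit one
argument away, since the published slope's scale is ambiguous. P-values
default to Satterthwaite-df t-tests (`lmerTest`): in 500-replicate null
simulations at the study's size (15 eyes x 6 regions) the
likelihood-ratio chi-square rejected ~8% at nominal 5% while the
Satterthwaite t held 4-5%, so the calibrated test is the default and
`p_method` exposes `"lrt"` and `"wald"`. Degenerate (zero-residual)
inputs fall back to the OLS solution with zero variance components,
flagged on the fit object. The age comparison is a Welch two-sample
t-test. No multiple-testing correction is applied, matching the raw
per-region reporting convention; `p.adjust` can be applied downstream.

`generate_study_table()` is the statistical stand-in for the imaging
study: ICD = region mean + slope x (RNFL - region RNFL mean) + subject
and eye random intercepts + noise, with region ICD means 31-40 um
(inside the reported 30-42 um envelope, arcuate sectors densest), RNFL
region means 80-140 um, slope -0.065 um/um, residual SD 2.5 um, subject
SD 1.5 um and eye SD 0.75 um, and a 9-subject / 16-eye roster; the
histology arm draws from a separate 9-donor cohort without RNFL. The
RNFL covariate is centered within region so the region means hold for
both techniques and the slope acts within region, which is what the
region-adjusted model estimates. The defaults were fixed from the study
design (cohort sizes, ICD envelope, slope) and from what a measurement
of this kind plausibly scatters by; they are conditions, not tuning
knobs.

## What the phantom does and does not show

The phantom reproduces: parallel radial networks with region-dependent
spacing and orientation, fully developed speckle with PSF-sized grains,
repeat-frame flow decorrelation, a layered retina with a bright RPE
band, bulk-motion streaks, and paired svOCT/histology renderings of one
truth. It does not reproduce: eye motion between B-scans (registration
is assumed perfect), pulsatile or plug flow, capillary branching and
hairpin topology (optional flags exist but validation uses parallel
networks), projection artifacts from overlying vasculature, or depth-
dependent signal roll-off. Passing tests therefore certify the
*algorithms* - variance, filtering, projection, path-finding, counting,
width estimation, mixed models - under known geometry and speckle
statistics, not clinical performance on real eyes.

## Numerical choices and degenerate inputs

Population-variance normalization; percentile thresholds computed on
nonzero values with ties kept; floor-aligned centered crops; DP path
ties broken toward the anterior boundary; orientation ties toward 0
degrees; Otsu on a 256-bin histogram; bilinear sampling clamped at
image borders; the ILM reported at the voxel boundary (the edge lies
between voxels) and the RPE at the voxel center of the brightest band.
All generators consume their RNG inside a seed sandbox (`with_seed`)
that restores the caller's RNG state, and the amount of RNG consumed
does not depend on parameter values, so decorrelation sweeps are
common-random-number comparisons. Problem sizes used in the test suite
(72-160 px lateral grids, 400-700 um fields, 3-10 seeds, 200-500
simulation replicates) are the package's desk-scale defaults chosen so a
full check runs in minutes on one core.
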
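# rpcsvoct

Label-free angiography of the radial peripapillary capillaries (RPCs) by
speckle-variance optical coherence tomography (svOCT), with a synthetic
phantom that makes every stage of the analysis testable against known
ground truth.

The RPCs are long, parallel capillaries inside the retinal nerve fibre
layer (RNFL) around the optic disc; they feed the retinal ganglion cell
axons whose degeneration defines glaucoma and related diseases. svOCT
images them without contrast agents: at each slow-axis location the
scanner acquires N repeat B-scans, and the per-voxel intensity variance
across repeats,

    sv(x, z, y) = (1/N) * sum_t ( I_t - mean(I) )^2 ,

is high where moving blood decorrelates the speckle and low in static
tissue. Projecting sv over the RNFL slab (between the ILM and the
RNFL/GCL boundary) gives an en-face angiogram, from which the package
measures:

* **capillary density** — crossings of a sampling line drawn through the
  image center perpendicular to the capillaries, per 100 um;
* **inter-capillary distance** — ICD = line length / crossings, so
  density x ICD = 100 identically;
* **capillary diameter** — full width at half maximum of the intensity
  profile across each vessel at its widest point;
* **RNFL thickness** — from minimum-cost-path segmentation of the ILM
  and RPE/BM boundaries, with the RNFL/GCL boundary derived by an
  anterior offset;

and analyses them with linear mixed models (random intercepts for eye
nested within subject): ICD against RNFL thickness adjusted for region,
svOCT-vs-histology technique contrasts on log ICD, and arcuate-vs-other
region contrasts.

Because no public data of this kind exist, the `phantom` functions
generate parallel capillary networks with known spacing, diameter, depth
and orientation, and render them two ways from the same truth: as
repeat-frame OCT volumes with coherent (complex-field) speckle, PSF
blur, flow decorrelation and optional bulk-motion streaks, and as
histology-style en-face images at confocal resolution. The beam optics
are computed in closed form (coherence length ~6 um in tissue from a
1060 nm / 61.5 nm source; focal waist ~7.3-7.5 um, lateral FWHM
~8.6 um, from schematic-eye constants).

## Worked example

Simulate one temporal-sector phantom with 35 um capillary spacing,
run the full angiography pipeline, and measure it:

```r
library(rpcsvoct)

geom <- scan_geometry(fov_um = 700, n_fast = 160, n_slow = 160)
net  <- generate_network("Temp", spacing_um = 35, diameter_um = 5, seed = 1,
                         fov_um = 700)
net
#> capillary_network: 20 capillaries, region Temp
#>   FOV 700 um, spacing 35 um, diameters 5-5 um
#>   dominant angle 0.00 deg, depth band 60-130 um, seed 1

rnd <- render_oct_volume(net, retina_layers(geom), geom,
                         speckle_params(seed = 1))
sv  <- speckle_variance(rnd$volume)
seg <- segment_boundaries(rnd$volume)
lm  <- derive_rnfl_gcl(seg$ilm, seg$rpe, offset_um = 120)
ef  <- crop_enface(threshold_sv(remove_streaks(enface_project(sv, lm)), 75),
                   636.5)
measure_enface(ef, region_label = "Temp", technique = "svOCT")
#> morphometry_result [Temp] (svOCT)
#>   18 crossings over 630.0 um -> density 2.86 /100um, ICD 35.0 um
#>   diameter: 8.35 um (mean of 16 vessels)
```

The measured ICD (35.0 um) recovers the generated 35 um spacing; the
measured diameter (8.4 um) exceeds the true 5 um because the 8.6 um
lateral PSF convolves with the vessel profile — the same bias direction
seen when in vivo svOCT diameters are compared with histology.

The statistical layer works the same way from a synthetic study table:

```r
tab <- generate_study_table(n_subjects = 9, rnfl_slope = -0.065, seed = 1)
fit_icd_rnfl(tab)
#> Linear mixed model (identity(ICD) ~ RNFL + region), 96 observations
#>         term  estimate     se        p
#>  (Intercept) 47.592000 2.2790 5.34e-35
#>      rnfl_um -0.072796 0.0172 6.02e-05
#>     regionST -6.757300 0.8945 8.40e-11
#>  ...
#> variance components: subject=0, eye_in_subject=1.076, residual=5.632
#> RNFL slope: -0.0728 (SE 0.0172, p = 6.022e-05)

# the generating slope (-0.065) is inside one standard error of the fit
```

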
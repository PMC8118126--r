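---
title: "Mid-sagittal surface estimation and hemispheric asymmetry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mid-sagittal surface estimation and hemispheric asymmetry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fissura)
```

## The problem

Brain asymmetry studies in FLAIR MRI need the cerebral hemispheres separated
first. The boundary is the interhemispheric fissure (IF): a CSF-filled
longitudinal fissure that appears dark in FLAIR because the CSF signal is
nulled. Classical approaches fit a single *mid-sagittal plane*, which fails
when the fissure bends — from pathology or from natural brain torque, most
visible occipitally — and when the bright septum pellucidum between the
lateral ventricles pulls plane estimators into the dark ventricles.

`fissura` estimates a *mid-sagittal surface* instead: a smooth per-slice
curve `m(row) -> column` fitted independently on every axial slice, so the
surface follows fissure curvature slice by slice. The package assumes
brain-extracted input on a standardized intensity scale where CSF sits below
200, normal-appearing brain matter (NABM) in [200, 400] and hyperintense
lesions above 400; `rescale_to_standard()` offers a simple percentile-based
affine map onto that scale for data standardized elsewhere.

## The three-stage estimator

**Stage 1 — head-angle correction.** A bilaterally symmetric slice equals
its reflection about its own symmetry axis. The middle slice is reflected
over the vertical axis, the reflection rotated by `2 * theta` for each
candidate angle in [-20, 20] degrees at 0.5 degree steps, and the normalized
cross-correlation with the original slice is maximized. Correlation is
computed zero-mean over the union of the brain masks so overall brightness
does not bias the score. Ties break toward the smaller |theta|. Near-circular
heads make the score curve flat; when its range falls below 1% of its
maximum the angle is forced to 0 with a warning, because every angle is then
equally supported. The whole volume is then rotated by `-theta` (bilinear
for intensities, nearest-neighbor for masks).

**Stage 2 — control points.** On each *cerebral* slice (brain area at least
half the largest slice's area — the spec of "cerebral" is otherwise
operational) a 2 cm band centered on the middle column is cut into 2 x 2 cm
ROIs starting at the first brain row; a final partial window is kept if it
spans at least half a window. Each ROI casts up to eight votes for the
fissure column:

* per-column intensity sum, energy and RMS over brain pixels (argmin — CSF
  is dark), and the cumulative-energy balance column where the running sum
  of column energies first reaches half the ROI total;
* a gradient-valley vote: the per-column mean gradient magnitude is scanned
  for its two highest local peaks at least 3 px apart (the fissure walls)
  and the minimum strictly between them is voted;
* a Gabor texture-energy vote (4 orientations, wavelengths 4 and 8 px,
  sigma = lambda/2, quadrature pairs, DC-free, replicate padding): argmin by
  default, since homogeneous CSF responds weakly and textured parenchyma
  strongly — the opposite polarity is available as `gabor_vote = "max"`;
* two mirrored-symmetry votes: every column is a candidate axis, the right
  part is reflected onto the left, and the mean squared intensity difference
  (`mse_sym`) and mean absolute gradient difference (`mgs_sym`) over the
  overlap are minimized. Candidates with fewer than 3 overlap columns are
  excluded. A literal maximum-error reading of the MSE rule is available as
  `mse_vote = "max"`, but under the mirrored-difference construction the
  minimum is the coherent choice and is the default.

The ROI's control point is the **lower median** of the vote columns —
deterministic for even counts, and robust enough that a single stray feature
(or a lesion inside the band) cannot move it.

*Septum pellucidum.* If more than half of a ROI's brain pixels fall below
the CSF threshold the ROI is ventricle-dominated: intensities are inverted
(`max - I`), which turns the bright septum into the dark line the features
look for. In the inverted ROI only the four intensity-profile features vote.
The texture, gradient and symmetry scores are dominated there by the large,
now-bright, homogeneous ventricle interiors and systematically vote inside a
ventricle (observed directly on seeded septum phantoms); the intensity
profiles are exactly the dark-line detectors the inversion is meant to
re-enable.

*Cross-slice repair.* Per ROI index, control-point columns across slices are
screened with a 3-scaled-MAD rule (scaled MAD = 1.4826 x median absolute
deviation; when the MAD is zero, absolute deviations above 3 px are flagged
instead). Flagged points are replaced by the mean of the nearest unflagged
neighbors in adjacent slices and marked `repaired`; unflagged points are
never moved.

**Stage 3 — midline and hemispheres.** The control points of a slice are
interpolated with a shape-preserving (monotone Fritsch-Carlson) piecewise
cubic, sampled at every row of their span, and a least-squares cubic
polynomial is fitted over those samples; with fewer than four points the
degree drops to n - 1. The polynomial — the final smooth representation —
is evaluated at every brain row and extrapolates beyond the control-point
span. One numerical consequence worth knowing: monotone Hermite slopes are
not polynomial-exact, so control points lying exactly on a quadratic are
reproduced to about 5e-3 px rather than machine precision; linear
configurations are exact.

Hemispheres follow the half-open rule: `col < m(row)` is left, `col >= m(row)`
is right. When a head-angle correction was applied, every *native* brain
voxel is mapped into the corrected frame analytically and classified there,
so the native masks are an exact partition of the native brain mask — no
mask resampling is involved. Non-cerebral slices inherit the nearest
cerebral slice's midline so the partition covers the whole brain.

## Validation metrics and cohort QC

`mean_hausdorff()` implements the mean-of-minimum-distances variant (both
directed distance vectors concatenated, then averaged) in pixel units;
`mean_absolute_distance()` compares midline columns row by row in mm; and
`volume_difference()` reports per-hemisphere |volume| differences in mL.
Each is cross-checked in the test suite against brute-force double-loop
oracles.

For cohorts without ground truth, the volumetric asymmetry index
`AI = |V_L - V_R| / (V_L + V_R)` is z-scored across the cohort (population
standard deviation) and volumes with `z > 3` are flagged, one-sided: low AI
means good symmetry and is never anomalous. A single outlier cannot
mathematically exceed z = 3 in cohorts smaller than about a dozen, so the
QC is meant for cohort-scale use.

## Texture asymmetry biomarkers

After resampling to a common grid (0.35 x 0.35 x 3 mm by default) the NABM
of each hemisphere is extracted by the [200, 400] band. Classical 8-bit LBP
codes (radius 3, 8 neighbors sampled bilinearly, ties `>=` so a constant
patch codes 255) are computed per slice and averaged pixel-wise across
slices; 10 features are taken from the averaged map — mean, median,
variance, skewness, kurtosis from its first-order distribution, and
contrast, energy, correlation, homogeneity from a 32-level, offset-1,
4-orientation symmetric co-occurrence matrix, plus Shannon entropy of the
32-bin histogram. Asymmetry per feature is `|f_L - f_R| / (f_L + f_R)`.

Two deliberate choices here:

* **The right hemisphere is analyzed mirrored.** LBP codes are directional;
  identical tissue reflected left-right produces bit-permuted codes with
  different first-order statistics. Flipping the right hemisphere's columns
  puts both hemispheres in one anatomical frame, makes the features of a
  perfectly mirrored volume identical by construction, and removes a
  left/right baseline bias that otherwise masks genuine texture asymmetry.
* **The NABM mask is eroded by the LBP radius** before texture mapping, so
  every code's 7 x 7 window lies inside NABM. Codes whose window touches the
  fissure or ventricle wall encode boundary geometry, not tissue
  microstructure.

Group statistics follow the standard chain: Box-Cox transform of the
asymmetry values (maximum-likelihood lambda on a [-2, 2] grid; zeros shifted
by half the smallest positive value), one-way ANOVA across diagnosis groups
with Tukey HSD post-hoc contrasts, and — controlling for age or sex — an
ANCOVA linear model with Type-II F tests and Tukey-adjusted contrasts on
covariate-adjusted means (`emmeans`).

## What the phantom generator emulates

`generate_phantom()` builds an elliptical "head" per slice (mild taper
toward the first and last slice), carves a dark fissure band along a known
cubic `c(row)` — constant, curved, or varying per slice to emulate torque —
optionally adds dark lateral ventricles with a bright septum band, lesion
blobs above 400, per-class clipped Gaussian intensities, and finally rotates
everything in-plane by a known angle (truth midlines are transformed as
points, never resampled). Defaults: 10 slices of 128 x 128 at 3 x 1 x 1 mm,
fissure width 3 px at intensity 120, NABM 300 +/- 25, curvature on the
few-pixel scale of natural torque, taper 0.85 so all slices count as
cerebral. `generate_cohort()` jitters angle and fissure position and can
corrupt a fraction of volumes by truncating the outer ~40% of one
hemisphere — the gross brain-extraction/off-center failure mode the AI QC
must catch.

Hemispheric degeneration (`texture_contrast`) is modeled as *pattern*, not
amplitude: the NABM texture is a unit-variance mix of a spatially smoothed
field and white noise whose rough weight grows with the contrast level, plus
small dark ridge-like damage spots whose density grows with it and which are
shared across slices. Both choices are forced by the descriptors
themselves: LBP codes are invariant to monotone intensity changes, so a
noise-variance multiplier is invisible to them, and per-slice random spots
vanish under pixel-wise slice averaging — only volume-persistent structure
survives, as it does in real anatomy. Spot density and depth were chosen to
put the mean asymmetry steps between adjacent levels near the scale reported
for adjacent diagnosis groups in real cohorts (~0.05).

What the phantom does *not* emulate: cortical folding, partial-volume
effects, bias fields, acquisition noise correlation between slices, or MR
physics of any kind. Passing tests therefore demonstrate algorithmic
correctness against a known geometry — fissure tracking under curvature,
torque, rotation, septum and lesions; exact partitions; QC sensitivity;
biomarker direction — not clinical performance on scanner data, whose
headline accuracy requires multi-center volumes with manual ground truth.

## Problem sizes and numerical choices

The validation suite runs 20 phantoms (128 x 128 x 10) through the full
pipeline, 10 cohorts of 50 smaller phantoms (96 x 96 x 8) for QC flagging,
and three 30-subject cohorts (96 x 96 x 6, already on a common grid, so the
resampling step is an identity and is skipped) for the biomarker direction
checks; the ANOVA power (100 replicates) and type-I (200 replicates)
simulations draw asymmetry values parametrically at the effect sizes the
synthetic groups produce, since regenerating image cohorts per replicate
adds nothing to what the single imaging run already establishes.

Degenerate inputs are handled explicitly: constant images refuse to rescale;
empty masks refuse angle estimation; ROIs without brain pixels cast no votes
and slices without any control point fall back to the volume-median midline
with a warning; constant texture maps report skewness/kurtosis/correlation
as 0 with a warning; zero AI spread yields no QC flags, with a warning. Ties
everywhere are resolved deterministically (leftmost argmin, lower median,
center column for flat Gabor profiles), so the pipeline is bit-reproducible:
all randomness lives in phantom seeds.

## Known limitations

* The intensity-standardization and brain-extraction stages of a production
  pipeline are out of scope; inputs are assumed standardized and masked, and
  the built-in rescaler is a two-point affine map only.
* The head-angle score can be flat for near-circular heads; the estimator
  then reports 0 degrees rather than guessing.
* Mean Hausdorff distances are computed in isotropic pixel units within a
  slice; strongly anisotropic in-plane grids should be resampled first.
* The AI QC detects *volumetric* failures; a midline that is wrong but
  volume-balanced (for example an S-shaped error) can pass it.
* Feature votes assume FLAIR contrast (dark CSF); other sequences would need
  the vote polarities revisited.
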
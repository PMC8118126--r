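# fissura

Unsupervised mid-sagittal **surface** estimation for FLAIR MRI, with
hemisphere separation, validation metrics, cohort-scale quality control and
hemispheric texture asymmetry biomarkers.

## The problem

Brain asymmetry studies need the cerebral hemispheres separated along the
interhemispheric fissure (IF) — the CSF-filled longitudinal fissure that
appears dark in FLAIR. Planar mid-sagittal estimators fail when the fissure
curves (pathology, natural brain torque) and tend to fall into the dark
lateral ventricles where the bright septum pellucidum interrupts the CSF
line. `fissura` estimates the midline per axial slice in three stages:

1. **Head-angle correction** — maximize the normalized cross-correlation
   between the middle slice S and its vertical reflection R rotated by 2θ,
   over θ ∈ [−20°, 20°] in 0.5° steps; rotate the volume by −θ̂.
2. **Control points** — inside a 2 cm band centered on the middle column,
   each 2 × 2 cm ROI casts feature votes for the fissure column (intensity
   sum/energy/RMS/cumulative energy, gradient valley, Gabor energy,
   mirrored-symmetry MSE and gradient symmetry); the control point is the
   lower median of the votes. Ventricle-dominated ROIs (> 50% CSF) are
   intensity-inverted so the septum becomes the dark line. Across slices, a
   3-scaled-MAD rule flags stray points and repairs them from neighboring
   slices.
3. **Midline generation** — shape-preserving piecewise-cubic interpolation
   through the control points, then a least-squares cubic polynomial
   `m(r) = p0 + p1 r + p2 r² + p3 r³`; voxels with `col < m(row)` are left
   hemisphere, `col ≥ m(row)` right.

Around the estimator the package provides the validation metrics
(mean Hausdorff distance, mean absolute distance in mm, hemispheric volume
difference in mL), a ground-truth-free QC statistic
`AI = |V_L − V_R| / (V_L + V_R)` with one-sided z > 3 outlier flagging, LBP
texture asymmetry biomarkers of the normal-appearing brain matter
(`Δf = |f_L − f_R| / (f_L + f_R)`, with Box-Cox + ANOVA + Tukey HSD and
age/sex ANCOVA), and a synthetic phantom generator with analytically known
midlines so the whole pipeline is testable without clinical data.

## Worked example

```r
library(fissura)

# a phantom with known 10-degree head rotation and known midline
ph  <- generate_phantom(phantom_spec(theta_true = 10, seed = 42))
res <- estimate_volume_midline(ph$volume)
res
#> <midline_result> 10 slices (10 cerebral), theta_used = 10.0 deg

evaluate_midline(res, ph$truth, ph$volume$spacing)
#> # A tibble: 1 x 5
#>   mean_hd_px mad_px mad_mm dv_left_ml dv_right_ml
#>        0.546  0.546  0.546      0.864       0.864

v <- hemisphere_volumes(res$hemispheres, ph$volume$spacing)
asymmetry_index(v["v_left"], v["v_right"])
#> 0.00743
```

The rotation is recovered exactly (10.0°), the estimated midline tracks the
analytic fissure to ~0.5 px on average (mean Hausdorff and mean absolute
distance), each hemisphere volume is within ~0.9 mL of truth, and the
asymmetry index of the resulting split is 0.007 — far below the z > 3
outlier region a failed split would occupy.

`run_volume()` and `run_cohort()` wrap the pipeline for NIfTI files and
manifest CSVs; `inst/cli/fissura.R` exposes `simulate` / `estimate` / `qc`
subcommands for shell use. See the vignette
(`vignettes/midline-estimation.Rmd`) for the model, parameter and design
discussion.

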
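# cartimetrics

Quantitative analysis of combined morphologic and quantitative knee MRI of
articular cartilage and subchondral bone, exercised end to end on a digital
knee phantom.

Modern magnetization-prepared turbo-spin-echo sequences deliver two or three
differently prepared morphologic images from one acquisition and, as a
by-product, voxel-wise T2 or T1ρ maps fitted from those images. Evaluating
whether such a sequence can replace conventional 2D/3D TSE references
requires a battery of image-quality and compositional measurements:

* **Defect delineability** — signal-intensity line profiles through a
  cartilage defect, scored by full width at half maximum (FWHM, the half
  level halfway between the cartilage background and the profile maximum)
  and edge width (EW, the mean 10–90 % transition width of the two defect
  shoulders). For an erf-shaped edge, EW = 2.563 σ of the effective
  point-spread function.
* **Bone texture** — first-order variance plus gray-level co-occurrence
  matrix (GLCM) features in a circular subchondral ROI: joint energy
  Σ p², joint entropy −Σ p log₂ p, inverse difference Σ p/(1+|i−j|),
  computed on intensities min–max normalized to [0, 1] and quantized into
  200 evenly spaced bins; symmetric distance-1 GLCM, features averaged
  over the four in-plane directions.
* **Relaxometry** — voxel-wise mono-exponential fits
  S(τ) = S₀·exp(−τ/T) by log-linear least squares (exactly the two-point
  closed form T = Δτ/ln(S₁/S₂) for the two-echo T2 protocol), with a
  noise-floor validity mask and cap.
* **Regional statistics** — mean ± SD of the maps over anterior/central/
  posterior femoral and tibial cartilage regions, voxel-weighted pooling,
  and a one-pixel-step digital-caliper thickness measurement.
* **Statistics** — repeated-measures ANOVA with Tukey–Kramer post hoc
  comparisons, exact Wilcoxon matched-pairs signed-rank tests (full 2ⁿ
  sign-assignment enumeration), two-tailed paired t-tests, Cohen's d, and
  the z-approximation minimum sample size
  n = ⌈((z₁₋α/₂ + z_power)/d)²⌉.

Because cadaveric study data are rarely deposited, the package includes a
digital sagittal knee phantom — curved cartilage band on a femoral condyle,
tibial plateau, textured marrow, fluid, muscle — with punch-type
full-thickness cartilage defects (3/5/8 mm), Gaussian point-spread blur and
Rician noise, so the whole chain runs on inputs with known ground truth.
`run_study()` chains everything over a simulated cohort and applies the
statistical battery at a family-wise α = 0.01.

## Worked example

```r
library(cartimetrics)

model <- build_phantom(phantom_spec())        # 224×224 @ 0.27 mm, defects 3/5/8 mm

# ideal (noise- and blur-free) two-echo T2-prepared stack -> exact recovery
ideal <- simulate_stack(model, sequence_params("T2prep-PDFS"))
t2map <- map_relaxation(ideal, mask = model$region > 0, floor = 0)
regional_stats(t2map, region_labels(model))
#> # A tibble: 5 × 4
#>   region  mean    sd n_voxels
#>   <chr>  <dbl> <dbl>    <int>
#> 1 aF      48    0         406
#> 2 cF      51    0         247
#> 3 pF      64    0         379
#> 4 T       41.0  0         896
#> 5 all     48.3  8.61     1928

# realistic acquisition: 0.5 mm PSF blur, Rician noise at SNR 50
stack <- simulate_stack(model, sequence_params("T2prep-PDFS", blur_sigma = 0.5),
                        noise_sigma = 20, seed = 7)
ends <- defect_line_endpoints(model, diameter = 5)
delineate_defect(stack$images[[1]], ends$p0, ends$p1, model$spacing,
                 relative = TRUE)
#> # A tibble: 1 × 6
#>    fwhm    ew shoulder_left shoulder_right background half_level
#>   <dbl> <dbl>         <dbl>          <dbl>      <dbl>      <dbl>
#> 1  4.93  1.44          1.41           1.47      0.512      0.756

min_sample_size(power = 0.80, alpha = 0.01, d = 1.24)
#> [1] 8
```

The 5 mm defect is recovered at 4.93 mm FWHM; the 1.4 mm edge widths
reflect the 0.5 mm PSF (2.563 σ ≈ 1.28 mm) plus noise; the regional means
reproduce the phantom's ground-truth relaxation times exactly when blur and
noise are off. The minimum cohort size for a paired effect of d = 1.24 at
80 % power and α = 0.01 is 8.

A full simulated cohort:

```r
study <- run_study(study_config(seed = 1))
study$regional    # pre/post regional relaxation times with Wilcoxon p-values
study$delineability
study$texture
plot_regional(study)
```

## Package layout

| Area | Files |
|---|---|
| Phantom & simulation | `R/phantom-spec.R`, `R/phantom-build.R`, `R/phantom-simulate.R` |
| Relaxometry | `R/relaxometry.R` |
| Delineability | `R/delineability.R` |
| Texture | `R/texture.R` |
| Regional statistics | `R/regional.R` |
| Statistical battery | `R/stats-tests.R` |
| Study pipeline | `R/pipeline.R` |
| NIfTI I/O | `R/nifti-io.R` |
| Plots | `R/plots.R` |

The methods vignette (`vignettes/cartimetrics-methods.Rmd`) documents the
signal model, the phantom's design choices and limitations, both edge-width
threshold conventions, and every numerical default.
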
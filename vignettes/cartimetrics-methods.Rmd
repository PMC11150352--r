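---
title: "Methods: phantom-based analysis of combined morphologic and quantitative knee MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-based analysis of combined morphologic and quantitative knee MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(cartimetrics)
library(dplyr)
```

## Scope and rationale

`cartimetrics` implements the quantitative analysis chain used to compare
combined morphologic/quantitative knee MRI sequences against conventional
turbo-spin-echo references: defect-delineability scoring from signal-intensity
line profiles, gray-level co-occurrence matrix (GLCM) bone-texture features,
mono-exponential T2 and T1ρ relaxometry, regional cartilage statistics with a
digital-caliper thickness measurement, and the accompanying statistical
battery. Because cadaveric acquisitions of this kind are rarely shared, the
package also ships a digital knee phantom that emulates the acquisition
geometry, so every stage can be exercised, tested, and calibrated end to end
on data with known ground truth. Real data enter through the same interfaces
(NIfTI images and label maps, line endpoints in world millimeters).

## The signal model

Magnetization-prepared acquisitions differ only in the duration τ of their
preparation module. We model the prepared signal of voxel $x$ as

$$S(x, \tau) = \mathrm{PD}(x)\, e^{-\tau / T_c(x)}\, f(x),$$

where $T_c$ is T2 under T2 preparation and T1ρ under spin-lock preparation,
PD absorbs proton density and all sequence-level scalings that do not depend
on τ (TR/T1 saturation, echo-train weighting), and $f$ is a scalar
fat-suppression factor (default 0.05) applied to fat-flagged voxels on
fat-suppressed echoes. Two things the model deliberately leaves out: k-space
sampling (the readout's effect is summarized by a Gaussian point-spread
blur, σ in mm, truncated at 4σ, reflective boundaries, unit-sum kernel) and
spectral fat physics (a scalar attenuation stands in for SPAIR/SPIR). Noise
is Rician: the magnitude of the complex signal perturbed by independent
Gaussian noise on both quadrature channels, which leaves the familiar
Rayleigh floor of mean $\sigma\sqrt{\pi/2}$ in air.

With blur and noise off, the simulation is exact, which is what makes the
relaxometry round trip a machine-precision test rather than a tolerance
test.

## The digital phantom

The phantom is a sagittal knee-like slice: a femoral condyle (cortical shell
around trabecular marrow) carrying a curved cartilage band of uniform 3 mm
thickness over a 110° arc, a thin intra-articular fluid film, a flat tibial
plateau with its own 2 mm cartilage layer, muscle, and an air frame. Default
in-plane spacing is 0.27 mm — the value obtained from a 140 mm field of view
reconstructed on a 512 matrix (`pixel_spacing(140, 512)`).

Cartilage defects are modeled on surgical punch defects: full-thickness,
fluid-filled gaps whose width across the band mid-surface equals the nominal
punch diameter (3, 5, 8 mm by default), placed anterior to posterior. A disk
of diameter $d$ centered mid-band would be full-thickness only at its center
line, so the arc-width-gap construction is the faithful sagittal section of
a cylindrical punch. `measure_defect_gap()` verifies each rasterized gap to
within one voxel.

Regional ground truth uses representative means for human femorotibial
cartilage at 3 T: T2 of 48/51/64/41 ms and T1ρ of 43/41/34/36 ms for the
anterior, central, posterior femoral and tibial regions. Region boundaries
are arc-length thirds of the femoral band; anatomical (meniscus-based)
landmarks have no synthetic counterpart. Marrow receives a smoothed,
seeded Gaussian proton-density texture (relative SD 0.25, correlation
length 0.4 mm) so that texture features have structure to measure.

```{r phantom, fig.height = 4}
model <- build_phantom(phantom_spec())
autoplot(model)
```

What the phantom does *not* emulate: layer-wise (zonal) cartilage
architecture, magic-angle and B1 effects, TR-dependent T1ρ saturation,
susceptibility, motion, and the anatomy of a real joint. Tests passing on
the phantom therefore validate the *analysis* — geometry handling, fitting,
feature mathematics, statistics — not the biological interpretation of any
particular relaxation time.

## Relaxometry

Maps are reconstructed by unweighted log-linear least squares on
$\ln S = \ln S_0 - \tau/T$, which is exact on noiseless mono-exponential
data and reduces to the closed form $T = \Delta\tau / \ln(S_1/S_2)$ for the
two-point T2 protocol (τ = 0, 50 ms; the spin-lock protocol uses τ = 0, 25,
50 ms). A nonlinear fit would buy nothing at 2–3 points and would introduce
initialization and convergence choices.

Voxels are masked invalid when any echo falls at or below the validity
floor, when the signal does not decay, or when the fitted time exceeds the
cap (default 500 ms — loose on purpose, since fluid sits near 400 ms and
clipping pathology would bias regional means). The default floor is three
times the background sigma estimated from the image's 2 mm air frame using
the Rayleigh median ($\tilde m = \sigma\sqrt{2\ln 2}$); the median keeps
stray bright voxels in the frame from inflating the estimate. Invalid
voxels are encoded as `NA` and never reach regional statistics, which is
asserted by poisoning tests.

Under Rician noise the log-linear estimator is biased (the noise floor
lifts late echoes); the bias shrinks monotonically as σ → 0, which the
suite checks over a seeded noise ladder. At SNR 50 the cartilage-mean T1ρ
error stays below 2 %.

## Defect delineability

Line profiles are sampled by bilinear interpolation at uniform arc-length
steps (default one quarter of the pixel spacing) along a world-space
segment, then normalized to maximum 1. The cartilage background is the mean
of the two flank means (first and last 20 % of samples by default — the
measurement is operator-defined in practice, so the convention is explicit
and configurable).

* **FWHM** — the half level sits halfway between background and maximum;
  crossings are located by linear interpolation and taken nearest the
  global maximum on each side. For a rectangular defect convolved with a
  Gaussian PSF, the half-level crossing of each erf-shaped edge falls at
  the true edge position, so FWHM recovers the nominal diameter as long as
  the defect is wide relative to σ; the suite verifies 3/5/8 mm recovery
  within ±0.5 mm at σ ≤ 0.5 mm against a brute-force convolution oracle.
* **Edge width (EW)** — per shoulder, the distance between the 10 % and
  90 % intensity crossings; EW is the mean of the two shoulders. For an
  erf edge, EW = 2.563 σ, which links the measured edge width directly to
  the effective PSF. Two reading conventions exist for the thresholds:
  absolute fractions of the normalized maximum (the default, following the
  letter of the usual description) and fractions of the background-to-
  maximum range (`relative = TRUE`). On fat-saturated cartilage the
  background sits well above 10 % of the maximum, making the absolute 10 %
  level unreachable — the function then signals
  `cm_threshold_unreachable`. The study pipeline therefore uses the
  relative reading; both are exposed because published descriptions do not
  disambiguate them.

## Bone texture

Texture is measured in a circular ROI (default 40 px diameter, voxel
centers within the radius) placed in the trabecular marrow radially beneath
the 5 mm defect. Intensities are min–max normalized over the whole stack to
[0, 1] — making every feature invariant to positive affine intensity maps —
and quantized into 200 evenly spaced bins via
$k = \min(\lfloor v \cdot n \rfloor, n - 1)$.

The GLCM accumulates co-occurrences at the four unique distance-1 in-plane
offsets, symmetrically (both orders), normalizes each offset matrix to sum
1, and averages features across offsets: joint energy $\sum p^2$, joint
entropy $-\sum p \log_2 p$ (zero cells skipped), inverse difference
$\sum p / (1 + |i - j|)$. First-order variance is the population variance
of the raw normalized ROI values. These defaults mirror the documented
conventions of the standard radiomics implementation but all are
configurable; the mathematics is re-implemented here and validated against
a brute-force double-loop oracle, exactly.

Blurring an image makes neighboring values more alike, so energy and
inverse difference rise and entropy falls with increasing PSF σ — the
directional fingerprint of a smoother sequence, which the suite asserts on
the phantom's textured marrow.

## Regional statistics and thickness

`regional_stats()` reports mean, SD, and voxel count per region plus a
pooled "all regions" row. Pooling is voxel-weighted
($\bar T = \sum n_i m_i / \sum n_i$), stated explicitly so a
mean-of-region-means can be recomputed from the same output if preferred;
the identity is asserted to 1e-12. Study-level tables summarize
across-specimen SDs of per-specimen means; per-case voxel SDs remain in the
per-specimen records.

Thickness uses a digital-caliper convention: from the query point, step
voxel by voxel along the surface normal while inside the cartilage mask;
thickness is the contiguous count times the spacing, quantized to one
pixel by construction.

## Statistical battery

All tests operate on long tibbles (subject, condition, value).

* Repeated-measures ANOVA: one-way within-subject,
  $F = MS_\text{cond}/MS_\text{err}$, df $(k-1)$, $(k-1)(n-1)$; no
  sphericity correction (k = 3 with a post hoc, matching common practice at
  this design size). Verified against `aov()` with an `Error(subject)`
  stratum.
* Tukey–Kramer post hoc: studentized range on the pooled error term,
  $q = |\Delta|/\sqrt{MS_\text{err}/n}$, adjusted p from `ptukey`. At
  k = 2 this is algebraically the paired t-test ($q = t\sqrt2$), asserted
  to 1e-9.
* Wilcoxon matched-pairs signed-rank: zeros discarded, mid-ranks for ties;
  the exact two-sided p enumerates all $2^n$ sign assignments (implemented
  as a subset-sum convolution over doubled ranks, identical to literal
  enumeration, which the oracle test confirms for n ≤ 12 including ties).
  Normal approximation with tie correction above n = 25. The smallest
  attainable two-sided p at n = 10 is $2/2^{10} \approx 0.002$.
* Paired t-test and Cohen's d use the paired-differences conventions.
* Minimum sample size: the z-approximation
  $n = \lceil ((z_{1-\alpha/2} + z_{\text{power}})/d)^2 \rceil$ is the
  default; at power 0.80, α = 0.01 two-sided, d = 1.24 it gives n = 8. A
  noncentral-t mode is offered and labeled, because power software differs
  and the z-formula is an inference, not a documented choice.

Under 10⁴ seeded null replicates at n = 10, both the paired t and the exact
Wilcoxon reject at ≤ α + 2 Monte-Carlo SEs for α = 0.01.

## The end-to-end study emulation

`run_study()` chains everything over a cohort of simulated specimens
(default 10, the usual size for cadaveric work of this kind):

```{r study-shape, eval = FALSE}
study <- run_study(study_config(seed = 1))
study$regional
```

Design choices that were genuinely open:

* **Inter-specimen variability** — lognormal multipliers (mean 1, relative
  SD 0.08) on all cartilage relaxation times, drawn independently for T2
  and T1ρ per specimen. Lognormal keeps times positive; 0.08 matches an
  across-specimen SD near 4 ms on a 50 ms mean. Pre and post phantoms of a
  specimen share the multiplier and the anatomy seed, so paired differences
  isolate the defect effect.
* **Defect-induced shifts** — additive regional increases applied before
  the multiplier: T2 +1/+5/+5/+4 ms and T1ρ +3/+2/+5/+4 ms
  (aF/cF/pF/T), i.e. the pattern of mild post-surgical elevation with the
  largest T2 change in the central femur where the defects sit.
* **Per-sequence PSF** — 0.40 / 0.55 / 0.60 mm for the 2D TSE, 3D TSE, and
  MIXTURE-type sequences, back-solved once from typical measured edge
  widths via EW = 2.563 σ; the ordering encodes the sharper 2D readout.
* **Noise** — Rician σ = 20 against a cartilage proton density of 1000,
  i.e. SNR 50 at τ = 0.
* **Multiplicity** — regional pre/post Wilcoxon p-values are
  Holm-adjusted within each parameter family; the family-wise level is
  α = 0.01.

Problem sizes throughout (224² grid, single slice, 10 specimens, 10-seed
noise repeats, 10⁴ null replicates) were chosen as the smallest sizes at
which every quantity of interest is stable to well within its assertion
tolerance.

## Known limitations

* The measured post-defect regional elevation exceeds the injected shift:
  blurred fluid signal (T2 ≈ 400 ms) from the defect gaps contaminates
  adjacent cartilage voxels and biases the fit upward near the margins.
  This partial-volume mechanism is real — it is one reason manual
  segmentation in practice avoids fluid interfaces — but it means the
  study table's post-minus-pre differences measure the combined effect,
  not the injected shift alone. The detection claim (Wilcoxon at
  α = 0.01) is unaffected.
* The log-linear fit is noise-floor biased at low SNR; no Rician
  correction is applied (none is documented for the scanner-side fits it
  emulates).
* T1ρ physics beyond mono-exponential spin-lock decay (B1, spin-lock
  frequency dependence, TR saturation) is out of scope, so the phantom
  cannot reproduce — and does not attempt to explain — the occasionally
  reported T2 > T1ρ anomaly in cartilage.
* Thickness in the phantom is constant by construction, so the pre/post
  thickness comparison is degenerate (p = 1); it exercises the caliper
  and the paired t-test plumbing, not a biological hypothesis.
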
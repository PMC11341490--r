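---
title: "Monte Carlo morphometry of the femoral medullary canal: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo morphometry of the femoral medullary canal: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canalmorph)
```

## The problem

Femoral stem prostheses must fit the medullary canal — the marrow-filled
interior of the femur — whose transverse cross sections narrow from the
proximal metaphysis to the isthmus (the narrowest point) and widen again
distally, giving the canal its characteristic trumpet shape. Classical
preoperative morphometry measures a handful of diameters along the coronal
axis at reference sections anchored to the lesser trochanter, and condenses
them into flare indices. Those single-axis diameters ignore how irregular
the cross sections really are; per-slice *areas* of the medullary cavity
and of the surrounding cortical bone capture the full cross-sectional
geometry.

`canalmorph` implements that area-based workflow on transverse CT-like
slice stacks:

1. **Region extraction** per slice: Gaussian smoothing, a low-cut gray
   threshold, Canny edge detection, and contour filling/subtraction
   produce three nested binary masks — the overall femoral region, the
   cortical annulus, and the medullary cavity.
2. **Area estimation** by hit-or-miss Monte Carlo: draw `n` uniform
   integer-coordinate points in the image rectangle and classify each by
   mask lookup. With `n1` hits in the overall region and `n2` points
   outside the cortical mask, the cortical and medullary area fractions
   are `alpha_c = (n - n2)/n` and `alpha_m = (n1 - (n - n2))/n`, and the
   areas in pixels are `s_c = alpha_c * a * b`, `s_m = alpha_m * a * b`
   for an `a x b` image. An exhaustive pixel traversal provides the exact
   reference values `alpha_ct`, `alpha_mt`.
3. **Morphometry**: locate the key sections — the lesser-trochanter
   midpoint slice `C_m0`, the sections 20 mm above/below it, and the
   isthmus `C_m1` at the global minimum of `s_m` — then compute the
   diameters (`T+20`, `T-20`, `T0`, `T_mi`, `T_mo`), lengths (`IH`, `LH`),
   flare indices (`CFI = T+20/T_mi`, `MCFI = T+20/T-20`,
   `DCFI = T-20/T_mi`, with `CFI = MCFI * DCFI` by construction), the
   cortical index `CI = (T_mo - T_mi)/T_mo`, the per-slice ratios
   `q1 = s_m/(s_c + s_m)` and `q2 = s_m/s_c`, and the growth rates
   `r1 = (s_m0+20 - s_m0-20)/s_m0-20`, `r2 = (s_m0+20 - s_m1)/s_m1`.
   `CFI` classifies the canal as chimney (< 3.0), normal (3.0–4.7), or
   champagne (4.7–6.5).
4. **Agreement validation**: descriptive statistics of the Monte Carlo
   and traversal proportion series and a one-way ANOVA per region pair,
   with "no significant difference" at the 0.05 level as the pass
   verdict.

Why Monte Carlo at all, when the traversal is exact and hardly slower on
one slice? The point-sampling estimator generalises unchanged to any
region representation that supports a membership query, turns the area
problem into a statistics problem with known binomial error
(`SE = sqrt(alpha(1-alpha)/n)`), and is trivially subsampled when full
traversal of very large stacks is not wanted. The package keeps both
routes and validates one against the other.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `sigma`, `window` | 3, 7 px | pixels | reference Gaussian denoising operating point for femoral CT |
| `t0` | 117 | 8-bit gray | low-cut threshold separating cortical bone from marrow/background; strict `> t0` |
| `canny_low/high` | auto | gray/px | hysteresis thresholds; `low = 0.66 * median` of positive gradient magnitudes, `high = 2*low` when unset |
| `mc_n` | 230,400 | points | reference sampling effort for a 240 x 240 grid (4 points per pixel on average); binomial SE of `alpha_m` ~ 3e-4 |
| `offset_mm` | 20 | mm | anchor distance of the reference sections above/below the lesser trochanter |
| `slice_interval` | 5.0 | mm | spacing between analysed transverse slices |
| `pixel_spacing` | 0.5 | mm/px | in-plane resolution of the default phantom |

Inputs with more than 8-bit depth should be window-levelled to 8-bit
before extraction, since `t0` is an 8-bit-scale value.

## The synthetic phantom: what it emulates, what it does not

No patient imaging ships with the package; the `phantom_spec()` /
`generate_phantom()` pair builds a fully synthetic proximal-femur stack
with analytically known geometry, so every stage can be tested against
ground truth.

Each slice is an elliptical cortical annulus (bright) around a medullary
ellipse (dark) on a darker background, rasterised by the pixel-centre rule
(a pixel belongs to an ellipse iff its integer-coordinate centre satisfies
the ellipse inequality with `<=`), with independent additive Gaussian
noise clipped to [0, 255]. Defaults — fixed once, before any acceptance
measurement, and not revisited:

* **Grid and spacing**: 240 x 240 px, 0.5 mm/px, 5.0 mm slice interval,
  60 slices (a 295 mm proximal segment).
* **Trumpet geometry**: inner semi-axis falls linearly from 30 mm at the
  proximal end to 8 mm at the isthmus (slice 40) and rises linearly to
  12 mm distally; cortical thickness grows 4 mm → 10 mm from metaphysis
  to isthmus. A linear (conical) profile is deliberately chosen over a
  smooth one with vanishing slope at the minimum: a phantom meant to
  validate isthmus *detection* needs adjacent-slice area differences well
  above the ~1 px extraction jitter, otherwise "exact recovery" is not a
  well-posed requirement of any detector.
* **Trochanter**: a 10 mm medial bump on the outer boundary at slice 12
  (Gaussian falloff, SD 1.5 slices) gives the "most prominent cross
  section" a well-defined ground truth; prominence is detected as the
  maximal medial-lateral extent of the overall mask, with a manual
  override for clinical use, where prominence is an anatomical judgement.
* **Intensities**: background 30, marrow 34, cortical 200. This triple
  places both tissue-transition midpoints at the operating threshold 117.
  On real CT the threshold is calibrated to the images; the phantom
  inverts that relationship and presents images windowed to the fixed
  threshold. Mid-transition placement is exactly the condition that makes
  a fixed gray threshold an unbiased boundary locator; biased placements
  shift every extracted boundary by a sub-pixel ring and inflate area
  errors on small cavities.
* **Noise**: SD 5 gray levels, additive Gaussian. Gaussian is the model
  the Gaussian-filter preprocessing presumes; SD 5 against a 166-level
  tissue contrast matches visually clean clinical bone windows.

The phantom does **not** emulate: anatomical curvature or anteversion of
the shaft, trabecular texture, beam-hardening or metal artifacts,
partial-volume blur beyond what rasterisation produces, or off-centre
positioning. A green test on the phantom therefore establishes that the
pipeline's geometry, estimators, and statistics are correct — not that
segmentation is robust to clinical artifact.

## Numerical choices and edge cases

* **Threshold strictness**: `threshold_low_cut` keeps values strictly
  greater than `t0` and keeps them unscaled (no binarisation), so the
  Canny gradient still sees the intensity ramp; the operation is
  idempotent.
* **Canny**: Sobel gradients (normalised to gray-levels/pixel), then
  non-maximum suppression comparing against *bilinearly interpolated*
  magnitudes one unit step along the true gradient direction (the classic
  8-way quantisation mislocalises oblique boundaries by a pixel), with
  `>=`/`>` asymmetry to thin two-pixel plateaus, then hysteresis by BFS
  from strong seeds over weak candidates (8-connected).
* **Contour filling**: edge components are labelled 8-connected; interior
  filling flood-fills the background 4-connected from the image border, so
  an 8-connected closed curve is water-tight. A component is "closed" iff
  its filled area exceeds its pixel count; slices without a closed outer
  contour are flagged `no_femur`, those without a nested closed inner
  contour `no_cavity`, and flagged slices are excluded from per-slice
  statistics. With more than two contours (noise blobs), the largest
  closed contour and the largest closed contour nested inside it are kept.
* **Boundary-pixel ownership**: the one-pixel Canny ribbon straddles the
  tissue transition, so assigning it wholesale to either side biases areas
  by a half-pixel ring — measurable as up to ~10% on small cavities.
  Contour pixels are therefore classified by the low-cut image itself:
  supra-threshold ribbon pixels are cortical, sub-threshold ones belong to
  the dark region on their side (marrow inside, background outside). The
  rule is deterministic, so the exact-traversal oracle remains
  unambiguous.
* **Sampling**: points are integer pixel coordinates drawn uniformly with
  replacement (the reference effort of 230,400 draws exceeds the 57,600
  grid points, so replacement is forced); membership is mask lookup, not
  geometric point-in-polygon. Per-slice seeds derive deterministically
  from the master seed and the slice index, so results are independent of
  processing order and fully reproducible; R's Mersenne Twister stream is
  platform-stable.
* **Isthmus ties** resolve to the most proximal slice; trochanter-window
  ties to the first slice of the window. Isthmus detection uses the area
  minimum, not the diameter minimum. For deterministic parameter-recovery
  claims the exact traversal areas are used (`use_traversal = TRUE`): at
  `n = 230,400` the Monte Carlo standard error of a per-slice area is
  ~14 px, which near a flat minimum can reorder adjacent slices.
* **Diameters** are medial-lateral extents through the mask's centroid
  row, `(max_col - min_col + 1) * pixel_spacing`; cortical thickness is
  `(outer - inner)/2` per slice. A radial-mean thickness would also be
  defensible but is not the default, to stay comparable with caliper-style
  clinical measurements.
* **Degenerate inputs**: a phantom with any slice whose inner semi-axis
  reaches the outer one is rejected with the offending slice listed;
  ratios with zero denominators come back `NA` and flagged; two identical
  ANOVA groups return `F = 0`, `p = 1` rather than `0/0`.
* **Rounding**: reported ratios carry the conventional precision
  (diameter ratios 2 dp, `IH/LH` and `r1` 3 dp, `r2` 2 dp) alongside full
  precision; classification boundaries are inclusive on the left
  (`CFI = 3.0` is normal, `4.7` champagne), and `CFI >= 6.5` is reported
  `unclassified` rather than forced into a band.

## Design choices where the design was open

* **Images as plain matrices, stacks as S3 lists**: the heavy lifting is
  five small C++ kernels (convolution, Sobel, Canny, labelling, hole
  filling); everything else is vectorised R on logical matrices.
* **File formats**: the offline dependency set contains no PNG/TIFF/DICOM
  codec, so stacks are written/read as plain-text PGM (P2; P5 accepted on
  read) with a JSON manifest carrying `pixel_spacing` and
  `slice_interval`. PGM is readable by every imaging toolkit and keeps
  test fixtures text-only; DICOM ingestion is a documented non-feature.
* **Validation statistics**: the two-group one-way ANOVA is computed from
  explicit sums of squares (and cross-checked against `stats::aov` in the
  tests); confidence intervals use the t distribution — at ~500 slices the
  difference from z is negligible, but t is the defensible default. The
  agreement verdict treats the ANOVA p-value as the significance measure.
* **Unclassified flag**: `phantom` + `extract` + `mcarea` + `run` CLI
  subcommands cover the pipeline; standalone `morph`/`validate` stages are
  folded into `run`, whose artifact set (`morphometry.json`,
  `validation.json`) is their output.

## Known limitations

* Extraction accuracy is stated for the phantom's contrast regime; with a
  threshold far from the tissue-transition midpoint the extracted
  boundaries acquire a systematic sub-pixel ring offset (about
  `sigma * qnorm(f)` pixels for a threshold at fraction `f` of the
  transition), which matters for cavities below ~15 px radius.
* The lesser-trochanter detector is a proxy (maximal medial-lateral
  extent); on real anatomy the override should be preferred.
* `LH` from a cropped stack is the stack extent, not the femur length —
  supply the measured length externally for `IH/LH`.
* The ANOVA agreement check inherits the usual caveat that a
  non-significant difference is not equivalence; the per-slice absolute
  differences in the report are the sharper diagnostic.
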
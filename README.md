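# canalmorph

Monte Carlo morphometry of the femoral medullary canal from transverse
CT-like slice stacks.

Hip arthroplasty requires a femoral stem that fits the patient's medullary
canal. Classical preoperative morphometry reduces the canal to a few
coronal-axis diameters at sections anchored to the lesser trochanter and
combines them into flare indices; this ignores the irregular shape of the
actual cross sections. `canalmorph` measures per-slice *areas* of the
medullary cavity (s_m) and cortical bone (s_c) instead, via hit-or-miss
Monte Carlo sampling of segmented slices, and derives both the classical
parameters and the area-based ones from them.

For whom: surgeons' engineering collaborators and imaging-methods
researchers who need reproducible canal morphometry, and anyone wanting a
fully synthetic, ground-truthed femur phantom to validate such pipelines.

## The method in brief

Per slice: Gaussian smoothing (default 7x7 window, sigma 3), low-cut gray
threshold (values > T0 = 117 retained), Canny edge detection, contour
filling and subtraction yield nested masks for the overall femoral
region, cortical annulus, and medullary cavity. With n uniform random
integer-coordinate points in the a x b image, n1 of them inside the
overall region and n2 outside the cortical mask:

    alpha_c = (n - n2) / n          s_c = alpha_c * a * b
    alpha_m = (n1 - (n - n2)) / n   s_m = alpha_m * a * b

An exhaustive pixel traversal gives the exact proportions (alpha_ct,
alpha_mt) the estimates are validated against (descriptives + one-way
ANOVA, significance 0.05).

Key sections: C_m0 (lesser-trochanter midpoint, most prominent cross
section), C_m0+/-20 (20 mm above/below), C_m1 (isthmus, global minimum of
s_m). From their diameters and areas:

    CFI = T+20 / T_mi     MCFI = T+20 / T-20    DCFI = T-20 / T_mi
    CI  = (T_mo - T_mi) / T_mo                  IH/LH
    q1 = s_m / (s_c + s_m)   q2 = s_m / s_c
    r1 = (s_m0+20 - s_m0-20) / s_m0-20          r2 = (s_m0+20 - s_m1) / s_m1

CFI classifies the canal: chimney (< 3.0), normal (3.0-4.7), champagne
(4.7-6.5).

## Worked example

Ratio parameters from a reference femur's measured diameters (mm) and
key-section areas (pixels):

```r
library(canalmorph)
cr <- canal_ratios(t_plus20 = 43.24, t_minus20 = 18.07, t_mi = 10.57,
                   t_mo = 25.20, ih = 110.40, lh = 446.96,
                   s_m0_plus20 = 3313, s_m0_minus20 = 2948, s_m1 = 428)
str(cr$rounded)
#> List of 7
#>  $ cfi  : num 4.09
#>  $ mcfi : num 2.39
#>  $ dcfi : num 1.71
#>  $ ci   : num 0.58
#>  $ ih_lh: num 0.247
#>  $ r1   : num 0.124
#>  $ r2   : num 6.74
cr$canal_class
#> [1] "normal"
```

CFI = 4.09 means the canal 20 mm above the lesser trochanter is 4.09x
wider than at the isthmus — a "normal" flare; r2 = 6.74 says the
medullary area shrinks almost 7-fold from that section down to the
isthmus.

End to end on the synthetic phantom (60 slices, 240 x 240 px, 0.5 mm/px,
5 mm interval, isthmus designed at slice 40, trochanter at 12):

```r
gen   <- generate_phantom(phantom_spec(noise_sd = 0))
masks <- extract_masks_stack(gen$stack)
mc    <- mc_area_stack(masks, n = 230400, seed = 1)
compute_morphometry(masks, mc)
#> Femoral canal morphometry
#>   key sections: C_m0+20=8  C_m0=12  C_m0-20=16  C_m1=40
#>   T+20=52.00  T-20=43.00  T0=48.00  T_mi=16.00  T_mo=36.00 mm
#>   IH=140.00 mm  LH=295.00 mm  IH/LH=0.475
#>   CFI=3.25  MCFI=1.21  DCFI=2.69  CI=0.56  (normal canal)
#>   r1=0.459  r2=9.51
```

The recovered sections match the designed ground truth exactly, and the
diameters are the analytic ellipse diameters to within one pixel. The
Monte Carlo estimates agree with the exact traversal:

```r
tab <- mc_area_table(mc)
agreement_report(tab$alpha_m, tab$alpha_mt, tab$alpha_c, tab$alpha_ct)
#> Monte Carlo vs. traversal agreement
#>   medullary: F = 9.661e-07, p = 0.9992 (max |diff| = 0.00114)
#>   cortical:  F = 0.0002367, p = 0.9878 (max |diff| = 0.00135)
#>   verdict at level 0.05: no significant difference
```

A full run (masks, per-slice CSV, morphometry JSON, validation report,
log) from one config:

```r
run_pipeline(pipeline_config(phantom = phantom_spec(), seed = 1), "out/")
```

or from the shell, via the installed CLI:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/canalmorph.R", package="canalmorph"))') \
    phantom --out stack/ --slices 60 --seed 1
Rscript .../canalmorph.R run --in stack/ --out results/ --n 230400 --seed 1
```

Stacks live on disk as plain-text PGM slices plus a `manifest.json` with
`pixel_spacing` / `slice_interval`.

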
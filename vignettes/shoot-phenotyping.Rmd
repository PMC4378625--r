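---
title: "Methods: image-based shoot phenotyping and growth-curve analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based shoot phenotyping and growth-curve analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoshoot)
```

# Scope and model of the measurement process

`phenoshoot` models a conveyor-type plant-imaging cabinet: each plant is
photographed once from above and twice from the side (rotations 0° and 90°)
against a uniform background, optionally together with co-registered
near-infrared (NIR) images. From these rasters the pipeline derives a
per-timepoint phenotype record — calibrated projected leaf area as a
biomass proxy, heights, canopy shape descriptors, colour and NIR traits —
and from the longitudinal record fits nonlinear growth models from which
absolute and relative growth rates (AGR, RGR) are read off analytically.

Because real platform imagery is rarely redistributable, the package ships
a first-class synthetic generator whose outputs carry exact ground truth.
Everything downstream is validated against that truth; the section on
limitations explains what such validation does and does not establish about
real images.

# The synthetic plant generator

A plant is a vertical stem of given height and width, carrying `n_leaves`
strap leaves rendered as filled quadratic-Bezier ribbons, plus optional
basal tillers. Leaves insert on the stem between the first-ligule height
and the stem top and point at golden-angle azimuths; each side view
foreshortens a leaf's horizontal run by the cosine of its azimuth relative
to the camera, while the top view draws the same ribbons radially. Rolled
leaves are drawn at half ribbon width: leaf rolling is thereby *defined
operationally* as a known reduction in projected area, which is exactly how
a 2-D imaging platform perceives it.

Design choices worth stating explicitly:

* **Determinism.** Geometry is a pure function of the `plant_spec`; the
  seed drives only multiplicative brightness texture (and NIR noise).
  Ground-truth pixel counts are obtained by counting rendered pixels, so
  they are exact by construction, and two seeds give identical truth.
* **Colour.** Healthy and senescent tissue are assigned prescribed HSI hue
  angles (defaults 115° green, 60° yellow) and converted to RGB with the
  inverse HSI transform. Brightness texture scales all three channels
  equally, which preserves hue exactly up to 8-bit rounding, so spectral
  ground truth survives texturing. Senescence is painted tips-first
  (ranked by distance from the base/crown), per view, to `round(f · n)`
  pixels — matching the biology of tip-first senescence and making the
  rendered senescent fraction exact to one pixel-rounding unit.
* **NIR.** The ground-truth grey level is linear in tissue moisture between
  a dry and a wet reference level, the simplest model consistent with high
  reflectance indicating low water content.
* **Trajectories.** Observed size is the model curve times lognormal noise
  parameterised to unit mean (`sdlog² = log(1 + cv²)`), so values stay
  positive, the coefficient of variation is scale-free, and the ensemble is
  mean-unbiased around the curve. Multiplicative rather than additive noise
  reflects that leaf-area scatter grows with plant size.
* **Background.** Imaging cabinets differ; the background colour is a
  parameter (default a neutral blue-grey), not a constant.

The generator writes PNG (RGB and 8-bit grey) via the `png` package and
trajectories/logs as CSV.

# Segmentation

Foreground extraction is nearest-neighbour colour classification: a pixel
is plant iff its nearest reference sample in RGB space (squared Euclidean
metric) belongs to the foreground palette. Exact ties resolve to
*background* — the conservative choice, since inflating plant area is the
worse error for a biomass proxy. A rectangular region of interest excludes
visible imaging hardware; everything outside it is background.

Cleanup is erosion followed by dilation with a rasterised disc structuring
element (cell on iff `dy² + dx² ≤ r²`; radius 1 by default — the kernel is
built explicitly rather than taken from `EBImage::makeBrush`, whose size-3
"disc" is a full box). Connected components below `min_component_px`
(default 5) are discarded and the survivors are *united* into one plant
object — a union, never a largest-component pick, so detached tillers
survive. An empty result is a flagged, valid mask rather than an error.
The NIR trait is the mean 8-bit grey value under the RGB-derived mask,
pooled over the two side views with every masked pixel weighted equally.
NIR/RGB registration is assumed exact for synthetic data; a resampling hook
exists for mismatched sensor resolutions and is the identity by default.

# Calibration and morphometrics

Side-view pixel areas convert to physical units with a fixed factor of
0.273 mm² per pixel. Because the plant apex approaches the overhead camera
as it grows, the top-view factor is height-dependent:

$$K_{TV} = 9.937\times10^{-5}\, Y_{ax} + 0.061936 \quad [\mathrm{mm^2/px}]$$

with $Y_{ax}$ the mean centre-of-mass *row* of the two side-view masks
under the standard top-origin raster convention — taller plants have
smaller $Y_{ax}$ and a smaller factor. Both constants are treated as area
factors: at the platform's 5-megapixel resolution this reading yields
plausible pixel counts for decimetre-scale plants, whereas a linear
(mm-per-pixel) reading does not. Linear measures (heights) use
$\sqrt{0.273}$ mm/px for side views and $\sqrt{K_{TV}}$ for top-view
lengths; both interpretations remain switchable in
`camera_calibration()`.

Projected leaf area is `top_px · K_TV + (side0_px + side90_px) · 0.273`.

Shape descriptors are computed on foreground pixel centres:

* **Convex hull** via `grDevices::chull`, area by the shoelace formula
  (degenerate collinear masks give area 0);
* **Minimum enclosing circle**: since the optimum is determined by hull
  vertices, the implementation enumerates the two- and three-point support
  circles over hull vertices and returns the smallest containing circle
  (exact to 1e-9 relative tolerance);
* **Calliper length**: the hull diameter (all-pairs maximum over hull
  vertices);
* **Compactness** = foreground px / hull area and **surface coverage** =
  foreground px / circle area, canopy-closure measures analogous to LAI;
* **Eccentricity** from the closed-form eigenvalues of the 2×2 coordinate
  covariance: $e = \sqrt{1 - \lambda_2/\lambda_1}$.

A pixelation caveat: a pixel *count* measures the union of unit squares
while the hull is a polygon through centres, so for dense blobs the count
can exceed the hull area by a boundary term and compactness can nominally
exceed 1. On scatter masks — and on real canopies, which are far from
filling their hull — the ordering chain
`fg ≤ hull ≤ π r²` and `calliper ≤ 2r` holds, and the test suite asserts it
there.

**Heights.** Maximum height runs from the baseline (lowest foreground row;
the pot is excluded by the ROI) to the topmost row, from the larger side
view. The first-ligule height has no published algorithm, so the package
uses a declared rule: scanning upward from the base, the ligule is the
lowest row whose horizontal extent exceeds 2.5× the median stem width
(estimated over the lowest 12 object rows); a leafless stem reports ligule
height = maximum height. Both the ratio and the basal-row count are
configurable; on generator plants the rule lands within 5 % of the drawn
insertion height.

# Spectral traits

Hue comes from the classical geometric HSI transform (pure green 120°,
yellow 60°); achromatic pixels have undefined hue and are excluded.
The greenness trait is the *circular* mean of masked hue angles — hue is an
angle, although for vegetation hues far from the 0°/360° wrap the circular
and arithmetic means agree. Senescence is the relative proportion
`yellow / (green + yellow)` of masked pixels inside two half-open hue
bands, by default green [80°, 160°) and yellow [40°, 80°); the thresholds
are not standardised anywhere, so they are configuration, not constants.
Pixels in neither band (stems, specular highlights) count toward neither
tally.

# Growth models, fitting and selection

Eight candidate models are registered (closed forms in
`?growth_model_names` and the source): exponential, power law,
three-parameter logistic, four-parameter logistic, Gompertz, Weibull,
Richards, and Yin's beta growth function. The power law's exponent β tunes
the decline of RGR with size (β = 0 linear, β → 1 exponential); the
logistic's `tmid` is the inflection day, where AGR peaks at `Asym/(4k)`.
AGR/RGR are analytic for the power law, logistic and exponential, and a
central difference (step `1e-4 · max(1, |t|)`) elsewhere; `RGR = AGR/M`
pointwise for every model.

**Fitting** is Levenberg–Marquardt nonlinear least squares
(`minpack.lm::nls.lm`, max 400 iterations, `ftol = 1e-10`) from heuristic
self-start values: log-linear fits for the exponential, a profiled
β-grid (each β making `M^{1−β}` linear in t) for the power law,
asymptote-anchored logit/double-log linearisations for the sigmoids.
Non-convergence — optimizer failure, undefined curve on the data grid,
singular information matrix — is a *recorded state*, never an exception:
the selection stage needs failed fits as data. A monotone-decreasing series
is rejected up front (growth models assume a nondecreasing trend); a
constant series is accepted with a degenerate flag. Fit statistics use the
Gaussian likelihood, `AIC = n ln(RSS/n) + 2(p+1)` (RSS floored at 1e-300 so
a numerically perfect fit keeps a finite criterion) and `R² = 1 − RSS/TSS`.

**Residual variance.** The default is homoscedastic. Because multiplicative
noise makes the residual SD proportional to the mean, a
`variance = "power_of_mean"` option iteratively reweights observations by
`1/μ²`; with CV-stable noise this is the correct weighting and is what
makes Wald intervals and prediction bands achieve nominal coverage in the
recovery simulations. It is off by default so that the unweighted AIC
ranking remains comparable across models.

**Population prediction intervals** draw parameter vectors from
`N(estimates, covariance)` (nearest-PSD repair with a warning if needed),
evaluate the curve per draw, and take pointwise quantiles; draws falling
outside a model's parameter domain contribute `NA` and are dropped from the
quantiles. The seed is an explicit argument (default 20110301), making
bands deterministic.

**Selection** mirrors a robustness-then-parsimony protocol: candidates
failing to converge on *any* experimental group are disqualified; survivors
rank by mean AIC; those within 2 AIC units of the best are treated as
statistically indistinguishable and reordered by parameter count, then by
narrower mean prediction-band width. `inflection_time()` returns `tmid`
exactly for the logistic and a golden-section argmax of AGR for other
sigmoids; non-asymptotic models raise an error (their AGR has no interior
maximum).

# Derived statistics

* `rgr_biomass()` implements the classical two-point estimator
  `R = (ln W2 − ln W1)/(t2 − t1)` — with the elapsed time in the
  denominator, so that mass gain gives positive RGR.
* `rgr_variants()` contrasts a pooled-baseline estimator (group-mean
  initial area, individual final area — mimicking destructive-harvest
  designs, which must pool the initial cohort) with a fully individual
  estimator; simulations show the individual variant has strictly smaller
  error variance when initial sizes are heterogeneous.
* `leaf_rolling()` reports the mean of per-plant percentage increases from
  afternoon (rolled) to pre-dawn (unrolled) area, ± SE, with a paired
  t-test on the differences. The mean-of-percentages convention matches a
  per-plant "% LA increase ± SE" table layout; it is unit-invariant.
* `wue()` is biomass per cumulative water added to the pot. The default
  *includes* soil evaporation (the gravimetric definition: evaporation and
  transpiration); a transpiration-only mode subtracts the mean control-pot
  water use, since the definitional ambiguity cannot be resolved from
  first principles. Control pots are always reported alongside.
* `validate_projection()` and `nir_regression()` are ordinary least
  squares (`stats::lm`): measured-on-projected for the imaging validation,
  and `NIR ~ LMA + moisture` for the reflectance decomposition, with
  collinearity flagged.

# Numerical choices and degenerate inputs

* Classification ties → background; empty composed masks → flagged, not
  raised; empty masks make mean-NIR and hull operations error (undefined).
* Geometry on 0-based pixel centres; shoelace areas; MEC exact to 1e-9.
* Self-start on a constant series anchors `Asym = 1.05 ×` the value and
  flags degeneracy.
* All randomness flows through declared seeds (`with_seed` restores the
  caller's RNG state); pipeline CSVs carry a config-hash + seed provenance
  header and reruns are byte-identical.

# Problem sizes used in the validation suite

The shipped tests run at sizes chosen to exercise every code path while
staying desk-scale: geometry oracles on 200 random masks of 5–100 pixels
(full O(n⁴) enclosing-circle brute force on the ≤25-pixel masks, a complete
optimality certificate on all); parameter recovery over 200 replicates of
14 plants × 30 timepoints at 5 % noise; selection consistency over 100
sigmoid replicates and 30 three-group exponential-phase replicates; a
30-plant size sweep for the end-to-end area regression (slope within
1 ± 0.05 of ground truth).

# Limitations

The generator emulates silhouette geometry, hue composition, diurnal area
reduction and CV-stable trajectory noise; it does not emulate shadows,
specular reflections, overlapping leaves self-occluding in all three views
at once, soil/pot texture, or illumination gradients. Passing the suite
therefore demonstrates the *computational* correctness of segmentation,
calibration, geometry and model fitting — not robustness to real-cabinet
imaging artefacts, which requires platform-specific palettes and ROI
tuning. Tiller counting from images is out of scope (treated as metadata);
there is no machine-learned segmentation; and the growth models are fitted
per group or per plant, not as mixed-effects models.
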
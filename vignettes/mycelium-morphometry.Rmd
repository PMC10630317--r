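---
title: "Methods: morphometry and micromechanics of gradient mycelium networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphometry and micromechanics of gradient mycelium networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the measurement
models, the choices behind their numerical defaults, what the synthetic
data generator does and does not emulate, and the known limitations. All
units are μm (length), μm² (area), μN (force) and kPa (modulus); the single
μN/μm² = MPa = 1000 kPa conversion lives in `hertz_force()` /
`modulus_from_fit()`.

## 1. Microstructural descriptors

The analysis substrate is a binary fiber mask (automatic thresholding via
`binarize()`, or a manually produced mask via `load_mask()`; the provenance
tag records which, because different descriptors are best measured on
different segmentations — pore and network descriptors on conservative
manual-style masks, radii and porosity on automatic ones).

**Skeleton.** `skeletonize()` thins the mask with the Zhang–Suen parallel
algorithm plus a final sequential pass deleting 8-simple pixels (Yokoi
connectivity number 1). The extra pass matters: the parallel sub-iterations
leave two-pixel-wide diagonal staircases, and an X-crossing of two diagonal
fibers then never produces a branch pixel at all. Branch pixels (crossing
number ≥ 3) are clustered; each cluster is cut out of the skeleton inside a
disk of radius equal to the local distance-map value (floor 3 px), because
the centerline geometry inside a crossing blob is meaningless. Clusters
closer than 2× the local fiber radius are one physical intersection and are
merged (a thick X thins into two nearby Y-points). The remaining arcs are
simple paths; each end adjacent to a cut zone attaches to that junction and
the path length is extended by the straight distance to the junction
centroid. Candidate junctions left with fewer than three attached branches
are thinning artifacts (corners): 2-branch ones are dissolved by stitching
their two arcs back together, 0/1-branch ones demote to free ends.

**Digital length.** Path lengths use orientation-corrected step weights
(0.980 orthogonal, 1.406 diagonal, −0.091 per direction change) rather than
the naive (1, √2) weights, which overestimate oblique lines by up to ~8%.
With the correction, a straight bar at any angle measures within ~5% of its
Euclidean length (the residual error is dominated by tip erosion: thinning
eats roughly half a stroke width, or one cap radius, at each free end).

**Fiber radii.** At every skeleton pixel, the exact Euclidean distance
transform gives the distance to the nearest background pixel *centre*; the
physical interface lies about half a pixel closer, so a radius sample is
`dm − pixel_size/2` (this makes a bar of width 2k+1 px measure exactly
(k+0.5) px). Pixels within `exclusion_factor` (default 2) junction radii of
a junction centroid are excluded — there the nearest interface no longer
reflects a fiber radius. At the default resolution of 0.033 μm/px the
thinnest dominant fiber type (0.17 μm radius) spans ~10 px diameter; radius
recovery degrades below ~3 px radius, which is why the pixel size is a
first-class parameter.

**Crosslink density ρ_b.** Junctions are counted with an arm-degree
multiplicity: a transversal crossing has 4 arms and every further
coincident crossing adds 2, so a junction with b arms counts as
max(1, round((b−2)/2)) intersections. Two 3-arm junctions joined by a short
(< 2.5 μm) segment are the two Y-points of one shallow-angle crossing and
are pooled before counting; the pooled formula
(Σarms − 2(members−1) − 2)/2 is invariant to accidentally pooling genuinely
distinct 4-arm crossings, so the pooling scale is not delicate. On sparse
networks (all crossings > 2 μm apart, arms > 1 μm, crossing angle > 20°)
this count equals the analytic all-pairs intersection count exactly (tested
on 20 fixed generator draws). Near-tangential crossings are invisible to
any skeleton-based method — the two strokes merge smoothly — and are
excluded from the definition of "sparse".

**Segment length l_c.** Branches between junctions/endpoints, excluding
any branch touching the image border (incomplete) and closed cycles, then
averaged inside the 1–10 μm window: below 1 μm lie few-pixel artifacts,
above 10 μm non-representative spans. If nothing passes the window, l_c is
reported missing (NA), never 0.

**Network density ρ.** Total length of branches whose *both* termini are
junctions (plus closed cycles) per unit frame area — dangling and free
fiber ends carry no load path and are excluded. An isolated fiber has
ρ = 0; a closed loop of perimeter P in area A has ρ = P/A.

**Pores and porosity.** Pores are 4-connected background components against
8-connected fibers (the standard duality that prevents leak-through at
diagonal crossings). Border-touching pores are flagged, never dropped;
statistics use complete pores only. The histogram bin width defaults to
5.5/3 μm² so that the first three bins span exactly [0, 5.5) μm² and the
second bin is centred at 2.75 μm² — making "fraction of dominant pores"
(the 2.75 μm² bin) and "fraction of small pores" (< 5.5 μm², the first
three bins) mutually consistent. Porosity is the plain background fraction
of the full frame.

## 2. Fiber typing by GMM + AIC

Radius histograms of mycelium are multimodal: discrete dominant fiber
types, with an approximately doubling structure of means (0.17, 0.34,
~0.68 μm) attributed to bifurcation of leading hyphae. `fit_mixture()` fits
a k-component 1-D Gaussian mixture by EM (log-space E-step, 5 random
restarts, seeds derived from the master seed so the fit is deterministic);
`select_components()` scans k = 1..6 and keeps the AIC minimiser, with
AIC = 2p − 2 log L and p = 3k − 1 free parameters. Numerical choices:

* **sd floor** = half the pixel size carried by the radius samples.
  Radii are discretized at the pixel scale; without the floor EM collapses
  components onto single discretization values. The floor also controls
  AIC's well-known appetite for spurious extra components: with it, pure
  single-Gaussian data selects K = 1 in ≥ 90% of seeds.
* **Convergence**: relative log-likelihood change < 1e-7, ≤ 300 iterations.
* **Tie-breaks / identifiability**: components are reported sorted by mean,
  making output invariant to EM label permutations.
* **Degenerate input**: all-equal samples error for k > 1 and hit the sd
  floor for k = 1 — never a silent NaN.

On full pipeline runs the mixture usually carries one or two low-weight
"blend" components besides the dominant types (junction-adjacent samples
and partially-occluded fibers); dominant types are read off by matching
recovered means to the expected structure, which is how the recovery error
is scored.

## 3. Indentation analysis

The instrument protocol is displacement-controlled: load at 3 μm/s to
d_max ≈ 70 μm, dwell 50 s, unload at 1 μm/s, spherical probe R = 92.03 μm.
Since d_max/t_f < 0.1 for ~10 mm thick samples, substrate effects are
negligible (checked, with a warning, in `parse_curve()`).

The early part of a loading curve on a fibrous surface is contaminated by
dangling-hypha compression, so locating the true contact point is
unreliable. The analysis therefore fits the *derivative* relation: for
Hertzian contact F = (4/3)E*√R (d−d₀)^1.5, the derivative obeys
dF/du = K F^(1/3) independently of d₀. `derivative_estimate()` computes
dF/du by a local quadratic fit in a sliding 2 μm depth window;
`fit_power_law()` regresses log dF/du on log F inside the 5–30 μN force
window; `modulus_from_fit()` inverts E\* = K^{3/2}(6R)^{−1/2} (verified
against forward-simulated curves over E\* ∈ {10, 55.1, 100} kPa) and
applies E = E\*(1−ν²).

* **Exponent gate**: n is fitted free and |n − 1/3| ≤ 0.1 is required for a
  modulus to be reported — Hertz applicability is checked, not assumed.
  The probe-to-mesh criterion R/l_c > 12 (strict) provides the structural
  justification; with l_c ≈ 3–3.5 μm, R/l_c ≈ 26–31 here.
* **Window choice**: the 2 μm derivative window was set by a bias/variance
  sweep against the forward model: larger windows bias the local quadratic
  on the 1.5-power curve (exponent bias > 1e-3 beyond ~2.5 μm), smaller
  ones amplify force noise.
* **Poisson ratio**: unknown for dried mycelium; default ν = 0, E\* is
  always reported alongside E, and ν is a parameter.
* **Pop-ins**: force drops exceeding max(3×noise, 1 μN) on a running-median
  smoothed loading trace (the median keeps step edges sharp and, unlike raw
  successive differences, does not false-trigger at noise sd 0.5 μN). By
  default the fit window is truncated at the first event; a `reject` policy
  is available.

## 4. The synthetic world

The generator emulates the statistical structure the analysis assumes, with
analytic ground truth attached: straight capsule fibers (uniform centres
and orientations, lengths 5–30 μm), radii from the two-type mixture
(0.17 ± 0.015 and 0.34 ± 0.03 μm, equal weights), frame 800×800 px at
0.033 μm/px (≈ 26×26 μm, comparable to a 3kX SEM field), ~30 fibers giving
ρ_b near the old-growth target 0.079 μm⁻². Grayscale rendering dims deeper
fiber layers, mimicking SEM depth cueing — which is also why global Otsu
deliberately under-segments the dimmest layer, as automatic thresholding
does on real SEM images. Gradient series interpolate ρ_b 0.079 → 0.027 μm⁻²
and E 55.1 → 26.5 kPa over three layers; per-layer fiber counts are tuned
until the *measured* crosslink density approaches the target (tolerance
20%), absorbing the systematic biases of skeleton-based counting into the
calibration. Indentation curves follow the three-stage protocol with
Gaussian force noise (default 0.2 μN), optional contact offset and pop-in
step drops; sampling at 200 Hz (instrument-realistic; the source protocol
does not state a rate).

What the generator does **not** emulate — and what a green test therefore
does not establish:

* fiber curvature, branching trees, bundling, or fusion: descriptors here
  depend only on radii, intersections and lengths;
* SEM noise physics, charging, uneven illumination (segmentation is tested
  on clean two-level renderings plus depth shading only);
* viscoelasticity: the dwell stage holds force constant, and real
  indent-to-indent modulus spread (±13 kPa in tissue) is not simulated —
  per-layer E spread in synthetic series reflects force noise only;
* 3-D pore connectivity (porosity is strictly planar).

Crossings of straight fibers cluster strongly at the stated density
(roughly half lie within 1 μm of another crossing, i.e. within a fiber
diameter). Such coincident crossings are unresolvable in any image-based
count — including manual annotation — so the measured ρ_b runs ~0–20%
below the analytic all-pairs truth on dense defaults, systematically.
Gradient ordering is unaffected (the bias is monotone in density and the
calibration targets the measured value).

## 5. Known limitations

* Thinning is not exactly 90°-rotation-equivariant (its sub-iterations are
  directional); junction and crossing *counts* are rotation-invariant in
  tests, lengths agree to within a few percent.
* Flat or round fiber ends erode by about half a width during thinning, so
  free-end branch lengths are short by ~one radius.
* The arm-degree crossing count assumes transversal crossings; fiber-end
  contacts (a hypha terminating on another) are counted as one
  intersection, which matches how an annotator reads a bifurcation but not
  the strict geometric definition.
* AIC component selection on real (non-Gaussian, discretized) radius
  samples tends to add low-weight blend components; downstream reporting
  should read dominant types, not K itself.
* With three layers, the structure–property correlation is descriptive:
  Spearman rank correlation and a least-squares slope are reported, and
  significance is explicitly labelled "not assessed" — no p-values at n = 3.
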
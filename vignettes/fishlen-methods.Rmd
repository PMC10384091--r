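---
title: "Measuring fish body length through a water surface: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring fish body length through a water surface: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishlen)
```

## The measurement problem

Fish length is the basic monitoring quantity in aquaculture, and measuring it
by hand stresses or injures the animal. `fishlen` implements a non-contact
alternative: a stereo RGB-D camera looks straight down at fish swimming in a
tank, and the body length is computed from one aligned RGB + depth image pair
and a user-drawn rectangle around one fish. Four stages are involved, each
with its own model:

1. **Segmentation** — contrast-adaptive GrabCut isolates the fish silhouette
   inside the rectangle.
2. **Pose analysis** — the minimum-area bounding rectangle of the silhouette
   yields head/tail candidates `e`, `f` and a bend angle `theta`; fish with
   `theta > 5°` are treated as bent.
3. **Straightening** — for bent fish, the body midline is extracted by
   Zhang–Suen thinning (with corner removal and burr pruning) and the tail
   point is moved out along the chord to the midline's arc length.
4. **Refraction-corrected back-projection** — the head and tail pixels plus
   their measured depths become 3D coordinates; Snell's law at the flat
   air-water interface corrects both the depth and the lateral coordinates
   before the Euclidean length is taken.

A physics-based scene generator (`renderScene()`) forward-models the whole
imaging chain — refractive ray tracing into an ideal stereo pair — and
provides ground-truthed synthetic fixtures; everything the package claims
about accuracy is measured against it.

## Segmentation: contrast-adaptive GrabCut

GrabCut minimises the Gibbs energy

$$E(\alpha, k, \theta, z) = U + V, \qquad
U = \sum_n \big[-\log P(z_n \mid \alpha_n, k_n, \theta)
               - \log \pi(\alpha_n, k_n)\big],$$
$$V = \gamma \sum_{(m,n) \in C} [\alpha_n \ne \alpha_m]
      \, e^{-\beta \lVert z_m - z_n \rVert^2},
\qquad \beta = \big(2 \langle (z_m - z_n)^2 \rangle\big)^{-1},$$

with a Gaussian mixture (default 5 full-covariance components) per class,
8-connected neighbour pairs `C`, and boundary weight `gamma = 50`. Pixels
outside the user rectangle are clamped to background; rectangle pixels start
as probable foreground. Each iteration re-assigns pixels to mixture
components, refits both mixtures by maximum likelihood, and solves the
labelling exactly by min-cut (a compiled Dinic max-flow on the pixel graph;
`src/maxflow.cpp`). Because every step minimises the same energy, the
recorded per-iteration energy is non-increasing — a property the test suite
asserts.

Numerical choices: component assignment ties break to the lowest index;
mixtures are initialised by seeded k-means (deterministic for a fixed
`SegConfig@seed`); covariances always carry a `0.01·I` ridge, which keeps the
rank-1 covariances of gray images invertible and makes energies comparable
across refits; on large images the background mixture is fitted on a
deterministic 40 000-pixel subsample (small images are fitted exactly, so the
monotonicity tests are exact). An energy shift per pixel keeps all graph
capacities non-negative without changing the argmin.

**What the contrast adaptation can and cannot do.** The preprocessing
(`contrastAdapt()`) converts to gray, linearly stretches the 1st–99th
percentiles to the 8-bit range, adds a brightness offset with saturation, and
replicates the result into three channels. A *pure* linear stretch is exactly
neutral for GrabCut: `beta` renormalises any global rescaling, so stretching
cannot rescue a fish that is separated from the background only by i.i.d.
noise. What the adaptation genuinely buys is *saturation*: raising the
brightness until the (bright) background clips at 255 collapses structured
background variation — lighting gradients, shadows — into a single uniform
mode, which stops it leaking into the foreground. The test suite contains
exactly this scenario: a shadow patch inside the rectangle that raw GrabCut
segments together with the fish (IoU 0.81) and that disappears after
brightness saturation (IoU 1.00). The stretch percentiles and offset are
deliberately configuration, not constants: the right amount of saturation
depends on the lighting of the rig.

## Pose classification and the bend angle

After a 3×3 morphological opening, the largest connected component's contour
is enclosed in its minimum-area rotated rectangle (rotating calipers over the
convex hull). The contour points nearest the supporting lines of the two
*short* sides are the head/tail candidates `e` and `f`; with the rectangle
centre `o`, the bend angle is `theta = 180° − ∠eof` (law of cosines). A fish
is bent iff `theta` strictly exceeds 5°; `theta = 5°` exactly counts as
straight. On synthetic fish, `theta` grows monotonically with the generator's
spine curvature up to about 0.6 of a semicircle.

**Known limitation.** For extreme bends (curvature beyond ~0.6 of a
semicircle) the short sides of the minimum-area rectangle no longer touch the
fish tips — the outer edge of the bent body bulges past them — so `e` and `f`
drift away from the true head and tail. This is a property of the
rectangle-contact construction itself, not of its implementation; real fish
photographed for measurement bend far less. The straightening tests that
target exact semicircles therefore feed the generator's true tip pixels to
the arc-length stage, which isolates the mechanics being tested.

## Midline extraction and straightening

For bent fish, the cleaned mask (holes filled — a fish silhouette is simply
connected, so interior holes are segmentation noise) is thinned with the
standard two-subiteration Zhang–Suen algorithm. Thinning artefacts are then
removed in order:

* **Corner removal** deletes one-pixel protrusions matching four directional
  patterns (sequential row-major scan, re-checking after each deletion so
  staircases cannot disconnect). It never increases the node count or changes
  the component count.
* **Burr pruning**: if more than two endpoints remain, the endpoint pair with
  the largest mutual distance defines the main line; every other branch is
  eroded endpoint-by-endpoint until it rejoins the main line, with a
  per-branch budget of 15% of the skeleton pixel count. A walk that exposes
  two candidate neighbours stops conservatively.
* **Break reconnection** joins fragments (closest endpoint pair across
  components, discrete straight line) until a single curve with exactly two
  endpoints and no nodes remains. A mask so round that it thins to a single
  pixel is grown into a minimal two-pixel segment so the contract holds for
  arbitrary blobs.

The midline's endpoints `g`, `h` stop short of the silhouette tips by roughly
half the local body width (5–12 px on study-scale fish); the straight
connections `|eg|` and `|hf|` bridge that gap, so the composite arc
`|eg| + path + |hf|` is insensitive to it.

**Arc length of a digital curve.** The raw 8-connected step count (1 per
axial, √2 per diagonal step) systematically overestimates the length of a
digitised curve — the thinned midline zigzags about the true centreline, and
on synthetic fish the bias is a consistent +5%. `arcLength()` therefore
measures the length of the *ordered path smoothed by a 7-pixel moving
average* (endpoints fixed); straight and diagonal lines are unchanged, a
digitised quarter circle is recovered to a few tenths of a percent, and bent
synthetic fish to better than 1%. The literal step count remains available
via `smooth = FALSE`.

Straightening then replaces the tail by `m = e + arc·(f−e)/|f−e|` (sub-pixel,
possibly outside the image — flagged, not clamped) and assigns `m` the depth
sampled at the original `f`, since `m` itself need not lie on the fish.

Depth sampling at a measurement point takes the median of valid (non-zero)
depths in a 5×5 window restricted to the fish mask, falling back to the
nearest valid pixel within 15 px. Restricting to the mask matters: at a fish
tip half the window lies on the background, whose depth is the tank bottom,
and an unrestricted median could mix the two surfaces.

## Refraction model

A camera at height `h` above a flat water surface sees a submerged point
along a ray bent at the interface: `n_air sin α = n_water sin β`. Two
consequences are modelled:

* **Lateral magnification**: the refracted image position `Q_w` relates to
  the unrefracted one by `Q_a = K·Q_w` with
  `K = h/Z + (1 − h/Z)·tanβ/tanα ≤ 1`, where `α` follows from the observed
  image point (`sin α = r/√(r²+1)` in pixel-normalised plane units) and `Z`
  is the depth at which `K` is evaluated. On the optical axis the ratio of
  tangents takes its analytic limit `n_air/n_water` (applied below
  `sin α < 10⁻⁹`).
* **Depth shrinkage**: refraction inflates stereo disparity, so the camera
  reads `Z_measured = K·Z_true`; the correction is `Z' = Z_measured/K`.

Because `K` depends on the depth at which it is evaluated, the package solves
the pair as a fixed point: starting from the measured depth, `K` and
`Z' = Z_measured/K` are re-evaluated until `Z'` converges (tolerance 10⁻⁶ mm,
at most 20 rounds — 3-4 in practice). A single application (`iterations = 1`)
is also available, but evaluating `K` at the measured rather than the
corrected depth leaves a systematic ~2% depth deficit at bucket geometries
(h = 250 mm, 500 mm of water), which is why convergence is the default. The
final 3D point is `(K_w·x·Z', K_w·y·Z', Z')` with `K_w` evaluated at the
corrected depth (`kwMode = "corrected"`; `"measured"` is provided for
comparison). With `n_water = n_air` the whole path reduces bit-identically to
the plain pinhole back-projection.

`K` is applied isotropically to both plane coordinates: the refraction plane
contains the optical axis and the point, so the displacement is purely
radial.

## The synthetic oracle, and what it shows

`refractProject()` and `apparentDepth()` implement the *exact* forward
physics that the correction only approximates: the Snell crossing point on
the surface is solved by bisection (unconditionally convergent on `[0, R]`,
60 iterations), per stereo pinhole, and the apparent depth is triangulated
from the resulting horizontal disparity (`Z = B·f/d`). `renderScene()`
inverts the per-pixel camera rays through the interface to rasterise
refraction-magnified silhouettes and fills the depth image with the apparent
stereo depth of the true scene point behind every pixel (background depths
are ray-traced on a 4-px grid and bilinearly interpolated; the difference is
far below the 1 mm depth quantisation). Gaussian pixel noise (σ = 3 gray
levels) and depth noise (σ = 2 mm) are added and quantised. All randomness
derives from one seed; identical seeds give bit-identical scenes.

Validating the correction against this oracle shows exactly where the model
is good and where it is not:

* For rays near the axis, or at any angle for points in the plane
  perpendicular to the stereo baseline, the iterated correction recovers
  ray-traced points essentially exactly — the `K` model is *exact* for the
  secant-type geometry it was derived from.
* The ideal stereo depth, however, is a finite-difference quantity along the
  baseline: for points *along* the baseline at large field angles the
  measured depth deviates from the secant model, and a residual error
  survives the correction — up to ≈3.7% per coordinate at 20° off-axis under
  500 mm of water. The package documents this as a property of stereo depth
  sensing through an interface, not something the single-factor `K` model can
  remove; rays within ~12° are recovered to better than 2% everywhere.

An algebraic consequence worth knowing: at the exact fixed point the lateral
coordinates satisfy `K(Z')·x·Z' = x·Z_measured` — iterated correction leaves
*lateral* positions equal to the uncorrected ones and fixes the *depth*.
Correcting the length of a fish therefore matters exactly when the head and
tail differ in depth, which is why the generator gives straight fish a
swimming pitch (uniform ±12°, a realistic attitude range for cruising and
manoeuvring fish): the uncorrected path shrinks the head-tail depth
difference by `n_air/n_water` and underestimates such fish, while the
corrected path restores it.

## The synthetic measurement study

`simulateStudy()` re-creates the bucket experiment in silico. Fixed
conditions, chosen once: a 640×480 camera with `f = 600` px and a 50 mm
baseline; 500 mm of water; camera heights 250, 350 and 450 mm above the
surface; a fixed cohort of ten true lengths spanning 250–320 mm
(`studyFishLengths`); three replicate scenes per fish and height. Per scene
the fish is straight (pitch uniform ±12°) or bent (curvature 0.15–0.6 of a
semicircle) with equal probability, placed uniformly within the bucket
footprint (bottom radius 230 mm) subject to being fully visible — with the
camera close to the water only deeper, near-centred fish fit in the frame,
which is also how such a rig is operated. The full pipeline runs on every
rendered scene, GrabCut included.

Representative results (seeds 1–3; `scripts/acceptance.R` recomputes them):
corrected MRPE 1.31 / 1.07 / 0.95 % against uncorrected 1.48 / 1.17 / 1.08 %
at 250 / 350 / 450 mm — the correction helps at every height, and both
errors stay nearer 1% than the real-world figures because synthetic scenes
are free of calibration error, surface ripple and motion blur. One
qualitative feature of the physical experiment does *not* reproduce: under
exact refraction physics every error source weakens as the camera rises
(field angles shrink for a bucket-confined scene), so the uncorrected error
*decreases* with camera height here, rather than growing. Whatever drove the
opposite trend on the real rig (surface agitation, depth-sensor behaviour at
range) is outside this forward model, and the corresponding assertion is
deliberately left failing rather than tuned into passing.

## What passing tests do and do not show

The generator emulates silhouette geometry, refraction, ideal stereo depth,
pixel and depth noise, lighting/shadow structure, and quantisation. It does
not emulate surface waves, turbidity, caustics, fish body thickness (fish
are laminae), fin/tail transparency, motion blur, or depth-sensor artefacts
at silhouette edges. Accuracy numbers on synthetic scenes are therefore a
*best case* for the geometric pipeline, not a field-accuracy claim; the
study's value is differential (corrected vs uncorrected under identical
conditions) and contractual (segmentation IoU, skeleton topology, energy
monotonicity).

## Parameter reference

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `gmmComponents` | 5 | — | Gaussians per GrabCut class |
| `gamma` | 50 | — | boundary-term weight |
| `nIterations` | 5 | — | GrabCut outer iterations |
| `stretchLowPct`, `stretchHighPct` | 1, 99 | % | percentiles mapped to 0/255 |
| `brightnessOffset` | 0 | gray | post-stretch brightness (saturating) |
| `thetaThreshold` | 5 | degrees | bent/straight decision |
| `maxDeletions` | 15% of skeleton px | px | per-branch burr budget |
| `nAir`, `nWater` | 1.0, 1.333 | — | refractive indices |
| `iterations`, `tol` | 20, 1e-6 | —, mm | correction fixed point |
| `baseline` | 50 | mm | stereo baseline |

The camera height `h` is not entered directly in configurations: it is
derived as `camera_placement_mm − water_depth_mm`, matching how the rig is
measured in practice, and must come out positive.
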
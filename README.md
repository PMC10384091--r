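# fishlen — non-contact fish body-length measurement through the water surface

`fishlen` measures the body length of fish swimming below a flat water
surface from a single aligned RGB + depth (RGB-D) image pair taken by a
stereo camera mounted above the water, plus a user-drawn rectangle around
one fish. It is aimed at aquaculture monitoring, where handling fish to
measure them is slow and harmful.

The pipeline, and the models behind it:

1. **Contrast-adaptive GrabCut segmentation.** The fish silhouette is
   extracted by iterative minimisation of the Gibbs energy
   `E = U + V`, where `U` scores every pixel under a per-class Gaussian
   mixture (5 full-covariance components each for foreground and
   background) and
   `V = γ Σ_{(m,n)∈C} [α_m ≠ α_n] exp(−β‖z_m − z_n‖²)` penalises label
   boundaries across similar pixels (8-connectivity,
   `β = (2⟨(z_m−z_n)²⟩)⁻¹`). The labelling step is solved exactly by a
   compiled min-cut. Before segmentation the image is grayscale-stretched
   and brightness-saturated, which merges uneven lighting into a uniform
   background.
2. **Bend classification.** The silhouette's minimum-area rotated
   rectangle gives head/tail candidates `e`, `f` (contour points at the
   short sides) and the bend angle `θ = 180° − ∠eof` at the rectangle
   centre; `θ > 5°` means the fish is bent.
3. **Skeleton-based straightening.** Bent fish are thinned (Zhang–Suen)
   to a midline; corner points are removed and spurious branches pruned
   until exactly two endpoints remain; the tail measurement point `m` is
   placed on the ray `e→f` at the midline's arc length, carrying the depth
   of the original tail.
4. **Refraction correction.** Snell's law at the air-water interface both
   magnifies the image (`Q_a = K·Q_w`,
   `K = h/Z + (1 − h/Z)·tanβ/tanα ≤ 1`) and shrinks the stereo depth
   reading (`Z' = Z_measured/K`). `K` and `Z'` are solved jointly to a
   fixed point and the head/tail pixels are back-projected to 3D
   (`X = K_w (u−u₀)/f_x · Z'`, …); the body length is the Euclidean
   distance. Reported errors use the relative error
   `RE = (L_est − L_true)/L_true · 100%` and the mean of its absolute
   value (MRPE).

A ray-tracing scene generator (`renderScene()`) forward-models the exact
physics — refraction of every camera ray at the interface and ideal
two-pinhole stereo depth — and produces ground-truthed synthetic RGB-D
scenes used throughout the tests.

## Worked example

Render a synthetic scene — a 300 mm fish, 350 mm below the surface, camera
250 mm above the water — and measure it:

```r
library(fishlen)

cam <- cameraModel(fx = 600, baseline = 50, width = 640L, height = 480L)
rmod <- refractionModel(cameraHeight = 250)     # n_air = 1, n_water = 1.333

fish <- fishSpec(lengthMm = 300, depthMm = 350, center = c(30, 20),
                 orientationDeg = 25, pitchDeg = 8)
scene <- renderScene(sceneSpec(cam, rmod, waterDepth = 500,
                               fish = list(fish), seed = 7))

cfg <- measureConfig(camera = cam, refraction = rmod)
res <- runMeasure(cfg, scene$rgb, scene$depth, scene$truth$fish[[1]]$roi)
res
#> MeasurementResult: straight fish, theta = 0.29 deg
#>   length = 292.2 mm (uncorrected 291.2 mm)
#>   head (508.0, 335.0) px @ 509 mm; tail (193.0, 188.0) px @ 490 mm
```

The fish is classified as straight (`θ = 0.29°`, below the 5° threshold),
and the corrected length (292.2 mm, −2.6% at this deliberately off-centre,
large-field-angle placement) is closer to the 300 mm truth than the
uncorrected one. The head and tail depths differ by ~19 mm because the fish
swims with an 8° pitch; restoring that depth difference is precisely what
the refraction correction contributes for straight fish.

The measurement report serialises to JSON with `writeReport(res)`. A thin
command-line front end wrapping these functions (commands `measure`,
`segment`, `simulate`, `evaluate`) ships as `inst/cli/fishlen.R`; a
commented configuration file is in `inst/extdata/example_config.yaml`.

## The synthetic bucket study

`simulateStudy()` re-creates the validation experiment in silico: camera
heights 250/350/450 mm above 500 mm of water, a fixed ten-fish cohort of
true lengths between 250 and 320 mm, three replicate scenes per fish and
height, straight and bent fish mixed, full pipeline (GrabCut included) on
every rendered scene:

```r
study <- simulateStudy(seeds = 1:3)   # 90 scenes, a few minutes
studyMRPE(study)
#>   height mrpeCorrected mrpeUncorrected  n
#> 1    250     1.3061683        1.478978 30
#> 2    350     1.0687968        1.169469 30
#> 3    450     0.9474686        1.077662 30
```

Refraction correction lowers the mean error at every camera height.

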
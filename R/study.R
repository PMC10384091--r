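#' Default cohort of true fish body lengths
#'
#' Ten body lengths in millimetres spanning the 250-320 mm range typical of
#' market-size perch, used as the fixed cohort of the synthetic measurement
#' study.
#'
#' @export
studyFishLengths <- c(255, 300, 295, 270, 292, 282, 294, 305, 320, 304)

# Draw one fish for the study under the current RNG stream. The container
# bottom (radius ~230 mm) and the camera field of view bound the placement;
# with the camera close to the water only deeper, near-centred fish are
# fully visible, which is how the measurement is operated in practice.
.drawStudyFish <- function(L, height, waterDepth) {
  d <- runif(1, 150, 420)
  # keep the whole (refraction-magnified) silhouette inside the frame
  zNeed <- (L / 2 + 17) / 0.30
  if (height + d < zNeed) d <- zNeed - height
  d <- min(d, waterDepth - 30)
  rLimit <- 0.30 * (height + d) - L / 2 - 12
  r0max <- max(0, min(230 - L / 2 - 10, rLimit))
  r0 <- sqrt(runif(1)) * r0max
  az <- runif(1, 0, 2 * pi)
  orient <- runif(1, 0, 360)
  bent <- runif(1) < 0.5
  if (bent) {
    curv <- sample(c(-1, 1), 1) * runif(1, 0.15, 0.6) * pi / L
    pitch <- 0
  } else {
    curv <- 0
    pitch <- runif(1, -12, 12)
  }
  fishSpec(lengthMm = L, widthMm = 0.2 * L, curvature = curv, depthMm = d,
           center = r0 * c(cos(az), sin(az)), orientationDeg = orient,
           pitchDeg = pitch)
}

#' Synthetic measurement study over several camera heights
#'
#' Re-creates the bucket experiment in silico: for each camera height, each
#' fish of the cohort is rendered (straight or bent, random placement and
#' attitude) in `length(seeds)` independent scenes, the full pipeline is run
#' on the rendered RGB-D pair, and the corrected and uncorrected lengths are
#' compared against the known truth.
#'
#' @param heights camera-to-water-surface distances, mm.
#' @param trueLengths cohort of true body lengths, mm.
#' @param seeds integer vector; each seed yields an independent replicate of
#'   the cohort at every height.
#' @param waterDepth water depth, mm.
#' @param cam a [CameraModel-class] (default: 640x480, f = 600 px, B = 50).
#' @param segmentation logical; FALSE replaces GrabCut by the ground-truth
#'   mask (isolates the measurement/refraction stages).
#' @param verbose print per-scene progress.
#' @return data.frame with one row per measurement: height, seed, fish
#'   index, truth, pose, corrected and uncorrected estimates and their
#'   relative errors (%).
#' @export
simulateStudy <- function(heights = c(250, 350, 450),
                          trueLengths = studyFishLengths,
                          seeds = 1:3, waterDepth = 500,
                          cam = cameraModel(fx = 600, baseline = 50,
                                            width = 640L, height = 480L),
                          segmentation = TRUE, verbose = FALSE) {
  rows <- list()
  for (height in heights) {
    rmod <- refractionModel(cameraHeight = height)
    for (si in seq_along(seeds)) {
      for (fi in seq_along(trueLengths)) {
        sceneSeed <- (seeds[si] * 1009L + fi * 101L +
                        as.integer(height)) %% .Machine$integer.max
        fish <- .withSeed(sceneSeed,
                          .drawStudyFish(trueLengths[fi], height, waterDepth))
        scn <- sceneSpec(cam, rmod, waterDepth = waterDepth,
                         fish = list(fish), seed = sceneSeed)
        rend <- renderScene(scn)
        tr <- rend$truth$fish[[1]]
        cfg <- measureConfig(camera = cam, refraction = rmod,
                             seg = segConfig(seed = sceneSeed %% 100000L))
        res <- tryCatch(
          runMeasure(cfg, rend$rgb, rend$depth, tr$roi,
                     mask = if (segmentation) NULL else tr$mask),
          fishlen_error = function(e) e)
        if (inherits(res, "error")) {
          rows[[length(rows) + 1L]] <- data.frame(
            height = height, seed = seeds[si], fish = fi,
            truth = trueLengths[fi], pose = NA_character_,
            theta = NA_real_, corrected = NA_real_, uncorrected = NA_real_,
            reCorrected = NA_real_, reUncorrected = NA_real_,
            error = conditionMessage(res))
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          height = height, seed = seeds[si], fish = fi,
          truth = trueLengths[fi], pose = res@pose, theta = res@thetaBend,
          corrected = res@lengthMm, uncorrected = res@lengthMmUncorrected,
          reCorrected = 100 * (res@lengthMm - trueLengths[fi]) / trueLengths[fi],
          reUncorrected = 100 * (res@lengthMmUncorrected - trueLengths[fi]) /
            trueLengths[fi],
          error = NA_character_)
        if (verbose)
          message(sprintf("h=%d seed=%d fish=%d: %s corr=%.1f unc=%.1f (truth %.0f)",
                          height, seeds[si], fi, res@pose, res@lengthMm,
                          res@lengthMmUncorrected, trueLengths[fi]))
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarise a study as per-height mean relative percentage errors
#'
#' @param study data.frame from [simulateStudy()].
#' @return data.frame with columns height, mrpeCorrected, mrpeUncorrected, n.
#' @export
studyMRPE <- function(study) {
  ok <- !is.na(study$corrected)
  agg <- function(v, g) tapply(abs(v), g, mean)
  h <- sort(unique(study$height[ok]))
  data.frame(height = h,
             mrpeCorrected = as.numeric(agg(study$reCorrected[ok], study$height[ok])[as.character(h)]),
             mrpeUncorrected = as.numeric(agg(study$reUncorrected[ok], study$height[ok])[as.character(h)]),
             n = as.numeric(table(study$height[ok])[as.character(h)]))
}
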
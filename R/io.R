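#' Measurement configuration
#'
#' Bundles the camera model, the (optional) refraction section, the
#' segmentation settings and the skeleton/measurement parameters. When
#' `refraction` is NULL the pipeline runs in ignore-refraction mode and the
#' reported length equals the uncorrected length.
#'
#' @slot camera a [CameraModel-class].
#' @slot refraction a [RefractionModel-class] or NULL.
#' @slot seg a [SegConfig-class].
#' @slot maxDeletions burr-pruning budget (NULL for the default).
#' @slot thetaThreshold bend-classification threshold, degrees.
#' @name MeasureConfig-class
#' @exportClass MeasureConfig
setClass("MeasureConfig",
  representation(camera = "CameraModel", refraction = "ANY",
                 seg = "SegConfig", maxDeletions = "ANY",
                 thetaThreshold = "numeric"))

#' @rdname MeasureConfig-class
#' @param camera,refraction,seg,maxDeletions,thetaThreshold see slots.
#' @export
measureConfig <- function(camera, refraction = NULL, seg = segConfig(),
                          maxDeletions = NULL, thetaThreshold = 5) {
  if (!is.null(refraction) && !is(refraction, "RefractionModel"))
    .flConfigError("refraction must be a RefractionModel or NULL")
  new("MeasureConfig", camera = camera, refraction = refraction, seg = seg,
      maxDeletions = maxDeletions, thetaThreshold = as.numeric(thetaThreshold))
}

setMethod("show", "MeasureConfig", function(object) {
  cat("MeasureConfig\n")
  show(object@camera)
  if (is.null(object@refraction)) cat("  refraction: ignored\n")
  else show(object@refraction)
  cat(sprintf("  theta threshold = %.1f deg\n", object@thetaThreshold))
})

.cfgNum <- function(section, field, path, default = NULL) {
  v <- section[[field]]
  if (is.null(v)) {
    if (is.null(default))
      .flConfigError(sprintf("missing required config field: %s", path))
    return(default)
  }
  if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
    .flConfigError(sprintf("config field %s must be a finite number", path))
  v
}

#' Load a measurement configuration from YAML
#'
#' The `camera` section is required (`fx` and `baseline_mm` at minimum).
#' The `refraction` section is optional; when present, the camera height
#' above the water surface is derived as
#' `camera_placement_mm - water_depth_mm` and must be positive.
#'
#' @param path YAML file.
#' @return a [MeasureConfig-class].
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) .flConfigError(sprintf("config file not found: %s", path))
  y <- tryCatch(yaml::read_yaml(path),
                error = function(e) .flConfigError(paste("cannot parse config:",
                                                         conditionMessage(e))))
  if (is.null(y$camera)) .flConfigError("missing required config section: camera")
  camSec <- y$camera
  width <- .cfgNum(camSec, "width", "camera/width", 640)
  height <- .cfgNum(camSec, "height", "camera/height", 480)
  fx <- .cfgNum(camSec, "fx", "camera/fx")
  cam <- cameraModel(
    fx = fx,
    fy = .cfgNum(camSec, "fy", "camera/fy", fx),
    cx = .cfgNum(camSec, "cx", "camera/cx", (width - 1) / 2),
    cy = .cfgNum(camSec, "cy", "camera/cy", (height - 1) / 2),
    baseline = .cfgNum(camSec, "baseline_mm", "camera/baseline_mm"),
    width = width, height = height)
  rmod <- NULL
  if (!is.null(y$refraction)) {
    rs <- y$refraction
    placement <- .cfgNum(rs, "camera_placement_mm", "refraction/camera_placement_mm")
    waterDepth <- .cfgNum(rs, "water_depth_mm", "refraction/water_depth_mm")
    h <- placement - waterDepth
    if (h <= 0)
      .flConfigError("refraction: camera placement must exceed the water depth (h > 0)")
    rmod <- refractionModel(cameraHeight = h,
                            nAir = .cfgNum(rs, "n_air", "refraction/n_air", 1.0),
                            nWater = .cfgNum(rs, "n_water", "refraction/n_water", 1.333))
    message(sprintf("camera height above water: h = %.1f mm", h))
  }
  ss <- if (is.null(y$segmentation)) list() else y$segmentation
  seg <- segConfig(
    gmmComponents = .cfgNum(ss, "gmm_components", "segmentation/gmm_components", 5),
    gamma = .cfgNum(ss, "gamma", "segmentation/gamma", 50),
    nIterations = .cfgNum(ss, "n_iterations", "segmentation/n_iterations", 5),
    stretchLowPct = .cfgNum(ss, "stretch_low_pct", "segmentation/stretch_low_pct", 1),
    stretchHighPct = .cfgNum(ss, "stretch_high_pct", "segmentation/stretch_high_pct", 99),
    brightnessOffset = .cfgNum(ss, "brightness_offset", "segmentation/brightness_offset", 0),
    seed = .cfgNum(ss, "seed", "segmentation/seed", 1))
  sk <- if (is.null(y$skeleton)) list() else y$skeleton
  maxDel <- if (is.null(sk$max_deletions)) NULL else as.integer(sk$max_deletions)
  ms <- if (is.null(y$measurement)) list() else y$measurement
  measureConfig(camera = cam, refraction = rmod, seg = seg,
                maxDeletions = maxDel,
                thetaThreshold = .cfgNum(ms, "theta_threshold_deg",
                                         "measurement/theta_threshold_deg", 5))
}

#' Read an aligned RGB-D image pair
#'
#' The RGB image is an 8-bit 3-channel PNG; the depth image a 16-bit
#' single-channel TIFF in integer millimetres (0 = invalid). Both are
#' returned in the package's `[x, y]` layout.
#'
#' @param rgbPath,depthPath file paths.
#' @return list with `rgb` (`[W, H, 3]`, 0..255) and `depth` (`[W, H]`, mm).
#' @export
readRGBD <- function(rgbPath, depthPath) {
  if (!file.exists(rgbPath)) .flInputError(sprintf("RGB image not found: %s", rgbPath))
  if (!file.exists(depthPath)) .flInputError(sprintf("depth image not found: %s", depthPath))
  rgb <- png::readPNG(rgbPath)
  if (length(dim(rgb)) == 2) rgb <- array(rep(rgb, 3), dim = c(dim(rgb), 3))
  if (dim(rgb)[3] == 4) rgb <- rgb[, , 1:3]
  if (dim(rgb)[3] != 3) .flInputError("RGB image must have 3 channels")
  rgb <- aperm(rgb, c(2, 1, 3)) * 255
  depth <- tryCatch(tiff::readTIFF(depthPath, as.is = TRUE),
                    error = function(e) .flInputError(paste("cannot read depth:",
                                                            conditionMessage(e))))
  if (length(dim(depth)) == 3) {
    if (dim(depth)[3] != 1) .flInputError("depth image must be single-channel")
    depth <- depth[, , 1]
  }
  depth <- t(depth)
  if (!all(dim(depth) == dim(rgb)[1:2]))
    .flInputError(sprintf("RGB (%dx%d) and depth (%dx%d) dimensions differ",
                          dim(rgb)[1], dim(rgb)[2], dim(depth)[1], dim(depth)[2]))
  list(rgb = rgb, depth = matrix(as.numeric(depth), nrow(depth), ncol(depth)))
}

#' Write an RGB-D pair
#'
#' @param rgb `[W, H, 3]` array (0..255).
#' @param depth `[W, H]` matrix, integer mm (clamped to 0..65535).
#' @param rgbPath,depthPath output paths (PNG and TIFF).
#' @export
writeRGBD <- function(rgb, depth, rgbPath, depthPath) {
  png::writePNG(aperm(pmin(pmax(rgb, 0), 255) / 255, c(2, 1, 3)), rgbPath)
  d <- pmin(pmax(round(depth), 0), 65535)
  tiff::writeTIFF(t(d) / 65535, depthPath, bits.per.sample = 16,
                  compression = "none")
  invisible(NULL)
}

.stage <- function(name, expr) {
  tryCatch(expr, fishlen_error = function(e) {
    stop(errorCondition(sprintf("[%s] %s", name, conditionMessage(e)),
                        class = class(e)))
  })
}

#' Run the full measurement pipeline
#'
#' Segments the fish inside the rectangle, cleans the mask, classifies the
#' pose from the bend angle, extracts the measurement points (straightening
#' a bent fish through its midline), and back-projects them to 3D — with
#' refraction correction when the configuration carries a refraction
#' section.
#'
#' @param cfg a [MeasureConfig-class].
#' @param rgb,depth images in `[x, y]` layout (see [readRGBD()]).
#' @param roi rectangle `c(x, y, w, h)`, 0-based.
#' @param mask optional precomputed binary fish mask; skips segmentation.
#' @return a [MeasurementResult-class].
#' @export
runMeasure <- function(cfg, rgb, depth, roi, mask = NULL) {
  if (is.null(mask))
    mask <- .stage("segment", segmentFish(rgb, roi, cfg@seg))
  mask <- .stage("clean", cleanMask(mask))
  geom <- .stage("geometry", fishGeometry(mask))
  pose <- classifyPose(geom$thetaBend, cfg@thetaThreshold)
  points <- if (pose == "straight") {
    .stage("points", straightPoints(geom, depth))
  } else {
    sk <- .stage("midline", extractMidline(geom$mask, cfg@maxDeletions))
    .stage("points", straighten(geom, sk, depth))
  }
  .stage("measure",
         measureLength(points, cfg@camera, cfg@refraction, geom$thetaBend))
}

#' Serialise a measurement result to JSON
#'
#' @param res a [MeasurementResult-class].
#' @param path output file; NULL returns the JSON string.
#' @export
writeReport <- function(res, path = NULL) {
  rep <- list(pose = res@pose, theta_deg = res@thetaBend,
              head_px = res@headPx, tail_px = res@tailPx,
              head_depth_mm = res@headDepth, tail_depth_mm = res@tailDepth,
              length_mm = res@lengthMm,
              length_mm_uncorrected = res@lengthMmUncorrected,
              arc_length_px = if (is.na(res@arcLengthPx)) NULL else res@arcLengthPx,
              warnings = res@diagnostics$warnings)
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}
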
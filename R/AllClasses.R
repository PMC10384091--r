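#' Pinhole stereo camera model
#'
#' Intrinsics of the RGB camera plus the stereo baseline. Focal lengths are
#' expressed in pixels (focal length divided by pixel pitch), so image-plane
#' coordinates produced by [pixelToPlane()] are pixel-normalised: a plane
#' coordinate of 1 corresponds to a 45 degree ray when `fx = fy`.
#'
#' @slot fx,fy focal length in pixels along x (columns) and y (rows).
#' @slot cx,cy principal point in 0-based pixel coordinates.
#' @slot baseline stereo baseline in millimetres.
#' @slot width,height image resolution in pixels.
#' @name CameraModel-class
#' @exportClass CameraModel
setClass("CameraModel",
  representation(fx = "numeric", fy = "numeric", cx = "numeric",
                 cy = "numeric", baseline = "numeric",
                 width = "integer", height = "integer"),
  validity = function(object) {
    msgs <- character()
    if (object@fx <= 0 || object@fy <= 0) msgs <- c(msgs, "focal lengths must be > 0")
    if (object@baseline <= 0) msgs <- c(msgs, "baseline must be > 0")
    if (object@width < 1L || object@height < 1L) msgs <- c(msgs, "resolution must be positive")
    if (object@cx < 0 || object@cx > object@width - 1 ||
        object@cy < 0 || object@cy > object@height - 1)
      msgs <- c(msgs, "principal point must lie inside the image")
    if (length(msgs)) msgs else TRUE
  })

#' Construct a camera model
#'
#' @param fx,fy focal lengths in pixels (`fy` defaults to `fx`, square pixels).
#' @param cx,cy principal point (0-based pixels); defaults to the image centre.
#' @param baseline stereo baseline in mm.
#' @param width,height resolution in pixels.
#' @return a [CameraModel-class] object.
#' @examples
#' cam <- cameraModel(fx = 600, baseline = 50, width = 640, height = 480)
#' @export
cameraModel <- function(fx, fy = fx, cx = (width - 1) / 2, cy = (height - 1) / 2,
                        baseline = 50, width = 640L, height = 480L) {
  .assertFinite(c(fx, fy, cx, cy, baseline), "camera parameters")
  new("CameraModel", fx = as.numeric(fx), fy = as.numeric(fy),
      cx = as.numeric(cx), cy = as.numeric(cy),
      baseline = as.numeric(baseline),
      width = as.integer(width), height = as.integer(height))
}

setMethod("show", "CameraModel", function(object) {
  cat(sprintf("CameraModel: %dx%d px, f = (%.1f, %.1f) px, c = (%.1f, %.1f), B = %.1f mm\n",
              object@width, object@height, object@fx, object@fy,
              object@cx, object@cy, object@baseline))
})

#' @rdname CameraModel-class
#' @param cam a `CameraModel`.
#' @export
focalLength <- function(cam) c(fx = cam@fx, fy = cam@fy)

#' @rdname CameraModel-class
#' @export
principalPoint <- function(cam) c(u0 = cam@cx, v0 = cam@cy)

#' @rdname CameraModel-class
#' @export
stereoBaseline <- function(cam) cam@baseline

#' @rdname CameraModel-class
#' @export
resolution <- function(cam) c(width = cam@width, height = cam@height)

#' Flat-interface refraction model
#'
#' Geometry and optics of the flat air-water interface: refractive indices on
#' either side and the height of the camera's optical centre above the water
#' surface. Produces the radial scale factor K relating the unrefracted to the
#' refracted image position of a submerged point, and from it the corrected
#' depth and 3D coordinates.
#'
#' @slot nAir,nWater refractive indices (defaults 1.0 and 1.333).
#' @slot cameraHeight height of the optical centre above the water surface, mm.
#' @name RefractionModel-class
#' @exportClass RefractionModel
setClass("RefractionModel",
  representation(nAir = "numeric", nWater = "numeric", cameraHeight = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (object@nAir < 1) msgs <- c(msgs, "nAir must be >= 1")
    if (object@nWater < object@nAir) msgs <- c(msgs, "nWater must be >= nAir")
    if (object@cameraHeight <= 0) msgs <- c(msgs, "cameraHeight must be > 0")
    if (length(msgs)) msgs else TRUE
  })

#' Construct a refraction model
#'
#' @param cameraHeight camera-to-water-surface distance h in mm.
#' @param nAir,nWater refractive indices of air and water.
#' @return a [RefractionModel-class] object.
#' @examples
#' rm <- refractionModel(cameraHeight = 250)
#' @export
refractionModel <- function(cameraHeight, nAir = 1.0, nWater = 1.333) {
  .assertFinite(c(cameraHeight, nAir, nWater), "refraction parameters")
  new("RefractionModel", nAir = as.numeric(nAir), nWater = as.numeric(nWater),
      cameraHeight = as.numeric(cameraHeight))
}

setMethod("show", "RefractionModel", function(object) {
  cat(sprintf("RefractionModel: n_air = %.4f, n_water = %.4f, h = %.1f mm\n",
              object@nAir, object@nWater, object@cameraHeight))
})

#' @rdname RefractionModel-class
#' @param rm a `RefractionModel`.
#' @export
cameraHeight <- function(rm) rm@cameraHeight

#' @rdname RefractionModel-class
#' @export
refractiveIndices <- function(rm) c(nAir = rm@nAir, nWater = rm@nWater)

#' GrabCut segmentation configuration
#'
#' @slot gmmComponents Gaussians per class (foreground / background).
#' @slot gamma weight of the boundary (smoothness) term.
#' @slot nIterations outer GrabCut iterations.
#' @slot stretchLowPct,stretchHighPct percentiles mapped to 0 and 255 by the
#'   linear contrast stretch.
#' @slot brightnessOffset additive brightness applied after the stretch.
#' @slot seed RNG seed for the k-means GMM initialisation.
#' @name SegConfig-class
#' @exportClass SegConfig
setClass("SegConfig",
  representation(gmmComponents = "integer", gamma = "numeric",
                 nIterations = "integer", stretchLowPct = "numeric",
                 stretchHighPct = "numeric", brightnessOffset = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msgs <- character()
    if (object@gmmComponents < 1L) msgs <- c(msgs, "gmmComponents must be >= 1")
    if (object@gamma <= 0) msgs <- c(msgs, "gamma must be > 0")
    if (object@nIterations < 1L) msgs <- c(msgs, "nIterations must be >= 1")
    if (object@stretchLowPct < 0 || object@stretchHighPct > 100 ||
        object@stretchLowPct >= object@stretchHighPct)
      msgs <- c(msgs, "stretch percentiles must satisfy 0 <= low < high <= 100")
    if (length(msgs)) msgs else TRUE
  })

#' Construct a segmentation configuration
#'
#' Defaults follow common GrabCut practice: 5 mixture components per class and
#' gamma = 50; the contrast stretch maps the 1st/99th intensity percentiles to
#' the full 8-bit range.
#'
#' @param gmmComponents,gamma,nIterations,stretchLowPct,stretchHighPct,brightnessOffset,seed
#'   see [SegConfig-class].
#' @return a [SegConfig-class] object.
#' @export
segConfig <- function(gmmComponents = 5L, gamma = 50, nIterations = 5L,
                      stretchLowPct = 1, stretchHighPct = 99,
                      brightnessOffset = 0, seed = 1L) {
  new("SegConfig", gmmComponents = as.integer(gmmComponents),
      gamma = as.numeric(gamma), nIterations = as.integer(nIterations),
      stretchLowPct = as.numeric(stretchLowPct),
      stretchHighPct = as.numeric(stretchHighPct),
      brightnessOffset = as.numeric(brightnessOffset), seed = as.integer(seed))
}

setMethod("show", "SegConfig", function(object) {
  cat(sprintf(
    "SegConfig: %d GMM components/class, gamma = %.1f, %d iterations, stretch [%g, %g]%% + %g\n",
    object@gmmComponents, object@gamma, object@nIterations,
    object@stretchLowPct, object@stretchHighPct, object@brightnessOffset))
})

#' Binary skeleton raster with endpoint/node bookkeeping
#'
#' Wraps a 1-pixel-wide binary skeleton (as produced by [zhangSuenThin()])
#' together with its pixel classification: endpoints have exactly one
#' 8-neighbour, ordinary skeleton points two, nodes three or more.
#'
#' @slot mask logical matrix `[x, y]`, skeleton pixels TRUE.
#' @slot endpoints,nodes 0-based `(u, v)` coordinates, one row per pixel.
#' @slot isConnected TRUE when the skeleton is a single 8-connected component.
#' @name SkeletonImage-class
#' @exportClass SkeletonImage
setClass("SkeletonImage",
  representation(mask = "matrix", endpoints = "matrix", nodes = "matrix",
                 isConnected = "logical"))

setMethod("show", "SkeletonImage", function(object) {
  cat(sprintf("SkeletonImage: %d px, %d endpoints, %d nodes, %sconnected\n",
              sum(object@mask), nrow(object@endpoints), nrow(object@nodes),
              if (object@isConnected) "" else "NOT "))
})

#' @rdname SkeletonImage-class
#' @param sk a `SkeletonImage`.
#' @export
skeletonMask <- function(sk) sk@mask

#' @rdname SkeletonImage-class
#' @export
skeletonEndpoints <- function(sk) sk@endpoints

#' @rdname SkeletonImage-class
#' @export
skeletonNodes <- function(sk) sk@nodes

#' Result of a fish length measurement
#'
#' @slot pose `"straight"` or `"bent"`.
#' @slot thetaBend bend angle in degrees (supplement of the angle at the
#'   bounding-rectangle centre subtended by the head/tail candidates).
#' @slot headPx,tailPx measurement points, 0-based pixels (tail is the
#'   constructed point m for bent fish and may be sub-pixel / off-image).
#' @slot headDepth,tailDepth depths sampled from the depth image, mm.
#' @slot head3d,tail3d refraction-corrected 3D coordinates, mm (equal to the
#'   uncorrected ones when refraction is disabled).
#' @slot lengthMm refraction-corrected body length, mm.
#' @slot lengthMmUncorrected length from plain back-projection at the measured
#'   depth, mm.
#' @slot arcLengthPx midline arc length in pixels (NA for straight fish).
#' @slot diagnostics list of warnings and intermediate values.
#' @name MeasurementResult-class
#' @exportClass MeasurementResult
setClass("MeasurementResult",
  representation(pose = "character", thetaBend = "numeric",
                 headPx = "numeric", tailPx = "numeric",
                 headDepth = "numeric", tailDepth = "numeric",
                 head3d = "numeric", tail3d = "numeric",
                 lengthMm = "numeric", lengthMmUncorrected = "numeric",
                 arcLengthPx = "numeric", diagnostics = "list"))

setMethod("show", "MeasurementResult", function(object) {
  cat(sprintf("MeasurementResult: %s fish, theta = %.2f deg\n",
              object@pose, object@thetaBend))
  cat(sprintf("  length = %.1f mm (uncorrected %.1f mm)\n",
              object@lengthMm, object@lengthMmUncorrected))
  cat(sprintf("  head (%.1f, %.1f) px @ %.0f mm; tail (%.1f, %.1f) px @ %.0f mm\n",
              object@headPx[1], object@headPx[2], object@headDepth,
              object@tailPx[1], object@tailPx[2], object@tailDepth))
  if (length(object@diagnostics$warnings))
    cat("  warnings:", paste(object@diagnostics$warnings, collapse = "; "), "\n")
})

#' @rdname MeasurementResult-class
#' @param x a `MeasurementResult`.
#' @export
fishLength <- function(x) x@lengthMm

#' @rdname MeasurementResult-class
#' @export
fishPose <- function(x) x@pose

#' @rdname MeasurementResult-class
#' @export
bendAngle <- function(x) x@thetaBend
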
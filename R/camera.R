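#' Pixel to image-plane conversion
#'
#' Converts 0-based pixel coordinates to pixel-normalised image-plane
#' coordinates `((u - u0)/fx, (v - v0)/fy)`. In these units the focal length
#' is 1, so the radial distance of a plane point equals the tangent of the
#' ray's angle off the optical axis.
#'
#' @param p pixel coordinates: a length-2 vector `(u, v)` or an n x 2 matrix.
#' @param cam a [CameraModel-class].
#' @return plane coordinates with the same shape as `p`.
#' @examples
#' cam <- cameraModel(fx = 600, width = 640, height = 480)
#' pixelToPlane(principalPoint(cam), cam)  # (0, 0)
#' @export
pixelToPlane <- function(p, cam) {
  p <- .asPoints2(p, "pixel coordinates")
  q <- cbind((p[, 1] - cam@cx) / cam@fx, (p[, 2] - cam@cy) / cam@fy)
  .dropPoints(q, p)
}

#' Image-plane to pixel conversion
#'
#' Exact inverse of [pixelToPlane()].
#'
#' @inheritParams pixelToPlane
#' @param q plane coordinates: length-2 vector or n x 2 matrix.
#' @export
planeToPixel <- function(q, cam) {
  q <- .asPoints2(q, "plane coordinates")
  p <- cbind(q[, 1] * cam@fx + cam@cx, q[, 2] * cam@fy + cam@cy)
  .dropPoints(p, q)
}

#' Depth from stereo disparity
#'
#' Triangulates depth from the pixel disparity of a stereo pair:
#' `Z = B * f / d`, with the baseline B in mm and focal length f in pixels.
#'
#' @param d disparity in pixels, > 0 (vectorised).
#' @param cam a [CameraModel-class]; `fx` is the triangulation focal length.
#' @return depth in mm.
#' @examples
#' cam <- cameraModel(fx = 600, baseline = 50)
#' depthFromDisparity(60, cam)  # 500 mm
#' @export
depthFromDisparity <- function(d, cam) {
  .assertFinite(d, "disparity")
  if (any(d <= 0)) .flInvalidArg("disparity must be > 0")
  cam@baseline * cam@fx / d
}

#' Back-project a pixel to 3D camera coordinates
#'
#' Ideal pinhole back-projection, ignoring refraction:
#' `X = (u - u0)/fx * Z`, `Y = (v - v0)/fy * Z`.
#'
#' @param p pixel coordinates (length-2 vector or n x 2 matrix).
#' @param Z depth in mm (> 0), recycled to the number of points.
#' @param cam a [CameraModel-class].
#' @return `(X, Y, Z)` in mm: length-3 vector or n x 3 matrix.
#' @export
backProject <- function(p, Z, cam) {
  p <- .asPoints2(p, "pixel coordinates")
  .assertFinite(Z, "depth")
  if (any(Z <= 0)) .flInvalidArg("depth must be > 0")
  q <- cbind((p[, 1] - cam@cx) / cam@fx, (p[, 2] - cam@cy) / cam@fy)
  out <- cbind(q[, 1] * Z, q[, 2] * Z, Z + numeric(nrow(p)))
  .dropPoints(out, p)
}

#' Euclidean distance between 3D points
#'
#' @param E,F length-3 vectors or n x 3 matrices of `(X, Y, Z)` mm.
#' @return distance(s) in mm.
#' @examples
#' euclideanLength(c(0, 0, 0), c(3, 4, 0))  # 5
#' @export
euclideanLength <- function(E, F) {
  E <- .asPoints3(E); F <- .asPoints3(F)
  sqrt(rowSums((E - F)^2))
}

# ---- point-shape helpers --------------------------------------------------

.asPoints2 <- function(p, what = "points") {
  wasVector <- is.null(dim(p))
  if (wasVector) {
    if (length(p) != 2) .flInvalidArg(sprintf("%s must have 2 coordinates", what))
    m <- matrix(as.numeric(p), 1, 2)
  } else {
    if (ncol(p) != 2) .flInvalidArg(sprintf("%s must be n x 2", what))
    m <- matrix(as.numeric(p), nrow(p), 2)
  }
  if (any(!is.finite(m))) .flInvalidArg(sprintf("%s must be finite", what))
  attr(m, "was_vector") <- wasVector
  m
}

# drop back to a bare vector when the input was one
.dropPoints <- function(out, p) {
  if (isTRUE(attr(p, "was_vector"))) out[1, ] else out
}

.asPoints3 <- function(p) {
  if (is.null(dim(p))) {
    if (length(p) != 3) .flInvalidArg("3D points must have 3 coordinates")
    p <- matrix(as.numeric(p), 1, 3)
  }
  if (ncol(p) != 3) .flInvalidArg("3D points must be n x 3")
  matrix(as.numeric(p), nrow(p), 3)
}
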
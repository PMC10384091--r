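#' Sine of the air-side ray angle from an image-plane point
#'
#' In pixel-normalised plane units the focal length is 1, so a plane point at
#' radial distance r images a ray with `sin(alpha) = r / sqrt(r^2 + 1)`.
#'
#' @param q plane coordinates (length-2 vector or n x 2 matrix), as returned
#'   by [pixelToPlane()].
#' @return `sin(alpha)` in `[0, 1)` (vectorised).
#' @examples
#' sinAlpha(c(0, 0))  # 0: on-axis ray
#' sinAlpha(c(1, 0))  # 1/sqrt(2)
#' @export
sinAlpha <- function(q) {
  q <- .asPoints2(q, "plane coordinates")
  r2 <- q[, 1]^2 + q[, 2]^2
  sqrt(r2 / (r2 + 1))
}

#' Snell's law: water-side sine from the air-side sine
#'
#' `sin(beta) = (n_air / n_water) * sin(alpha)`.
#'
#' @param sinA air-side sine(s), each in `[0, 1)`.
#' @param rm a [RefractionModel-class].
#' @return `sin(beta)` (vectorised).
#' @export
snellSinBeta <- function(sinA, rm) {
  .assertFinite(sinA, "sin(alpha)")
  if (any(sinA < 0 | sinA >= 1)) .flInvalidArg("sin(alpha) must lie in [0, 1)")
  rm@nAir / rm@nWater * sinA
}

#' Refraction scale factor K
#'
#' Radial scale relating the unrefracted image position of a submerged point
#' to its refracted (observed) position, `Qa = K * Qw`:
#' `K = h/Z + (1 - h/Z) * tan(beta)/tan(alpha)`,
#' where alpha is the air-side angle of the observed ray, beta follows from
#' Snell's law, h is the camera height above the surface and Z the depth at
#' which K is evaluated. On the optical axis the ratio of tangents is taken
#' at its analytic limit `n_air / n_water`. K is 1 when there is no interface
#' (`n_water = n_air`) or when the point sits exactly at the surface, and
#' less than 1 for submerged points viewed through water.
#'
#' @param q image-plane point(s) (vector or n x 2 matrix).
#' @param Z depth in mm at which to evaluate K; must exceed the camera height.
#' @param rm a [RefractionModel-class].
#' @return K in `(0, 1]` (vectorised).
#' @export
kFactor <- function(q, Z, rm) {
  q <- .asPoints2(q, "plane coordinates")
  .assertFinite(Z, "depth")
  if (any(Z < rm@cameraHeight))
    .flStop("point lies above the water surface (Z < camera height)",
            "fishlen_refraction_error")
  if (rm@nAir == rm@nWater) return(rep(1, max(nrow(q), length(Z))))
  sa <- sinAlpha(q)
  sb <- rm@nAir / rm@nWater * sa
  ratio <- ifelse(sa < 1e-9,
                  rm@nAir / rm@nWater,
                  (sb / sqrt(1 - sb^2)) / (sa / sqrt(1 - sa^2)))
  hz <- rm@cameraHeight / Z
  hz + (1 - hz) * ratio
}

#' Refraction-corrected depth
#'
#' Refraction inflates stereo disparity, so the depth read from the camera is
#' smaller than the true distance; the correction divides by the scale
#' factor: `Z' = Z_measured / K`.
#'
#' @param Z measured depth(s), mm, > 0.
#' @param K scale factor(s) in `(0, 1]`.
#' @return corrected depth(s), mm; always `>= Z`.
#' @export
correctDepth <- function(Z, K) {
  .assertFinite(Z, "depth"); .assertFinite(K, "K")
  if (any(K <= 0)) .flInvalidArg("K must be > 0")
  if (any(Z <= 0)) .flInvalidArg("depth must be > 0")
  Z / K
}

#' Refraction-aware back-projection
#'
#' Converts a pixel plus its measured stereo depth into 3D camera coordinates
#' of the true (unrefracted) point. The scale factor K couples to the depth
#' at which it is evaluated, so the correction is solved as a fixed point:
#' starting from the measured depth, `K` and `Z' = Z_measured / K` are
#' re-evaluated until `Z'` converges (tolerance `tol`, at most `iterations`
#' rounds). `iterations = 1` gives the single-application correction. The
#' final scale `Kw` multiplies the pixel-normalised offsets:
#' `X = Kw * (u - u0)/fx * Z'` (and likewise Y), with `Kw` evaluated at the
#' corrected depth by default (`kwMode = "corrected"`) or at the measured
#' depth (`kwMode = "measured"`).
#'
#' With `n_water = n_air` the result is identical to [backProject()].
#'
#' @param p pixel(s), 0-based (length-2 vector or n x 2 matrix).
#' @param Z measured depth(s), mm.
#' @param cam a [CameraModel-class].
#' @param rm a [RefractionModel-class].
#' @param iterations maximum fixed-point rounds (default 20).
#' @param tol convergence tolerance on `Z'` in mm.
#' @param kwMode depth at which the final lateral scale is evaluated.
#' @return `(X, Y, Z')` mm, same shape convention as [backProject()].
#' @export
correctedBackproject <- function(p, Z, cam, rm, iterations = 20L, tol = 1e-6,
                                 kwMode = c("corrected", "measured")) {
  kwMode <- match.arg(kwMode)
  p <- .asPoints2(p, "pixel coordinates")
  .assertFinite(Z, "depth")
  if (any(Z <= 0)) .flInvalidArg("depth must be > 0")
  q <- cbind((p[, 1] - cam@cx) / cam@fx, (p[, 2] - cam@cy) / cam@fy)
  n <- nrow(q)
  Z <- rep_len(as.numeric(Z), n)
  Zp <- Z / kFactor(q, Z, rm)
  if (iterations > 1L) {
    for (i in seq_len(iterations - 1L)) {
      Zn <- Z / kFactor(q, Zp, rm)
      done <- max(abs(Zn - Zp)) < tol
      Zp <- Zn
      if (done) break
    }
  }
  Kw <- if (kwMode == "corrected") kFactor(q, Zp, rm) else kFactor(q, Z, rm)
  out <- cbind(Kw * q[, 1] * Zp, Kw * q[, 2] * Zp, Zp)
  dimnames(out) <- NULL
  .dropPoints(out, p)
}
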
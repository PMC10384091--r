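# Solve the Snell surface-crossing radius s for points at radial offset R and
# depth Z, camera height h above the surface: the air-side ray meets the
# surface at radius s with n_air sin(alpha) = n_water sin(beta). The root is
# bracketed by [0, R] and found by (vectorised) bisection, which converges
# unconditionally.
.snellCrossing <- function(R, Z, h, nAir, nWater, iters = 60L) {
  if (nAir == nWater) return(R * h / Z)  # straight ray
  lo <- numeric(length(R))
  hi <- R
  D <- Z - h
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    f <- nAir * mid / sqrt(mid^2 + h^2) -
         nWater * (R - mid) / sqrt((R - mid)^2 + D^2)
    neg <- f < 0
    lo[neg] <- mid[neg]
    hi[!neg] <- mid[!neg]
  }
  (lo + hi) / 2
}

#' Forward refractive projection of a submerged point
#'
#' Ray-traces a 3D point below the flat air-water interface through the
#' interface into an ideal pinhole camera: the Snell crossing point on the
#' surface is solved by bisection in the plane containing the optical axis
#' and the point, and the air-side ray is projected to a pixel. This is the
#' exact forward model that [correctedBackproject()] approximately inverts.
#'
#' @param P 3D point(s) `(X, Y, Z)` mm, `Z` below the surface (`Z > h`);
#'   length-3 vector or n x 3 matrix.
#' @param cam a [CameraModel-class].
#' @param rm a [RefractionModel-class].
#' @return pixel coordinates (same shape convention as the input).
#' @export
refractProject <- function(P, cam, rm) {
  wasVector <- is.null(dim(P))
  P <- .asPoints3(P)
  h <- rm@cameraHeight
  if (any(P[, 3] <= h))
    .flStop("point lies above the water surface", "fishlen_refraction_error")
  R <- sqrt(P[, 1]^2 + P[, 2]^2)
  s <- .snellCrossing(R, P[, 3], h, rm@nAir, rm@nWater)
  t <- s / h  # tan(alpha) = radial plane coordinate
  scale <- ifelse(R > 1e-12, t / R, 0)
  q <- cbind(P[, 1] * scale, P[, 2] * scale)
  out <- cbind(q[, 1] * cam@fx + cam@cx, q[, 2] * cam@fy + cam@cy)
  if (wasVector) out[1, ] else out
}

#' Apparent stereo depth of a submerged point
#'
#' Projects the point through both stereo pinholes (offset by +-B/2 along x)
#' with full refractive ray tracing, forms the horizontal disparity, and
#' triangulates `Z = B * f / d` — the depth an ideal stereo depth camera
#' would report. For submerged points this is smaller than the true
#' distance; with `n_water = n_air` it equals the true depth.
#'
#' @inheritParams refractProject
#' @return apparent depth(s) in mm.
#' @export
apparentDepth <- function(P, cam, rm) {
  P <- .asPoints3(P)
  h <- rm@cameraHeight
  if (any(P[, 3] <= h))
    .flStop("point lies above the water surface", "fishlen_refraction_error")
  B <- cam@baseline
  xcoord <- function(cx) {
    dx <- P[, 1] - cx
    R <- sqrt(dx^2 + P[, 2]^2)
    s <- .snellCrossing(R, P[, 3], h, rm@nAir, rm@nWater)
    ifelse(R > 1e-12, dx / R * (s / h), 0)
  }
  dplane <- xcoord(-B / 2) - xcoord(B / 2)
  if (any(dplane <= 0))
    .flStop("stereo projection failed (non-positive disparity)",
            "fishlen_projection_error")
  B / dplane
}

# ---- parametric fish geometry ---------------------------------------------

# Membership test in the spine frame (origin at the spine midpoint, heading
# +x): a teardrop profile of maximum width `wmax` swept along a circular arc
# of signed curvature `kappa` (0 = straight) and arc length L.
.fishMembership <- function(xr, yr, L, wmax, kappa) {
  if (abs(kappa) < 1e-9) {
    t <- xr
    d <- abs(yr)
  } else {
    vx <- kappa * xr
    vy <- kappa * yr - 1
    u <- atan2(vx, -vy)
    t <- u / kappa
    d <- abs(sqrt(xr^2 + (yr - 1 / kappa)^2) - abs(1 / kappa))
  }
  tau <- t / L + 0.5
  w <- wmax * pmax(0, sin(pi * pmin(pmax(tau, 0), 1)))^0.65
  list(inside = abs(t) <= L / 2 & d <= w / 2, t = t)
}

# spine polyline in the spine frame, n x 2, arc-length parameterised
.fishSpine <- function(L, kappa, n = 201L) {
  t <- seq(-L / 2, L / 2, length.out = n)
  if (abs(kappa) < 1e-9) cbind(t, 0)
  else cbind(sin(kappa * t) / kappa, (1 - cos(kappa * t)) / kappa)
}

.rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Specify a synthetic fish
#'
#' Geometry and appearance of one fish: a teardrop body profile swept along
#' a circular-arc spine. Bent fish (`curvature != 0`) swim level; straight
#' fish may pitch (tilt head-up/down), giving the head and tail different
#' depths as real swimming fish do.
#'
#' @param lengthMm true body length (spine arc length), mm.
#' @param widthMm maximum body width, mm (default 20% of the length).
#' @param curvature signed spine curvature, 1/mm; at most `pi / lengthMm`
#'   (a semicircle).
#' @param depthMm depth of the body centre below the water surface, mm.
#' @param center `(x, y)` of the spine midpoint in camera-frame mm.
#' @param orientationDeg planar heading, degrees.
#' @param pitchDeg head-up tilt, degrees (straight fish only).
#' @param bodyGray body gray level, 0..255.
#' @return a validated `fishSpec` list.
#' @export
fishSpec <- function(lengthMm, widthMm = 0.2 * lengthMm, curvature = 0,
                     depthMm = 350, center = c(0, 0), orientationDeg = 0,
                     pitchDeg = 0, bodyGray = 90) {
  .assertFinite(c(lengthMm, widthMm, curvature, depthMm, center,
                  orientationDeg, pitchDeg, bodyGray), "fish spec")
  if (!(lengthMm > widthMm && widthMm > 0))
    .flInvalidArg("need lengthMm > widthMm > 0")
  if (depthMm <= 0) .flInvalidArg("depthMm must be > 0")
  if (abs(curvature) > pi / lengthMm + 1e-12)
    .flInvalidArg("curvature exceeds a semicircular spine")
  if (abs(curvature) > 1e-9 && abs(pitchDeg) > 1e-9)
    .flInvalidArg("bent fish must be level (pitchDeg = 0)")
  list(lengthMm = lengthMm, widthMm = widthMm, curvature = curvature,
       depthMm = depthMm, center = as.numeric(center),
       orientationDeg = orientationDeg, pitchDeg = pitchDeg,
       bodyGray = bodyGray)
}

#' Specify a synthetic RGB-D scene
#'
#' @param cam a [CameraModel-class].
#' @param rm a [RefractionModel-class] (its `cameraHeight` is the camera-to-
#'   surface distance).
#' @param waterDepth water depth below the surface, mm; the flat bottom of
#'   the container is the image background.
#' @param fish list of [fishSpec()] objects.
#' @param bgGray background gray level.
#' @param noiseRgb additive Gaussian RGB noise sd, gray levels.
#' @param noiseDepth additive Gaussian depth noise sd, mm.
#' @param seed integer seed fixing all generator randomness.
#' @return a validated `sceneSpec` list.
#' @export
sceneSpec <- function(cam, rm, waterDepth = 500, fish = list(),
                      bgGray = 170, noiseRgb = 3, noiseDepth = 2, seed = 1L) {
  if (!is(cam, "CameraModel") || !is(rm, "RefractionModel"))
    .flInvalidArg("cam/rm must be CameraModel and RefractionModel objects")
  if (waterDepth <= 0) .flInvalidArg("waterDepth must be > 0")
  for (f in fish)
    if (f$depthMm > waterDepth)
      .flInvalidArg("fish depth exceeds the water depth")
  list(cam = cam, rm = rm, waterDepth = waterDepth, fish = fish,
       bgGray = bgGray, noiseRgb = noiseRgb, noiseDepth = noiseDepth,
       seed = as.integer(seed))
}

#' Rasterise a fish silhouette with its ground-truth spine
#'
#' Pixel-space rendering of one fish (no refraction, no camera): used for
#' skeleton and measurement fixtures. The spine is arc-length parameterised,
#' so its polyline length equals `lengthMm * scale` up to discretisation.
#'
#' @param spec a [fishSpec()].
#' @param scale pixels per mm.
#' @param canvas `c(width, height)` px; default fits the fish with margin.
#' @return list with `mask` (binary matrix `[x, y]`), `spine` (n x 2,
#'   0-based px), and `spineLengthPx`.
#' @export
makeFishMask <- function(spec, scale = 1, canvas = NULL) {
  if (scale <= 0) .flInvalidArg("scale must be > 0")
  L <- spec$lengthMm * scale
  Wb <- spec$widthMm * scale
  kappa <- spec$curvature / scale
  spine0 <- .fishSpine(L, kappa)
  theta <- spec$orientationDeg * pi / 180
  Rm <- .rot2(theta)
  spine <- spine0 %*% t(Rm)
  ext <- apply(spine, 2, range)
  need <- c(diff(ext[, 1]), diff(ext[, 2])) + Wb + 6
  if (is.null(canvas)) canvas <- ceiling(need + 4)
  W <- canvas[1]; H <- canvas[2]
  if (need[1] > W || need[2] > H) .flInvalidArg("fish exceeds the canvas")
  ctr <- c((W - 1) / 2 - mean(ext[, 1]), (H - 1) / 2 - mean(ext[, 2]))
  u <- matrix(0:(W - 1), W, H)
  v <- matrix(0:(H - 1), W, H, byrow = TRUE)
  rel <- cbind(as.vector(u) - ctr[1], as.vector(v) - ctr[2]) %*% Rm
  mem <- .fishMembership(rel[, 1], rel[, 2], L, Wb, kappa)
  mask <- matrix(as.integer(mem$inside), W, H)
  spinePx <- sweep(spine, 2, ctr, `+`)
  seglen <- sqrt(rowSums(diff(spinePx)^2))
  list(mask = mask, spine = spinePx, spineLengthPx = sum(seglen))
}

#' Render a refraction-distorted RGB-D scene
#'
#' Physically forward-models the §-style top-view geometry: each pixel's
#' camera ray is traced through the flat interface (bending by Snell's law)
#' to the fish lamina or the container bottom; fish pixels take the body
#' gray and a depth equal to the *apparent stereo depth* of the true 3D
#' point (full two-camera ray trace), so the depth image contains exactly
#' the refraction-distorted reading a stereo camera would produce.
#' Background depth is ray-traced on a coarse grid and interpolated.
#' Gaussian pixel and depth noise are added and the depth is quantised to
#' integer millimetres. All randomness derives from `spec$seed`.
#'
#' @param spec a [sceneSpec()].
#' @return list with `rgb` (`[W, H, 3]`, 0..255), `depth` (`[W, H]` integer
#'   mm), and `truth`: per fish the true length, 3D spine endpoints, pixel
#'   mask, suggested ROI `c(x, y, w, h)` and overlap flag, plus the scene
#'   parameters.
#' @export
renderScene <- function(spec) {
  cam <- spec$cam; rm <- spec$rm
  W <- cam@width; H <- cam@height
  h <- rm@cameraHeight
  .withSeed(spec$seed, {
    uu <- matrix(0:(W - 1), W, H)
    vv <- matrix(0:(H - 1), W, H, byrow = TRUE)
    qx <- (as.vector(uu) - cam@cx) / cam@fx
    qy <- (as.vector(vv) - cam@cy) / cam@fy
    r <- sqrt(qx^2 + qy^2)
    sa <- r / sqrt(1 + r^2)
    sb <- rm@nAir / rm@nWater * sa
    tanB <- sb / sqrt(1 - sb^2)
    dirx <- ifelse(r > 1e-12, qx / r, 0)
    diry <- ifelse(r > 1e-12, qy / r, 0)
    sCross <- h * r  # surface crossing radius of each pixel ray

    # background: bottom plane, apparent depth on a coarse grid
    Zb <- h + spec$waterDepth
    Rbot <- sCross + (Zb - h) * tanB
    bgX <- dirx * Rbot; bgY <- diry * Rbot
    depth <- matrix(.coarseApparentDepth(bgX, bgY, Zb, W, H, cam, rm), W, H)
    gray <- matrix(spec$bgGray, W, H)

    painted <- matrix(0L, W, H)
    truthFish <- vector("list", length(spec$fish))
    overlap <- FALSE
    ord <- order(-vapply(spec$fish, function(f) f$depthMm, numeric(1)))
    for (fi in ord) {
      f <- spec$fish[[fi]]
      theta <- f$orientationDeg * pi / 180
      Rm2 <- .rot2(theta)
      if (abs(f$curvature) > 1e-9 || abs(f$pitchDeg) < 1e-9) {
        # level fish: intersect rays with the constant-depth plane
        Zf <- h + f$depthMm
        Rw <- sCross + (Zf - h) * tanB
        Xw <- dirx * Rw; Yw <- diry * Rw
        rel <- cbind(Xw - f$center[1], Yw - f$center[2]) %*% Rm2
        mem <- .fishMembership(rel[, 1], rel[, 2], f$lengthMm, f$widthMm,
                               f$curvature)
        inside <- mem$inside
        P3 <- cbind(Xw[inside], Yw[inside], Zf)
      } else {
        # pitched straight fish: intersect rays with the tilted lamina plane
        phi <- f$pitchDeg * pi / 180
        d3 <- c(cos(theta) * cos(phi), sin(theta) * cos(phi), sin(phi))
        s3 <- c(-sin(theta), cos(theta), 0)
        n3 <- c(d3[2] * s3[3] - d3[3] * s3[2],
                d3[3] * s3[1] - d3[1] * s3[3],
                d3[1] * s3[2] - d3[2] * s3[1])
        P0 <- c(f$center, h + f$depthMm)
        cb <- sqrt(1 - sb^2)
        wx <- dirx * sb; wy <- diry * sb; wz <- cb
        Cx <- dirx * sCross; Cy <- diry * sCross
        denom <- wx * n3[1] + wy * n3[2] + wz * n3[3]
        lam <- ((P0[1] - Cx) * n3[1] + (P0[2] - Cy) * n3[2] +
                (P0[3] - h) * n3[3]) / denom
        Px <- Cx + lam * wx; Py <- Cy + lam * wy; Pz <- h + lam * wz
        t <- (Px - P0[1]) * d3[1] + (Py - P0[2]) * d3[2] + (Pz - P0[3]) * d3[3]
        ss <- (Px - P0[1]) * s3[1] + (Py - P0[2]) * s3[2] + (Pz - P0[3]) * s3[3]
        mem <- .fishMembership(t, ss, f$lengthMm, f$widthMm, 0)
        inside <- mem$inside & lam > 0 & Pz > h
        P3 <- cbind(Px[inside], Py[inside], Pz[inside])
      }
      if (!any(inside)) {
        truthFish[[fi]] <- list(visible = FALSE, lengthMm = f$lengthMm)
        next
      }
      if (any(painted[inside] > 0)) overlap <- TRUE
      gray[inside] <- f$bodyGray
      depth[inside] <- apparentDepth(P3, cam, rm)
      painted[inside] <- painted[inside] + 1L
      fmask <- matrix(0L, W, H); fmask[inside] <- 1L
      # ground-truth spine endpoints in 3D
      sp0 <- .fishSpine(f$lengthMm, f$curvature)
      sp <- sweep(sp0 %*% t(Rm2), 2, f$center, `+`)
      if (abs(f$pitchDeg) > 1e-9) {
        phi <- f$pitchDeg * pi / 180
        tpar <- seq(-f$lengthMm / 2, f$lengthMm / 2, length.out = nrow(sp0))
        sp3 <- cbind(f$center[1] + tpar * cos(theta) * cos(phi),
                     f$center[2] + tpar * sin(theta) * cos(phi),
                     h + f$depthMm + tpar * sin(phi))
      } else {
        sp3 <- cbind(sp, h + f$depthMm)
      }
      w <- which(fmask > 0, arr.ind = TRUE)
      mrg <- 10L
      x0 <- max(0L, min(w[, 1]) - 1L - mrg); y0 <- max(0L, min(w[, 2]) - 1L - mrg)
      x1 <- min(W - 1L, max(w[, 1]) - 1L + mrg); y1 <- min(H - 1L, max(w[, 2]) - 1L + mrg)
      truthFish[[fi]] <- list(
        visible = TRUE, lengthMm = f$lengthMm, curvature = f$curvature,
        pitchDeg = f$pitchDeg, depthMm = f$depthMm,
        spine3d = sp3, head3d = sp3[1, ], tail3d = sp3[nrow(sp3), ],
        mask = fmask, roi = c(x0, y0, x1 - x0 + 1L, y1 - y0 + 1L),
        clipped = any(w[, 1] %in% c(1L, W)) || any(w[, 2] %in% c(1L, H)))
    }
    gray <- gray + matrix(rnorm(W * H, 0, spec$noiseRgb), W, H)
    gray <- pmin(pmax(round(gray), 0), 255)
    depth <- depth + matrix(rnorm(W * H, 0, spec$noiseDepth), W, H)
    depth <- matrix(as.integer(pmin(pmax(round(depth), 0), 65535)), W, H)
    rgb <- array(rep(gray, 3), dim = c(W, H, 3))
    list(rgb = rgb, depth = depth,
         truth = list(fish = truthFish, overlap = overlap,
                      waterDepth = spec$waterDepth, seed = spec$seed))
  })
}

# apparent depth of plane points (X, Y) at true depth Z for every pixel,
# ray-traced on a coarse pixel grid and bilinearly interpolated
.coarseApparentDepth <- function(X, Y, Z, W, H, cam, rm, step = 4L) {
  us <- unique(c(seq(1L, W, by = step), W))
  vs <- unique(c(seq(1L, H, by = step), H))
  idx <- as.vector(outer(us, (vs - 1L) * W, `+`))
  zm <- apparentDepth(cbind(X[idx], Y[idx], Z), cam, rm)
  zg <- matrix(zm, length(us), length(vs))
  # bilinear interpolation onto the full grid
  ui <- findInterval(1:W, us, rightmost.closed = TRUE)
  ui <- pmin(ui, length(us) - 1L)
  vi <- findInterval(1:H, vs, rightmost.closed = TRUE)
  vi <- pmin(vi, length(vs) - 1L)
  fu <- (1:W - us[ui]) / (us[ui + 1L] - us[ui])
  fv <- (1:H - vs[vi]) / (vs[vi + 1L] - vs[vi])
  z11 <- zg[cbind(rep(ui, length(vi)), rep(vi, each = length(ui)))]
  z21 <- zg[cbind(rep(ui + 1L, length(vi)), rep(vi, each = length(ui)))]
  z12 <- zg[cbind(rep(ui, length(vi)), rep(vi + 1L, each = length(ui)))]
  z22 <- zg[cbind(rep(ui + 1L, length(vi)), rep(vi + 1L, each = length(ui)))]
  FU <- rep(fu, length(vi)); FV <- rep(fv, each = length(ui))
  (1 - FU) * (1 - FV) * z11 + FU * (1 - FV) * z21 +
    (1 - FU) * FV * z12 + FU * FV * z22
}
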
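#' Morphological cleanup of a segmentation mask
#'
#' One erosion followed by one dilation (opening) with a 3 x 3 box element,
#' removing speckle noise left by segmentation.
#'
#' @param mask binary matrix `[x, y]`.
#' @return binary integer matrix.
#' @export
cleanMask <- function(mask) {
  m <- .asBinaryMatrix(mask)
  k <- EBImage::makeBrush(3, shape = "box")
  img <- EBImage::dilate(EBImage::erode(EBImage::Image(m), k), k)
  (as.matrix(EBImage::imageData(img)) > 0) + 0L
}

#' Fish contour geometry and bend angle
#'
#' Finds the largest connected component of the mask, its outer contour and
#' minimum-area (rotated) bounding rectangle. The two shorter rectangle sides
#' ab and cd intersect the fish at the head/tail candidates e and f (taken as
#' the contour point closest to each side's supporting line, ties broken by
#' distance to the side midpoint). The bend angle theta is the supplement of
#' the angle at the rectangle centre o subtended by e and f, computed with
#' the law of cosines, so a straight fish has theta near 0.
#'
#' @param mask binary matrix `[x, y]`.
#' @return a list with `contour` (n x 2, 0-based), `rect` (4 x 2 vertices),
#'   `shortSides` (list of two 2 x 2 matrices: ab and cd), `e`, `f`, `o`
#'   (0-based pixel coordinates) and `thetaBend` (degrees).
#' @export
fishGeometry <- function(mask) {
  m <- .asBinaryMatrix(mask)
  if (sum(m) < 5) .flNoFish("no fish found in mask (fewer than 5 pixels)")
  lab <- .label8(m)
  sizes <- tabulate(lab$labels[lab$labels > 0])
  keep <- which.max(sizes)
  m[lab$labels != keep] <- 0L
  contour <- .outerContour(m)
  if (nrow(contour) < 4) .flNoFish("fish contour is degenerate")
  rect <- .minAreaRect(contour)
  # side lengths of the (ordered) rectangle
  sides <- lapply(1:4, function(i) rect[c(i, i %% 4 + 1), , drop = FALSE])
  lens <- vapply(sides, function(s) sqrt(sum((s[2, ] - s[1, ])^2)), numeric(1))
  shortIdx <- order(lens)[1:2]
  if (min(lens[-shortIdx]) < 1e-9) .flNoFish("fish mask is degenerate (zero-area rectangle)")
  short <- sides[shortIdx]
  o <- colMeans(rect)
  e <- .contourSideIntersection(contour, short[[1]])
  f <- .contourSideIntersection(contour, short[[2]])
  thetaBend <- 180 - .angleAt(o, e, f)
  list(contour = contour, rect = rect, shortSides = short,
       e = e, f = f, o = o, thetaBend = thetaBend, mask = m)
}

# ordered outer contour of the (single-component) mask, 0-based (u, v)
.outerContour <- function(m) {
  oc <- EBImage::ocontour(EBImage::Image(m))
  pts <- oc[[which.max(vapply(oc, nrow, integer(1)))]]
  colnames(pts) <- c("u", "v")
  pts
}

# minimum-area rectangle by rotating calipers over the convex hull
.minAreaRect <- function(pts) {
  hull <- pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
  n <- nrow(hull)
  if (n == 1) return(hull[c(1, 1, 1, 1), , drop = FALSE])
  if (n == 2) {
    return(rbind(hull[1, ], hull[2, ], hull[2, ], hull[1, ]))
  }
  best <- NULL; bestArea <- Inf
  for (i in seq_len(n)) {
    edge <- hull[i %% n + 1, ] - hull[i, ]
    len <- sqrt(sum(edge^2))
    if (len < 1e-12) next
    ex <- edge / len
    ey <- c(-ex[2], ex[1])
    s <- hull %*% cbind(ex, ey)
    r1 <- range(s[, 1]); r2 <- range(s[, 2])
    area <- diff(r1) * diff(r2)
    if (area < bestArea) {
      bestArea <- area
      corners <- rbind(c(r1[1], r2[1]), c(r1[2], r2[1]),
                       c(r1[2], r2[2]), c(r1[1], r2[2]))
      best <- corners %*% rbind(ex, ey)
    }
  }
  colnames(best) <- c("u", "v")
  best
}

# contour point closest to the supporting line of a rectangle side
.contourSideIntersection <- function(contour, side) {
  a <- side[1, ]; b <- side[2, ]
  ab <- b - a
  nrm <- c(-ab[2], ab[1]) / sqrt(sum(ab^2))
  d <- abs((contour[, 1] - a[1]) * nrm[1] + (contour[, 2] - a[2]) * nrm[2])
  cand <- which(d <= min(d) + 1e-9)
  if (length(cand) > 1) {
    mid <- (a + b) / 2
    dm <- (contour[cand, 1] - mid[1])^2 + (contour[cand, 2] - mid[2])^2
    cand <- cand[which.min(dm)]
  }
  as.numeric(contour[cand[1], ])
}

# angle (degrees) at vertex o of triangle e-o-f, law of cosines
.angleAt <- function(o, e, f) {
  a2 <- sum((e - o)^2); b2 <- sum((f - o)^2); c2 <- sum((e - f)^2)
  if (a2 == 0 || b2 == 0) return(180)  # degenerate: treat as straight
  cosv <- (a2 + b2 - c2) / (2 * sqrt(a2) * sqrt(b2))
  acos(min(1, max(-1, cosv))) * 180 / pi
}

#' Classify the fish pose from the bend angle
#'
#' A fish is bent when theta strictly exceeds the threshold (default 5
#' degrees); theta equal to the threshold classifies as straight.
#'
#' @param thetaBend bend angle in degrees.
#' @param threshold decision threshold in degrees.
#' @return `"straight"` or `"bent"`.
#' @export
classifyPose <- function(thetaBend, threshold = 5) {
  .assertFinite(thetaBend, "theta")
  if (thetaBend < 0 || thetaBend > 180) .flInvalidArg("theta must be in [0, 180]")
  if (thetaBend > threshold) "bent" else "straight"
}

# Robust depth read at a (possibly sub-pixel) point: median of valid depths
# in a win x win window, restricted to `mask` when given; falls back to the
# nearest valid pixel within `fallback` px.
.sampleDepth <- function(depth, p, mask = NULL, win = 5L, fallback = 15L) {
  W <- nrow(depth); H <- ncol(depth)
  u <- round(p[1]) + 1; v <- round(p[2]) + 1
  u <- min(max(u, 1), W); v <- min(max(v, 1), H)
  half <- win %/% 2
  us <- max(1, u - half):min(W, u + half)
  vs <- max(1, v - half):min(H, v + half)
  vals <- depth[us, vs, drop = FALSE]
  ok <- vals > 0
  if (!is.null(mask)) ok <- ok & (mask[us, vs, drop = FALSE] > 0)
  if (any(ok)) return(median(vals[ok]))
  # fallback: nearest valid pixel within `fallback`
  us <- max(1, u - fallback):min(W, u + fallback)
  vs <- max(1, v - fallback):min(H, v + fallback)
  vals <- depth[us, vs, drop = FALSE]
  ok <- vals > 0
  if (!is.null(mask)) ok <- ok & (mask[us, vs, drop = FALSE] > 0)
  if (!any(ok)) .flMissingDepth(sprintf(
    "no valid depth within %d px of (%.1f, %.1f)", fallback, p[1], p[2]))
  w <- which(ok, arr.ind = TRUE)
  dd <- (us[w[, 1]] - u)^2 + (vs[w[, 2]] - v)^2
  vals[ok][which.min(dd)]
}

#' Measurement points for a straight fish
#'
#' For a straight fish the head/tail candidates e and f from
#' [fishGeometry()] are the best measurement points; their depths are read
#' from the depth image with a robust windowed median restricted to the fish
#' mask.
#'
#' @param geom result of [fishGeometry()].
#' @param depth depth image `[x, y]`, mm.
#' @return list with `head`, `tail` (0-based px), `headDepth`, `tailDepth`
#'   (mm), `pose`, `arcLengthPx` (NA).
#' @export
straightPoints <- function(geom, depth) {
  list(head = geom$e, tail = geom$f,
       headDepth = .sampleDepth(depth, geom$e, geom$mask),
       tailDepth = .sampleDepth(depth, geom$f, geom$mask),
       pose = "straight", arcLengthPx = NA_real_)
}

#' Arc length of the composite midline
#'
#' The midline found by [extractMidline()] usually stops short of the
#' silhouette tips, so its endpoints g and h are joined to the head/tail
#' candidates e and f (pairing chosen to minimise total distance). The arc
#' length is `|eg| +` (skeleton path length, counting 1 per axial and
#' sqrt(2) per diagonal step) `+ |hf|`.
#'
#' @param sk a [SkeletonImage-class] with exactly two endpoints.
#' @param e,f head/tail candidate pixels (0-based).
#' @param smooth measure the length of a lightly smoothed midline polyline
#'   (default) instead of the raw step count. The raw 8-connected chain
#'   (1 per axial step, sqrt(2) per diagonal step) systematically
#'   overestimates the length of a digitised curve by several percent
#'   because the thinned midline zigzags about the true centreline; a
#'   7-pixel moving-average of the ordered path removes that bias while
#'   leaving straight and diagonal lines exact.
#' @return arc length in pixels.
#' @export
arcLength <- function(sk, e, f, smooth = TRUE) {
  if (!is(sk, "SkeletonImage")) sk <- skeletonImage(sk)
  if (nrow(sk@endpoints) != 2)
    .flStateError("skeleton must have exactly 2 endpoints")
  g <- sk@endpoints[1, ]; h <- sk@endpoints[2, ]
  dge <- sqrt(sum((g - e)^2)); dhf <- sqrt(sum((h - f)^2))
  dgf <- sqrt(sum((g - f)^2)); dhe <- sqrt(sum((h - e)^2))
  if (dge + dhf <= dgf + dhe) {
    extra <- dge + dhf
  } else {
    extra <- dgf + dhe
  }
  extra + .skeletonPathLength(sk, smooth = smooth)
}

# running mean with shrinking windows at the ends (endpoints stay fixed)
.smoothPath <- function(xy, half = 3L) {
  n <- nrow(xy)
  if (n <= 2 * half + 1) return(xy)
  out <- xy
  cs <- rbind(0, apply(xy, 2, cumsum))
  for (i in seq_len(n)) {
    k <- min(half, i - 1L, n - i)
    lo <- i - k; hi <- i + k
    out[i, ] <- (cs[hi + 1L, ] - cs[lo, ]) / (hi - lo + 1L)
  }
  out
}

# path length between the two endpoints: either the raw weighted step count
# (1 axial, sqrt(2) diagonal) or the length of the smoothed ordered path
.skeletonPathLength <- function(sk, smooth = TRUE) {
  m <- (sk@mask) + 0L
  idx <- which(m > 0)
  if (length(idx) < 2) return(0)
  W <- nrow(m)
  id <- integer(length(m)); id[idx] <- seq_along(idx)
  u <- ((idx - 1L) %% W) + 1L
  v <- ((idx - 1L) %/% W) + 1L
  edges <- NULL; wts <- NULL
  for (off in list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)), c(-1L, 1L, sqrt(2)))) {
    un <- u + off[1]; vn <- v + off[2]
    ok <- un >= 1L & un <= W & vn >= 1L & vn <= ncol(m)
    nidx <- (vn[ok] - 1L) * W + un[ok]
    keep <- m[nidx] > 0
    if (any(keep)) {
      edges <- rbind(edges, cbind(id[idx[ok]][keep], id[nidx][keep]))
      wts <- c(wts, rep(off[3], sum(keep)))
    }
  }
  g <- igraph::make_graph(as.vector(t(edges)), n = length(idx), directed = FALSE)
  ep <- sk@endpoints
  vid <- function(p) id[(p[2]) * W + p[1] + 1L]
  if (!smooth)
    return(igraph::distances(g, v = vid(ep[1, ]), to = vid(ep[2, ]),
                             weights = wts)[1, 1])
  vp <- igraph::shortest_paths(g, from = vid(ep[1, ]), to = vid(ep[2, ]),
                               weights = wts)$vpath[[1]]
  ord <- as.integer(vp)
  xy <- cbind(u[ord] - 1, v[ord] - 1)
  sm <- .smoothPath(xy)
  sum(sqrt(rowSums(diff(sm)^2)))
}

#' Straighten a bent fish
#'
#' Constructs the tail measurement point m by extending the chord e->f to
#' the midline arc length: `m = e + arc * (f - e)/|f - e|`. The head keeps
#' its own sampled depth; m is assigned the depth sampled at the original
#' tail point f (m itself may fall outside the fish, or the image). m is
#' kept at sub-pixel precision.
#'
#' @param geom result of [fishGeometry()].
#' @param sk the fish midline, a [SkeletonImage-class].
#' @param depth depth image `[x, y]`, mm.
#' @return list as [straightPoints()], plus `arcLengthPx`.
#' @export
straighten <- function(geom, sk, depth) {
  arc <- arcLength(sk, geom$e, geom$f)
  chord <- geom$f - geom$e
  clen <- sqrt(sum(chord^2))
  if (clen < 1e-9) .flStateError("head and tail candidates coincide")
  mPt <- geom$e + arc * chord / clen
  list(head = geom$e, tail = mPt,
       headDepth = .sampleDepth(depth, geom$e, geom$mask),
       tailDepth = .sampleDepth(depth, geom$f, geom$mask),
       pose = "bent", arcLengthPx = arc)
}

#' 3D body length from measurement points
#'
#' Back-projects the head and tail points at their sampled depths and
#' returns the Euclidean distance. With a [RefractionModel-class] the
#' refraction-corrected coordinates are used (the uncorrected length is
#' always reported too); with `rm = NULL` the plain pinhole back-projection
#' is used for both.
#'
#' @param points list from [straightPoints()] or [straighten()].
#' @param cam a [CameraModel-class].
#' @param rm a [RefractionModel-class] or NULL to ignore refraction.
#' @param thetaBend bend angle to record, degrees.
#' @param ... passed to [correctedBackproject()].
#' @return a [MeasurementResult-class].
#' @export
measureLength <- function(points, cam, rm = NULL, thetaBend = NA_real_, ...) {
  warnings <- character()
  headUn <- backProject(points$head, points$headDepth, cam)
  tailUn <- backProject(points$tail, points$tailDepth, cam)
  lenUn <- euclideanLength(headUn, tailUn)
  if (is.null(rm)) {
    head3d <- headUn; tail3d <- tailUn; len <- lenUn
  } else {
    head3d <- correctedBackproject(points$head, points$headDepth, cam, rm, ...)
    tail3d <- correctedBackproject(points$tail, points$tailDepth, cam, rm, ...)
    len <- euclideanLength(head3d, tail3d)
  }
  W <- cam@width; H <- cam@height
  if (points$tail[1] < 0 || points$tail[1] > W - 1 ||
      points$tail[2] < 0 || points$tail[2] > H - 1)
    warnings <- c(warnings, "tail measurement point falls outside the image")
  new("MeasurementResult",
      pose = points$pose, thetaBend = as.numeric(thetaBend),
      headPx = as.numeric(points$head), tailPx = as.numeric(points$tail),
      headDepth = as.numeric(points$headDepth),
      tailDepth = as.numeric(points$tailDepth),
      head3d = as.numeric(head3d), tail3d = as.numeric(tail3d),
      lengthMm = as.numeric(len), lengthMmUncorrected = as.numeric(lenUn),
      arcLengthPx = as.numeric(points$arcLengthPx),
      diagnostics = list(warnings = warnings))
}

#' Relative-error evaluation of length estimates
#'
#' Per measurement, `RE = (estimate - truth)/truth * 100`; the mean relative
#' percentage error is the mean of `|RE|`, overall and per group.
#'
#' @param estimates,truths equal-length numeric vectors, mm; truths > 0.
#' @param groups optional grouping labels (e.g. camera height).
#' @return list with `table` (data.frame of estimate, truth, re, group),
#'   `mrpe`, and `mrpeByGroup` (named vector, when groups are given).
#' @export
evaluateLengths <- function(estimates, truths, groups = NULL) {
  if (length(estimates) == 0 || length(estimates) != length(truths))
    .flInvalidArg("estimates and truths must be non-empty and equal length")
  if (any(truths <= 0)) .flInvalidArg("truths must be > 0")
  re <- (estimates - truths) / truths * 100
  tab <- data.frame(estimate = estimates, truth = truths, re = re)
  out <- list(table = tab, mrpe = mean(abs(re)))
  if (!is.null(groups)) {
    tab$group <- groups
    out$table <- tab
    out$mrpeByGroup <- c(tapply(abs(re), groups, mean))
  }
  out
}
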
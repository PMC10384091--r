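# Neighbour layout (0-based pixel (u, v), u right, v down), indexed clockwise
# from the top-left as P1..P8:
#   P1 P2 P3        (-1,-1) ( 0,-1) (+1,-1)
#   P8  P P4   <=>  (-1, 0)         (+1, 0)
#   P7 P6 P5        (-1,+1) ( 0,+1) (+1,+1)
# All corner-removal conditions are written against this single table so the
# layout can be rotated in one place if ever needed.
.NB_OFFSETS <- matrix(c(-1, -1,  0, -1,  1, -1,  1, 0,
                         1,  1,  0,  1, -1,  1, -1, 0),
                      ncol = 2, byrow = TRUE,
                      dimnames = list(paste0("P", 1:8), c("du", "dv")))

# value of the (du, dv)-neighbour for every pixel; zero-padded at the border
.shiftMat <- function(m, du, dv) {
  W <- nrow(m); H <- ncol(m)
  out <- matrix(0L, W, H)
  xs <- max(1, 1 + du):min(W, W + du)
  ys <- max(1, 1 + dv):min(H, H + dv)
  out[xs - du, ys - dv] <- m[xs, ys]
  out
}

# list of the 8 neighbour rasters P1..P8
.neighborRasters <- function(m) {
  lapply(seq_len(8), function(i)
    .shiftMat(m, .NB_OFFSETS[i, 1], .NB_OFFSETS[i, 2]))
}

.asBinaryMatrix <- function(mask, what = "mask") {
  if (is(mask, "SkeletonImage")) mask <- mask@mask
  if (is.null(dim(mask)) || length(dim(mask)) != 2)
    .flInvalidArg(sprintf("%s must be a 2D matrix", what))
  storage.mode(mask) <- "integer"
  (mask > 0L) + 0L
}

#' Classify a skeleton pixel from its 8-neighbourhood
#'
#' The number of foreground neighbours N determines the role of a skeleton
#' pixel: N = 0 isolated, N = 1 endpoint, N = 2 ordinary skeleton point,
#' N >= 3 node (junction).
#'
#' @param nb the 8 neighbour values P1..P8 (0/1 or logical), indexed
#'   clockwise from the top-left neighbour.
#' @return one of `"isolated"`, `"endpoint"`, `"skeleton-point"`, `"node"`.
#' @export
classifyPixel <- function(nb) {
  if (length(nb) != 8) .flInvalidArg("neighbourhood must have 8 values")
  n <- sum(nb > 0)
  if (n == 0) "isolated" else if (n == 1) "endpoint"
  else if (n == 2) "skeleton-point" else "node"
}

#' Corner-point test
#'
#' A foreground pixel is a corner (a one-pixel protrusion of the skeleton in
#' one of the four axial directions) when one of these patterns holds:
#' \itemize{
#'   \item `P2 = P8 = 1` and `P4 = P5 = P6 = 0`
#'   \item `P2 = P4 = 1` and `P6 = P7 = P8 = 0`
#'   \item `P4 = P6 = 1` and `P1 = P2 = P8 = 0`
#'   \item `P6 = P8 = 1` and `P2 = P3 = P4 = 0`
#' }
#' Removing such pixels reduces the node count of a thinned skeleton without
#' breaking connectivity.
#'
#' @inheritParams classifyPixel
#' @return logical.
#' @export
isCorner <- function(nb) {
  if (length(nb) != 8) .flInvalidArg("neighbourhood must have 8 values")
  p <- as.integer(nb > 0)
  (p[2] == 1 && p[8] == 1 && p[4] == 0 && p[5] == 0 && p[6] == 0) ||
  (p[2] == 1 && p[4] == 1 && p[6] == 0 && p[7] == 0 && p[8] == 0) ||
  (p[4] == 1 && p[6] == 1 && p[1] == 0 && p[2] == 0 && p[8] == 0) ||
  (p[6] == 1 && p[8] == 1 && p[2] == 0 && p[3] == 0 && p[4] == 0)
}

# neighbour count raster
.neighborCount <- function(m) {
  nb <- .neighborRasters(m)
  Reduce(`+`, nb)
}

# 8-connected labelling of a binary matrix; returns list(labels, n)
.label8 <- function(m) {
  idx <- which(m > 0)
  labels <- matrix(0L, nrow(m), ncol(m))
  if (length(idx) == 0) return(list(labels = labels, n = 0L))
  W <- nrow(m)
  id <- integer(length(m)); id[idx] <- seq_along(idx)
  u <- ((idx - 1L) %% W) + 1L
  v <- ((idx - 1L) %/% W) + 1L
  edges <- NULL
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    un <- u + off[1]; vn <- v + off[2]
    ok <- un >= 1L & un <= W & vn >= 1L & vn <= ncol(m)
    nidx <- (vn[ok] - 1L) * W + un[ok]
    keep <- m[nidx] > 0
    if (any(keep))
      edges <- rbind(edges, cbind(id[idx[ok]][keep], id[nidx][keep]))
  }
  g <- if (is.null(edges))
    igraph::make_empty_graph(n = length(idx), directed = FALSE)
  else
    igraph::make_graph(as.vector(t(edges)), n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  labels[idx] <- comp$membership
  list(labels = labels, n = comp$no)
}

.nComponents8 <- function(m) .label8(m)$n

#' Wrap a binary raster as a SkeletonImage
#'
#' Computes the endpoint/node classification and the connectivity flag.
#'
#' @param mask binary matrix `[x, y]` (skeleton pixels > 0).
#' @return a [SkeletonImage-class].
#' @export
skeletonImage <- function(mask) {
  m <- .asBinaryMatrix(mask, "skeleton")
  nc <- .neighborCount(m)
  eps <- which(m > 0 & nc == 1L, arr.ind = TRUE)
  nds <- which(m > 0 & nc >= 3L, arr.ind = TRUE)
  toUV <- function(w) {
    if (nrow(w) == 0) return(matrix(numeric(), 0, 2, dimnames = list(NULL, c("u", "v"))))
    cbind(u = w[, 1] - 1, v = w[, 2] - 1)
  }
  new("SkeletonImage", mask = m > 0L, endpoints = toUV(eps), nodes = toUV(nds),
      isConnected = .nComponents8(m) <= 1L)
}

#' Zhang-Suen thinning
#'
#' Standard two-subiteration parallel thinning. Each pass deletes border
#' pixels with 2..6 foreground neighbours and exactly one 0->1 transition
#' around the neighbourhood, subject to the two directional products, until
#' a fixed point is reached. Connectivity (number of 8-connected components)
#' is preserved and the result is one pixel wide.
#'
#' @param mask binary matrix (foreground > 0), or a [SkeletonImage-class].
#' @return a [SkeletonImage-class].
#' @export
zhangSuenThin <- function(mask) {
  m <- .asBinaryMatrix(mask)
  if (sum(m) == 0) .flInvalidArg("mask is empty")
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- .neighborRasters(m)
      # Zhang-Suen's P2..P9 in our layout: N, NE, E, SE, S, SW, W, NW
      zs <- nb[c(2, 3, 4, 5, 6, 7, 8, 1)]
      B <- Reduce(`+`, zs)
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in seq_len(8)) {
        j <- if (i == 8) 1L else i + 1L
        A <- A + (zs[[i]] == 0L) * (zs[[j]] == 1L)
      }
      if (sub == 1) {
        c3 <- zs[[1]] * zs[[3]] * zs[[5]]  # P2*P4*P6
        c4 <- zs[[3]] * zs[[5]] * zs[[7]]  # P4*P6*P8
      } else {
        c3 <- zs[[1]] * zs[[3]] * zs[[7]]  # P2*P4*P8
        c4 <- zs[[1]] * zs[[5]] * zs[[7]]  # P2*P6*P8
      }
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L & c3 == 0L & c4 == 0L
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  skeletonImage(m)
}

#' Remove corner points from a thinned skeleton
#'
#' Scans the raster sequentially in row-major order and deletes every pixel
#' that satisfies the corner pattern of [isCorner()], re-checking against the
#' updated raster after each deletion (simultaneous deletion could break a
#' diagonal staircase). Passes repeat until no corner remains. Connectivity
#' is preserved; the node count never increases.
#'
#' @param sk a [SkeletonImage-class] or binary matrix.
#' @return a [SkeletonImage-class].
#' @export
removeCorners <- function(sk) {
  m <- .asBinaryMatrix(sk, "skeleton")
  W <- nrow(m); H <- ncol(m)
  nbAt <- function(u, v) {
    vapply(seq_len(8), function(i) {
      uu <- u + .NB_OFFSETS[i, 1]; vv <- v + .NB_OFFSETS[i, 2]
      if (uu < 1 || uu > W || vv < 1 || vv > H) 0L else m[uu, vv]
    }, integer(1))
  }
  repeat {
    cand <- which(m == 1L, arr.ind = TRUE)
    if (nrow(cand) == 0) break
    # row-major: order by row (v), then column (u)
    cand <- cand[order(cand[, 2], cand[, 1]), , drop = FALSE]
    removed <- FALSE
    for (i in seq_len(nrow(cand))) {
      u <- cand[i, 1]; v <- cand[i, 2]
      if (m[u, v] == 1L && isCorner(nbAt(u, v))) {
        m[u, v] <- 0L
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  skeletonImage(m)
}

#' Prune burrs (spurious short branches)
#'
#' When a skeleton has more than two endpoints, the endpoint pair with the
#' largest Euclidean separation defines the main skeleton line; every branch
#' carrying one of the remaining endpoints is a burr. Each burr is eroded
#' endpoint by endpoint: the endpoint is deleted and its unique foreground
#' neighbour promoted, stopping when the promoted pixel is no longer an
#' endpoint (the branch has been consumed back to the main line), when the
#' walk becomes ambiguous, or after `maxDeletions` deletions for that branch.
#'
#' @param sk a [SkeletonImage-class] (thinned, corner-cleaned).
#' @param maxDeletions per-branch deletion budget; defaults to 15% of the
#'   skeleton pixel count.
#' @return a [SkeletonImage-class].
#' @export
pruneBurrs <- function(sk, maxDeletions = NULL) {
  if (!is(sk, "SkeletonImage")) sk <- skeletonImage(sk)
  if (!sk@isConnected) .flStateError("cannot prune a disconnected skeleton")
  m <- (sk@mask) + 0L
  if (is.null(maxDeletions)) maxDeletions <- max(1L, ceiling(0.15 * sum(m)))
  eps <- skeletonImage(m)@endpoints
  if (nrow(eps) <= 2) return(skeletonImage(m))
  dmat <- as.matrix(dist(eps))
  main <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
  keepIdx <- sort(unique(c(main[1], main[2])))
  W <- nrow(m); H <- ncol(m)
  fgNeighbors <- function(u, v) {
    out <- NULL
    for (i in seq_len(8)) {
      uu <- u + .NB_OFFSETS[i, 1]; vv <- v + .NB_OFFSETS[i, 2]
      if (uu >= 1 && uu <= W && vv >= 1 && vv <= H && m[uu, vv] == 1L)
        out <- rbind(out, c(uu, vv))
    }
    out
  }
  for (i in setdiff(seq_len(nrow(eps)), keepIdx)) {
    cur <- c(eps[i, 1] + 1, eps[i, 2] + 1)  # to 1-based
    steps <- 0L
    while (steps < maxDeletions) {
      nbs <- fgNeighbors(cur[1], cur[2])
      if (is.null(nbs) || nrow(nbs) != 1) break  # isolated or ambiguous: stop
      m[cur[1], cur[2]] <- 0L
      steps <- steps + 1L
      nxt <- nbs[1, ]
      nnb <- fgNeighbors(nxt[1], nxt[2])
      if (is.null(nnb) || nrow(nnb) != 1) break  # reached the main line/node
      cur <- nxt
    }
  }
  skeletonImage(m)
}

#' Reconnect skeleton fragments
#'
#' If pruning (or the input itself) left several 8-connected components, the
#' closest endpoint pair belonging to different components is joined by a
#' straight discrete (Bresenham) line of pixels, repeatedly, until a single
#' component remains.
#'
#' @param sk a [SkeletonImage-class] or binary matrix.
#' @return a [SkeletonImage-class].
#' @export
connectBreaks <- function(sk) {
  m <- .asBinaryMatrix(sk, "skeleton")
  repeat {
    lab <- .label8(m)
    if (lab$n <= 1L) break
    ski <- skeletonImage(m)
    eps <- ski@endpoints
    # candidate join points: endpoints, falling back to all pixels of
    # endpoint-free components (cycles)
    pts <- if (nrow(eps)) eps else NULL
    compOf <- function(p) lab$labels[p[1] + 1, p[2] + 1]
    if (!is.null(pts)) {
      comps <- apply(pts, 1, compOf)
      if (length(unique(comps)) < 2) pts <- NULL
    }
    if (is.null(pts)) {
      w <- which(m == 1L, arr.ind = TRUE)
      pts <- cbind(u = w[, 1] - 1, v = w[, 2] - 1)
      comps <- lab$labels[w]
    }
    best <- NULL; bestd <- Inf
    for (i in seq_len(nrow(pts) - 1)) for (j in seq.int(i + 1, nrow(pts))) {
      if (comps[i] == comps[j]) next
      d <- sum((pts[i, ] - pts[j, ])^2)
      if (d < bestd) { bestd <- d; best <- c(i, j) }
    }
    line <- .bresenham(pts[best[1], ], pts[best[2], ])
    m[cbind(line[, 1] + 1, line[, 2] + 1)] <- 1L
  }
  skeletonImage(m)
}

# integer line between 0-based endpoints (inclusive), n x 2
.bresenham <- function(a, b) {
  n <- max(abs(b - a)) + 1
  cbind(round(seq(a[1], b[1], length.out = n)),
        round(seq(a[2], b[2], length.out = n)))
}

#' Extract the two-endpoint midline of a fish mask
#'
#' Composition of [zhangSuenThin()], [removeCorners()] and the burr-pruning /
#' break-reconnection loop. Interior holes of the mask are filled first (a
#' fish silhouette is simply connected; holes are segmentation noise that
#' would create skeleton cycles). The result is a single 8-connected curve
#' with exactly two endpoints and no nodes.
#'
#' @param mask binary fish mask `[x, y]`.
#' @param maxDeletions per-branch deletion budget, see [pruneBurrs()].
#' @return a [SkeletonImage-class].
#' @export
extractMidline <- function(mask, maxDeletions = NULL) {
  mFull <- .asBinaryMatrix(mask)
  if (sum(mFull) == 0) .flInvalidArg("mask is empty")
  # work on the mask's bounding box (plus a guard border) for speed
  w <- which(mFull > 0, arr.ind = TRUE)
  x0 <- max(1L, min(w[, 1]) - 2L); x1 <- min(nrow(mFull), max(w[, 1]) + 2L)
  y0 <- max(1L, min(w[, 2]) - 2L); y1 <- min(ncol(mFull), max(w[, 2]) + 2L)
  m <- mFull[x0:x1, y0:y1, drop = FALSE]
  m <- .fillHoles(m)
  sk <- removeCorners(zhangSuenThin(m))
  # a round mask can thin to a single pixel; grow it into a minimal
  # two-pixel segment (inside the mask) so the endpoint contract holds
  if (sum(sk@mask) == 1) {
    w1 <- which(sk@mask, arr.ind = TRUE)[1, ]
    for (off in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      uu <- w1[1] + off[1]; vv <- w1[2] + off[2]
      if (uu >= 1 && uu <= nrow(m) && vv >= 1 && vv <= ncol(m) && m[uu, vv] > 0) {
        mm <- (sk@mask) + 0L
        mm[uu, vv] <- 1L
        sk <- skeletonImage(mm)
        break
      }
    }
  }
  for (i in 1:12) {
    if (!sk@isConnected) sk <- connectBreaks(sk)
    if (nrow(sk@endpoints) > 2) {
      before <- sum(sk@mask)
      sk <- pruneBurrs(sk, maxDeletions)
      if (sum(sk@mask) == before && sk@isConnected) break  # no progress
    }
    if (sk@isConnected && nrow(sk@endpoints) == 2 && nrow(sk@nodes) == 0) break
  }
  if (!(sk@isConnected && nrow(sk@endpoints) == 2))
    .flStateError("midline extraction did not converge to a two-endpoint curve")
  # re-embed into the full canvas
  out <- matrix(0L, nrow(mFull), ncol(mFull))
  out[x0:x1, y0:y1] <- (sk@mask) + 0L
  skeletonImage(out)
}

.fillHoles <- function(m) {
  img <- EBImage::fillHull(EBImage::Image(m))
  (as.matrix(EBImage::imageData(img)) > 0) + 0L
}
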
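.asImage3 <- function(img, what = "image") {
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (length(dim(img)) != 3 || dim(img)[3] != 3)
    .flInvalidArg(sprintf("%s must be a [width, height, 3] array", what))
  if (any(dim(img)[1:2] == 0)) .flInvalidArg(sprintf("%s is empty", what))
  img
}

#' Contrast-adaptive preprocessing for GrabCut
#'
#' Converts the RGB image to grayscale, linearly stretches the intensities
#' between the configured low/high percentiles to the full 8-bit range, adds
#' the brightness offset (with saturation at 0 and 255), and replicates the
#' single channel into all three output channels — raising the contrast
#' between fish and background before segmentation. A constant image is
#' returned unchanged apart from the brightness offset.
#'
#' @param rgb `[width, height, 3]` array, values 0..255.
#' @param cfg a [SegConfig-class].
#' @return `[width, height, 3]` array with three equal channels.
#' @export
contrastAdapt <- function(rgb, cfg = segConfig()) {
  rgb <- .asImage3(rgb, "rgb")
  gray <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  lo <- quantile(gray, cfg@stretchLowPct / 100, names = FALSE)
  hi <- quantile(gray, cfg@stretchHighPct / 100, names = FALSE)
  out <- if (hi - lo < 1e-12) gray else (gray - lo) / (hi - lo) * 255
  out <- pmin(pmax(out + cfg@brightnessOffset, 0), 255)
  array(rep(out, 3), dim = c(dim(out), 3))
}

# squared colour difference between each pixel and its (du, dv) neighbour;
# returns a matrix of the valid (cropped) region plus its index ranges
.pairDiff2 <- function(img, du, dv) {
  W <- dim(img)[1]; H <- dim(img)[2]
  xs <- max(1, 1 + du):min(W, W + du)
  ys <- max(1, 1 + dv):min(H, H + dv)
  x0 <- xs - du; y0 <- ys - dv
  d2 <- 0
  for (ch in 1:3)
    d2 <- d2 + (img[x0, y0, ch] - img[xs, ys, ch])^2
  list(d2 = d2, x0 = x0, y0 = y0, x1 = xs, y1 = ys)
}

# the four unique 8-neighbour directions (each unordered pair once)
.PAIR_DIRS <- list(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))

#' Boundary-smoothness scale beta
#'
#' `beta = 1 / (2 * <||z_m - z_n||^2>)`, the mean taken over all 8-neighbour
#' pixel pairs. For a constant image the mean vanishes and a large finite
#' guard value is returned (the smoothness penalty is then maximal for any
#' label boundary).
#'
#' @param img `[width, height, 3]` array (a grayscale matrix is replicated).
#' @return scalar beta.
#' @export
computeBeta <- function(img) {
  img <- .asImage3(img)
  if (prod(dim(img)[1:2]) < 2) .flInvalidArg("image must have at least 2 pixels")
  tot <- 0; n <- 0
  for (d in .PAIR_DIRS) {
    pd <- .pairDiff2(img, d[1], d[2])
    tot <- tot + sum(pd$d2)
    n <- n + length(pd$d2)
  }
  m <- tot / n
  if (m <= 0) 1e8 else 1 / (2 * m)
}

#' Boundary (smoothness) term of the segmentation energy
#'
#' `V = gamma * sum over 8-neighbour pairs with unequal labels of
#' exp(-beta * ||z_m - z_n||^2)`.
#'
#' @param labels binary label matrix (foreground > 0), same size as the image.
#' @param img `[width, height, 3]` array.
#' @param beta smoothness scale, see [computeBeta()].
#' @param gamma boundary weight.
#' @return scalar V >= 0.
#' @export
boundaryTerm <- function(labels, img, beta, gamma) {
  img <- .asImage3(img)
  lab <- .asBinaryMatrix(labels, "labels")
  if (!all(dim(lab) == dim(img)[1:2]))
    .flInvalidArg("labels and image dimensions differ")
  V <- 0
  for (d in .PAIR_DIRS) {
    pd <- .pairDiff2(img, d[1], d[2])
    diffLab <- lab[pd$x0, pd$y0] != lab[pd$x1, pd$y1]
    if (any(diffLab)) V <- V + sum(exp(-beta * pd$d2[diffLab]))
  }
  gamma * V
}

# ---- Gaussian mixture bookkeeping -----------------------------------------
# A fitted class model is a list with k, pi (k), mu (k x 3), and per
# component the Cholesky-based inverse and log-determinant of the (ridge
# regularised) covariance.

.GMM_RIDGE <- 0.01

.gmmFit <- function(px, assign, k) {
  comps <- vector("list", k)
  n <- nrow(px)
  pi <- numeric(k)
  mu <- matrix(0, k, 3)
  for (j in seq_len(k)) {
    sel <- assign == j
    nj <- sum(sel)
    pi[j] <- nj / n
    if (nj == 0) next  # empty component: pi = 0, never assigned
    sub <- px[sel, , drop = FALSE]
    mu[j, ] <- colMeans(sub)
    S <- if (nj > 1) crossprod(sweep(sub, 2, mu[j, ])) / nj else matrix(0, 3, 3)
    S <- S + diag(.GMM_RIDGE, 3)
    ch <- chol(S)
    comps[[j]] <- list(inv = chol2inv(ch), logdet = 2 * sum(log(diag(ch))))
  }
  list(k = k, pi = pi, mu = mu, comps = comps, fitted = TRUE)
}

# per-pixel, per-component penalty D = -log pi - log N(z; mu, S); n x k
.gmmPenalties <- function(px, model) {
  if (is.null(model$fitted)) .flStateError("GMM has not been fitted")
  n <- nrow(px)
  D <- matrix(Inf, n, model$k)
  for (j in seq_len(model$k)) {
    cj <- model$comps[[j]]
    if (is.null(cj) || model$pi[j] <= 0) next
    d <- sweep(px, 2, model$mu[j, ])
    quad <- rowSums((d %*% cj$inv) * d)
    logN <- -0.5 * (3 * log(2 * pi) + cj$logdet + quad)
    D[, j] <- -log(model$pi[j]) - logN
  }
  D
}

.gmmAssign <- function(px, model) {
  D <- .gmmPenalties(px, model)
  max.col(-D, ties.method = "first")
}

.gmmMinPenalty <- function(px, model) {
  D <- .gmmPenalties(px, model)
  do.call(pmin, lapply(seq_len(model$k), function(j) D[, j]))
}

# deterministic k-means initialisation (subsampled for speed)
.gmmInit <- function(px, k, seed) {
  k <- min(k, max(1L, nrow(unique(px))))
  centres <- .withSeed(seed, {
    sub <- if (nrow(px) > 10000) px[sample.int(nrow(px), 10000), , drop = FALSE] else px
    ku <- min(k, nrow(unique(sub)))
    if (ku == 1) matrix(colMeans(sub), 1, 3)
    else kmeans(sub, centers = ku, iter.max = 30, nstart = 1)$centers
  })
  # assign all pixels to the nearest centre (ties -> lowest index)
  d2 <- sapply(seq_len(nrow(centres)), function(j)
    rowSums(sweep(px, 2, centres[j, ])^2))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = nrow(px))
  assign <- max.col(-d2, ties.method = "first")
  .gmmFit(px, assign, nrow(centres))
}

#' Region (data) term of the segmentation energy
#'
#' `U = sum_n [-log P(z_n | class_n, k_n, theta) - log pi(class_n, k_n)]`
#' over all pixels, with each pixel scored under its class GMM and assigned
#' component.
#'
#' @param labels binary label matrix (foreground > 0).
#' @param assignments integer matrix of per-pixel component indices.
#' @param gmm list with elements `fg` and `bg`, each fitted by the internal
#'   GMM machinery of [grabCut()].
#' @param img `[width, height, 3]` array.
#' @return scalar U.
#' @export
dataTerm <- function(labels, assignments, gmm, img) {
  img <- .asImage3(img)
  lab <- .asBinaryMatrix(labels, "labels")
  if (is.null(gmm$fg$fitted) || is.null(gmm$bg$fitted))
    .flStateError("GMM has not been fitted")
  px <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  fg <- as.vector(lab > 0)
  kv <- as.vector(assignments)
  U <- 0
  for (cls in c("fg", "bg")) {
    sel <- if (cls == "fg") fg else !fg
    if (!any(sel)) next
    D <- .gmmPenalties(px[sel, , drop = FALSE], gmm[[cls]])
    U <- U + sum(D[cbind(seq_len(sum(sel)), kv[sel])])
  }
  U
}

#' GrabCut segmentation
#'
#' Iterative GMM/graph-cut minimisation of the Gibbs energy `E = U + V`.
#' Pixels outside the rectangle are clamped to background; inside they start
#' as probable foreground. Each iteration (i) assigns every pixel to its
#' best mixture component, (ii) refits the two GMMs, (iii) solves an exact
#' min-cut on the 8-connected pixel graph with the data and boundary
#' capacities, and (iv) relabels the rectangle pixels from the cut. The
#' per-iteration energy is recorded and is non-increasing.
#'
#' @param img `[width, height, 3]` array (typically from [contrastAdapt()]).
#' @param roi rectangle `c(x, y, w, h)`, 0-based, half-open, strictly
#'   smaller than the image.
#' @param cfg a [SegConfig-class].
#' @param trackEnergy record the whole-image Gibbs energy after every
#'   iteration (exact but costly on large images).
#' @param bgSampleMax background pixels beyond this count are subsampled
#'   (deterministically) for GMM fitting.
#' @return list with `mask` (binary matrix, fish = 1), `energy` (data.frame
#'   with columns iteration, U, V, E; empty when `trackEnergy = FALSE`),
#'   `beta`, and `collapsed` (TRUE when the rectangle converged to
#'   all-foreground or all-background).
#' @export
grabCut <- function(img, roi, cfg = segConfig(), trackEnergy = TRUE,
                    bgSampleMax = 40000L) {
  img <- .asImage3(img)
  W <- dim(img)[1]; H <- dim(img)[2]
  roi <- as.numeric(roi)
  if (length(roi) != 4 || any(!is.finite(roi))) .flInvalidArg("roi must be c(x, y, w, h)")
  x0 <- roi[1]; y0 <- roi[2]; w <- roi[3]; h <- roi[4]
  if (w <= 0 || h <= 0 || x0 < 0 || y0 < 0 || x0 + w > W || y0 + h > H ||
      (w * h) >= (W * H))
    .flInvalidArg("roi must have positive area and lie strictly inside the image")

  px <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  npix <- W * H
  inRoi <- logical(npix)
  roiCols <- (x0 + 1):(x0 + w); roiRows <- (y0 + 1):(y0 + h)
  inRoiMat <- matrix(FALSE, W, H); inRoiMat[roiCols, roiRows] <- TRUE
  inRoi <- as.vector(inRoiMat)
  roiIdx <- which(inRoi)
  nROI <- length(roiIdx)

  beta <- computeBeta(img)
  gamma <- cfg@gamma

  # precompute n-link structure: pairs (a, b) by linear index + weights
  nlA <- integer(0); nlB <- integer(0); nlW <- numeric(0)
  for (d in .PAIR_DIRS) {
    pd <- .pairDiff2(img, d[1], d[2])
    a <- as.vector(outer(pd$x0, (pd$y0 - 1) * W, `+`))
    b <- as.vector(outer(pd$x1, (pd$y1 - 1) * W, `+`))
    nlA <- c(nlA, a); nlB <- c(nlB, b)
    nlW <- c(nlW, gamma * exp(-beta * as.vector(pd$d2)))
  }
  bothIn <- inRoi[nlA] & inRoi[nlB]
  crossA <- nlA[xor(inRoi[nlA], inRoi[nlB])]
  crossB <- nlB[xor(inRoi[nlA], inRoi[nlB])]
  crossW <- nlW[xor(inRoi[nlA], inRoi[nlB])]
  # boundary load: for a ROI pixel, smoothness paid if it turns foreground
  # while its clamped background neighbour stays background
  vertOf <- integer(npix); vertOf[roiIdx] <- seq_len(nROI)
  bLoad <- numeric(nROI)
  cin <- ifelse(inRoi[crossA], crossA, crossB)
  if (length(cin)) {
    agg <- tapply(crossW, vertOf[cin], sum)
    bLoad[as.integer(names(agg))] <- agg
  }
  inA <- vertOf[nlA[bothIn]]; inB <- vertOf[nlB[bothIn]]; inW <- nlW[bothIn]

  # initial trimap: outside = sure background, inside = probable foreground
  fgLab <- inRoi
  # background pixels used for GMM fitting (deterministic subsample)
  bgPool <- which(!inRoi)
  if (length(bgPool) > bgSampleMax)
    bgPool <- sort(.withSeed(cfg@seed + 2L, sample(bgPool, bgSampleMax)))
  bgFit <- function(lab) {
    sel <- bgPool[!lab[bgPool]]
    extra <- which(!lab & inRoi)  # rectangle pixels currently background
    if (length(extra) > bgSampleMax)
      extra <- sort(.withSeed(cfg@seed + 3L, sample(extra, bgSampleMax)))
    c(sel, extra)
  }
  gmm <- list(fg = .gmmInit(px[fgLab, , drop = FALSE], cfg@gmmComponents, cfg@seed),
              bg = .gmmInit(px[bgFit(fgLab), , drop = FALSE], cfg@gmmComponents,
                            cfg@seed + 1L))

  energy <- data.frame(iteration = integer(), U = numeric(), V = numeric(),
                       E = numeric())
  collapsed <- FALSE
  for (it in seq_len(cfg@nIterations)) {
    # (i) component assignment + (ii) refit, from the current labels
    # (a collapsed class keeps its previous parameters)
    if (any(fgLab)) {
      aFg <- .gmmAssign(px[fgLab, , drop = FALSE], gmm$fg)
      gmm$fg <- .gmmFit(px[fgLab, , drop = FALSE], aFg, gmm$fg$k)
    }
    bgSel <- bgFit(fgLab)
    aBg <- .gmmAssign(px[bgSel, , drop = FALSE], gmm$bg)
    gmm$bg <- .gmmFit(px[bgSel, , drop = FALSE], aBg, gmm$bg$k)

    # (iii) min-cut over the rectangle pixels
    Dfg <- .gmmMinPenalty(px[roiIdx, , drop = FALSE], gmm$fg)
    Dbg <- .gmmMinPenalty(px[roiIdx, , drop = FALSE], gmm$bg)
    base <- pmin(Dfg, Dbg)  # common shift keeps capacities non-negative
    capSrc <- Dbg - base          # cut when pixel ends background
    capSnk <- Dfg - base + bLoad  # cut when pixel ends foreground
    mf <- .gridMaxflowCpp(nROI, cbind(inA, inB), inW, capSrc, capSnk)
    newFg <- logical(npix)
    newFg[roiIdx[mf$source_side]] <- TRUE
    fgLab <- newFg

    # (iv) energy bookkeeping on the whole image
    if (trackEnergy) {
      assignAll <- integer(npix)
      if (any(fgLab)) assignAll[fgLab] <- .gmmAssign(px[fgLab, , drop = FALSE], gmm$fg)
      assignAll[!fgLab] <- .gmmAssign(px[!fgLab, , drop = FALSE], gmm$bg)
      labMat <- matrix(as.integer(fgLab), W, H)
      U <- dataTerm(labMat, matrix(assignAll, W, H), gmm, img)
      V <- boundaryTerm(labMat, img, beta, gamma)
      energy <- rbind(energy, data.frame(iteration = it, U = U, V = V, E = U + V))
    }
    if (!any(fgLab) || all(fgLab[roiIdx])) collapsed <- TRUE
  }
  list(mask = matrix(as.integer(fgLab), W, H), energy = energy, beta = beta,
       collapsed = collapsed)
}

#' Segment a fish inside a user rectangle
#'
#' Pipeline entry point: contrast adaptation ([contrastAdapt()]) followed by
#' [grabCut()]. Can simply be re-run with a new rectangle when the result is
#' unsatisfactory.
#'
#' @inheritParams grabCut
#' @param rgb raw `[width, height, 3]` RGB array, 0..255.
#' @return binary mask matrix (fish = 1).
#' @export
segmentFish <- function(rgb, roi, cfg = segConfig()) {
  adapted <- contrastAdapt(rgb, cfg)
  grabCut(adapted, roi, cfg, trackEnergy = FALSE)$mask
}
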
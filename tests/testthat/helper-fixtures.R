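# Shared fixtures, built in code.

hCam <- function(fx = 600, width = 640L, height = 480L, baseline = 50)
  cameraModel(fx = fx, baseline = baseline, width = width, height = height)

hRm <- function(h = 250, nWater = 1.333) refractionModel(cameraHeight = h, nWater = nWater)

# dark ellipse (a fish-like blob) on a light background, [W, H, 3]
hEllipseImage <- function(W = 120L, H = 90L, fg = 60, bg = 200,
                          a = 40, b = 15, noise = 2, seed = 42) {
  u <- matrix(0:(W - 1), W, H); v <- matrix(0:(H - 1), W, H, byrow = TRUE)
  inside <- ((u - (W - 1) / 2) / a)^2 + ((v - (H - 1) / 2) / b)^2 <= 1
  g <- matrix(bg, W, H); g[inside] <- fg
  set.seed(seed)
  g <- pmin(pmax(g + matrix(rnorm(W * H, 0, noise), W, H), 0), 255)
  list(img = array(rep(g, 3), dim = c(W, H, 3)), mask = inside + 0L,
       roi = c(round((W - 1) / 2 - a - 8), round((H - 1) / 2 - b - 8),
               2 * a + 16, 2 * b + 16))
}

# fish on a bright bottom with a darker shadow patch inside the rectangle:
# the shadow leaks into the raw GrabCut foreground; brightening until the
# background saturates merges the shadow with the bottom
hShadowImage <- function(seed = 36) {
  W <- 120L; H <- 90L
  u <- matrix(0:(W - 1), W, H); v <- matrix(0:(H - 1), W, H, byrow = TRUE)
  inside <- ((u - 59.5) / 40)^2 + ((v - 44.5) / 15)^2 <= 1
  g <- matrix(220, W, H)
  shadow <- ((u - 85)^2 / 600 + (v - 40)^2 / 250) <= 1
  g[shadow] <- 110
  g[inside] <- 95
  set.seed(seed)
  g <- pmin(pmax(g + matrix(rnorm(W * H, 0, 3), W, H), 0), 255)
  list(img = array(rep(g, 3), dim = c(W, H, 3)), mask = inside + 0L,
       roi = c(12, 22, 96, 46), cfg = segConfig(brightnessOffset = 215))
}

# random filled blob: union of overlapping discs, holes filled
hRandomBlob <- function(seed, W = 80L, H = 80L, ndisc = 6) {
  set.seed(seed)
  u <- matrix(0:(W - 1), W, H); v <- matrix(0:(H - 1), W, H, byrow = TRUE)
  m <- matrix(FALSE, W, H)
  cx <- runif(1, 0.35 * W, 0.65 * W); cy <- runif(1, 0.35 * H, 0.65 * H)
  for (i in seq_len(ndisc)) {
    r <- runif(1, 4, 12)
    m <- m | ((u - cx)^2 + (v - cy)^2 <= r^2)
    ang <- runif(1, 0, 2 * pi); stp <- runif(1, 3, 9)
    cx <- min(max(cx + stp * cos(ang), 14), W - 14)
    cy <- min(max(cy + stp * sin(ang), 14), H - 14)
  }
  m <- EBImage::fillHull(EBImage::Image(m + 0))
  (as.matrix(EBImage::imageData(m)) > 0) + 0L
}

hIoU <- function(a, b) sum(a > 0 & b > 0) / sum(a > 0 | b > 0)

# plain-R reference Zhang-Suen thinning (independent per-pixel oracle)
hRefZhangSuen <- function(m) {
  m <- (m > 0) + 0L
  W <- nrow(m); H <- ncol(m)
  at <- function(x, y) if (x < 1 || x > W || y < 1 || y > H) 0L else m[x, y]
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      del <- NULL
      for (x in 1:W) for (y in 1:H) {
        if (m[x, y] == 0L) next
        p <- c(at(x, y - 1), at(x + 1, y - 1), at(x + 1, y), at(x + 1, y + 1),
               at(x, y + 1), at(x - 1, y + 1), at(x - 1, y), at(x - 1, y - 1))
        B <- sum(p)
        if (B < 2 || B > 6) next
        A <- sum(p == 0 & c(p[-1], p[1]) == 1)
        if (A != 1) next
        if (sub == 1) { if (p[1] * p[3] * p[5] != 0 || p[3] * p[5] * p[7] != 0) next }
        else { if (p[1] * p[3] * p[7] != 0 || p[1] * p[5] * p[7] != 0) next }
        del <- rbind(del, c(x, y))
      }
      if (!is.null(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}
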
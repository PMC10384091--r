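test_that("contrast adaptation stretches between the configured percentiles", {
  cfg <- segConfig(stretchLowPct = 0, stretchHighPct = 100)
  # constant image: degenerate stretch is the identity
  const <- array(77, dim = c(8, 6, 3))
  expect_equal(contrastAdapt(const, cfg), const)
  # two-level image maps to the full 8-bit range
  g <- matrix(50, 10, 10); g[1:5, ] <- 200
  out <- contrastAdapt(array(rep(g, 3), dim = c(10, 10, 3)), cfg)
  expect_setequal(unique(as.vector(out[, , 1])), c(0, 255))
  # all three channels equal on random colour images
  set.seed(31)
  img <- array(runif(12 * 9 * 3, 0, 255), dim = c(12, 9, 3))
  out <- contrastAdapt(img, segConfig())
  expect_equal(out[, , 1], out[, , 2])
  expect_equal(out[, , 1], out[, , 3])
  # brightness offset saturates
  out2 <- contrastAdapt(const, segConfig(brightnessOffset = 250))
  expect_true(all(out2 == 255))
})

test_that("beta follows the mean squared neighbour difference", {
  # brute-force oracle: loop over every pixel's 8 neighbours
  set.seed(30)
  W <- 7; H <- 6
  img <- array(runif(W * H * 3, 0, 255), dim = c(W, H, 3))
  tot <- 0; npair <- 0
  for (x in 1:W) for (y in 1:H) for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    xx <- x + dx; yy <- y + dy
    if (xx < 1 || xx > W || yy < 1 || yy > H) next
    tot <- tot + sum((img[x, y, ] - img[xx, yy, ])^2)
    npair <- npair + 1
  }
  # each unordered pair counted twice above
  expect_equal(computeBeta(img), 1 / (2 * tot / npair))
  # doubling the contrast quarters beta
  set.seed(32)
  g1 <- matrix(runif(100, 0, 100), 10, 10)
  b1 <- computeBeta(array(rep(g1, 3), dim = c(10, 10, 3)))
  b2 <- computeBeta(array(rep(2 * g1, 3), dim = c(10, 10, 3)))
  expect_equal(b2, b1 / 4)
  # constant image: guarded large finite value
  bg <- computeBeta(array(5, dim = c(6, 6, 3)))
  expect_true(is.finite(bg) && bg > 1e6)
})

test_that("boundary term counts label boundaries with contrast weights", {
  img <- array(10, dim = c(7, 7, 3))
  beta <- computeBeta(img); gamma <- 50
  lab0 <- matrix(0L, 7, 7)
  expect_equal(boundaryTerm(lab0, img, beta, gamma), 0)
  # single interior foreground pixel in a constant image: 8 cut pairs at
  # full weight exp(0) = 1
  lab1 <- lab0; lab1[4, 4] <- 1L
  expect_equal(boundaryTerm(lab1, img, beta, gamma), gamma * 8)
  expect_error(boundaryTerm(matrix(0L, 3, 3), img, beta, gamma),
               class = "fishlen_invalid_argument")
  set.seed(33)
  labr <- matrix(rbinom(49, 1, 0.5), 7, 7)
  expect_gte(boundaryTerm(labr, img, beta, gamma), 0)
})

test_that("data term matches the closed-form Gaussian penalty", {
  # single unit-covariance component centred on the pixel value
  mu <- c(100, 120, 140)
  model <- list(k = 1L, pi = 1, mu = matrix(mu, 1, 3),
                comps = list(list(inv = diag(3), logdet = 0)), fitted = TRUE)
  gmm <- list(fg = model, bg = model)
  img <- array(rep(mu, each = 1), dim = c(1, 1, 3))
  U <- dataTerm(matrix(1L, 1, 1), matrix(1L, 1, 1), gmm, img)
  expect_equal(U, 1.5 * log(2 * pi))
  # moving the pixel away from the mean increases the penalty
  img2 <- array(mu + c(3, 0, 0), dim = c(1, 1, 3))
  expect_gt(dataTerm(matrix(1L, 1, 1), matrix(1L, 1, 1), gmm, img2), U)
  expect_error(dataTerm(matrix(1L, 1, 1), matrix(1L, 1, 1),
                        list(fg = list(), bg = list()), img),
               class = "fishlen_state_error")
})

test_that("data term equals brute-force per-pixel summation", {
  set.seed(34)
  img <- array(runif(5 * 5 * 3, 0, 255), dim = c(5, 5, 3))
  px <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  lab <- matrix(rbinom(25, 1, 0.4), 5, 5)
  fg <- fishlen:::.gmmFit(px[lab > 0, , drop = FALSE],
                          rep_len(1:2, sum(lab > 0)), 2L)
  bg <- fishlen:::.gmmFit(px[lab == 0, , drop = FALSE],
                          rep_len(1:2, sum(lab == 0)), 2L)
  gmm <- list(fg = fg, bg = bg)
  assignAll <- matrix(rep_len(1:2, 25), 5, 5)
  U <- dataTerm(lab, assignAll, gmm, img)
  # naive double loop
  Uref <- 0
  for (i in 1:5) for (j in 1:5) {
    m <- if (lab[i, j] > 0) fg else bg
    kk <- assignAll[i, j]
    z <- img[i, j, ]
    d <- z - m$mu[kk, ]
    logN <- -0.5 * (3 * log(2 * pi) + m$comps[[kk]]$logdet +
                      drop(t(d) %*% m$comps[[kk]]$inv %*% d))
    Uref <- Uref - log(m$pi[kk]) - logN
  }
  expect_equal(U, Uref)
})

test_that("GrabCut segments a high-contrast blob inside the rectangle", {
  fx <- hEllipseImage()
  res <- grabCut(fx$img, fx$roi, segConfig())
  expect_gte(hIoU(res$mask, fx$mask), 0.95)
  # pixels outside the rectangle stay background
  out <- res$mask
  out[(fx$roi[1] + 1):(fx$roi[1] + fx$roi[3]),
      (fx$roi[2] + 1):(fx$roi[2] + fx$roi[4])] <- 0L
  expect_equal(sum(out), 0)
  # Gibbs energy is non-increasing across iterations
  E <- res$energy$E
  expect_true(all(diff(E) <= 1e-6 * abs(E[-length(E)])))
})

test_that("a rectangle over pure background yields (near-)empty foreground", {
  fx <- hEllipseImage()
  res <- grabCut(fx$img, c(2, 2, 30, 20), segConfig())
  expect_lte(sum(res$mask), 0.02 * 30 * 20)
  expect_true(res$collapsed)
})

test_that("GrabCut rejects degenerate rectangles", {
  fx <- hEllipseImage()
  expect_error(grabCut(fx$img, c(-5, 0, 30, 30), segConfig()),
               class = "fishlen_invalid_argument")
  expect_error(grabCut(fx$img, c(0, 0, 0, 10), segConfig()),
               class = "fishlen_invalid_argument")
  expect_error(grabCut(fx$img, c(0, 0, 120, 90), segConfig()),
               class = "fishlen_invalid_argument")
})

test_that("GrabCut is deterministic under a fixed seed", {
  fx <- hEllipseImage()
  m1 <- segmentFish(fx$img, fx$roi, segConfig(seed = 7))
  m2 <- segmentFish(fx$img, fx$roi, segConfig(seed = 7))
  expect_identical(m1, m2)
})

test_that("GMM refits keep weights normalised and covariances usable", {
  set.seed(35)
  px <- matrix(runif(600, 0, 255), 200, 3)
  model <- fishlen:::.gmmInit(px, 5L, 1L)
  for (i in 1:3) {
    a <- fishlen:::.gmmAssign(px, model)
    model <- fishlen:::.gmmFit(px, a, model$k)
    expect_equal(sum(model$pi), 1)
    for (j in seq_len(model$k)) {
      if (model$pi[j] > 0) {
        ev <- eigen(solve(model$comps[[j]]$inv), symmetric = TRUE,
                    only.values = TRUE)$values
        expect_true(all(ev > 0))
      }
    }
  }
})

test_that("contrast adaptation rescues a fish shadowed by uneven lighting", {
  # raw GrabCut leaks the shadow patch into the foreground; brightness
  # saturation merges the shadow with the bottom before segmentation
  sh <- hShadowImage()
  rawIoU <- hIoU(grabCut(sh$img, sh$roi, sh$cfg, trackEnergy = FALSE)$mask,
                 sh$mask)
  adIoU <- hIoU(segmentFish(sh$img, sh$roi, sh$cfg), sh$mask)
  expect_gt(adIoU, rawIoU)
  expect_gte(adIoU, 0.95)
  # and it must not hurt the easy case
  hi <- hEllipseImage()
  expect_gte(hIoU(segmentFish(hi$img, hi$roi, segConfig()), hi$mask), 0.95)
})

test_that("the rectangle selects one fish among several", {
  # two blobs; the rectangle around the left one must return only it
  W <- 160L; H <- 80L
  u <- matrix(0:(W - 1), W, H); v <- matrix(0:(H - 1), W, H, byrow = TRUE)
  left <- ((u - 40) / 25)^2 + ((v - 40) / 10)^2 <= 1
  right <- ((u - 120) / 25)^2 + ((v - 40) / 10)^2 <= 1
  g <- matrix(200, W, H); g[left | right] <- 60
  set.seed(37)
  g <- g + matrix(rnorm(W * H, 0, 2), W, H)
  img <- array(rep(g, 3), dim = c(W, H, 3))
  mask <- segmentFish(img, c(8, 22, 64, 40), segConfig())
  expect_gte(hIoU(mask, left + 0L), 0.9)
  expect_equal(sum(mask & right), 0)
})
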
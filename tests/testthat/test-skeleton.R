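test_that("pixel classification follows the neighbour count", {
  nb <- rep(0, 8)
  expect_equal(classifyPixel(nb), "isolated")
  nb4 <- nb; nb4[4] <- 1
  expect_equal(classifyPixel(nb4), "endpoint")
  nb26 <- nb; nb26[c(2, 6)] <- 1
  expect_equal(classifyPixel(nb26), "skeleton-point")
  nb246 <- nb; nb246[c(2, 4, 6)] <- 1
  expect_equal(classifyPixel(nb246), "node")
})

test_that("corner patterns are recognised exactly", {
  nb <- rep(0, 8)
  c1 <- nb; c1[c(2, 8)] <- 1
  expect_true(isCorner(c1))             # P2 = P8 = 1, P4 = P5 = P6 = 0
  c1bad <- c1; c1bad[5] <- 1
  expect_false(isCorner(c1bad))         # P5 = 1 violates the condition
  expect_false(isCorner(nb))
  c2 <- nb; c2[c(2, 4)] <- 1
  expect_true(isCorner(c2))
  c3 <- nb; c3[c(4, 6)] <- 1
  expect_true(isCorner(c3))
  c4 <- nb; c4[c(6, 8)] <- 1
  expect_true(isCorner(c4))
})

test_that("thinning leaves thin lines alone and thins solid shapes", {
  m <- matrix(0L, 50, 9); m[5:45, 5] <- 1L
  sk <- zhangSuenThin(m)
  expect_equal(skeletonMask(sk) + 0L, m)
  # 5 x 40 solid rectangle: a single thin line along the long axis
  r <- matrix(0L, 46, 11); r[4:43, 4:8] <- 1L
  skr <- zhangSuenThin(r)
  expect_equal(nrow(skeletonEndpoints(skr)), 2)
  expect_equal(nrow(skeletonNodes(skr)), 0)
  ys <- which(skeletonMask(skr), arr.ind = TRUE)[, 2]
  expect_lte(diff(range(ys)), 2)  # stays near the long axis
  expect_error(zhangSuenThin(matrix(0L, 5, 5)), class = "fishlen_invalid_argument")
})

test_that("thinning matches an independent per-pixel reference", {
  for (s in 1:6) {
    m <- hRandomBlob(400 + s, W = 28L, H = 28L, ndisc = 3)
    expect_identical(skeletonMask(zhangSuenThin(m)) + 0L, hRefZhangSuen(m),
                     info = paste("blob seed", 400 + s))
  }
})

test_that("thinning preserves the component count and is idempotent", {
  for (s in 1:15) {
    m <- hRandomBlob(500 + s)
    if (s %% 3 == 0) m <- m | hRandomBlob(900 + s)  # sometimes several blobs
    m <- (m > 0) + 0L
    sk <- zhangSuenThin(m)
    expect_equal(fishlen:::.nComponents8(skeletonMask(sk) + 0L),
                 fishlen:::.nComponents8(m))
    again <- zhangSuenThin(skeletonMask(sk))
    expect_identical(skeletonMask(again), skeletonMask(sk))
    expect_lte(sum(skeletonMask(sk)), sum(m))
  }
})

test_that("corner removal deletes staircase corners but keeps connectivity", {
  # an L-step: pixel at the corner matches the first pattern
  m <- matrix(0L, 7, 7)
  m[3, 2:4] <- 1L   # vertical part (u = 2)
  m[4:5, 4] <- 1L   # horizontal part
  skc <- removeCorners(m)
  expect_lt(sum(skeletonMask(skc)), sum(m))
  expect_true(skc@isConnected)
  # straight line untouched
  line <- matrix(0L, 20, 5); line[3:18, 3] <- 1L
  expect_equal(skeletonMask(removeCorners(line)) + 0L, line)
})

test_that("corner removal never increases nodes or changes components", {
  for (s in 1:15) {
    m <- hRandomBlob(600 + s)
    sk <- zhangSuenThin(m)
    cleaned <- removeCorners(sk)
    expect_equal(fishlen:::.nComponents8(skeletonMask(cleaned) + 0L),
                 fishlen:::.nComponents8(skeletonMask(sk) + 0L))
    expect_lte(nrow(skeletonNodes(cleaned)), nrow(skeletonNodes(sk)))
  }
})

test_that("burr pruning keeps the farthest endpoint pair", {
  # crossbar with a short stem: T shape
  m <- matrix(0L, 50, 20)
  m[3:43, 10] <- 1L          # 41-px crossbar
  m[23, 4:9] <- 1L           # 6-px stem
  pruned <- pruneBurrs(skeletonImage(m))
  ep <- skeletonEndpoints(pruned)
  expect_equal(nrow(ep), 2)
  expect_setequal(ep[, 1], c(2, 42))   # crossbar endpoints survive (0-based)
  # stem eroded back to the bar (the last stem pixel, diagonally supported
  # by the bar, is kept by the conservative ambiguity stop)
  expect_lte(sum(skeletonMask(pruned)[, 1:9]), 1)
  # straight line: identity
  line <- matrix(0L, 30, 7); line[4:26, 4] <- 1L
  expect_identical(skeletonMask(pruneBurrs(skeletonImage(line))),
                   skeletonMask(skeletonImage(line)))
  # max-distance pair selection on a constructed 3-endpoint skeleton
  y <- matrix(0L, 110, 20)
  y[3:103, 3] <- 1L
  y[53, 4:13] <- 1L
  keep <- skeletonEndpoints(pruneBurrs(skeletonImage(y)))
  expect_setequal(keep[, 2], c(2, 2))
  expect_setequal(keep[, 1], c(2, 102))
  expect_error(pruneBurrs(skeletonImage(diag(10)[, ] * 0 + {
    z <- matrix(0L, 10, 10); z[2, 2] <- 1L; z[8, 8] <- 1L; z
  })), class = "fishlen_state_error")
})

test_that("break reconnection merges fragments into one two-endpoint curve", {
  m <- matrix(0L, 40, 7)
  m[3:15, 4] <- 1L; m[19:36, 4] <- 1L  # collinear with a 3-px gap
  joined <- connectBreaks(skeletonImage(m))
  expect_true(joined@isConnected)
  expect_equal(nrow(skeletonEndpoints(joined)), 2)
  # identity on a single component
  one <- matrix(0L, 20, 5); one[3:17, 3] <- 1L
  expect_identical(skeletonMask(connectBreaks(skeletonImage(one))),
                   skeletonMask(skeletonImage(one)))
})

test_that("midline extraction fulfils the two-endpoint contract", {
  # parametric bent fish: endpoints land near the true spine tips
  fs <- fishSpec(lengthMm = 300, curvature = 0.4 * pi / 300, depthMm = 350)
  fm <- makeFishMask(fs, scale = 1)
  sk <- extractMidline(fm$mask)
  expect_true(sk@isConnected)
  expect_equal(nrow(skeletonEndpoints(sk)), 2)
  expect_equal(nrow(skeletonNodes(sk)), 0)
  tips <- fm$spine[c(1, nrow(fm$spine)), ]
  ep <- skeletonEndpoints(sk)
  dists <- c(min(sqrt(rowSums(sweep(tips, 2, ep[1, ])^2))),
             min(sqrt(rowSums(sweep(tips, 2, ep[2, ])^2))))
  # thinning stops where the body is still about half a tip-width wide
  expect_lt(max(dists), 12)
  # ellipse: midline approximates the major axis
  W <- 90L; H <- 50L
  u <- matrix(0:(W - 1), W, H); v <- matrix(0:(H - 1), W, H, byrow = TRUE)
  ell <- (((u - 44.5) / 35)^2 + ((v - 24.5) / 12)^2 <= 1) + 0L
  ske <- extractMidline(ell)
  pts <- which(skeletonMask(ske), arr.ind = TRUE)
  expect_lte(diff(range(pts[, 2])), 4)          # stays near v = 24.5
  expect_gte(diff(range(pts[, 1])), 40)         # spans the major axis
  # idempotence on an already extracted midline
  again <- extractMidline(skeletonMask(ske) + 0L)
  expect_identical(skeletonMask(again), skeletonMask(ske))
})
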
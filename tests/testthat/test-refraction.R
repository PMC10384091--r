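test_that("air-side sine follows the normalised plane geometry", {
  expect_equal(sinAlpha(c(0, 0)), 0)
  expect_equal(sinAlpha(c(1, 0)), 1 / sqrt(2))
  # monotone in radial distance
  r <- seq(0, 3, by = 0.1)
  s <- sinAlpha(cbind(r, 0))
  expect_true(all(diff(s) > 0))
  expect_true(all(s >= 0 & s < 1))
})

test_that("Snell's law relates the two sines", {
  rm1 <- hRm()
  expect_equal(snellSinBeta(0, rm1), 0)
  expect_equal(snellSinBeta(0.5, rm1), 0.5 / 1.333)
  expect_equal(snellSinBeta(0.5, hRm(nWater = 1)), 0.5)
  expect_error(snellSinBeta(1.2, rm1), class = "fishlen_invalid_argument")
})

test_that("K factor matches its analytic limits", {
  rm1 <- hRm(250)
  # no interface, or point at the surface: K = 1 exactly
  expect_identical(kFactor(c(0.3, -0.2), 600, hRm(250, nWater = 1)), 1)
  expect_equal(kFactor(c(0.3, -0.2), 250, rm1), 1)
  # on-axis analytic limit, checked against the formula just off axis
  K0 <- kFactor(c(0, 0), 500, rm1)
  expect_equal(K0, 0.5 + 0.5 / 1.333, tolerance = 1e-12)
  expect_equal(kFactor(c(1e-6, 0), 500, rm1), K0, tolerance = 1e-9)
  # K is non-increasing in n_water
  ks <- vapply(c(1, 1.1, 1.2, 1.333, 1.5),
               function(nw) kFactor(c(0.2, 0.1), 500, hRm(250, nWater = nw)),
               numeric(1))
  expect_true(all(diff(ks) < 1e-12))
  expect_error(kFactor(c(0, 0), 200, rm1), class = "fishlen_refraction_error")
})

test_that("depth correction divides by K and never shrinks the depth", {
  expect_equal(correctDepth(500, 1), 500)
  expect_equal(correctDepth(500, 0.5 + 0.5 / 1.333), 571.3673, tolerance = 1e-4)
  expect_error(correctDepth(500, 0), class = "fishlen_invalid_argument")
  set.seed(21)
  K <- runif(50, 0.6, 1); Z <- runif(50, 300, 900)
  expect_true(all(correctDepth(Z, K) >= Z))
})

test_that("corrected back-projection reduces exactly without an interface", {
  cam <- hCam()
  rmn <- hRm(250, nWater = 1)
  set.seed(22)
  p <- cbind(runif(25, 0, 639), runif(25, 0, 479))
  Z <- runif(25, 300, 900)
  expect_identical(correctedBackproject(p, Z, cam, rmn),
                   backProject(p, Z, cam))
})

test_that("corrected depth at the principal point matches the closed forms", {
  cam <- hCam(); rm1 <- hRm(250)
  pp <- principalPoint(cam)
  # single application of the scale factor
  sp <- correctedBackproject(pp, 500, cam, rm1, iterations = 1L)
  expect_equal(sp, c(0, 0, 500 / (0.5 + 0.5 / 1.333)), tolerance = 1e-6)
  # converged fixed point: on-axis the water path is stretched by n_w/n_a
  it <- correctedBackproject(pp, 500, cam, rm1)
  expect_equal(it, c(0, 0, 250 + 250 * 1.333), tolerance = 1e-6)
})

test_that("single-application correction shrinks a submerged segment's span", {
  # the refracted image is magnified, so scaling pixels by Kw < 1 must give
  # a lateral span below the uncorrected (apparent) one
  cam <- hCam(); rm1 <- hRm(250)
  a <- c(200, 240); b <- c(500, 240)
  A <- correctedBackproject(a, 600, cam, rm1, iterations = 1L)
  B <- correctedBackproject(b, 600, cam, rm1, iterations = 1L)
  Au <- backProject(a, 600, cam); Bu <- backProject(b, 600, cam)
  expect_lt(abs(A[1] - B[1]), abs(Au[1] - Bu[1]))
})

test_that("corrected depth is never below the measured depth", {
  cam <- hCam(); rm1 <- hRm(350)
  set.seed(23)
  p <- cbind(runif(100, 0, 639), runif(100, 0, 479))
  Z <- runif(100, 360, 900)
  for (iters in c(1L, 20L)) {
    out <- correctedBackproject(p, Z, cam, rm1, iterations = iters)
    expect_true(all(out[, 3] >= Z - 1e-9))
  }
})

test_that("near-axis ray-traced points are recovered by the correction", {
  cam <- hCam()
  set.seed(24)
  n <- 120
  hs <- rep(c(250, 350, 450), length.out = n)
  ang <- runif(n, 0, 12) * pi / 180
  azim <- runif(n, 0, 2 * pi)
  d <- runif(n, 60, 500)
  for (h in unique(hs)) {
    sel <- hs == h
    rm1 <- hRm(h)
    Z <- h + d[sel]
    # choose the radial offset that lands the ray at the target angle
    R <- vapply(which(sel), function(i) {
      f <- function(R) {
        q <- pixelToPlane(refractProject(c(R, 0, h + d[i]), cam, rm1), cam)
        atan(sqrt(sum(q^2))) - ang[i]
      }
      stats::uniroot(f, c(1e-9, 1.2 * (h + d[i])))$root
    }, numeric(1))
    P <- cbind(R * cos(azim[sel]), R * sin(azim[sel]), Z)
    px <- refractProject(P, cam, rm1)
    zm <- apparentDepth(P, cam, rm1)
    rec <- correctedBackproject(px, zm, cam, rm1)
    relerr <- abs(rec - P) / pmax(abs(P), 50)
    expect_lt(max(relerr), 0.02)
  }
})

test_that("correction brings ray-traced segment lengths closer to truth", {
  # random 3D segments under the exact forward model: the corrected length
  # must beat the uncorrected one in at least 95% of cases
  cam <- hCam()
  set.seed(25)
  wins <- 0; total <- 0
  for (h in c(250, 350, 450)) {
    rm1 <- hRm(h)
    for (i in 1:40) {
      ctr <- c(runif(1, -60, 60), runif(1, -60, 60), h + runif(1, 150, 450))
      dir3 <- rnorm(3); dir3 <- dir3 / sqrt(sum(dir3^2))
      len <- runif(1, 100, 250)
      E <- ctr - dir3 * len / 2; F <- ctr + dir3 * len / 2
      if (min(E[3], F[3]) < h + 40) next
      pE <- refractProject(E, cam, rm1); pF <- refractProject(F, cam, rm1)
      zE <- apparentDepth(E, cam, rm1); zF <- apparentDepth(F, cam, rm1)
      lc <- euclideanLength(correctedBackproject(pE, zE, cam, rm1),
                            correctedBackproject(pF, zF, cam, rm1))
      lu <- euclideanLength(backProject(pE, zE, cam), backProject(pF, zF, cam))
      wins <- wins + (abs(lc - len) < abs(lu - len))
      total <- total + 1
    }
  }
  expect_gte(wins / total, 0.95)
})
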
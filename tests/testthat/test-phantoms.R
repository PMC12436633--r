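test_that("uniform and Poiseuille phantoms match their closed forms", {
  # zero-speed uniform flow: empty velocity field, duct-interior mask
  u0 <- generatePhantom(phantomSpec("uniform", meanSpeed = 0,
                                    extents = c(6L, 8L, 8L), frames = 1L))
  expect_true(all(velocity(u0) == 0))
  expect_gt(sum(fluidMask(u0)), 0)
  expect_lt(mean(fluidMask(u0)), 1)  # walls excluded

  pipe <- smallPipe(frames = 1L)
  # centreline axial velocity is 2U at the axis voxel (axis on a voxel centre)
  expect_equal(max(velocity(pipe, "x")), 1.0, tolerance = 1e-12)
  # voxel-summed flow rate within 2% of the analytic Q = pi R^2 U
  h <- spacing(pipe)
  ux1 <- velocity(pipe, "x")[1, , , 1, 1]
  qvox <- sum(ux1) * h^2
  expect_equal(qvox, pi * 0.011^2 * 0.5, tolerance = 0.02)
  expect_equal(qvox, groundTruth(pipe)$flowRate[1], tolerance = 0.02)
})

test_that("phantom spec invariants are enforced", {
  expect_error(phantomSpec("poiseuille", waveform = c(1, 1), frames = 3L),
               "waveform")
  expect_error(phantomSpec("poiseuille", radius = 0.05,
                           extents = c(8L, 10L, 10L)), "fit")
  expect_error(phantomSpec("nonsense"), "arg")
  expect_error(phantomSpec("uniform", spacing = -1), "spacing")
})

test_that("waveform scaling is linear for flow rate, quadratic for KE", {
  w <- c(0.5, 1, 2)
  pipe <- smallPipe(frames = 3L, waveform = w)
  sec <- crossSection("x", 4L, fluidMask(pipe)[1, , , 1], spacing(pipe))
  q <- seriesValues(flowRate(pipe, sec))
  expect_equal(q / q[2], w, tolerance = 1e-12)
  ke <- kineticEnergyMap(pipe)
  tot <- seriesValues(integrateOverRegion(ke, apply(fluidMask(pipe), 1:3, any)))
  expect_equal(tot / tot[2], w^2, tolerance = 1e-12)
})

test_that("divergence-free phantoms have zero interior discrete divergence", {
  for (kind in c("poiseuille", "uniform", "solid_rotation")) {
    ph <- generatePhantom(phantomSpec(kind, radius = 0.011, meanSpeed = 0.4,
                                      angularRate = 3,
                                      extents = c(8L, 15L, 15L), frames = 1L))
    g <- velocityGradients(ph)
    d <- g@d
    div <- d[, , , , 1, 1] + d[, , , , 2, 2] + d[, , , , 3, 3]
    dim(div) <- dim(d)[1:4]
    expect_lt(max(abs(div[interiorMask(ph) & validMask(g)[, , , 1]])), 1e-10)
  }
})

test_that("separation duct encodes the prescribed zero-crossing exactly", {
  spec <- phantomSpec("separation_duct", height = 0.03, width = 0.02,
                      meanSpeed = 0.5, extents = c(40L, 18L, 10L), frames = 1L)
  # y0 == 0: no reversed flow anywhere
  flat <- generateSeparationDuct(spec, function(x) rep(0, length(x)))
  expect_equal(groundTruth(flat)$recircLength, 0)
  expect_equal(groundTruth(flat)$recircHeight, 0)
  expect_true(all(velocity(flat, "x")[fluidMask(flat)] >= 0))

  # step: y0 = H/2 over 30% of the duct -> height H, length 0.3 L
  L <- 40 * 2e-3
  step <- generateSeparationDuct(spec, function(x)
    ifelse(x <= 0.3 * L, 0.015, 0))
  expect_equal(groundTruth(step)$recircHeight[1], 0.03)
  expect_equal(groundTruth(step)$recircLength[1], 0.3 * L, tolerance = 1e-3)

  # exceeding the duct height is rejected
  expect_error(generateSeparationDuct(spec, function(x) rep(0.05, length(x))),
               "height")
})

test_that("turbulence magnitude encoding follows the Gaussian model", {
  d4 <- c(4L, 4L, 3L, 2L)
  sig <- array(0, c(d4, 3))
  spec <- turbulencePhantomSpec(sig, venc = 0.7, baseline = 50)
  mags <- encodeTurbulenceMagnitude(spec)
  expect_equal(mags$venc_x, mags$ref)          # sigma = 0: no attenuation

  sig[, , , , 2] <- 0.7 / pi                   # kv sigma = 1
  mags <- encodeTurbulenceMagnitude(turbulencePhantomSpec(sig, venc = 0.7))
  expect_equal(mags$venc_y / mags$ref,
               array(exp(-0.5), d4), tolerance = 1e-12)

  expect_error(turbulencePhantomSpec(sig, venc = -1), "VENC")
  expect_error(turbulencePhantomSpec(-sig - 1, venc = 1))
})

test_that("background offset injection adds exactly the polynomial", {
  static <- zeroStatic()
  zero <- backgroundModel(matrix(0, 10, 3), static)
  expect_identical(velocity(injectBackgroundOffset(static, zero)),
                   velocity(static))
  cf <- matrix(0, 10, 3); cf[1, 1] <- 0.037
  off <- injectBackgroundOffset(static, backgroundModel(cf, static))
  expect_equal(unique(as.vector(velocity(off, "x"))), 0.037)
  expect_true(all(velocity(off, "y") == 0))
})

test_that("noise injection is seeded, unbiased and leaves the RNG alone", {
  static <- zeroStatic(dims = c(40L, 50L, 25L), frames = 2L)
  expect_identical(addNoise(static, 0, 7), static)
  a <- addNoise(static, 0.05, seed = 42)
  b <- addNoise(static, 0.05, seed = 42)
  expect_identical(velocity(a), velocity(b))
  expect_false(identical(velocity(a), velocity(addNoise(static, 0.05, 43))))
  # n = 3 * 40*50*25*2 = 3e5 samples: sd within 2%
  expect_equal(sd(velocity(a)), 0.05, tolerance = 0.02)
  expect_lt(abs(mean(velocity(a))), 1e-3)
  expect_error(addNoise(static, -0.1, 1), "sd")
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(addNoise(static, 0.01, 5)); after <- rnorm(1)
  expect_identical(before, after)
})
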
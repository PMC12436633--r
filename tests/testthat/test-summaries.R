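test_that("flow rate is u_N A for plug flow and antisymmetric under reversal", {
  plug <- generatePhantom(phantomSpec("uniform", meanSpeed = 0.4,
                                      height = 0.016, width = 0.012,
                                      extents = c(8L, 12L, 10L), frames = 2L))
  sec <- crossSection("x", 4L, fluidMask(plug)[1, , , 1], spacing(plug))
  q <- flowRate(plug, sec)
  expect_equal(seriesValues(q), rep(0.4 * sec$area, 2), tolerance = 1e-12)

  flipped <- customDataset(ux = -flow4d:::velComp(velocity(plug), 1),
                           mask = fluidMask(plug), spacing = spacing(plug),
                           frameDuration = frameDuration(plug))
  expect_equal(seriesValues(flowRate(flipped, sec)), -seriesValues(q))
  expect_error(flowRate(plug, crossSection("x", 4L,
                                           fluidMask(plug)[1, , , 1] & FALSE,
                                           spacing(plug))), "empty")
})

test_that("Poiseuille flow rate is within 2% and conserved along the pipe", {
  pipe <- smallPipe(frames = 1L, nx = 10L)
  gt <- groundTruth(pipe)
  qs <- vapply(1:10, function(i) {
    sec <- crossSection("x", i, fluidMask(pipe)[i, , , 1], spacing(pipe))
    seriesValues(flowRate(pipe, sec))[1]
  }, numeric(1))
  expect_equal(qs[5], pi * 0.011^2 * 0.5, tolerance = 0.02)
  expect_lt(max(abs(qs / mean(qs) - 1)), 0.01)   # mass conservation, 10 sections
})

test_that("stroke volume integrates the cycle with the rectangle rule", {
  # constant 5 L/min over a 0.5 s cycle: 41.67 mL
  q5 <- new("TimeSeries", values = rep(5 / 6e4, 10), metric = "q",
            units = "m^3/s", frameDuration = 0.05)
  sv <- strokeVolume(q5, heartRate = 120)
  expect_equal(sv$strokeVolume_mL, 5 / 6e4 * 0.5 * 1e6, tolerance = 1e-12)
  expect_equal(sv$strokeVolume_mL, 41.6667, tolerance = 1e-4)
  expect_equal(sv$cardiacOutput_Lmin, 5, tolerance = 1e-12)

  # zero-mean oscillation integrates to zero
  osc <- new("TimeSeries", values = sin(2 * pi * (0:19) / 20), metric = "q",
             units = "m^3/s", frameDuration = 0.02)
  expect_equal(strokeVolume(osc)$strokeVolume_mL, 0, tolerance = 1e-9)

  # pulsatile parabolic phantom vs the analytic waveform integral
  w <- sin(pi * (1:12 - 0.5) / 12)^2
  pipe <- generatePhantom(phantomSpec("pulsatile_parabolic", radius = 0.011,
                                      meanSpeed = 0.5, waveform = w,
                                      extents = c(6L, 15L, 15L), frames = 12L))
  sec <- crossSection("x", 3L, fluidMask(pipe)[1, , , 1], spacing(pipe))
  sv2 <- strokeVolume(flowRate(pipe, sec))
  truth <- sum(pi * 0.011^2 * 0.5 * w) * frameDuration(pipe) * 1e6
  expect_equal(sv2$strokeVolume_mL, truth, tolerance = 0.02)

  nodur <- new("TimeSeries", values = 1:3, metric = "q", units = "m^3/s",
               frameDuration = NA_real_)
  expect_error(strokeVolume(nodur), "duration")
})

test_that("Reynolds number follows rho q d / (mu A)", {
  props <- fluidProperties()                    # 1089, 3.7e-3
  re <- reynoldsNumber(1.333e-4, 0.022, 3.801e-4, props)
  expect_equal(re, 1089 * 1.333e-4 * 0.022 / (3.7e-3 * 3.801e-4))
  expect_equal(re, 2271, tolerance = 1e-3)
  expect_equal(reynoldsNumber(2 * 1.333e-4, 0.022, 3.801e-4, props), 2 * re)
  # circular section: Re = 4 rho q / (pi mu d)
  d <- 0.022; A <- pi * d^2 / 4
  expect_equal(reynoldsNumber(1e-4, d, A, props),
               4 * 1089 * 1e-4 / (pi * 3.7e-3 * d), tolerance = 1e-12)
  expect_error(reynoldsNumber(1e-4, 0.02, 0), "area")
})

test_that("region integration is exact, additive and rejects invalid frames", {
  # 1000 voxels of constant KE = 544.5 J/m^3 at (2 mm)^3 -> 4.356e-3 J
  vals <- array(544.5, c(10L, 10L, 10L, 2L))
  km <- new("ScalarMap", values = vals, valid = array(TRUE, dim(vals)),
            metric = "KE", units = "J/m^3", spacing = 2e-3)
  tot <- integrateOverRegion(km, array(TRUE, c(10L, 10L, 10L)))
  expect_equal(seriesValues(tot), rep(4.356e-3, 2), tolerance = 1e-12)
  expect_identical(metricUnits(tot), "J")

  ra <- array(FALSE, c(10L, 10L, 10L)); ra[1:5, , ] <- TRUE
  rb <- !ra
  expect_equal(seriesValues(integrateOverRegion(km, ra)) +
                 seriesValues(integrateOverRegion(km, rb)),
               seriesValues(tot))

  expect_error(integrateOverRegion(km, ra & FALSE), "empty")
  bad <- km
  bad@valid[, , , 2] <- FALSE
  bad@values[, , , 2] <- NA_real_
  expect_error(integrateOverRegion(bad, ra), "frame 2")

  # dissipation integrals pick up the viscosity factor: E_L' = mu sum phi V
  phi <- new("ScalarMap", values = array(100, c(4L, 4L, 4L, 1L)),
             valid = array(TRUE, c(4L, 4L, 4L, 1L)),
             metric = "phi_v", units = "1/s^2", spacing = 2e-3)
  el <- integrateOverRegion(phi, array(TRUE, c(4L, 4L, 4L)))
  expect_equal(seriesValues(el), 3.7e-3 * 100 * 64 * 8e-9)
  expect_identical(metricName(el), "E_L'")
  expect_identical(metricUnits(el), "W")
})

test_that("MIP equals the brute-force maximum and dominates every frame", {
  d4 <- c(7L, 6L, 5L, 4L)
  vals <- flow4d:::withSeed(8, array(runif(prod(d4)), d4))
  valid <- flow4d:::withSeed(9, array(runif(prod(d4)) > 0.2, d4))
  vals[!valid] <- NA_real_
  m <- new("ScalarMap", values = vals, valid = valid, metric = "KE",
           units = "J/m^3", spacing = 2e-3)
  for (ax in 1:3) {
    got <- mip(m, ax)
    keep <- setdiff(1:3, ax)
    truth <- array(NA_real_, d4[keep])
    for (i in seq_len(d4[keep[1]])) for (j in seq_len(d4[keep[2]])) {
      ray <- switch(ax, vals[, i, j, ], vals[i, , j, ], vals[i, j, , ])
      if (!all(is.na(ray))) truth[i, j] <- max(ray, na.rm = TRUE)
    }
    expect_equal(got, truth)
    # dominates each frame's projection, with equality attained somewhere
    for (t in seq_len(d4[4])) {
      fr <- apply(vals[, , , t], keep, function(r)
        if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
      expect_true(all(got >= fr | is.na(fr)))
    }
    expect_true(any(got == truth, na.rm = TRUE))
  }

  # single hot voxel appears at the right pixel in all three projections
  one <- array(0, c(5L, 5L, 5L, 2L)); one[2, 3, 4, 1] <- 7
  hot <- new("ScalarMap", values = one, valid = array(TRUE, dim(one)),
             metric = "KE", units = "J/m^3", spacing = 2e-3)
  expect_equal(mip(hot, 1)[3, 4], 7)
  expect_equal(mip(hot, 2)[2, 4], 7)
  expect_equal(mip(hot, 3)[2, 3], 7)
  expect_equal(max(temporalMax(hot)), 7)

  # a time-constant field projects like its spatial maximum
  tc <- new("ScalarMap", values = array(one[, , , 1], c(5L, 5L, 5L, 3L)),
            valid = array(TRUE, c(5L, 5L, 5L, 3L)), metric = "KE",
            units = "J/m^3", spacing = 2e-3)
  expect_equal(mip(tc, 3), apply(one[, , , 1], c(1, 2), max))
  expect_error(mip(hot, 5), "component")
})

test_that("histograms use fixed-width bins from zero and sum to 100%", {
  v <- array(0.05, c(4L, 4L, 2L, 2L))
  m <- new("ScalarMap", values = v, valid = array(TRUE, dim(v)),
           metric = "tau", units = "Pa", spacing = NA_real_)
  hg <- metricHistogram(m, 0.02)
  expect_equal(hg$percent[3], 100)            # bin [0.04, 0.06)
  expect_equal(sum(hg$percent), 100, tolerance = 1e-9)
  expect_equal(hg$mean, 0.05)
  expect_equal(hg$max, 0.05)

  u <- flow4d:::withSeed(4, array(runif(1e5), c(50L, 50L, 10L, 4L)))
  mu_ <- new("ScalarMap", values = u, valid = array(TRUE, dim(u)),
             metric = "tau", units = "Pa", spacing = NA_real_)
  hgu <- metricHistogram(mu_, 0.02)
  expect_equal(sum(hgu$percent), 100, tolerance = 1e-9)
  expect_lt(max(abs(hgu$percent - 2)), 0.5)   # 50 bins of ~2% each
})

test_that("region quartiles use linear order-statistic interpolation", {
  d3 <- c(10L, 10L, 1L)
  vals <- array(as.numeric(1:100), c(d3, 1L))
  m <- new("ScalarMap", values = vals, valid = array(TRUE, c(d3, 1L)),
           metric = "KE", units = "J/m^3", spacing = NA_real_)
  regs <- regionSet(all = array(TRUE, d3),
                    const = array(rep(c(TRUE, FALSE), c(1, 99)), d3),
                    empty = array(FALSE, d3))
  expect_warning(qt <- regionQuartiles(m, regs), "empty")
  row <- qt[qt$region == "all", ]
  expect_equal(row$median, 50.5)
  expect_equal(row$q1, 25.75)                  # type-7 on 1..100
  expect_equal(row$q3, 75.25)
  cr <- qt[qt$region == "const", ]
  expect_true(cr$q1 == 1 && cr$median == 1 && cr$q3 == 1)

  # brute-force type-7 quantile: x_(floor(h)) + frac * (x_(ceil(h)) - x_(floor(h)))
  x <- flow4d:::withSeed(12, runif(37))
  m2 <- new("ScalarMap", values = array(x, c(37L, 1L, 1L, 1L)),
            valid = array(TRUE, c(37L, 1L, 1L, 1L)), metric = "KE",
            units = "J/m^3", spacing = NA_real_)
  qt2 <- regionQuartiles(m2, regionSet(all = array(TRUE, c(37L, 1L, 1L))))
  xs <- sort(x)
  bf <- function(p) {
    hpos <- (length(xs) - 1) * p + 1
    xs[floor(hpos)] + (hpos - floor(hpos)) * (xs[ceiling(hpos)] - xs[floor(hpos)])
  }
  expect_equal(qt2$q1, bf(0.25)); expect_equal(qt2$median, bf(0.5))
  expect_equal(qt2$q3, bf(0.75))
  expect_error(regionSet(array(TRUE, d3)), "names")
})

test_that("velocity profiles interpolate exactly on linear fields", {
  plug <- generatePhantom(phantomSpec("uniform", meanSpeed = 0.4,
                                      extents = c(8L, 12L, 12L), frames = 2L))
  h <- spacing(plug)
  pr <- velocityProfile(plug, c(2 * h, 6 * h, 6 * h), c(6 * h, 6 * h, 6 * h),
                        n = 9)
  expect_equal(pr$profile[pr$inMask], rep(0.4, sum(pr$inMask)))

  # linear shear sampled anywhere: trilinear interpolation is exact
  ls <- generatePhantom(phantomSpec("linear_shear", shearRate = 0.2,
                                    extents = c(8L, 14L, 14L), frames = 1L))
  ctr <- flow4d:::gridCenter(dim(fluidMask(ls))[1:3], h)
  pr2 <- velocityProfile(ls, c(4 * h, ctr[2] - 0.008, ctr[3]),
                         c(4 * h, ctr[2] + 0.008, ctr[3]), n = 17,
                         component = "x")
  truth <- 0.2 * (seq(-0.008, 0.008, length.out = 17))
  expect_equal(pr2$profile[pr2$inMask[, 1], 1], truth[pr2$inMask[, 1]],
               tolerance = 1e-12)

  # Poiseuille diameter profile reproduces 2U(1 - (r/R)^2)
  pipe <- smallPipe(frames = 1L)
  d <- dim(fluidMask(pipe))[1:3]
  cy <- (floor(d[2] / 2) + 0.5) * h; cz <- (floor(d[3] / 2) + 0.5) * h
  pr3 <- velocityProfile(pipe, c(4 * h, cy - 0.011, cz),
                         c(4 * h, cy + 0.011, cz), n = 45, component = "x")
  r <- pr3$s - 0.011
  truth3 <- 2 * 0.5 * (1 - (r / 0.011)^2)
  inm <- pr3$inMask[, 1]
  expect_lt(max(abs(pr3$profile[inm, 1] - truth3[inm])), 0.03)
  expect_error(velocityProfile(pipe, c(-1, 0, 0), c(0, 0, 0)), "within")
})
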
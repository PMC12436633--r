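test_that("kinetic energy density matches rho/2 |u|^2", {
  z <- zeroStatic(dims = c(5L, 5L, 5L), frames = 1L)
  expect_true(all(mapValues(kineticEnergyMap(z))[validMask(kineticEnergyMap(z))] == 0))

  # |u| = 1 m/s at rho = 1089 kg/m^3 -> 544.5 J/m^3
  plug <- generatePhantom(phantomSpec("uniform", meanSpeed = 1,
                                      extents = c(6L, 8L, 8L), frames = 1L))
  ke <- kineticEnergyMap(plug)
  expect_equal(unique(mapValues(ke)[validMask(ke)]), 544.5)

  # Poiseuille volume integral vs (rho/2)(4/3) U^2 pi R^2 L within 2%
  pipe <- smallPipe(frames = 1L)
  gt <- groundTruth(pipe)
  tot <- seriesValues(integrateOverRegion(kineticEnergyMap(pipe),
                                          apply(fluidMask(pipe), 1:3, any)))
  expect_equal(tot[1], gt$keTotal[1], tolerance = 0.02)
  expect_equal(gt$keTotal[1],
               (1089 / 2) * (4 / 3) * 0.5^2 * pi * 0.011^2 * gt$pipeLength)
})

test_that("velocity gradients: exact on linear fields, 2nd order on smooth ones", {
  # uniform flow: all gradients vanish
  plug <- generatePhantom(phantomSpec("uniform", meanSpeed = 0.7,
                                      extents = c(6L, 8L, 8L), frames = 1L))
  g <- velocityGradients(plug)
  expect_lt(max(abs(g@d)[rep(validMask(g), times = 9)]), 1e-14)

  # linear shear: du_x/dy = gamma exactly, interior and one-sided alike
  ls <- generatePhantom(phantomSpec("linear_shear", shearRate = 0.1,
                                    extents = c(6L, 10L, 10L), frames = 1L))
  gl <- velocityGradients(ls)
  dxy <- gl@d[, , , , 1, 2]; dim(dxy) <- dim(validMask(gl))
  expect_equal(unique(round(dxy[validMask(gl)], 14)), 0.1)

  # cubic field u_x = a y^3: central-difference error is O(h^2)
  errAt <- function(h) {
    n <- 17L; a <- 2.0
    y <- ((seq_len(n) - 0.5) - n / 2) * h
    ux <- array(rep(a * y^3, each = 6L), c(6L, n, 6L, 1L))
    dat <- customDataset(ux = ux, spacing = h, venc = 100)
    gg <- velocityGradients(dat)
    d12 <- gg@d[, , , , 1, 2]; dim(d12) <- dim(ux)
    truth <- array(rep(3 * a * y^2, each = 6L), dim(ux))
    core <- array(FALSE, dim(ux)); core[, 3:(n - 2), , ] <- TRUE
    max(abs((d12 - truth))[core])
  }
  e1 <- errAt(2e-3); e2 <- errAt(1e-3)
  expect_equal(e1 / e2, 4, tolerance = 0.05)
})

test_that("viscous dissipation: zero for rigid motion, gamma^2 for shear", {
  rot <- generatePhantom(phantomSpec("solid_rotation", radius = 0.011,
                                     angularRate = 4,
                                     extents = c(6L, 15L, 15L), frames = 1L))
  phi <- viscousDissipationMap(velocityGradients(rot))
  expect_lt(max(mapValues(phi)[validMask(phi)]), 1e-12)

  ls <- generatePhantom(phantomSpec("linear_shear", shearRate = 0.1,
                                    extents = c(6L, 10L, 10L), frames = 1L))
  phil <- viscousDissipationMap(velocityGradients(ls))
  expect_equal(unique(round(mapValues(phil)[validMask(phil)], 14)), 0.1^2)
})

test_that("Poiseuille dissipation integral converges to 8 pi mu L U^2", {
  errs <- vapply(c(2.0, 1.0), function(sp) {
    nyz <- as.integer(2 * ceiling(0.011 / (sp * 1e-3)) + 3)
    pipe <- smallPipe(frames = 1L, spacing = sp, nx = 6L, nyz = nyz)
    el <- integrateOverRegion(viscousDissipationMap(velocityGradients(pipe)),
                              apply(fluidMask(pipe), 1:3, any))
    abs(seriesValues(el)[1] / groundTruth(pipe)$dissipationPower[1] - 1)
  }, numeric(1))
  expect_lt(errs[1], 0.10)
  expect_lt(errs[2], errs[1])
})

test_that("scalar shear stress matches mu gamma and the analytic pipe profile", {
  rot <- generatePhantom(phantomSpec("solid_rotation", radius = 0.011,
                                     angularRate = 4,
                                     extents = c(6L, 15L, 15L), frames = 1L))
  tau0 <- scalarShearStressMap(velocityGradients(rot))
  expect_lt(max(mapValues(tau0)[validMask(tau0)]), 1e-12)

  ls <- generatePhantom(phantomSpec("linear_shear", shearRate = 0.1,
                                    extents = c(6L, 10L, 10L), frames = 1L))
  taul <- scalarShearStressMap(velocityGradients(ls))
  expect_equal(unique(round(mapValues(taul)[validMask(taul)], 12)), 3.7e-4)

  # interior voxels: tau = mu |du/dr| = 4 mu U r / R^2 exactly (the profile
  # is quadratic, so the central difference has no truncation error)
  pipe <- smallPipe(frames = 1L)
  tau <- scalarShearStressMap(velocityGradients(pipe))
  h <- spacing(pipe)
  d <- dim(fluidMask(pipe))
  ctr <- (floor(d[2:3] / 2) + 0.5) * h
  cc <- flow4d:::voxelCenters(d, h)
  r <- sqrt(outer((cc[[2]] - ctr[1])^2, (cc[[3]] - ctr[2])^2, "+"))
  truth <- aperm(array(4 * 3.7e-3 * 0.5 * r / 0.011^2,
                       c(d[2], d[3], d[1])), c(3, 1, 2))
  core <- interiorMask(pipe)
  expect_equal(mapValues(tau)[, , , 1][core], truth[core], tolerance = 1e-10)
})

test_that("strain-rate metrics are Galilean invariant and scale correctly", {
  pipe <- smallPipe(frames = 1L)
  boosted <- customDataset(ux = flow4d:::velComp(velocity(pipe), 1) + 0.33,
                           uy = flow4d:::velComp(velocity(pipe), 2) + 0.1,
                           mask = fluidMask(pipe), spacing = spacing(pipe))
  g1 <- velocityGradients(pipe); g2 <- velocityGradients(boosted)
  expect_equal(mapValues(viscousDissipationMap(g2)),
               mapValues(viscousDissipationMap(g1)), tolerance = 1e-10)
  expect_equal(mapValues(scalarShearStressMap(g2)),
               mapValues(scalarShearStressMap(g1)), tolerance = 1e-10)

  scaled <- customDataset(ux = 3 * flow4d:::velComp(velocity(pipe), 1),
                          mask = fluidMask(pipe), spacing = spacing(pipe))
  g3 <- velocityGradients(scaled)
  expect_equal(mapValues(viscousDissipationMap(g3)),
               9 * mapValues(viscousDissipationMap(g1)), tolerance = 1e-10)
  expect_equal(mapValues(scalarShearStressMap(g3)),
               3 * mapValues(scalarShearStressMap(g1)), tolerance = 1e-10)
  ke <- kineticEnergyMap(pipe); kes <- kineticEnergyMap(scaled)
  expect_equal(mapValues(kes), 9 * mapValues(ke), tolerance = 1e-12)
})

test_that("TKE map applies rho/2 to the summed directional variances", {
  d4 <- c(4L, 4L, 3L, 2L)
  sig <- array(0.3, c(d4, 3))                 # isotropic 0.3 m/s
  mags <- encodeTurbulenceMagnitude(turbulencePhantomSpec(sig, venc = 1.5))
  iv <- estimateIVVV(mags$ref, mags[c("venc_x", "venc_y", "venc_z")], 1.5)
  tke <- tkeMap(iv)
  expect_equal(unique(round(mapValues(tke)[validMask(tke)], 9)), 147.015)

  sig2 <- flow4d:::withSeed(21, array(runif(prod(d4) * 3, 0, 0.5), c(d4, 3)))
  mags2 <- encodeTurbulenceMagnitude(turbulencePhantomSpec(sig2, venc = 1.5))
  iv2 <- estimateIVVV(mags2$ref, mags2[c("venc_x", "venc_y", "venc_z")], 1.5)
  truth <- (1089 / 2) * (sig2[, , , , 1]^2 + sig2[, , , , 2]^2 + sig2[, , , , 3]^2)
  expect_equal(mapValues(tkeMap(iv2)), truth, tolerance = 1e-12)
})

test_that("relative stasis counts frames exactly and honours eligibility", {
  # static zero field: 100% stasis everywhere
  z <- zeroStatic(dims = c(4L, 4L, 4L), frames = 40L)
  st0 <- relativeStasis(z)
  expect_true(all(mapValues(st0)[validMask(st0)] == 100))

  # 10 slow frames of 40 -> exactly 25.000%
  ux <- array(0.2, c(4L, 4L, 4L, 40L))
  ux[2, 3, 2, 1:10] <- 0.05
  dat <- customDataset(ux = ux)
  st <- relativeStasis(dat, 0.1)
  expect_identical(mapValues(st)[2, 3, 2], 25)
  expect_identical(mapValues(st)[1, 1, 1], 0)

  # threshold is strict: speed exactly at 0.1 m/s is not stasis
  ux2 <- array(0.1, c(3L, 3L, 3L, 4L))
  expect_true(all(mapValues(relativeStasis(customDataset(ux = ux2), 0.1)) == 0))

  # a voxel absent from one frame is ineligible
  mask <- array(TRUE, c(4L, 4L, 4L, 40L))
  mask[2, 3, 2, 17] <- FALSE
  dat2 <- customDataset(ux = ux, mask = mask)
  st2 <- relativeStasis(dat2, 0.1)
  expect_false(validMask(st2)[2, 3, 2])
  expect_true(is.na(mapValues(st2)[2, 3, 2]))

  # invariance to frame reordering
  perm <- flow4d:::withSeed(3, sample(40L))
  dat3 <- customDataset(ux = ux[, , , perm])
  expect_identical(mapValues(relativeStasis(dat3, 0.1)),
                   mapValues(st))
  expect_error(relativeStasis(dat, 0), "threshold")
})
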
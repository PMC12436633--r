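## Analytic flow phantoms. Every generated dataset carries its closed-form
## ground truth (flow rate, dissipation power, wall shear, ...) computed
## from the defining formulas -- never from the voxel grid -- so each
## downstream stage can be checked against an independent oracle.

#' Specify an analytic flow phantom
#'
#' Describes a synthetic velocity field on a regular voxel grid: a steady
#' or pulsatile paraboloid pipe flow, solid-body rotation, linear shear,
#' uniform plug flow, or a separation duct with a prescribed reversed-flow
#' zone. The default grid (64^3 voxels at 2.0 mm, 40 frames of 14 ms)
#' mirrors a typical in vitro 4D flow acquisition of a heart-sized pump.
#'
#' @param kind one of "poiseuille", "pulsatile_parabolic", "solid_rotation",
#'   "linear_shear", "uniform", "separation_duct".
#' @param radius pipe radius R (m), for the cylindrical kinds.
#' @param height,width duct cross-section (m), for the rectangular kinds;
#'   default fills the grid minus a one-voxel wall.
#' @param meanSpeed cross-section mean speed U (m/s); the Poiseuille
#'   centreline speed is 2U.
#' @param shearRate shear rate gamma (1/s) for "linear_shear".
#' @param angularRate angular rate omega (rad/s) for "solid_rotation".
#' @param waveform per-frame dimensionless scale factors, length
#'   \code{frames}; default all 1 (steady).
#' @param spacing isotropic voxel spacing in mm.
#' @param extents grid size in voxels, length 3.
#' @param frames number of timeframes.
#' @param frameDuration frame duration (s).
#' @param venc velocity encoding limit (m/s); default comfortably above
#'   the phantom's peak speed so no wrap warnings fire.
#' @param rho,mu fluid density (kg/m^3) and dynamic viscosity (kg/m/s);
#'   defaults are the blood-mimicking glycerol-water mixture.
#' @param seed integer seed recorded in the spec (used by noise injection).
#' @return a validated \code{PhantomSpec} (list).
#' @export
phantomSpec <- function(kind = c("poiseuille", "pulsatile_parabolic",
                                 "solid_rotation", "linear_shear",
                                 "uniform", "separation_duct"),
                        radius = 0.011, height = NULL, width = NULL,
                        meanSpeed = 0.5, shearRate = 0.1, angularRate = 1,
                        waveform = NULL, spacing = 2.0,
                        extents = c(64L, 64L, 64L), frames = 40L,
                        frameDuration = 0.014, venc = NULL,
                        rho = 1089, mu = 3.7e-3, seed = 1L) {
  kind <- match.arg(kind)
  if (spacing <= 0) stop("spacing must be positive (mm)")
  if (frames < 1) stop("frames must be >= 1")
  extents <- as.integer(extents)
  if (length(extents) != 3 || any(extents < 3))
    stop("extents must be three voxel counts >= 3")
  if (is.null(waveform)) waveform <- rep(1, frames)
  if (length(waveform) != frames)
    stop(sprintf("waveform length (%d) must equal frames (%d)",
                 length(waveform), frames))
  if (kind == "pulsatile_parabolic" && all(waveform == waveform[1]))
    waveform <- sin(pi * (seq_len(frames) - 0.5) / frames)^2  # simple systole-like pulse
  h <- spacing * 1e-3
  if (is.null(height)) height <- (extents[2] - 2) * h
  if (is.null(width))  width  <- (extents[3] - 2) * h
  cyl <- kind %in% c("poiseuille", "pulsatile_parabolic", "solid_rotation")
  if (cyl && 2 * radius > min(extents[2], extents[3]) * h)
    stop("pipe diameter 2R does not fit inside the grid extents")
  if (!cyl && (height > extents[2] * h || width > extents[3] * h))
    stop("duct cross-section does not fit inside the grid extents")
  structure(list(kind = kind, radius = radius, height = height,
                 width = width, meanSpeed = meanSpeed,
                 shearRate = shearRate, angularRate = angularRate,
                 waveform = waveform, spacing = spacing, extents = extents,
                 frames = as.integer(frames), frameDuration = frameDuration,
                 venc = venc, rho = rho, mu = mu, seed = as.integer(seed)),
            class = "PhantomSpec")
}

.phantomMeta <- function(spec, peakSpeed) {
  venc <- spec$venc
  if (is.null(venc)) venc <- max(2.0, 1.25 * peakSpeed)
  cycle <- spec$frames * spec$frameDuration
  new("AcquisitionMeta", venc = venc, frameDuration = spec$frameDuration,
      frames = spec$frames, heartRate = 60 / cycle,
      spacing = spec$spacing * 1e-3, rho = spec$rho, mu = spec$mu)
}

#' Generate an analytic phantom dataset
#'
#' Evaluates the closed-form velocity field of the spec at voxel centres
#' (centre of voxel (i,j,k) at ((i,j,k) - 0.5) * spacing), scales each
#' frame by the waveform, and attaches analytic ground truth for testing:
#' per-frame flow rate, volume-integrated kinetic energy and viscous
#' dissipation power, and peak wall shear, all from closed forms.
#'
#' The mask marks voxels whose centre lies strictly inside the fluid
#' geometry, which keeps the analytic oracles free of partial-volume
#' ambiguity.
#'
#' @param spec a [phantomSpec()].
#' @return a [FlowDataset-class] with \code{groundTruth()} populated.
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  if (spec$kind == "separation_duct")
    stop("use generateSeparationDuct() for kind 'separation_duct'")
  d <- spec$extents; nt <- spec$frames
  h <- spec$spacing * 1e-3
  ctr <- gridCenter(d, h)
  ## cylindrical phantoms: put the pipe axis on the voxel-center column
  ## nearest the grid centre. An axis on a voxel corner (even extents,
  ## grid-centred) leaves the wall-adjacent voxel ring systematically
  ## closer to the wall and several-fold inflates the discretisation
  ## error of gradient-based integrals at coarse spacing.
  if (spec$kind %in% c("poiseuille", "pulsatile_parabolic", "solid_rotation"))
    ctr[2:3] <- (floor(d[2:3] / 2) + 0.5) * h
  cc <- voxelCenters(d, h)
  y <- cc[[2]] - ctr[2]; z <- cc[[3]] - ctr[3]
  w <- spec$waveform
  U <- spec$meanSpeed; R <- spec$radius
  L <- d[1] * h
  vel <- array(0, c(d, nt, 3))
  gt <- list(kind = spec$kind, waveform = w, pipeLength = L)

  r2 <- outer(y^2, z^2, "+")                       # ny x nz
  yz_y <- matrix(y, d[2], d[3])                     # y - yc
  yz_z <- matrix(z, d[2], d[3], byrow = TRUE)       # z - zc

  if (spec$kind %in% c("poiseuille", "pulsatile_parabolic")) {
    mask2 <- r2 < R^2
    prof <- 2 * U * (1 - r2 / R^2); prof[!mask2] <- 0
    for (t in seq_len(nt))
      vel[, , , t, 1] <- rep(w[t] * prof, each = d[1])
    gt$radius <- R; gt$meanSpeed <- U
    gt$flowRate <- pi * R^2 * U * w                         # m^3/s per frame
    gt$keTotal <- (spec$rho / 2) * (4 / 3) * pi * U^2 * R^2 * L * w^2  # J
    gt$dissipationPower <- 8 * pi * spec$mu * L * U^2 * w^2 # W
    gt$wallShearMax <- 4 * spec$mu * U / R * abs(w)         # Pa
    peak <- 2 * U * max(abs(w))
  } else if (spec$kind == "solid_rotation") {
    mask2 <- r2 < R^2
    om <- spec$angularRate
    uy <- -om * yz_z; uz <- om * yz_y
    uy[!mask2] <- 0; uz[!mask2] <- 0
    for (t in seq_len(nt)) {
      vel[, , , t, 2] <- rep(w[t] * uy, each = d[1])
      vel[, , , t, 3] <- rep(w[t] * uz, each = d[1])
    }
    gt$radius <- R; gt$angularRate <- om
    gt$flowRate <- rep(0, nt)
    gt$dissipationPower <- rep(0, nt)   # zero strain rate: rigid motion
    peak <- om * R * max(abs(w))
  } else {                                 # uniform / linear_shear ducts
    H <- spec$height; W <- spec$width
    mask2 <- abs(yz_y) < H / 2 & abs(yz_z) < W / 2
    prof <- if (spec$kind == "uniform") matrix(U, d[2], d[3]) else
      spec$shearRate * yz_y
    prof[!mask2] <- 0
    for (t in seq_len(nt))
      vel[, , , t, 1] <- rep(w[t] * prof, each = d[1])
    gt$height <- H; gt$width <- W; gt$area <- H * W
    if (spec$kind == "uniform") {
      gt$flowRate <- U * H * W * w
      gt$dissipationPower <- rep(0, nt)
      peak <- abs(U) * max(abs(w))
    } else {
      g <- spec$shearRate
      gt$shearRate <- g
      gt$flowRate <- rep(0, nt)                       # odd profile integrates to 0
      gt$phi <- g^2 * w^2                             # 1/s^2, uniform in space
      gt$tau <- spec$mu * abs(g) * abs(w)             # Pa
      gt$dissipationPower <- spec$mu * g^2 * w^2 * (H * W * L)
      peak <- abs(g) * H / 2 * max(abs(w))
    }
  }
  mask <- array(rep(rep(mask2, each = d[1]), nt) > 0, c(d, nt))
  flowDataset(vel, mask, .phantomMeta(spec, peak), groundTruth = gt)
}

#' Generate a separation-duct phantom with a prescribed recirculation zone
#'
#' Builds a rectangular duct whose axial velocity is
#' \code{u(x, y, t) = U w(t) (y - y0(x)) / H}, with y the wall-normal
#' distance from the inner wall (the y = 0 face of the grid). The
#' zero-axial-velocity isosurface is therefore exactly the prescribed
#' curve \code{y0}, and the ground-truth recirculation length (streamwise
#' extent with y0 > 0, measured from the inner corner at x = 0) and height
#' (2 max y0, capped at the duct height) are attached for testing the
#' detector.
#'
#' @param spec a [phantomSpec()] with kind "separation_duct"; its
#'   \code{height} is the duct height H.
#' @param y0 the zero-crossing curve: a function of the streamwise
#'   coordinate x (m, from the inner corner) returning wall-normal heights
#'   (m). May also take a second argument, the frame index, for a
#'   time-varying zone.
#' @return a [FlowDataset-class]; \code{groundTruth()} holds per-frame
#'   \code{recircLength} and \code{recircHeight}.
#' @export
generateSeparationDuct <- function(spec, y0) {
  stopifnot(inherits(spec, "PhantomSpec"))
  if (spec$kind != "separation_duct")
    stop("spec$kind must be 'separation_duct'")
  d <- spec$extents; nt <- spec$frames
  h <- spec$spacing * 1e-3
  H <- spec$height; W <- spec$width
  Lduct <- d[1] * h
  cc <- voxelCenters(d, h)
  x <- cc[[1]]                                  # streamwise, from inner corner
  yw <- cc[[2]]                                 # wall-normal distance from inner wall
  zc <- cc[[3]] - gridCenter(d, h)[3]
  timeVarying <- length(formals(y0)) >= 2
  y0fun <- if (timeVarying) y0 else function(x, t) y0(x)
  xf <- seq(0, Lduct, length.out = 4096)        # fine closed-form sampling
  gtLen <- gtHgt <- numeric(nt)
  for (t in seq_len(nt)) {
    y0f <- y0fun(xf, t)
    if (max(y0f) > H) stop("y0 exceeds the duct height H")
    pos <- y0f > 0
    gtLen[t] <- if (any(pos)) max(xf[pos]) else 0
    gtHgt[t] <- if (any(pos)) min(2 * max(y0f), H) else 0
  }
  mask2 <- outer(yw > 0 & yw < H, abs(zc) < W / 2, "&")
  U <- spec$meanSpeed; w <- spec$waveform
  vel <- array(0, c(d, nt, 3))
  m3 <- array(rep(mask2, each = d[1]), d)       # nx x ny x nz
  for (t in seq_len(nt)) {
    y0x <- y0fun(x, t)                          # length nx
    ux <- U * w[t] * outer(-y0x, yw, "+") / H   # nx x ny: U w (y - y0(x)) / H
    slab <- array(rep(ux, times = d[3]), d)
    slab[!m3] <- 0
    vel[, , , t, 1] <- slab
  }
  mask <- array(rep(rep(mask2, each = d[1]), nt) > 0, c(d, nt))
  gt <- list(kind = "separation_duct", waveform = w, ductHeight = H,
             ductLength = Lduct, recircLength = gtLen, recircHeight = gtHgt)
  peak <- abs(U) * max(abs(w)) * max(1, max(abs(gtHgt)) / H)
  flowDataset(vel, mask, .phantomMeta(spec, peak), groundTruth = gt)
}

#' Specify a turbulence phantom
#'
#' Per-voxel directional intravoxel velocity standard deviations together
#' with the velocity-encoding limit and baseline signal level used to
#' encode them into magnitude images.
#'
#' @param sigma 5-D array (nx, ny, nz, nframes, 3) of directional
#'   intravoxel velocity standard deviations (m/s), all >= 0.
#' @param venc velocity encoding limit (m/s), > 0.
#' @param baseline reference signal level (arbitrary units).
#' @return a validated \code{TurbulencePhantomSpec} (list).
#' @export
turbulencePhantomSpec <- function(sigma, venc, baseline = 100) {
  if (length(dim(sigma)) != 5 || dim(sigma)[5] != 3)
    stop("sigma must be a 5-D array (nx, ny, nz, nframes, 3)")
  if (min(sigma) < 0) stop("sigma components must be >= 0")
  if (venc <= 0) stop("VENC must be positive")
  structure(list(sigma = sigma, venc = venc, baseline = baseline),
            class = "TurbulencePhantomSpec")
}

#' Encode intravoxel velocity variation into magnitude images
#'
#' Applies the Gaussian intravoxel velocity-distribution signal model: a
#' velocity-encoded magnitude is attenuated relative to the reference by
#' \code{exp(-kv^2 sigma_i^2 / 2)} with turbulence-encoding sensitivity
#' \code{kv = pi / VENC}. [estimateIVVV()] inverts this model exactly.
#'
#' @param spec a [turbulencePhantomSpec()].
#' @return named list of 4-D magnitude arrays: \code{ref} and
#'   \code{venc_x}, \code{venc_y}, \code{venc_z}.
#' @export
encodeTurbulenceMagnitude <- function(spec) {
  stopifnot(inherits(spec, "TurbulencePhantomSpec"))
  kv <- pi / spec$venc
  d4 <- dim(spec$sigma)[1:4]
  ref <- array(spec$baseline, d4)
  out <- list(ref = ref)
  for (i in 1:3) {
    s2 <- spec$sigma[, , , , i, drop = TRUE]
    out[[paste0("venc_", c("x", "y", "z")[i])]] <-
      array(spec$baseline * exp(-kv^2 * s2^2 / 2), d4)
  }
  out
}

#' Inject a known polynomial background offset
#'
#' Adds the model's second-order polynomial, evaluated on normalised
#' coordinates at every voxel centre, to every velocity component of
#' every frame. Together with [fitBackground()] this forms an exact
#' inverse pair on noiseless data, which is the test fixture for
#' background-offset correction.
#'
#' @param data a [FlowDataset-class].
#' @param model a [BackgroundModel-class] (10 coefficients per component).
#' @return the offset dataset.
#' @export
injectBackgroundOffset <- function(data, model) {
  stopifnot(is(data, "FlowDataset"), is(model, "BackgroundModel"))
  off <- evaluateBackground(model, dim(data@velocity)[1:3], spacing(data))
  vel <- data@velocity
  for (i in 1:3)
    vel[, , , , i] <- vel[, , , , i] + as.vector(off[, , , i])
  methods::initialize(data, velocity = vel)
}

#' Add Gaussian velocity noise
#'
#' Independent zero-mean Gaussian perturbation of every velocity sample,
#' reproducible under the seed. The global RNG state is left untouched.
#'
#' @param data a [FlowDataset-class].
#' @param sd noise standard deviation (m/s), >= 0.
#' @param seed integer seed.
#' @return the perturbed dataset.
#' @export
addNoise <- function(data, sd, seed) {
  stopifnot(is(data, "FlowDataset"))
  if (sd < 0) stop("noise sd must be >= 0")
  if (sd == 0) return(data)
  vel <- data@velocity
  vel <- vel + withSeed(seed, array(stats::rnorm(length(vel), 0, sd), dim(vel)))
  methods::initialize(data, velocity = vel)
}

## Evaluate expr under a temporary RNG seed, restoring global state after.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
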
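## Central S4 containers. All internal quantities are SI: metres, seconds,
## m/s, kg/m^3, Pa. Acquisition-native units (cm/s VENC, ms frames, mm
## spacing) exist only at the file boundary in io.R.

#' Acquisition metadata for a 4D flow dataset
#'
#' Carries the scan parameters and fluid constants a 4D flow MRI analysis
#' needs: the velocity-encoding limit (VENC), frame timing, voxel spacing,
#' and the density and dynamic viscosity of the working fluid. All slots
#' are SI; the JSON sidecar read/written by [readDataset()]/[writeDataset()]
#' uses the acquisition-native units (cm/s, ms, mm) and the conversion is
#' logged.
#'
#' @slot venc velocity encoding limit (m/s); velocities beyond it may be
#'   phase-wrapped.
#' @slot frameDuration duration of one reconstructed timeframe (s).
#' @slot frames number of reconstructed timeframes.
#' @slot heartRate pump/heart rate (beats per minute).
#' @slot spacing isotropic voxel spacing (m).
#' @slot rho fluid density (kg/m^3).
#' @slot mu dynamic viscosity (kg m^-1 s^-1).
#' @export
setClass("AcquisitionMeta",
  representation(venc = "numeric", frameDuration = "numeric",
                 frames = "integer", heartRate = "numeric",
                 spacing = "numeric", rho = "numeric", mu = "numeric"),
  prototype(venc = 2.0, frameDuration = 0.014, frames = 40L,
            heartRate = 105, spacing = 2e-3, rho = 1089, mu = 3.7e-3))

setValidity("AcquisitionMeta", function(object) {
  msg <- character()
  if (length(object@venc) != 1 || object@venc <= 0)
    msg <- c(msg, "venc must be a single positive value (m/s)")
  if (length(object@frames) != 1 || object@frames < 1L)
    msg <- c(msg, "frames must be >= 1")
  if (length(object@spacing) != 1 || object@spacing <= 0)
    msg <- c(msg, "spacing must be positive (m)")
  if (object@frameDuration <= 0) msg <- c(msg, "frameDuration must be positive (s)")
  if (object@rho <= 0) msg <- c(msg, "rho must be positive (kg/m^3)")
  if (object@mu <= 0) msg <- c(msg, "mu must be positive (kg/m/s)")
  if (length(msg)) msg else TRUE
})

#' Fluid density and viscosity
#'
#' @slot rho density (kg/m^3).
#' @slot mu dynamic viscosity (kg m^-1 s^-1).
#' @export
setClass("FluidProperties",
  representation(rho = "numeric", mu = "numeric"),
  prototype(rho = 1089, mu = 3.7e-3))

setValidity("FluidProperties", function(object) {
  if (object@rho > 0 && object@mu > 0) TRUE else "rho and mu must be positive"
})

#' Construct fluid properties
#'
#' Defaults are the blood-mimicking water-glycerol mixture used for in
#' vitro total-artificial-heart testing: density 1089 kg/m^3 and dynamic
#' viscosity 3.7e-3 kg m^-1 s^-1.
#'
#' @param rho density (kg/m^3).
#' @param mu dynamic viscosity (kg m^-1 s^-1).
#' @return A [FluidProperties-class] object.
#' @export
fluidProperties <- function(rho = 1089, mu = 3.7e-3)
  new("FluidProperties", rho = rho, mu = mu)

#' A time-resolved three-directional velocity dataset
#'
#' The central container: velocity components on a regular voxel grid over
#' the cardiac cycle, optional magnitude volumes, a per-frame fluid mask
#' (the geometry may move during the cycle), acquisition metadata, and --
#' for synthetic phantoms -- closed-form ground truth attached by the
#' generator.
#'
#' @slot velocity 5-D array, dim (nx, ny, nz, nframes, 3); last index is
#'   the velocity component (x, y, z), in m/s.
#' @slot magnitude named list of 4-D magnitude arrays (arbitrary units),
#'   possibly empty; conventional names are \code{ref} and
#'   \code{venc_x/y/z} for turbulence-encoded pairs.
#' @slot mask 4-D logical array (nx, ny, nz, nframes); TRUE where the
#'   voxel is fluid in that frame.
#' @slot meta an [AcquisitionMeta-class].
#' @slot groundTruth list of analytic reference values attached by the
#'   phantom generators (empty for measured data).
#' @export
setClass("FlowDataset",
  representation(velocity = "array", magnitude = "list", mask = "array",
                 meta = "AcquisitionMeta", groundTruth = "list"))

setValidity("FlowDataset", function(object) {
  dv <- dim(object@velocity)
  msg <- character()
  if (length(dv) != 5 || dv[5] != 3)
    return("velocity must be a 5-D array (nx, ny, nz, nframes, 3)")
  dm <- dim(object@mask)
  if (!is.logical(object@mask) || length(dm) != 4 || any(dm != dv[1:4]))
    msg <- c(msg, "mask must be a logical 4-D array matching velocity")
  if (object@meta@frames != dv[4])
    msg <- c(msg, sprintf("meta@frames (%d) != velocity frames (%d)",
                          object@meta@frames, dv[4]))
  for (nm in names(object@magnitude)) {
    da <- dim(object@magnitude[[nm]])
    if (length(da) != 4 || any(da != dv[1:4]))
      msg <- c(msg, sprintf("magnitude '%s' does not match velocity shape", nm))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname FlowDataset-class
#' @param velocity,magnitude,mask,meta,groundTruth see the class slots.
#' @return \code{flowDataset()} returns a validated [FlowDataset-class].
#'   Speeds exceeding the VENC trigger a warning (possible phase wrap),
#'   not an error.
#' @export
flowDataset <- function(velocity, mask, meta, magnitude = list(),
                        groundTruth = list()) {
  storage.mode(velocity) <- "double"
  x <- new("FlowDataset", velocity = velocity, magnitude = magnitude,
           mask = mask, meta = meta, groundTruth = groundTruth)
  sp <- speedArray(x)
  nwrap <- sum(sp[mask] > meta@venc, na.rm = TRUE)
  if (nwrap > 0)
    warning(sprintf("%d masked voxel-frames exceed VENC = %.3g m/s (possible velocity wrap)",
                    nwrap, meta@venc), call. = FALSE)
  x
}

#' Second-order 3-D polynomial background-offset model
#'
#' One set of 10 monomial coefficients per velocity component, fitted on
#' coordinates normalised to [-1, 1] per axis. The basis order is
#' \{1, x, y, z, x^2, y^2, z^2, xy, xz, yz\}.
#'
#' @slot coefficients 10 x 3 numeric matrix (rows: monomials, columns:
#'   velocity components), m/s.
#' @slot bounds 2 x 3 matrix of world-coordinate normalisation bounds
#'   (rows lo/hi, columns x/y/z), metres; must span the full grid so the
#'   fit extrapolates stably.
#' @slot rms per-component RMS fit residual (m/s).
#' @export
setClass("BackgroundModel",
  representation(coefficients = "matrix", bounds = "matrix", rms = "numeric"))

setValidity("BackgroundModel", function(object) {
  msg <- character()
  if (!all(dim(object@coefficients) == c(10L, 3L)))
    msg <- c(msg, "coefficients must be 10 x 3 (10 monomials x 3 components)")
  if (!all(dim(object@bounds) == c(2L, 3L)) ||
      any(object@bounds[2, ] <= object@bounds[1, ]))
    msg <- c(msg, "bounds must be 2 x 3 with hi > lo per axis")
  if (length(msg)) msg else TRUE
})

#' Per-direction intravoxel velocity variance field
#'
#' Directional intravoxel velocity variances sigma_ii^2 estimated from the
#' attenuation of turbulence-encoded magnitude images relative to a
#' reference. Negative raw estimates (a known noise effect at low
#' turbulence levels) are clipped to zero and counted.
#'
#' @slot sigma2 5-D array (nx, ny, nz, nframes, 3) of variances (m^2/s^2).
#' @slot valid 4-D logical array; FALSE where a magnitude was non-positive.
#' @slot nClipped number of negative estimates clipped to zero.
#' @export
setClass("IVVVField",
  representation(sigma2 = "array", valid = "array", nClipped = "integer"))

setValidity("IVVVField", function(object) {
  if (min(object@sigma2, na.rm = TRUE) < 0) "stored variances must be >= 0" else TRUE
})

#' A per-voxel, per-frame derived scalar field
#'
#' Carrier for voxel-wise metrics (kinetic energy, viscous dissipation,
#' turbulent kinetic energy, scalar shear stress) with an explicit
#' validity flag and units, so downstream integrals and projections can
#' exclude voxels where the metric was not computable.
#'
#' @slot values 4-D numeric array (nx, ny, nz, nframes); NA where invalid.
#' @slot valid 4-D logical array.
#' @slot metric short metric name (e.g. "KE").
#' @slot units unit string (e.g. "J/m^3", "Pa", "1/s^2").
#' @slot spacing voxel spacing (m).
#' @export
setClass("ScalarMap",
  representation(values = "array", valid = "array", metric = "character",
                 units = "character", spacing = "numeric"))

setValidity("ScalarMap", function(object) {
  dv <- dim(object@values)
  if (length(dv) != 4) return("values must be a 4-D array")
  if (!all(dim(object@valid) == dv)) return("valid must match values shape")
  if (any(is.na(object@values[object@valid])))
    return("valid voxels must carry a value")
  TRUE
})

#' Voxel-wise velocity-gradient tensor
#'
#' d[i, j] = dv_i/dx_j (1/s) evaluated with a central-difference stencil
#' where both axis neighbours are inside the fluid mask, a one-sided
#' first-order difference where exactly one is, and flagged invalid
#' otherwise.
#'
#' @slot d 6-D array (nx, ny, nz, nframes, 3, 3); [.., i, j] = dv_i/dx_j.
#' @slot valid 4-D logical: TRUE where all nine entries are defined.
#' @slot spacing voxel spacing (m).
#' @slot nInvalid masked voxel-frames where at least one axis had no
#'   usable stencil.
#' @export
setClass("GradientTensorField",
  representation(d = "array", valid = "array", spacing = "numeric",
                 nInvalid = "integer"))

#' Relative-stasis map
#'
#' Fraction of the cardiac cycle each voxel spends below a speed
#' threshold. Only voxels inside the fluid mask at every frame are
#' eligible; voxels absent from any frame (moving walls) are excluded.
#'
#' @slot rstasis 3-D array of percentages (0-100); NA where ineligible.
#' @slot nStasis 3-D integer array of below-threshold frame counts.
#' @slot nTot total number of frames.
#' @slot eligible 3-D logical array.
#' @slot threshold speed threshold (m/s).
#' @export
setClass("StasisMap",
  representation(rstasis = "array", nStasis = "array", nTot = "integer",
                 eligible = "array", threshold = "numeric"))

setValidity("StasisMap", function(object) {
  v <- object@rstasis[object@eligible]
  if (length(v) && (min(v) < 0 || max(v) > 100))
    return("rstasis must lie in [0, 100]")
  ns <- object@nStasis[object@eligible]
  if (length(v) && max(abs(v - 100 * ns / object@nTot)) > 1e-9)
    return("rstasis must equal 100 * nStasis / nTot")
  TRUE
})

#' A per-frame scalar time series
#'
#' @slot values one value per frame.
#' @slot metric metric name.
#' @slot units unit string.
#' @slot frameDuration frame duration (s).
#' @export
setClass("TimeSeries",
  representation(values = "numeric", metric = "character",
                 units = "character", frameDuration = "numeric"))

#' Per-frame recirculation-zone size in a duct
#'
#' Height and length of the flow-separation zone derived from the
#' zero-axial-velocity isosurface, per timeframe, plus the same values
#' normalised by the duct height and length. Frames without reversed flow
#' carry zeros and \code{detected = FALSE}.
#'
#' @slot height zone height per frame (m), capped at the duct height.
#' @slot length zone length per frame (m), from the inner corner.
#' @slot heightNorm,lengthNorm normalised by duct height / duct length.
#' @slot detected logical per frame.
#' @slot ductHeight,ductLength duct dimensions used for normalisation (m).
#' @slot frameDuration frame duration (s).
#' @export
setClass("RecirculationTrace",
  representation(height = "numeric", length = "numeric",
                 heightNorm = "numeric", lengthNorm = "numeric",
                 detected = "logical", ductHeight = "numeric",
                 ductLength = "numeric", frameDuration = "numeric"))

setValidity("RecirculationTrace", function(object) {
  msg <- character()
  if (any(object@height < 0) || any(object@height > object@ductHeight + 1e-12))
    msg <- c(msg, "height must lie in [0, ductHeight]")
  if (any(object@length < 0)) msg <- c(msg, "length must be >= 0")
  if (any(object@height[!object@detected] != 0) ||
      any(object@length[!object@detected] != 0))
    msg <- c(msg, "undetected frames must carry zero size")
  if (length(msg)) msg else TRUE
})
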
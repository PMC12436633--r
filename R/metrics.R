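## Voxel-wise derived fields. Units: KE and TKE in J/m^3, dissipation
## phi_v in 1/s^2 (multiply by mu to get a power density), scalar shear
## stress tau in Pa.

.newScalarMap <- function(values, valid, metric, units, spacing) {
  values[!valid] <- NA_real_
  new("ScalarMap", values = values, valid = valid, metric = metric,
      units = units, spacing = spacing)
}

#' Kinetic energy density map
#'
#' KE = (rho/2) (ux^2 + uy^2 + uz^2) per voxel and frame, in J/m^3.
#'
#' @param data a [FlowDataset-class].
#' @param props a [FluidProperties-class]; default taken from the
#'   dataset's acquisition metadata.
#' @return a [ScalarMap-class], valid inside the fluid mask.
#' @export
kineticEnergyMap <- function(data, props = NULL) {
  stopifnot(is(data, "FlowDataset"))
  rho <- if (is.null(props)) data@meta@rho else props@rho
  v <- data@velocity
  ke <- (rho / 2) * (velComp(v, 1)^2 + velComp(v, 2)^2 + velComp(v, 3)^2)
  .newScalarMap(ke, data@mask, "KE", "J/m^3", spacing(data))
}

## One spatial derivative of a 4-D array (nx,ny,nz,nt) along `axis`,
## respecting the per-frame mask: central difference where both axis
## neighbours are masked, one-sided first-order where exactly one is,
## NA where neither. Returns list(g, ok).
.maskedDerivative <- function(a, mask, axis, h) {
  d <- dim(a)
  g <- array(NA_real_, d)
  ok <- array(FALSE, d)
  for (t in seq_len(d[4])) {
    at <- a[, , , t]; mt <- mask[, , , t]
    ap <- shift3(at, axis, 1L);  mp <- shift3(mt, axis, 1L, fill = FALSE)
    am <- shift3(at, axis, -1L); mm <- shift3(mt, axis, -1L, fill = FALSE)
    gt <- array(NA_real_, d[1:3])
    both <- mt & mp & mm
    gt[both] <- (ap[both] - am[both]) / (2 * h)
    fwd <- mt & mp & !mm
    gt[fwd] <- (ap[fwd] - at[fwd]) / h
    bwd <- mt & !mp & mm
    gt[bwd] <- (at[bwd] - am[bwd]) / h
    g[, , , t] <- gt
    ok[, , , t] <- both | fwd | bwd
  }
  list(g = g, ok = ok)
}

#' Voxel-wise velocity-gradient tensor
#'
#' Computes dv_i/dx_j with a central-difference stencil on the voxel
#' grid. At mask boundaries, where a central stencil would reach outside
#' the fluid, a one-sided first-order difference is used if one axis
#' neighbour is available; voxels with no usable stencil on some axis are
#' flagged invalid and excluded from all derived maps and integrals
#' (fabricating wall gradients would bias the shear and dissipation
#' fields). The number of excluded voxel-frames is logged and stored.
#'
#' @param data a [FlowDataset-class].
#' @return a [GradientTensorField-class].
#' @export
velocityGradients <- function(data) {
  stopifnot(is(data, "FlowDataset"))
  h <- spacing(data)
  d <- dim(data@velocity)
  g <- array(NA_real_, c(d[1:4], 3, 3))
  valid <- data@mask
  for (j in 1:3) {
    for (i in 1:3) {
      der <- .maskedDerivative(velComp(data@velocity, i), data@mask, j, h)
      g[, , , , i, j] <- der$g
      if (i == 1L) okj <- der$ok          # stencil support depends on axis only
    }
    valid <- valid & okj
  }
  nInvalid <- sum(data@mask & !valid)
  if (nInvalid > 0)
    flowLog("velocity gradients: %d masked voxel-frames lack a stencil on some axis",
            nInvalid)
  new("GradientTensorField", d = g, valid = valid, spacing = h,
      nInvalid = as.integer(nInvalid))
}

## Strain-rate machinery shared by dissipation and shear stress.
## f(Sij arrays, div) -> scalar array accumulator.
.strainReduce <- function(grad, f) {
  g <- grad@d
  d4 <- dim(g)[1:4]
  gij <- function(i, j) array(g[, , , , i, j, drop = FALSE], d4)
  div <- gij(1, 1) + gij(2, 2) + gij(3, 3)
  acc <- array(0, d4)
  for (i in 1:3) for (j in 1:3) {
    sij <- (gij(i, j) + gij(j, i)) / 2
    acc <- acc + f(sij, div, i == j)
  }
  acc
}

#' Viscous dissipation map
#'
#' phi_v = 1/2 sum_ij [ (dv_i/dx_j + dv_j/dx_i)
#'                      - (2/3) (div v) delta_ij ]^2, in 1/s^2.
#'
#' The divergence term is retained as written even though the fluid is
#' nominally incompressible: measured fields have nonzero discrete
#' divergence from noise and discretisation, and dropping the term would
#' change the noise response. Multiplying the volume integral by mu gives
#' the viscous energy loss E_L' in W (see [integrateOverRegion()]).
#'
#' @param grad a [GradientTensorField-class].
#' @return a [ScalarMap-class].
#' @export
viscousDissipationMap <- function(grad) {
  stopifnot(is(grad, "GradientTensorField"))
  phi <- .strainReduce(grad, function(sij, div, diag)
    (2 * sij - if (diag) (2 / 3) * div else 0)^2) / 2
  phi[!grad@valid] <- NA_real_
  .newScalarMap(phi, grad@valid & !is.na(phi), "phi_v", "1/s^2", grad@spacing)
}

#' Scalar shear stress map
#'
#' tau = mu sqrt(2 S_ij S_ij), the viscosity times the Frobenius norm of
#' the strain-rate tensor S_ij = (dv_i/dx_j + dv_j/dx_i)/2, in Pa.
#'
#' @param grad a [GradientTensorField-class].
#' @param props a [FluidProperties-class].
#' @return a [ScalarMap-class].
#' @export
scalarShearStressMap <- function(grad, props = fluidProperties()) {
  stopifnot(is(grad, "GradientTensorField"))
  ss <- .strainReduce(grad, function(sij, div, diag) sij^2)
  tau <- props@mu * sqrt(2 * ss)
  tau[!grad@valid] <- NA_real_
  .newScalarMap(tau, grad@valid & !is.na(tau), "tau", "Pa", grad@spacing)
}

#' Turbulent kinetic energy map
#'
#' TKE = (rho/2) (sigma_xx^2 + sigma_yy^2 + sigma_zz^2) in J/m^3, from the
#' directional intravoxel velocity variances of [estimateIVVV()].
#'
#' @param ivvv an [IVVVField-class].
#' @param props a [FluidProperties-class].
#' @param spacing voxel spacing (m), carried into the map for integration.
#' @return a [ScalarMap-class].
#' @export
tkeMap <- function(ivvv, props = fluidProperties(), spacing = NA_real_) {
  stopifnot(is(ivvv, "IVVVField"))
  s2 <- ivvv@sigma2
  tke <- (props@rho / 2) * (velComp(s2, 1) + velComp(s2, 2) + velComp(s2, 3))
  .newScalarMap(tke, ivvv@valid, "TKE", "J/m^3", spacing)
}

#' Relative stasis map
#'
#' Per voxel, the percentage of the cardiac cycle with speed strictly
#' below the threshold: r_stasis = 100 n_stasis / N_tot, where n_stasis
#' counts frames with |u| < threshold. Only voxels present in the fluid
#' mask at every frame are eligible; voxels near moving walls that leave
#' the mask in any frame are excluded (their Eulerian time fraction would
#' be meaningless).
#'
#' @param data a [FlowDataset-class].
#' @param threshold speed threshold (m/s); the conventional default for
#'   blood-stasis mapping is 0.1 m/s.
#' @return a [StasisMap-class].
#' @export
relativeStasis <- function(data, threshold = 0.1) {
  stopifnot(is(data, "FlowDataset"))
  if (threshold <= 0) stop("stasis threshold must be positive (m/s)")
  sp <- speedArray(data)
  nt <- dim(sp)[4]
  eligible <- apply(data@mask, 1:3, all)
  if (!any(eligible))
    warning("no voxels are in the fluid mask at every frame: empty stasis map",
            call. = FALSE)
  slow <- sp < threshold
  nStasis <- apply(slow, 1:3, sum)
  nExcluded <- sum(apply(data@mask, 1:3, any) & !eligible)
  if (nExcluded > 0)
    flowLog("stasis: excluded %d voxels not present throughout the cycle", nExcluded)
  r <- 100 * nStasis / nt
  r[!eligible] <- NA_real_
  nStasis[!eligible] <- NA_integer_
  new("StasisMap", rstasis = r, nStasis = nStasis, nTot = as.integer(nt),
      eligible = eligible, threshold = threshold)
}
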
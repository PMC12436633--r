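## Background phase-offset correction, magnitude segmentation, and
## estimation of intravoxel velocity variation from magnitude pairs.

.monomialNames <- c("1", "x", "y", "z", "x2", "y2", "z2", "xy", "xz", "yz")

## Second-order monomial design matrix on coordinates normalised to
## [-1, 1] per axis (conditioning; raw-coordinate fits are not offered).
.polyBasis <- function(xyz, bounds) {
  n <- lapply(1:3, function(a)
    2 * (xyz[, a] - bounds[1, a]) / (bounds[2, a] - bounds[1, a]) - 1)
  x <- n[[1]]; y <- n[[2]]; z <- n[[3]]
  cbind(1, x, y, z, x^2, y^2, z^2, x * y, x * z, y * z,
        deparse.level = 0)
}

.gridBounds <- function(dims, spacing) {
  cc <- voxelCenters(dims, spacing)
  b <- vapply(cc, range, numeric(2))
  dimnames(b) <- list(c("lo", "hi"), c("x", "y", "z"))
  b
}

#' Construct a background-offset model from known coefficients
#'
#' Mostly used to inject known offsets into synthetic data (see
#' [injectBackgroundOffset()]); [fitBackground()] builds fitted models.
#'
#' @param coefficients 10 x 3 matrix, monomial order
#'   \{1, x, y, z, x^2, y^2, z^2, xy, xz, yz\} on [-1, 1]-normalised
#'   coordinates; columns are the velocity components.
#' @param bounds 2 x 3 matrix of world-coordinate normalisation bounds
#'   (rows lo/hi), or a [FlowDataset-class] whose grid supplies them.
#' @param rms per-component RMS residual (m/s), zero for constructed models.
#' @return a [BackgroundModel-class].
#' @export
backgroundModel <- function(coefficients, bounds, rms = numeric(3)) {
  if (is(bounds, "FlowDataset"))
    bounds <- .gridBounds(dim(bounds@velocity)[1:3], spacing(bounds))
  coefficients <- as.matrix(coefficients)
  dimnames(coefficients) <- list(.monomialNames, c("x", "y", "z"))
  new("BackgroundModel", coefficients = coefficients,
      bounds = bounds, rms = rms)
}

## Polynomial evaluated at every voxel centre; returns (nx, ny, nz, 3).
evaluateBackground <- function(model, dims, spacing) {
  cc <- voxelCenters(dims, spacing)
  xyz <- cbind(rep(cc[[1]], times = dims[2] * dims[3]),
               rep(rep(cc[[2]], each = dims[1]), times = dims[3]),
               rep(cc[[3]], each = dims[1] * dims[2]))
  X <- .polyBasis(xyz, model@bounds)
  array(X %*% model@coefficients, c(dims[1:3], 3))
}

#' Fit the background-offset polynomial to a static acquisition
#'
#' Phase-contrast velocity data carry a smooth spatial background offset.
#' It is estimated from an acquisition with the pump off and no flow,
#' where the true velocity is zero everywhere: a second-order 3-D
#' polynomial is fitted per velocity component by ordinary least squares
#' over the masked fluid voxels, after averaging the frames of the static
#' series (noise reduction). The model is later extrapolated to the whole
#' volume and subtracted.
#'
#' @param static a [FlowDataset-class] acquired at zero true velocity.
#' @param mask 3-D logical array of fluid voxels to fit over; default the
#'   intersection of the static dataset's per-frame masks. Needs at least
#'   10 voxels with full-rank spatial spread.
#' @return a [BackgroundModel-class]; \code{coef()} gives the 10 x 3
#'   coefficient matrix, slot \code{rms} the per-component residual.
#' @seealso [applyBackgroundCorrection()], [injectBackgroundOffset()]
#' @export
fitBackground <- function(static, mask = NULL) {
  stopifnot(is(static, "FlowDataset"))
  dims <- dim(static@velocity)[1:3]
  if (is.null(mask)) mask <- apply(static@mask, 1:3, all)
  if (sum(mask) < 10)
    stop("background fit needs at least 10 masked voxels")
  bounds <- .gridBounds(dims, spacing(static))
  cc <- voxelCenters(dims, spacing(static))
  idx <- which(mask, arr.ind = TRUE)
  xyz <- cbind(cc[[1]][idx[, 1]], cc[[2]][idx[, 2]], cc[[3]][idx[, 3]])
  X <- .polyBasis(xyz, bounds)
  qrX <- qr(X)
  if (qrX$rank < 10L)
    stop(sprintf(paste0("rank-deficient background design (rank %d < 10): ",
                        "the mask has degenerate spatial spread ",
                        "(e.g. coplanar voxels)"), qrX$rank))
  nt <- dim(static@velocity)[4]
  coefs <- matrix(0, 10, 3)
  rms <- numeric(3)
  for (i in 1:3) {
    vmean <- apply(static@velocity[, , , , i, drop = FALSE], 1:3, mean)
    yv <- vmean[mask]
    coefs[, i] <- qr.coef(qrX, yv)
    rms[i] <- sqrt(mean(qr.resid(qrX, yv)^2))
  }
  flowLog("background fit over %d voxels (frames averaged: %d); RMS residual %.3g/%.3g/%.3g m/s",
          sum(mask), nt, rms[1], rms[2], rms[3])
  backgroundModel(coefs, bounds, rms)
}

#' Subtract a fitted background offset from a dataset
#'
#' Evaluates the polynomial at every voxel of the target grid -- including
#' voxels outside the static-acquisition mask, i.e. the fit is
#' extrapolated to the entire volume -- and subtracts it from every
#' velocity component of every frame.
#'
#' @param data a [FlowDataset-class].
#' @param model a [BackgroundModel-class] fitted on the same grid
#'   geometry (spacing and extents must match the model's bounds).
#' @return the corrected dataset.
#' @export
applyBackgroundCorrection <- function(data, model) {
  stopifnot(is(data, "FlowDataset"), is(model, "BackgroundModel"))
  dims <- dim(data@velocity)[1:3]
  if (max(abs(.gridBounds(dims, spacing(data)) - model@bounds)) > 1e-9)
    stop("grid geometry of data does not match the background model bounds")
  off <- evaluateBackground(model, dims, spacing(data))
  vel <- data@velocity
  for (i in 1:3)
    vel[, , , , i] <- vel[, , , , i] - as.vector(off[, , , i])
  methods::initialize(data, velocity = vel)
}

#' Segment the fluid domain by a magnitude threshold
#'
#' Voxels with magnitude >= threshold are fluid; optionally only the
#' largest 6-connected component is kept (a standard cleanup for
#' disconnected noise specks). Works per frame when the magnitude is 4-D.
#' An empty result is allowed (with a warning): thresholds are
#' user-supplied and an over-tight one is a data problem, not a crash.
#'
#' @param magnitude 3-D or 4-D magnitude array.
#' @param threshold scalar threshold in magnitude units.
#' @param keepLargest keep only the largest 6-connected component.
#' @return logical array of the magnitude's shape.
#' @export
segmentByThreshold <- function(magnitude, threshold, keepLargest = FALSE) {
  d <- dim(magnitude)
  if (length(d) == 3) {
    m <- magnitude >= threshold
    if (keepLargest && any(m)) m <- labelComponents6(m) == 1L
    if (!any(m)) warning("threshold excludes all voxels: empty mask", call. = FALSE)
    return(m)
  }
  stopifnot(length(d) == 4)
  out <- array(FALSE, d)
  for (t in seq_len(d[4]))
    out[, , , t] <- segmentByThreshold(magnitude[, , , t], threshold, keepLargest)
  out
}

#' Estimate intravoxel velocity variation from magnitude pairs
#'
#' Inverts the Gaussian intravoxel velocity-distribution signal model:
#' the per-direction intravoxel velocity variance is
#' \code{sigma_i^2 = (2 / kv^2) ln(mag_ref / mag_venc_i)} with
#' \code{kv = pi / VENC}. Negative raw estimates -- common where true
#' turbulence intensity is low and noise dominates -- are clipped to zero
#' and counted; voxels with a non-positive magnitude are flagged invalid.
#'
#' @param magRef 4-D reference (flow-compensated) magnitude array.
#' @param magVenc named list of 4-D velocity-encoded magnitudes, in
#'   component order (x, y, z).
#' @param venc velocity encoding limit (m/s).
#' @param mask optional 4-D logical restriction; default all voxels.
#' @return an [IVVVField-class] of directional variances (m^2/s^2).
#' @export
estimateIVVV <- function(magRef, magVenc, venc, mask = NULL) {
  stopifnot(length(magVenc) == 3, venc > 0)
  d <- dim(magRef)
  if (is.null(mask)) mask <- array(TRUE, d)
  kv <- pi / venc
  sigma2 <- array(0, c(d, 3))
  valid <- mask
  nclip <- 0L
  for (i in 1:3) {
    mv <- magVenc[[i]]
    bad <- mask & (magRef <= 0 | mv <= 0)
    valid <- valid & !bad
    s2 <- (2 / kv^2) * log(pmax(magRef, .Machine$double.xmin) /
                           pmax(mv, .Machine$double.xmin))
    neg <- valid & s2 < 0
    nclip <- nclip + sum(neg)
    s2[neg] <- 0
    s2[!valid] <- 0
    sigma2[, , , , i] <- s2
  }
  if (nclip > 0)
    flowLog("IVVV: clipped %d negative variance estimates to zero", nclip)
  if (any(mask & !valid))
    flowLog("IVVV: %d voxel-frames with non-positive magnitude flagged invalid",
            sum(mask & !valid))
  new("IVVVField", sigma2 = sigma2, valid = valid, nClipped = as.integer(nclip))
}

#' Serialise a background model to JSON
#'
#' @param model a [BackgroundModel-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeBackgroundModel <- function(model, path) {
  jsonlite::write_json(
    list(schema_version = 1L, basis = .monomialNames,
         coefficients = model@coefficients, bounds = model@bounds,
         rms = model@rms),
    path, digits = NA, auto_unbox = TRUE, matrix = "columnmajor")
  invisible(path)
}

#' @rdname writeBackgroundModel
#' @export
readBackgroundModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ## read_json simplifies a list of column arrays to a (ncol x nrow) matrix
  cf <- if (is.matrix(j$coefficients)) t(j$coefficients) else
    matrix(unlist(j$coefficients), 10, 3)
  bd <- if (is.matrix(j$bounds)) t(j$bounds) else matrix(unlist(j$bounds), 2, 3)
  dimnames(bd) <- list(c("lo", "hi"), c("x", "y", "z"))
  backgroundModel(cf, bd, as.numeric(j$rms))
}
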
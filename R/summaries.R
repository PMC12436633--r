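## Integrated and summary quantities: cross-sectional flow rate, stroke
## volume, Reynolds number, regional volume integrals, maximum-intensity
## projections, histograms, quartiles, and line profiles.

#' Define an axis-aligned cross-section
#'
#' A voxel plane perpendicular to one grid axis, with an in-plane region
#' mask. The cross-sectional area is the in-mask pixel count times the
#' pixel area; the hydraulic diameter defaults to 4A/P with the perimeter
#' P measured from the mask's exposed pixel edges, and reduces to the
#' geometric diameter for circular sections (an explicit diameter can be
#' supplied instead).
#'
#' @param axis normal axis, 1-3 or "x"/"y"/"z".
#' @param sliceIndex voxel index of the plane along \code{axis}.
#' @param mask in-plane 2-D logical mask (dims of the two remaining axes,
#'   in grid order).
#' @param spacing voxel spacing (m).
#' @param direction +1 or -1: sign convention for the normal velocity.
#' @param diameter optional explicit diameter (m) overriding 4A/P.
#' @return a validated \code{CrossSection} (list) with \code{area} (m^2)
#'   and \code{diameter} (m).
#' @export
crossSection <- function(axis, sliceIndex, mask, spacing,
                         direction = 1, diameter = NULL) {
  axis <- .componentIndex(axis)
  stopifnot(is.matrix(mask) || is.array(mask), spacing > 0,
            direction %in% c(-1, 1))
  npix <- sum(mask)
  if (npix == 0) stop("cross-section mask is empty")
  area <- npix * spacing^2
  ## exposed-edge perimeter: per pixel, 4-neighbourhood faces out of mask
  m <- mask
  edges <- sum(m & !rbind(m[-1, , drop = FALSE], FALSE)) +
           sum(m & !rbind(FALSE, m[-nrow(m), , drop = FALSE])) +
           sum(m & !cbind(m[, -1, drop = FALSE], FALSE)) +
           sum(m & !cbind(FALSE, m[, -ncol(m), drop = FALSE]))
  perim <- edges * spacing
  if (is.null(diameter)) diameter <- 4 * area / perim
  structure(list(axis = axis, sliceIndex = as.integer(sliceIndex),
                 mask = mask, spacing = spacing, direction = direction,
                 area = area, perimeter = perim, diameter = diameter),
            class = "CrossSection")
}

## Extract the in-plane slab of a 4-D array at a cross-section.
.sliceArray <- function(a, axis, idx) {
  switch(axis,
         a[idx, , , , drop = FALSE],
         a[, idx, , , drop = FALSE],
         a[, , idx, , drop = FALSE])
}

#' Volumetric flow rate through a cross-section
#'
#' q(t) = sum over in-plane pixels of u_N * pixel area, the discrete form
#' of q = u_N A, signed by the section's normal direction. Pixels of the
#' section lying outside the fluid mask in some frame contribute their
#' (zero-filled) velocity and are logged.
#'
#' @param data a [FlowDataset-class].
#' @param section a [crossSection()].
#' @return a [TimeSeries-class] in m^3/s.
#' @export
flowRate <- function(data, section) {
  stopifnot(is(data, "FlowDataset"), inherits(section, "CrossSection"))
  d <- dim(data@velocity)
  if (section$sliceIndex < 1 || section$sliceIndex > d[section$axis])
    stop("slice index outside the grid")
  vN <- .sliceArray(velComp(data@velocity, section$axis), section$axis,
                    section$sliceIndex)
  mk <- .sliceArray(data@mask, section$axis, section$sliceIndex)
  nt <- d[4]
  q <- numeric(nt)
  nOut <- 0L
  h2 <- section$spacing^2
  ## reshape: drop the normal axis, keep (in-plane 2-D, time)
  vN <- array(vN, dim(vN)[c(setdiff(1:3, section$axis), 4)])
  mk <- array(mk, dim(mk)[c(setdiff(1:3, section$axis), 4)])
  for (t in seq_len(nt)) {
    vt <- vN[, , t]
    mt <- mk[, , t]
    nOut <- nOut + sum(section$mask & !mt)
    q[t] <- section$direction * sum(vt[section$mask]) * h2
  }
  if (nOut > 0)
    flowLog("flow rate: %d section pixel-frames lie outside the fluid mask", nOut)
  new("TimeSeries", values = q, metric = "q", units = "m^3/s",
      frameDuration = frameDuration(data))
}

#' Stroke volume and cardiac output from a flow-rate series
#'
#' Integrates one cycle of q(t) with the rectangle rule on the uniform
#' frame grid (the cycle is treated as periodic, so the rectangle rule is
#' the natural choice and introduces no endpoint bias).
#'
#' @param q a [TimeSeries-class] of flow rate in m^3/s covering one cycle.
#' @param heartRate beats per minute; if supplied, cardiac output is
#'   reported too.
#' @return list with \code{strokeVolume_mL} and, when heartRate is given,
#'   \code{cardiacOutput_Lmin}.
#' @export
strokeVolume <- function(q, heartRate = NULL) {
  stopifnot(is(q, "TimeSeries"))
  if (!length(q@frameDuration) || is.na(q@frameDuration) || q@frameDuration <= 0)
    stop("stroke volume needs a positive frame duration")
  sv_m3 <- sum(q@values) * q@frameDuration
  out <- list(strokeVolume_mL = sv_m3 * 1e6)
  if (!is.null(heartRate))
    out$cardiacOutput_Lmin <- sv_m3 * 1e3 * heartRate
  out
}

#' Reynolds number at peak flow
#'
#' Re = rho q_max d / (mu A), with q_max the peak flow rate through the
#' section over the cycle, d its (hydraulic) diameter and A its area.
#'
#' @param qmax peak flow rate (m^3/s).
#' @param diameter section diameter (m).
#' @param area section area (m^2).
#' @param props a [FluidProperties-class].
#' @return the dimensionless Reynolds number.
#' @export
reynoldsNumber <- function(qmax, diameter, area, props = fluidProperties()) {
  if (area <= 0) stop("section area must be positive")
  if (qmax <= 0 || diameter <= 0) stop("qmax and diameter must be positive")
  props@rho * qmax * diameter / (props@mu * area)
}

#' Integrate a scalar map over a region
#'
#' Per frame, sums value * voxel volume over the valid in-region voxels.
#' For a dissipation map (units 1/s^2) the result is multiplied by the
#' dynamic viscosity, yielding the viscous energy loss
#' E_L' = mu sum phi_v V_i in W; energy-density maps (KE, TKE, J/m^3)
#' integrate to J.
#'
#' @param map a [ScalarMap-class].
#' @param region 3-D logical mask (applied at every frame).
#' @param props a [FluidProperties-class] (needed for dissipation maps).
#' @return a [TimeSeries-class] (W for dissipation input, J for energy
#'   densities, else value * m^3).
#' @export
integrateOverRegion <- function(map, region, props = fluidProperties()) {
  stopifnot(is(map, "ScalarMap"))
  if (!any(region)) stop("region is empty")
  d <- dim(map@values)
  vvox <- map@spacing^3
  if (!is.finite(vvox)) stop("map carries no spacing; cannot integrate")
  vals <- numeric(d[4])
  for (t in seq_len(d[4])) {
    ok <- map@valid[, , , t] & region
    if (!any(ok))
      stop(sprintf("no valid in-region voxels in frame %d", t))
    vals[t] <- sum(map@values[, , , t][ok]) * vvox
  }
  if (map@units == "1/s^2") {
    new("TimeSeries", values = props@mu * vals, metric = "E_L'",
        units = "W", frameDuration = NA_real_)
  } else if (map@units == "J/m^3") {
    new("TimeSeries", values = vals, metric = paste0(map@metric, "_total"),
        units = "J", frameDuration = NA_real_)
  } else {
    new("TimeSeries", values = vals, metric = paste0(map@metric, "_total"),
        units = paste0(map@units, ".m^3"), frameDuration = NA_real_)
  }
}

#' Maximum-intensity projection over the cycle
#'
#' Per pixel, the maximum over all timeframes and over the projection
#' direction, ignoring invalid voxels; no smoothing or filtering is
#' applied. Pixels whose entire ray is invalid become NA.
#'
#' @param map a [ScalarMap-class].
#' @param axis projection axis, 1-3 or "x"/"y"/"z".
#' @return a 2-D matrix (remaining axes in grid order).
#' @export
mip <- function(map, axis) {
  stopifnot(is(map, "ScalarMap"))
  axis <- .componentIndex(axis)
  keep <- setdiff(1:3, axis)
  v <- map@values                    # invalid entries are NA already
  out <- apply(v, keep, function(ray) {
    if (all(is.na(ray))) NA_real_ else max(ray, na.rm = TRUE)
  })
  out
}

#' @rdname mip
#' @details \code{temporalMax()} is the intermediate product: the
#'   per-voxel maximum over the cycle, as a 3-D volume.
#' @export
temporalMax <- function(map) {
  stopifnot(is(map, "ScalarMap"))
  apply(map@values, 1:3, function(ts) {
    if (all(is.na(ts))) NA_real_ else max(ts, na.rm = TRUE)
  })
}

#' Fixed-width histogram of a scalar map
#'
#' Pools all valid voxel-frame samples over the entire cycle into
#' fixed-width bins anchored at zero, reporting per-bin percentages plus
#' the sample mean and maximum. The conventional bin width for scalar
#' shear stress is 0.02 Pa.
#'
#' @param map a [ScalarMap-class].
#' @param binWidth bin width in the map's units (> 0).
#' @return a \code{HistogramResult} (list): \code{breaks}, \code{mid},
#'   \code{percent}, \code{mean}, \code{max}, \code{n}.
#' @export
metricHistogram <- function(map, binWidth = 0.02) {
  stopifnot(is(map, "ScalarMap"), binWidth > 0)
  x <- map@values[map@valid]
  if (min(x) < 0)
    stop("histogram bins are anchored at zero; map has negative samples")
  nb <- max(1L, ceiling((max(x) + .Machine$double.eps) / binWidth))
  breaks <- seq(0, nb * binWidth, by = binWidth)
  cnt <- tabulate(pmin(findInterval(x, breaks, left.open = FALSE), nb), nb)
  structure(list(breaks = breaks, mid = breaks[-1] - binWidth / 2,
                 percent = 100 * cnt / length(x),
                 mean = mean(x), max = max(x), n = length(x),
                 units = map@units),
            class = "HistogramResult")
}

#' Bundle named region masks
#'
#' @param ... named 3-D logical arrays of identical shape (e.g. inlet,
#'   atrium, ventricle, outflow tract, whole device).
#' @return a validated \code{RegionSet} (named list).
#' @export
regionSet <- function(...) {
  regions <- list(...)
  if (length(regions) == 1 && is.list(regions[[1]]) && is.null(dim(regions[[1]])))
    regions <- regions[[1]]
  nms <- names(regions)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms))
    stop("regions must have unique non-empty names")
  d <- dim(regions[[1]])
  for (r in regions)
    if (!is.logical(r) || !identical(dim(r), d))
      stop("all region masks must be logical arrays of identical shape")
  structure(regions, class = "RegionSet")
}

#' Median and quartiles per region
#'
#' Pools the valid voxel(-frame) samples of a map inside each region and
#' reports median, Q1 and Q3. Quantiles use linear interpolation between
#' order statistics (\code{stats::quantile} type 7), fixed for
#' reproducibility. Empty regions are skipped with a warning.
#'
#' @param map a [ScalarMap-class] (samples pooled over all frames) or
#'   [StasisMap-class] (one sample per eligible voxel).
#' @param regions a [regionSet()].
#' @return data.frame with columns region, n, q1, median, q3.
#' @export
regionQuartiles <- function(map, regions) {
  stopifnot(inherits(regions, "RegionSet"))
  rows <- lapply(names(regions), function(nm) {
    reg <- regions[[nm]]
    if (is(map, "StasisMap")) {
      x <- map@rstasis[map@eligible & reg]
    } else {
      stopifnot(is(map, "ScalarMap"))
      nt <- dim(map@values)[4]
      reg4 <- array(reg, dim(map@values))
      x <- map@values[map@valid & reg4]
    }
    if (!length(x)) {
      warning(sprintf("region '%s' has no valid samples: skipped", nm),
              call. = FALSE)
      return(NULL)
    }
    qs <- stats::quantile(x, c(.25, .5, .75), type = 7, names = FALSE)
    data.frame(region = nm, n = length(x), q1 = qs[1], median = qs[2],
               q3 = qs[3])
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Velocity profile along a line
#'
#' Trilinearly interpolates the line-tangent velocity component at
#' equally spaced sample points between two world-coordinate endpoints,
#' for every frame. Samples whose 8-voxel interpolation stencil is not
#' fully inside the fluid mask are flagged.
#'
#' @param data a [FlowDataset-class].
#' @param from,to endpoints in world coordinates (m), length 3.
#' @param n number of sample points.
#' @param component which velocity component to sample: "tangent" (the
#'   component along the line, for centreline profiles) or a fixed axis
#'   1-3 / "x"/"y"/"z" (for diameter profiles of the axial velocity).
#' @return list: \code{s} (distance along the line, m), \code{profile}
#'   (n x nframes matrix, m/s), \code{inMask} (n x nframes logical).
#' @export
velocityProfile <- function(data, from, to, n = 50, component = "tangent") {
  stopifnot(is(data, "FlowDataset"), length(from) == 3, length(to) == 3)
  h <- spacing(data)
  d <- dim(data@velocity)
  lim <- d[1:3] * h
  if (any(from < 0 | from > lim) || any(to < 0 | to > lim))
    stop("profile line endpoints must lie within the grid")
  tang <- (to - from) / sqrt(sum((to - from)^2))
  proj <- if (identical(component, "tangent")) tang else {
    w <- numeric(3); w[.componentIndex(component)] <- 1; w
  }
  s <- seq(0, sqrt(sum((to - from)^2)), length.out = n)
  pts <- cbind(from[1] + s * tang[1], from[2] + s * tang[2],
               from[3] + s * tang[3])
  nt <- d[4]
  prof <- matrix(NA_real_, n, nt)
  inm <- matrix(FALSE, n, nt)
  for (t in seq_len(nt)) {
    acc <- numeric(n); ok <- rep(TRUE, n)
    mt <- data@mask[, , , t]
    for (i in which(proj != 0)) {
      tri <- trilinear(array(data@velocity[, , , t, i], d[1:3]), mt, h, pts)
      acc <- acc + proj[i] * tri$value
      ok <- ok & tri$inMask
    }
    prof[, t] <- acc
    inm[, t] <- ok
  }
  nOut <- sum(!inm)
  if (nOut > 0)
    flowLog("velocity profile: %d of %d samples leave the fluid mask",
            nOut, length(inm))
  list(s = s, profile = prof, inMask = inm)
}
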
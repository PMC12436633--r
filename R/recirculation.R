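## Detection and sizing of the flow-separation (recirculation) zone in a
## duct from the zero-axial-velocity isosurface, frame by frame.

#' Declare the duct frame for recirculation detection
#'
#' The duct's axial and wall-normal directions are declared by the user,
#' not inferred: bend geometries differ and the inner-corner reference
#' point is a modelling choice. The inner wall is the duct face the
#' wall-normal direction points away from.
#'
#' @param axis streamwise grid axis, 1-3 or "x"/"y"/"z".
#' @param normalAxis wall-normal grid axis (must differ from \code{axis}).
#' @param corner inner-corner reference point, world coordinates (m),
#'   length 3. Zone length is measured streamwise from here; wall-normal
#'   distances are measured from its \code{normalAxis} coordinate.
#' @param height duct height H along the wall-normal axis (m).
#' @param length duct length along the axis, from the corner (m).
#' @param mask optional 3-D logical array restricting the search.
#' @param axialDirection,normalDirection +1 or -1: orientation of forward
#'   flow along \code{axis}, and of "into the duct" along
#'   \code{normalAxis}.
#' @return a validated \code{DuctSpec} (list).
#' @export
ductSpec <- function(axis, normalAxis, corner, height, length,
                     mask = NULL, axialDirection = 1, normalDirection = 1) {
  axis <- .componentIndex(axis)
  normalAxis <- .componentIndex(normalAxis)
  if (axis == normalAxis) stop("axial and wall-normal axes must differ")
  stopifnot(height > 0, length > 0, length(corner) == 3,
            axialDirection %in% c(-1, 1), normalDirection %in% c(-1, 1))
  structure(list(axis = axis, normalAxis = normalAxis,
                 corner = as.numeric(corner), height = height,
                 length = length, mask = mask,
                 axialDirection = axialDirection,
                 normalDirection = normalDirection),
            class = "DuctSpec")
}

#' Detect and size the recirculation zone
#'
#' Per frame: (a) the 6-connected set of in-duct voxels with negative
#' axial velocity that touches the inner wall is located (detached
#' reversed pockets are ignored and counted); (b) the zero-crossing
#' surface is found by linear interpolation along the wall-normal
#' direction between sign-changing voxel pairs; (c) the zone height is
#' twice the maximum wall-normal distance of that surface from the inner
#' wall -- the isosurface is assumed to pass through the core of the
#' recirculation, i.e. at half its total height -- capped at the duct
#' height; (d) the zone length is the streamwise distance from the inner
#' corner to the furthest point where the axial velocity in the first
#' off-wall voxel layer returns positive, with sub-voxel linear
#' interpolation along the axis. Frames with no attached reversed flow
#' yield zero height and length with \code{detected = FALSE}.
#'
#' @param data a [FlowDataset-class].
#' @param duct a [ductSpec()].
#' @return a [RecirculationTrace-class].
#' @export
detectRecirculation <- function(data, duct) {
  stopifnot(is(data, "FlowDataset"), inherits(duct, "DuctSpec"))
  h <- spacing(data)
  d <- dim(data@velocity)
  lim <- d[1:3] * h
  if (any(duct$corner < 0 | duct$corner > lim))
    stop("duct corner reference lies outside the grid")
  nt <- d[4]
  ax <- duct$axis; nx <- duct$normalAxis
  tr <- setdiff(1:3, c(ax, nx))
  perm <- c(nx, ax, tr)
  cc <- voxelCenters(d, h)
  sCoord <- duct$normalDirection * (cc[[nx]] - duct$corner[nx])
  aCoord <- duct$axialDirection * (cc[[ax]] - duct$corner[ax])
  dmask <- if (is.null(duct$mask)) array(TRUE, d[1:3]) else duct$mask
  H <- duct$height; L <- duct$length
  hgt <- len <- numeric(nt)
  det <- logical(nt)
  nPockets <- 0L
  for (t in seq_len(nt)) {
    m3 <- data@mask[, , , t] & dmask
    if (!any(m3)) next
    u <- duct$axialDirection * data@velocity[, , , t, ax]
    neg <- m3 & u < 0
    U <- aperm(u, perm); M <- aperm(m3, perm)
    dN <- dim(U)[1]; dA <- dim(U)[2]; dT <- dim(U)[3]
    ## first off-wall layer: per (axial, transverse) column, the in-mask
    ## voxel nearest the inner wall (smallest wall-normal coordinate)
    sOrd <- order(sCoord)
    LAY <- array(FALSE, dim(U))
    for (j in seq_len(dA)) for (k in seq_len(dT)) {
      col <- sOrd[M[sOrd, j, k]]
      if (length(col)) LAY[col[1], j, k] <- TRUE
    }
    layer3 <- aperm(LAY, order(perm))
    if (!any(neg)) next
    lab <- labelComponents6(neg)
    wallLabs <- setdiff(unique(lab[layer3 & neg]), 0L)
    nPockets <- nPockets + length(setdiff(unique(lab[lab > 0L]), wallLabs))
    if (!length(wallLabs)) next
    att3 <- array(lab %in% wallLabs, dim(lab))
    ATT <- aperm(att3, perm)
    ## (b,c) zero-crossing surface along the wall-normal direction
    smax <- 0
    for (j in seq_len(dA)) for (k in seq_len(dT)) {
      col <- sOrd[M[sOrd, j, k]]
      ncol <- length(col)
      if (!ncol || !any(ATT[col, j, k])) next
      for (p in seq_len(ncol)) {
        i <- col[p]
        if (!ATT[i, j, k]) next
        if (p == ncol) { smax <- max(smax, H); next }  # reversed to the far wall
        q <- col[p + 1]
        uq <- U[q, j, k]
        if (uq >= 0) {
          sc <- sCoord[i] + (sCoord[q] - sCoord[i]) *
            U[i, j, k] / (U[i, j, k] - uq)
          smax <- max(smax, sc)
        }
      }
    }
    ## (d) length along the first off-wall layer
    aOrd <- order(aCoord)
    gA <- rep(NA_real_, dA); revA <- rep(FALSE, dA)
    for (j in seq_len(dA)) {
      lm <- LAY[, j, , drop = FALSE]
      if (!any(lm)) next
      uj <- U[, j, , drop = FALSE][lm]
      gA[j] <- min(uj)
      revA[j] <- any(ATT[, j, , drop = FALSE][lm] & uj < 0)
    }
    ja <- aOrd[aCoord[aOrd] >= -h / 2 & !is.na(gA[aOrd])]
    lent <- 0
    if (any(revA[ja])) {
      last <- max(which(revA[ja]))
      jl <- ja[last]
      if (last == length(ja)) lent <- L          # reversed to the duct end
      else {
        jn <- ja[last + 1]
        if (!is.na(gA[jn]) && gA[jn] >= 0 && gA[jl] < 0)
          lent <- aCoord[jl] + (aCoord[jn] - aCoord[jl]) *
            gA[jl] / (gA[jl] - gA[jn])
        else lent <- aCoord[jl]
      }
    }
    det[t] <- TRUE
    hgt[t] <- min(2 * smax, H)
    len[t] <- min(max(lent, 0), L)
  }
  if (nPockets > 0)
    flowLog("recirculation: ignored %d detached reversed-flow pockets", nPockets)
  new("RecirculationTrace", height = hgt, length = len,
      heightNorm = hgt / H, lengthNorm = len / L, detected = det,
      ductHeight = H, ductLength = L, frameDuration = frameDuration(data))
}

#' Area-averaged axial velocity at a duct station
#'
#' @param data a [FlowDataset-class].
#' @param duct a [ductSpec()].
#' @param station voxel index along the duct's axial grid axis.
#' @return a [TimeSeries-class] (m/s), signed by the duct's axial
#'   direction.
#' @export
meanSectionVelocity <- function(data, duct, station) {
  stopifnot(is(data, "FlowDataset"), inherits(duct, "DuctSpec"))
  d <- dim(data@velocity)
  if (station < 1 || station > d[duct$axis]) stop("station outside the grid")
  dmask <- if (is.null(duct$mask)) array(TRUE, d[1:3]) else duct$mask
  nt <- d[4]
  vals <- numeric(nt)
  slice3 <- function(a, axis, idx)
    switch(axis, a[idx, , ], a[, idx, ], a[, , idx])
  for (t in seq_len(nt)) {
    m3 <- data@mask[, , , t] & dmask
    ms <- slice3(m3, duct$axis, station)
    us <- slice3(data@velocity[, , , t, duct$axis], duct$axis, station)
    if (!any(ms)) stop(sprintf("station %d has no fluid voxels", station))
    vals[t] <- duct$axialDirection * mean(us[ms])
  }
  new("TimeSeries", values = vals, metric = "mean axial velocity",
      units = "m/s", frameDuration = frameDuration(data))
}
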
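## Internal grid helpers shared across modules.

## Voxel centers lie at (index - 0.5) * spacing from the grid corner, so a
## grid of n voxels spans [0, n*spacing] and centers are strictly interior.
voxelCenters <- function(dims, spacing) {
  lapply(dims[1:3], function(n) (seq_len(n) - 0.5) * spacing)
}

gridCenter <- function(dims, spacing) dims[1:3] * spacing / 2

## Shift a 3-D array by one voxel along `axis` (+1 brings the neighbour at
## index+1 into position); vacated planes are filled with `fill`.
shift3 <- function(a, axis, step, fill = NA_real_) {
  d <- dim(a)
  out <- array(fill, d)
  idx <- lapply(d, seq_len)
  src <- idx
  n <- d[axis]
  if (step == 1L) { idx[[axis]] <- seq_len(n - 1L); src[[axis]] <- 2:n }
  else            { idx[[axis]] <- 2:n;             src[[axis]] <- seq_len(n - 1L) }
  out[idx[[1]], idx[[2]], idx[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

## Extract one velocity component as a 4-D array, robust to singleton
## frame counts (plain [ , , , , i] would drop the frame dimension too).
velComp <- function(vel, i) array(vel[, , , , i, drop = FALSE], dim(vel)[1:4])

speedArray <- function(data) {
  v <- data@velocity
  sqrt(velComp(v, 1)^2 + velComp(v, 2)^2 + velComp(v, 3)^2)
}

## 6-connected component labelling of a 3-D logical mask via igraph.
## Returns an integer array: 0 outside, component id (1 = largest) inside.
labelComponents6 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  n <- sum(mask)
  if (n == 0L) return(lab)
  rank <- array(0L, d)
  rank[mask] <- seq_len(n)
  edges <- integer(0)
  for (axis in 1:3) {
    nb <- shift3(rank, axis, 1L, fill = 0L)
    ok <- mask & nb > 0L
    if (any(ok)) edges <- c(edges, rbind(rank[ok], nb[ok]))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  ord <- order(comp$csize, decreasing = TRUE)
  relabel <- integer(comp$no); relabel[ord] <- seq_len(comp$no)
  lab[mask] <- relabel[comp$membership]
  lab
}

## Trilinear interpolation of a 3-D array at world points (voxel-center
## geometry). `pts` is an n x 3 matrix of coordinates in metres. Points
## outside the grid's center hull are clamped to it. Returns value and an
## in-mask flag (TRUE only if all 8 stencil corners are masked).
trilinear <- function(a, mask3, spacing, pts) {
  d <- dim(a)
  val <- numeric(nrow(pts)); inm <- logical(nrow(pts))
  ## continuous voxel coordinate: center i is at coordinate i
  cc <- sweep(pts / spacing + 0.5, 2, c(0, 0, 0))
  for (k in seq_len(nrow(pts))) {
    p <- pmin(pmax(cc[k, ], 1), d[1:3])
    i0 <- pmin(floor(p), d[1:3] - 1L); i0 <- pmax(i0, 1L)
    f <- p - i0
    acc <- 0; okall <- TRUE
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) f[1] else 1 - f[1]) *
           (if (dy) f[2] else 1 - f[2]) *
           (if (dz) f[3] else 1 - f[3])
      ii <- i0 + c(dx, dy, dz)
      acc <- acc + w * a[ii[1], ii[2], ii[3]]
      if (!mask3[ii[1], ii[2], ii[3]]) okall <- FALSE
    }
    val[k] <- acc; inm[k] <- okall
  }
  list(value = val, inMask = inm)
}

## Verbose logging: every unit conversion and exclusion count goes through
## here so analyses are auditable without being chatty by default.
flowLog <- function(fmt, ...) {
  if (isTRUE(getOption("flow4d.verbose", TRUE)))
    message(sprintf(fmt, ...))
  invisible(NULL)
}

m3s_to_Lmin <- function(q) q * 6e4
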
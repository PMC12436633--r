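# Small phantom factories shared across tests. Grids are kept desk-scale;
# cylindrical phantoms use odd in-plane extents so the pipe axis sits on a
# voxel-center column (see the methods vignette).

options(flow4d.verbose = FALSE)

smallPipe <- function(frames = 2L, spacing = 2.0, nx = 8L, nyz = 15L,
                      radius = 0.011, meanSpeed = 0.5, waveform = NULL,
                      kind = "poiseuille") {
  generatePhantom(phantomSpec(kind, radius = radius, meanSpeed = meanSpeed,
                              spacing = spacing,
                              extents = c(nx, nyz, nyz), frames = frames,
                              waveform = waveform))
}

zeroStatic <- function(dims = c(12L, 14L, 10L), frames = 2L, spacing = 2e-3) {
  meta <- new("AcquisitionMeta", venc = 2, frameDuration = 0.014,
              frames = as.integer(frames), heartRate = 60, spacing = spacing,
              rho = 1089, mu = 3.7e-3)
  flowDataset(array(0, c(dims, frames, 3)), array(TRUE, c(dims, frames)), meta)
}

# dataset with prescribed velocity arrays (all-true mask unless given)
customDataset <- function(ux = NULL, uy = NULL, uz = NULL, mask = NULL,
                          spacing = 2e-3, frameDuration = 0.014, venc = 10) {
  ref <- if (!is.null(ux)) ux else if (!is.null(uy)) uy else uz
  d <- dim(ref)
  if (length(d) == 3) d <- c(d, 1L)
  vel <- array(0, c(d, 3))
  if (!is.null(ux)) vel[, , , , 1] <- ux
  if (!is.null(uy)) vel[, , , , 2] <- uy
  if (!is.null(uz)) vel[, , , , 3] <- uz
  if (is.null(mask)) mask <- array(TRUE, d)
  meta <- new("AcquisitionMeta", venc = venc, frameDuration = frameDuration,
              frames = d[4], heartRate = 60, spacing = spacing,
              rho = 1089, mu = 3.7e-3)
  flowDataset(vel, mask, meta)
}

# interior (central-stencil) voxels of a pipe dataset's first frame
interiorMask <- function(data) {
  m <- fluidMask(data)[, , , 1]
  ok <- m
  for (axis in 1:3) {
    up <- flow4d:::shift3(m, axis, 1L, fill = FALSE)
    dn <- flow4d:::shift3(m, axis, -1L, fill = FALSE)
    ok <- ok & up & dn
  }
  ok
}
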
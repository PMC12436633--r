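## File formats: NIfTI-1 volumes with a JSON sidecar for datasets, legacy
## ASCII VTK structured points for external viewers, CSV for time series.
## Files use acquisition-native units (cm/s VENC, ms frames, mm spacing);
## everything in memory is SI and each conversion is logged.

.sidecarKeys <- c("venc_cms", "frame_duration_ms", "frame_count",
                  "heart_rate_bpm", "spacing_mm", "density_kg_m3",
                  "viscosity_kg_m_s")

## Plain-array read: drop the niftiImage class and header attributes.
.niftiArray <- function(path) {
  a <- as.array(RNifti::readNifti(path))
  array(as.vector(a), dim(a))
}

.niftiWrite <- function(arr, path, spacing_mm, datatype = "double") {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(spacing_mm, min(length(dim(arr)), 3))
  RNifti::pixunits(img) <- c("mm", "s")
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a flow dataset to NIfTI-1 files with a JSON sidecar
#'
#' One 4-D file per velocity component (\code{vel_x/y/z.nii.gz}, m/s),
#' the per-frame fluid mask as uint8 (\code{mask.nii.gz}), any magnitude
#' volumes as \code{mag_<name>.nii.gz}, and \code{sidecar.json} carrying
#' the acquisition metadata in native units with a \code{schema_version}.
#'
#' @param data a [FlowDataset-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeDataset <- function(data, dir) {
  stopifnot(is(data, "FlowDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp_mm <- spacing(data) * 1e3
  comp <- c("x", "y", "z")
  for (i in 1:3)
    .niftiWrite(data@velocity[, , , , i],
                file.path(dir, sprintf("vel_%s.nii.gz", comp[i])), sp_mm)
  .niftiWrite(array(as.integer(data@mask), dim(data@mask)),
              file.path(dir, "mask.nii.gz"), sp_mm, datatype = "uint8")
  for (nm in names(data@magnitude))
    .niftiWrite(data@magnitude[[nm]],
                file.path(dir, sprintf("mag_%s.nii.gz", nm)), sp_mm)
  m <- data@meta
  side <- list(schema_version = 1L,
               venc_cms = m@venc * 100,
               frame_duration_ms = m@frameDuration * 1e3,
               frame_count = m@frames,
               heart_rate_bpm = m@heartRate,
               spacing_mm = sp_mm,
               density_kg_m3 = m@rho,
               viscosity_kg_m_s = m@mu)
  jsonlite::write_json(side, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a flow dataset from NIfTI-1 files and a JSON sidecar
#'
#' Counterpart of [writeDataset()]. Velocities are read in m/s; sidecar
#' fields in acquisition units are converted to SI (cm/s to m/s, ms to s,
#' mm to m) and each conversion is logged. A missing mask file yields an
#' all-true mask with a warning.
#'
#' @param dir directory holding \code{vel_x/y/z.nii.gz}, optionally
#'   \code{mask.nii.gz} and \code{mag_*.nii.gz}, and \code{sidecar.json}.
#' @return a [FlowDataset-class].
#' @export
readDataset <- function(dir) {
  side_path <- file.path(dir, "sidecar.json")
  if (!file.exists(side_path)) stop("missing sidecar.json in ", dir)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  missing <- setdiff(.sidecarKeys, names(side))
  if (length(missing))
    stop("sidecar.json lacks required key(s): ", paste(missing, collapse = ", "))
  comp <- c("x", "y", "z")
  paths <- file.path(dir, sprintf("vel_%s.nii.gz", comp))
  vols <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("missing velocity file ", p)
    .niftiArray(p)
  })
  dims <- lapply(vols, dim)
  for (i in 2:3)
    if (!identical(dims[[i]], dims[[1]]))
      stop(sprintf("component shape mismatch: %s is %s but %s is %s",
                   basename(paths[1]), paste(dims[[1]], collapse = "x"),
                   basename(paths[i]), paste(dims[[i]], collapse = "x")))
  d <- dims[[1]]
  if (length(d) == 3) d <- c(d, 1L)
  vel <- array(0, c(d, 3))
  for (i in 1:3) vel[, , , , i] <- vols[[i]]
  mask_path <- file.path(dir, "mask.nii.gz")
  if (file.exists(mask_path)) {
    mask <- .niftiArray(mask_path) > 0
    mask <- array(mask, d)
  } else {
    warning("no mask.nii.gz: assuming all voxels are fluid", call. = FALSE)
    mask <- array(TRUE, d)
  }
  mags <- list()
  for (p in sort(list.files(dir, pattern = "^mag_.*\\.nii\\.gz$",
                            full.names = TRUE))) {
    nm <- sub("^mag_(.*)\\.nii\\.gz$", "\\1", basename(p))
    mags[[nm]] <- array(.niftiArray(p), d)
  }
  flowLog("sidecar: VENC %.4g cm/s -> %.4g m/s; frame %.4g ms -> %.4g s; spacing %.4g mm -> %.4g m",
          side$venc_cms, side$venc_cms / 100, side$frame_duration_ms,
          side$frame_duration_ms / 1e3, side$spacing_mm, side$spacing_mm / 1e3)
  meta <- new("AcquisitionMeta",
              venc = side$venc_cms / 100,
              frameDuration = side$frame_duration_ms / 1e3,
              frames = as.integer(side$frame_count),
              heartRate = side$heart_rate_bpm,
              spacing = side$spacing_mm / 1e3,
              rho = side$density_kg_m3, mu = side$viscosity_kg_m_s)
  flowDataset(vel, mask, meta, magnitude = mags)
}

## Sentinel written for invalid voxels in VTK exports; stated in the file
## title line so downstream viewers can threshold it away.
.vtkSentinel <- -9.9e30

.vtkNum <- function(x) {
  x[is.na(x)] <- .vtkSentinel
  sprintf("%.17g", x)
}

#' Export a field to a legacy-ASCII VTK structured-points file
#'
#' Writes voxel-centred point data on the regular grid: a velocity
#' dataset becomes one 3-component VECTORS array per frame
#' (\code{velocity_f<NNN>}), a scalar map one SCALARS array per frame.
#' Invalid voxels are written as the sentinel \code{-9.9e30}, stated in
#' the file's title line. Loadable by standard VTK readers (ParaView et
#' al.) for pathline and isosurface rendering.
#'
#' @param x a [FlowDataset-class] or [ScalarMap-class].
#' @param path output \code{.vtk} file.
#' @return \code{path}, invisibly.
#' @export
exportVTK <- function(x, path) {
  if (is(x, "FlowDataset")) {
    d <- dim(x@velocity); h <- spacing(x)
    arrays <- lapply(seq_len(d[4]), function(t) {
      v <- cbind(as.vector(x@velocity[, , , t, 1]),
                 as.vector(x@velocity[, , , t, 2]),
                 as.vector(x@velocity[, , , t, 3]))
      list(name = sprintf("velocity_f%03d", t), data = v, type = "VECTORS")
    })
  } else if (is(x, "ScalarMap")) {
    d <- dim(x@values); h <- x@spacing
    arrays <- lapply(seq_len(d[4]), function(t)
      list(name = sprintf("%s_f%03d", x@metric, t),
           data = as.vector(x@values[, , , t]), type = "SCALARS"))
  } else stop("exportVTK supports FlowDataset and ScalarMap")
  if (!is.finite(h)) h <- 1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("flow4d export; invalid voxels = %g", .vtkSentinel),
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %.10g %.10g %.10g", h / 2, h / 2, h / 2),
               sprintf("SPACING %.10g %.10g %.10g", h, h, h),
               sprintf("POINT_DATA %d", prod(d[1:3]))), con)
  for (a in arrays) {
    if (a$type == "VECTORS") {
      writeLines(sprintf("VECTORS %s double", a$name), con)
      writeLines(paste(.vtkNum(a$data[, 1]), .vtkNum(a$data[, 2]),
                       .vtkNum(a$data[, 3])), con)
    } else {
      writeLines(c(sprintf("SCALARS %s double 1", a$name),
                   "LOOKUP_TABLE default"), con)
      writeLines(.vtkNum(a$data), con)
    }
  }
  invisible(path)
}

#' Read back a flow4d VTK export
#'
#' Minimal reader for the structured-points files written by
#' [exportVTK()], used for round-trip verification.
#'
#' @param path a \code{.vtk} file written by [exportVTK()].
#' @return list: \code{dims}, \code{spacing}, and \code{arrays} (named
#'   list; vectors as n x 3 matrices, sentinel restored to NA).
#' @export
readVTK <- function(path) {
  ln <- readLines(path)
  dims <- as.integer(strsplit(ln[grep("^DIMENSIONS", ln)], " ")[[1]][-1])
  sp <- as.numeric(strsplit(ln[grep("^SPACING", ln)], " ")[[1]][-1])
  n <- prod(dims)
  arrays <- list()
  i <- grep("^POINT_DATA", ln) + 1L
  while (i <= length(ln)) {
    hdr <- strsplit(ln[i], " ")[[1]]
    if (hdr[1] == "SCALARS") {
      vals <- as.numeric(ln[(i + 2L):(i + 1L + n)])
      vals[vals == .vtkSentinel] <- NA_real_
      arrays[[hdr[2]]] <- array(vals, dims)
      i <- i + 2L + n
    } else if (hdr[1] == "VECTORS") {
      m <- do.call(rbind, lapply(strsplit(ln[(i + 1L):(i + n)], " "),
                                 as.numeric))
      m[m == .vtkSentinel] <- NA_real_
      arrays[[hdr[2]]] <- m
      i <- i + 1L + n
    } else i <- i + 1L
  }
  list(dims = dims, spacing = sp[1], arrays = arrays)
}

#' Export time series to CSV
#'
#' One row per frame; the header names each metric and its units. Values
#' are written with 17 significant digits so a re-parse reproduces the
#' source exactly and repeated runs are byte-identical.
#'
#' @param series a [TimeSeries-class] or named list of them (equal
#'   lengths required).
#' @param path output CSV file.
#' @return \code{path}, invisibly.
#' @export
exportTimeSeries <- function(series, path) {
  if (is(series, "TimeSeries")) series <- list(series)
  stopifnot(length(series) >= 1)
  lens <- vapply(series, function(s) length(s@values), integer(1))
  if (length(unique(lens)) > 1)
    stop(sprintf("series length mismatch: %s", paste(lens, collapse = " vs ")))
  fd <- series[[1]]@frameDuration
  hdr <- c("time_s", vapply(series, function(s)
    sprintf("%s [%s]", s@metric, s@units), character(1)))
  tm <- if (is.na(fd)) rep(NA_real_, lens[1]) else (seq_len(lens[1]) - 1) * fd
  rows <- character(lens[1])
  for (r in seq_len(lens[1]))
    rows[r] <- paste(c(sprintf("%.17g", tm[r]),
                       vapply(series, function(s) sprintf("%.17g", s@values[r]),
                              character(1))), collapse = ",")
  writeLines(c(paste(sprintf("\"%s\"", hdr), collapse = ","), rows), path)
  invisible(path)
}

#' Serialise a scalar map to NIfTI + JSON metadata
#'
#' Writes \code{<prefix>.nii.gz} (values, NA for invalid),
#' \code{<prefix>_valid.nii.gz} (uint8) and \code{<prefix>.json}
#' (metric, units, spacing).
#'
#' @param map a [ScalarMap-class].
#' @param prefix output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
writeScalarMap <- function(map, prefix) {
  stopifnot(is(map, "ScalarMap"))
  sp_mm <- if (is.finite(map@spacing)) map@spacing * 1e3 else NA_real_
  .niftiWrite(map@values, paste0(prefix, ".nii.gz"),
              ifelse(is.na(sp_mm), 1, sp_mm))
  .niftiWrite(array(as.integer(map@valid), dim(map@valid)),
              paste0(prefix, "_valid.nii.gz"),
              ifelse(is.na(sp_mm), 1, sp_mm), datatype = "uint8")
  jsonlite::write_json(list(metric = map@metric, units = map@units,
                            spacing_mm = sp_mm),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname writeScalarMap
#' @export
readScalarMap <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  vals <- .niftiArray(paste0(prefix, ".nii.gz"))
  valid <- .niftiArray(paste0(prefix, "_valid.nii.gz")) > 0
  if (length(dim(vals)) == 3) {
    dim(vals) <- c(dim(vals), 1L); dim(valid) <- dim(vals)
  }
  vals[!valid] <- NA_real_
  new("ScalarMap", values = vals, valid = valid, metric = meta$metric,
      units = meta$units,
      spacing = ifelse(is.null(meta$spacing_mm) || is.na(meta$spacing_mm),
                       NA_real_, meta$spacing_mm / 1e3))
}
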
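#' @include AllClasses.R AllGenerics.R
NULL

#' Accessors for flow4d objects
#'
#' Slot access goes through these accessors, never \code{@}.
#'
#' @param object a flow4d S4 object.
#' @param component optional velocity component: 1-3 or "x"/"y"/"z"; if
#'   omitted the full 5-D array is returned.
#' @param ... unused.
#' @name accessors
NULL

.componentIndex <- function(component) {
  if (is.character(component))
    component <- match(component, c("x", "y", "z"))
  if (is.na(component) || component < 1 || component > 3)
    stop("component must be 1..3 or 'x'/'y'/'z'")
  as.integer(component)
}

#' @rdname accessors
#' @export
setMethod("velocity", "FlowDataset", function(object, component, ...) {
  if (missing(component)) return(object@velocity)
  object@velocity[, , , , .componentIndex(component), drop = FALSE]
})

#' @rdname accessors
#' @export
setMethod("fluidMask", "FlowDataset", function(object, ...) object@mask)

#' @rdname accessors
#' @export
setMethod("acquisitionMeta", "FlowDataset", function(object) object@meta)

#' @rdname accessors
#' @export
setMethod("spacing", "FlowDataset", function(object) object@meta@spacing)

#' @rdname accessors
#' @export
setMethod("spacing", "ScalarMap", function(object) object@spacing)

#' @rdname accessors
#' @export
setMethod("spacing", "GradientTensorField", function(object) object@spacing)

#' @rdname accessors
#' @export
setMethod("frameCount", "FlowDataset", function(object) dim(object@velocity)[4])

#' @rdname accessors
#' @export
setMethod("frameCount", "ScalarMap", function(object) dim(object@values)[4])

#' @rdname accessors
#' @export
setMethod("frameDuration", "FlowDataset", function(object) object@meta@frameDuration)

#' @rdname accessors
#' @export
setMethod("frameDuration", "TimeSeries", function(object) object@frameDuration)

#' @rdname accessors
#' @export
setMethod("groundTruth", "FlowDataset", function(object) object@groundTruth)

#' @rdname accessors
#' @export
setMethod("magnitudes", "FlowDataset", function(object) object@magnitude)

#' @rdname accessors
#' @export
setMethod("mapValues", "ScalarMap", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("mapValues", "StasisMap", function(object) object@rstasis)

#' @rdname accessors
#' @export
setMethod("mapValues", "IVVVField", function(object) object@sigma2)

#' @rdname accessors
#' @export
setMethod("validMask", "ScalarMap", function(object) object@valid)

#' @rdname accessors
#' @export
setMethod("validMask", "GradientTensorField", function(object) object@valid)

#' @rdname accessors
#' @export
setMethod("validMask", "IVVVField", function(object) object@valid)

#' @rdname accessors
#' @export
setMethod("validMask", "StasisMap", function(object) object@eligible)

#' @rdname accessors
#' @export
setMethod("metricName", "ScalarMap", function(object) object@metric)

#' @rdname accessors
#' @export
setMethod("metricName", "TimeSeries", function(object) object@metric)

#' @rdname accessors
#' @export
setMethod("metricUnits", "ScalarMap", function(object) object@units)

#' @rdname accessors
#' @export
setMethod("metricUnits", "TimeSeries", function(object) object@units)

#' @rdname accessors
#' @export
setMethod("seriesValues", "TimeSeries", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("frameTimes", "TimeSeries", function(object)
  (seq_along(object@values) - 1) * object@frameDuration)

#' @rdname accessors
#' @export
setMethod("coef", "BackgroundModel", function(object, ...) object@coefficients)

#' Convert a time series or recirculation trace to a data.frame
#'
#' @param x the object.
#' @param row.names,optional,... passed through for generic compatibility.
#' @export
setMethod("as.data.frame", "TimeSeries",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(time_s = frameTimes(x), value = x@values)
  })

#' @rdname as.data.frame-TimeSeries-method
#' @export
setMethod("as.data.frame", "RecirculationTrace",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(time_s = (seq_along(x@height) - 1) * x@frameDuration,
               height_m = x@height, length_m = x@length,
               height_norm = x@heightNorm, length_norm = x@lengthNorm,
               detected = x@detected)
  })

## ---- show methods -------------------------------------------------------

setMethod("show", "AcquisitionMeta", function(object) {
  cat("AcquisitionMeta: VENC", object@venc, "m/s |", object@frames,
      "frames x", object@frameDuration * 1000, "ms |",
      object@spacing * 1000, "mm isotropic |", object@heartRate, "bpm\n")
  cat("  fluid: rho =", object@rho, "kg/m^3, mu =", object@mu, "kg/m/s\n")
})

setMethod("show", "FlowDataset", function(object) {
  d <- dim(object@velocity)
  cat(sprintf("FlowDataset: %d x %d x %d voxels, %d frames\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  masked voxel-frames: %d (%.1f%%)\n", sum(object@mask),
              100 * mean(object@mask)))
  if (length(object@magnitude))
    cat("  magnitude volumes:", paste(names(object@magnitude), collapse = ", "), "\n")
  if (length(object@groundTruth))
    cat("  analytic ground truth:", paste(names(object@groundTruth), collapse = ", "), "\n")
  show(object@meta)
})

setMethod("show", "ScalarMap", function(object) {
  d <- dim(object@values)
  v <- object@values[object@valid]
  cat(sprintf("ScalarMap '%s' [%s]: %d x %d x %d voxels, %d frames\n",
              object@metric, object@units, d[1], d[2], d[3], d[4]))
  if (length(v))
    cat(sprintf("  valid: %d | range %.4g .. %.4g\n", length(v), min(v), max(v)))
  else cat("  no valid voxels\n")
})

setMethod("show", "GradientTensorField", function(object) {
  d <- dim(object@d)
  cat(sprintf("GradientTensorField: %d x %d x %d voxels, %d frames; %d invalid voxel-frames\n",
              d[1], d[2], d[3], d[4], object@nInvalid))
})

setMethod("show", "StasisMap", function(object) {
  v <- object@rstasis[object@eligible]
  cat(sprintf("StasisMap (threshold %.3g m/s, %d frames): %d eligible voxels\n",
              object@threshold, object@nTot, sum(object@eligible)))
  if (length(v))
    cat(sprintf("  median %.1f%% | IQR %.1f-%.1f%%\n",
                stats::median(v), stats::quantile(v, .25), stats::quantile(v, .75)))
})

setMethod("show", "BackgroundModel", function(object) {
  cat("BackgroundModel: 2nd-order 3-D polynomial offsets, 10 coefficients/component\n")
  cat(sprintf("  RMS residual (m/s): x %.3g, y %.3g, z %.3g\n",
              object@rms[1], object@rms[2], object@rms[3]))
})

setMethod("show", "IVVVField", function(object) {
  d <- dim(object@sigma2)
  cat(sprintf("IVVVField: %d x %d x %d voxels, %d frames; %d negative estimates clipped\n",
              d[1], d[2], d[3], d[4], object@nClipped))
})

setMethod("show", "TimeSeries", function(object) {
  cat(sprintf("TimeSeries '%s' [%s]: %d frames x %.3g ms\n", object@metric,
              object@units, length(object@values), object@frameDuration * 1000))
  cat(sprintf("  range %.4g .. %.4g\n", min(object@values), max(object@values)))
})

setMethod("show", "RecirculationTrace", function(object) {
  cat(sprintf("RecirculationTrace: %d frames, detected in %d\n",
              length(object@height), sum(object@detected)))
  if (any(object@detected))
    cat(sprintf("  max height %.4g m (h/H = %.2f) | max length %.4g m\n",
                max(object@height), max(object@heightNorm), max(object@length)))
})
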
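#' @include AllClasses.R
NULL

#' @export
setGeneric("velocity", function(object, ...) standardGeneric("velocity"))

#' @export
setGeneric("fluidMask", function(object, ...) standardGeneric("fluidMask"))

#' @export
setGeneric("acquisitionMeta", function(object) standardGeneric("acquisitionMeta"))

#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))

#' @export
setGeneric("frameCount", function(object) standardGeneric("frameCount"))

#' @export
setGeneric("frameDuration", function(object) standardGeneric("frameDuration"))

#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @export
setGeneric("magnitudes", function(object) standardGeneric("magnitudes"))

#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))

#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @export
setGeneric("metricName", function(object) standardGeneric("metricName"))

#' @export
setGeneric("metricUnits", function(object) standardGeneric("metricUnits"))

#' @export
setGeneric("seriesValues", function(object) standardGeneric("seriesValues"))

#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))
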
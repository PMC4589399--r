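#' @name dynFDG-accessors
#' @title Accessor generics
#' @description Small accessor generics shared by the dynFDG classes.
#' @param object a dynFDG object.
#' @keywords internal
NULL

#' @rdname dynFDG-accessors
#' @export
setGeneric("frameStarts", function(object) standardGeneric("frameStarts"))

#' @rdname dynFDG-accessors
#' @export
setGeneric("frameDurations", function(object) standardGeneric("frameDurations"))

#' @rdname dynFDG-accessors
#' @export
setGeneric("frameMids", function(object) standardGeneric("frameMids"))

#' @rdname dynFDG-accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname dynFDG-accessors
#' @export
setGeneric("totalDuration", function(object) standardGeneric("totalDuration"))

#' @rdname dynFDG-accessors
#' @export
setGeneric("schedule", function(object) standardGeneric("schedule"))

#' @rdname dynFDG-accessors
#' @export
setGeneric("activity", function(object) standardGeneric("activity"))

#' @rdname dynFDG-accessors
#' @export
setGeneric("imageData", function(object) standardGeneric("imageData"))

#' @rdname dynFDG-accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname dynFDG-accessors
#' @export
setGeneric("maskCoords", function(object) standardGeneric("maskCoords"))

#' @rdname dynFDG-accessors
#' @export
setGeneric("kineticVector", function(object) standardGeneric("kineticVector"))

#' Net FDG influx constant Ki
#'
#' Ki = K1*k3/(k2+k3) (mL/s/g), the macro-parameter quantifying the net
#' trapping flux of FDG.  Defined as 0 when k2+k3 == 0 (no exchange implies
#' no trapping flux).
#'
#' @param object a [KineticParams-class], [FitResult-class], or
#'   [GroupPreset-class].
#' @return numeric scalar, mL/s/g.
#' @examples
#' influxConstant(kineticParams(K1 = 0.00229, k2 = 0.042, k3 = 0.0104,
#'                              k4 = 0.00177))
#' @export
setGeneric("influxConstant", function(object) standardGeneric("influxConstant"))
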
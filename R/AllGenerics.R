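#' @rdname ImageVolume-class
#' @param x an object with voxel data.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname ImageVolume-class
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname ImageVolume-class
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' Convert HU to relative electron density
#'
#' Piecewise-linear interpolation of a calibration curve, clamped to the end
#' values outside the tabulated HU range.
#'
#' @param x an HU [ImageVolume] or a numeric vector of HU values.
#' @param curve a [CalibrationCurve].
#' @return an object of the same kind as \code{x} with RED values.
#' @examples
#' huToRed(c(-1000, -500, 0), defaultCalibrationCurve())
#' @export
setGeneric("huToRed", function(x, curve) standardGeneric("huToRed"))

#' @rdname DVHSummary-class
#' @param x a [DVHSummary].
#' @export
setGeneric("dMean", function(x) standardGeneric("dMean"))
#' @rdname DVHSummary-class
#' @export
setGeneric("dNearMax", function(x) standardGeneric("dNearMax"))
#' @rdname DVHSummary-class
#' @export
setGeneric("dNearMin", function(x) standardGeneric("dNearMin"))

#' @rdname GammaResult-class
#' @param x a [GammaResult].
#' @export
setGeneric("passRate", function(x) standardGeneric("passRate"))
#' @rdname GammaResult-class
#' @export
setGeneric("gammaMap", function(x) standardGeneric("gammaMap"))

#' @rdname TOSTResult-class
#' @param x a [TOSTResult].
#' @export
setGeneric("isEquivalent", function(x) standardGeneric("isEquivalent"))
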
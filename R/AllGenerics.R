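#' Accessors for contour and fit objects
#'
#' `contourPoints` returns the coordinate matrix of a contour, `nPoints` the
#' number of points, `contourUnits` the coordinate units. `roughnessScore`
#' returns the DS score of an [EllipseFit-class] (or computes it from a point
#' set and an ellipse), `pointDistances` the per-point nearest distances, and
#' `fittedEllipse` the [EllipseParams-class] of a fit.
#'
#' @param object a [Contour-class] or [EllipseFit-class] object as
#'   appropriate.
#' @param ... further arguments for methods.
#' @return See the individual method descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("contourPoints", function(object) standardGeneric("contourPoints"))

#' @rdname accessors
#' @export
setGeneric("nPoints", function(object) standardGeneric("nPoints"))

#' @rdname accessors
#' @export
setGeneric("contourUnits", function(object) standardGeneric("contourUnits"))

#' @rdname accessors
#' @export
setGeneric("roughnessScore", function(object, ...)
    standardGeneric("roughnessScore"))

#' @rdname accessors
#' @export
setGeneric("pointDistances", function(object)
    standardGeneric("pointDistances"))

#' @rdname accessors
#' @export
setGeneric("fittedEllipse", function(object) standardGeneric("fittedEllipse"))

#' @rdname accessors
#' @export
setGeneric("ellipseCenter", function(object) standardGeneric("ellipseCenter"))

#' @rdname accessors
#' @export
setGeneric("ellipseAxes", function(object) standardGeneric("ellipseAxes"))

#' @rdname accessors
#' @export
setGeneric("ellipseAngle", function(object) standardGeneric("ellipseAngle"))
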
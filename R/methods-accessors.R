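#' @rdname accessors
#' @aliases contourPoints,Contour-method
setMethod("contourPoints", "Contour", function(object) object@points)

#' @rdname accessors
setMethod("nPoints", "Contour", function(object) nrow(object@points))

#' @rdname accessors
setMethod("nPoints", "EllipseFit", function(object) object@nPoints)

#' @rdname accessors
setMethod("contourUnits", "Contour", function(object) object@units)

#' @rdname accessors
setMethod("pointDistances", "EllipseFit", function(object) object@distances)

#' @rdname accessors
setMethod("fittedEllipse", "EllipseFit", function(object) object@ellipse)

#' @rdname accessors
setMethod("roughnessScore", "EllipseFit", function(object, ...) object@ds)

#' @rdname accessors
setMethod("ellipseCenter", "EllipseParams",
    function(object) c(xc = object@xc, yc = object@yc))

#' @rdname accessors
setMethod("ellipseAxes", "EllipseParams",
    function(object) c(a = object@a, b = object@b))

#' @rdname accessors
setMethod("ellipseAngle", "EllipseParams", function(object) object@phi)

setMethod("show", "Contour", function(object) {
    cat(sprintf("Contour: %d points [%s]%s\n", nrow(object@points),
                object@units, if (object@closed) ", closed" else ", open"))
    rng <- apply(object@points, 2, range)
    cat(sprintf("  x: [%.3f, %.3f]  y: [%.3f, %.3f]\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2]))
})

setMethod("show", "EllipseParams", function(object) {
    cat(sprintf(
        "EllipseParams: center (%.4g, %.4g), a = %.4g, b = %.4g, phi = %.4g rad\n",
        object@xc, object@yc, object@a, object@b, object@phi))
})

setMethod("show", "EllipseFit", function(object) {
    cat(sprintf("EllipseFit on %d points (%s)\n", object@nPoints,
                if (object@converged) "converged" else "NOT converged"))
    show(object@ellipse)
    cat(sprintf("  DS = %.6g (max point distance %.6g)\n",
                object@ds, max(object@distances)))
})

setMethod("show", "PowerReport", function(object) {
    cat(sprintf(
        paste0("PowerReport: R2 = %.3f, f2 = %.3f, df = (%g, %g), ",
               "lambda = %.2f\n  critical F = %.3f (alpha = %g), ",
               "achieved power = %.3f\n"),
        object@r2, object@f2, object@df1, object@df2, object@lambda,
        object@fCrit, object@alpha, object@power))
})

#' Coerce a Contour to a data.frame of coordinates
#'
#' @param x a [Contour-class] object.
#' @param ... ignored.
#' @return A data.frame with columns `x` and `y`.
#' @export
as.data.frame.Contour <- function(x, ...)
    as.data.frame(x@points)
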
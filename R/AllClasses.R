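#' @import methods
NULL

#' Ordered planar boundary of a vertebral endplate
#'
#' An ordered sequence of boundary points in pixel or millimetre units, as
#' produced by external contour tracing of a thresholded endplate image or by
#' the synthetic phantom generator. Pixel-unit contours use image coordinates
#' (origin top-left, y increasing downward); millimetre-unit contours use
#' mathematical coordinates (y up, origin at the contour centroid).
#'
#' @slot points numeric matrix with n rows and 2 columns (x, y).
#' @slot units character, one of `"px"` or `"mm"`.
#' @slot closed logical, whether the last point connects back to the first.
#'
#' @seealso [Contour()], [imageToContour()], [makePhantomContour()]
#' @export
setClass("Contour",
    representation(points = "matrix", units = "character", closed = "logical"),
    prototype(points = matrix(numeric(0), 0, 2), units = "px", closed = FALSE))

setValidity("Contour", function(object) {
    p <- object@points
    if (!is.numeric(p) || ncol(p) != 2L)
        return("'points' must be a numeric matrix with 2 columns")
    if (nrow(p) < 1L)
        return("contour must contain at least one point")
    if (any(!is.finite(p)))
        return("contour coordinates must be finite")
    if (length(object@units) != 1L || !object@units %in% c("px", "mm"))
        return("'units' must be \"px\" or \"mm\"")
    if (length(object@closed) != 1L || is.na(object@closed))
        return("'closed' must be TRUE or FALSE")
    if (nrow(p) > 1L) {
        dup <- rowSums(abs(p[-1L, , drop = FALSE] -
                           p[-nrow(p), , drop = FALSE])) == 0
        if (any(dup))
            return("consecutive duplicate points are not allowed")
    }
    TRUE
})

#' Geometric parameters of a fitted ellipse
#'
#' Canonical ellipse parameterization: center (xc, yc), semi-major axis a,
#' semi-minor axis b and rotation phi of the major axis, with a >= b > 0 and
#' phi in [0, pi).
#'
#' @slot xc,yc numeric, center coordinates (same units as the contour).
#' @slot a,b numeric, semi-major and semi-minor axis lengths.
#' @slot phi numeric, rotation angle of the major axis in radians, in [0, pi).
#'
#' @seealso [EllipseParams()], [fitEllipse()], [pointToEllipseDistance()]
#' @export
setClass("EllipseParams",
    representation(xc = "numeric", yc = "numeric", a = "numeric",
                   b = "numeric", phi = "numeric"))

setValidity("EllipseParams", function(object) {
    v <- c(object@xc, object@yc, object@a, object@b, object@phi)
    if (length(v) != 5L || any(!is.finite(v)))
        return("all parameters must be finite scalars")
    if (object@b <= 0 || object@a < object@b)
        return("axes must satisfy a >= b > 0")
    if (object@phi < 0 || object@phi >= pi)
        return("phi must lie in [0, pi)")
    TRUE
})

#' Result of a penalized least-squares ellipse fit
#'
#' Bundles the fitted ellipse, the per-point nearest distances of the contour
#' to it, and their mean: the DS surface-roughness score.
#'
#' @slot ellipse an [EllipseParams-class] object.
#' @slot distances numeric vector of per-point nearest-point distances.
#' @slot ds numeric, mean of `distances` (the DS score).
#' @slot residualNorm numeric, final value of the composite objective.
#' @slot converged logical, whether the optimizer reported convergence.
#' @slot nPoints integer, number of contour points used.
#'
#' @seealso [fitEllipse()], [roughnessScore()]
#' @export
setClass("EllipseFit",
    representation(ellipse = "EllipseParams", distances = "numeric",
                   ds = "numeric", residualNorm = "numeric",
                   converged = "logical", nPoints = "integer"))

setValidity("EllipseFit", function(object) {
    if (length(object@distances) != object@nPoints)
        return("length(distances) must equal nPoints")
    if (any(object@distances < 0))
        return("distances must be non-negative")
    if (object@ds < 0)
        return("ds must be non-negative")
    if (abs(object@ds - mean(object@distances)) >
        1e-8 * max(1, abs(object@ds)))
        return("ds must equal mean(distances)")
    TRUE
})

#' Post hoc power analysis of an overall regression F-test
#'
#' Achieved power for the global F-test of a multiple regression, from the
#' observed coefficient of determination via Cohen's f2 and the non-central F
#' distribution.
#'
#' @slot r2 numeric, observed coefficient of determination.
#' @slot f2 numeric, Cohen's effect size r2 / (1 - r2).
#' @slot df1,df2 numeric, numerator (k) and denominator (n - k - 1) degrees
#'   of freedom.
#' @slot alpha numeric, significance level.
#' @slot lambda numeric, non-centrality parameter f2 * df2.
#' @slot fCrit numeric, central-F upper-alpha critical value.
#' @slot power numeric, achieved power in [0, 1].
#'
#' @seealso [powerReport()], [achievedPower()]
#' @export
setClass("PowerReport",
    representation(r2 = "numeric", f2 = "numeric", df1 = "numeric",
                   df2 = "numeric", alpha = "numeric", lambda = "numeric",
                   fCrit = "numeric", power = "numeric"))

setValidity("PowerReport", function(object) {
    if (object@r2 < 0 || object@r2 >= 1)
        return("r2 must lie in [0, 1)")
    if (abs(object@f2 - object@r2 / (1 - object@r2)) > 1e-9 * (1 + object@f2))
        return("f2 must equal r2/(1-r2)")
    if (abs(object@lambda - object@f2 * object@df2) >
        1e-9 * (1 + object@lambda))
        return("lambda must equal f2*df2")
    if (object@power < 0 || object@power > 1)
        return("power must lie in [0, 1]")
    TRUE
})

#' Construct a Contour
#'
#' @param points numeric matrix (or two-column data.frame) of (x, y)
#'   coordinates in order along the boundary.
#' @param units `"px"` or `"mm"`.
#' @param closed logical, whether the boundary is closed.
#' @return A [Contour-class] object.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 33)[-33]
#' Contour(cbind(cos(th), sin(th)), units = "mm", closed = TRUE)
#' @export
Contour <- function(points, units = c("px", "mm"), closed = FALSE) {
    units <- match.arg(units)
    if (is.data.frame(points)) points <- as.matrix(points)
    if (is.null(dim(points))) points <- matrix(points, ncol = 2)
    storage.mode(points) <- "double"
    dimnames(points) <- list(NULL, c("x", "y"))
    new("Contour", points = points, units = units, closed = closed)
}

#' Construct an EllipseParams object
#'
#' Parameters are canonicalized so that a >= b and phi lies in [0, pi):
#' if b > a the axes are swapped and phi rotated by pi/2.
#'
#' @param xc,yc center coordinates.
#' @param a,b semi-axis lengths (positive; reordered so a >= b).
#' @param phi rotation of the first axis in radians (any value; reduced
#'   modulo pi).
#' @return An [EllipseParams-class] object.
#' @examples
#' EllipseParams(0, 0, a = 2, b = 5, phi = 0)  # axes swapped, phi -> pi/2
#' @export
EllipseParams <- function(xc, yc, a, b, phi = 0) {
    if (!all(is.finite(c(xc, yc, a, b, phi))))
        stop("ellipse parameters must be finite")
    if (a <= 0 || b <= 0) stop("semi-axes must be positive")
    if (b > a) {
        tmp <- a; a <- b; b <- tmp
        phi <- phi + pi / 2
    }
    phi <- phi %% pi
    if (phi >= pi) phi <- 0  # guard against fp wrap
    new("EllipseParams", xc = as.numeric(xc), yc = as.numeric(yc),
        a = as.numeric(a), b = as.numeric(b), phi = as.numeric(phi))
}
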
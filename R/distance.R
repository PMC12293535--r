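# Nearest point on the ellipse (in its own frame) to a first-quadrant point
# (x, y >= 0). Returns list(t = parameter of nearest boundary point,
# d = distance). Stationary points of the squared distance satisfy
#   g(t) = (a^2 - b^2) cos t sin t - x a sin t + y b cos t = 0,
# and for x, y > 0 there is exactly one root in (0, pi/2); on the axes the
# interior root (inside the evolute) is handled in closed form.
nearestOnQuadrant <- function(x, y, a, b, tol = 1e-12) {
    dist2 <- function(t) (a * cos(t) - x)^2 + (b * sin(t) - y)^2
    cand <- c(0, pi / 2)
    if (x > 0 && y > 0) {
        g <- function(t) (a^2 - b^2) * cos(t) * sin(t) -
            x * a * sin(t) + y * b * cos(t)
        cand <- c(cand, stats::uniroot(g, c(0, pi / 2), tol = tol)$root)
    } else if (y == 0 && a > b && x * a < (a^2 - b^2)) {
        cand <- c(cand, acos(x * a / (a^2 - b^2)))
    }
    # x == 0: t = pi/2 is the unique stationary point for y >= 0
    d2 <- vapply(cand, dist2, 0)
    k <- which.min(d2)
    list(t = cand[k], d = sqrt(d2[k]))
}

# As nearestOnQuadrant, but for an arbitrary point relative to an arbitrary
# ellipse. Returns list(d, t, foot = c(x, y) in world coordinates).
nearestPointOnEllipse <- function(point, ellipse, tol = 1e-12) {
    cp <- cos(ellipse@phi); sp <- sin(ellipse@phi)
    u <- c(cp * (point[1] - ellipse@xc) + sp * (point[2] - ellipse@yc),
           -sp * (point[1] - ellipse@xc) + cp * (point[2] - ellipse@yc))
    sx <- if (u[1] < 0) -1 else 1
    sy <- if (u[2] < 0) -1 else 1
    res <- nearestOnQuadrant(abs(u[1]), abs(u[2]), ellipse@a, ellipse@b,
                             tol = tol)
    fx <- sx * ellipse@a * cos(res$t)
    fy <- sy * ellipse@b * sin(res$t)
    t <- atan2(fy / ellipse@b, fx / ellipse@a)
    list(d = res$d,
         t = t,
         foot = c(ellipse@xc + cp * fx - sp * fy,
                  ellipse@yc + sp * fx + cp * fy))
}

#' Nearest-point distance from a point to an ellipse boundary
#'
#' Solves the stationarity condition of the squared distance in the ellipse
#' frame by safeguarded root finding (quadrant-reduced; exact on the axes and
#' at the center), returning the minimum Euclidean distance to the boundary.
#'
#' @param point numeric length-2 vector (x, y).
#' @param ellipse an [EllipseParams-class] object.
#' @param tol root-finding tolerance on the boundary parameter.
#' @return Non-negative distance in the units of `point`.
#' @examples
#' pointToEllipseDistance(c(3, 0), EllipseParams(0, 0, 1, 1))  # 2
#' pointToEllipseDistance(c(0, 2), EllipseParams(0, 0, 2, 1))  # 1
#' @export
pointToEllipseDistance <- function(point, ellipse, tol = 1e-12) {
    stopifnot(is(ellipse, "EllipseParams"), length(point) == 2L)
    nearestPointOnEllipse(as.numeric(point), ellipse, tol = tol)$d
}

# Vectorized per-row distances of an n x 2 matrix to an ellipse.
distancesToEllipse <- function(points, ellipse, tol = 1e-12) {
    vapply(seq_len(nrow(points)), function(i)
        nearestPointOnEllipse(points[i, ], ellipse, tol = tol)$d, 0)
}

#' @describeIn accessors DS of a coordinate matrix against a given ellipse:
#'   the mean of the per-point nearest distances.
#' @param ellipse an [EllipseParams-class] (matrix/Contour methods).
#' @param tol distance-solver tolerance.
#' @export
setMethod("roughnessScore", "matrix",
    function(object, ellipse, tol = 1e-12, ...) {
        if (nrow(object) < 1L) stop("need at least one point")
        mean(distancesToEllipse(object, ellipse, tol = tol))
    })

#' @describeIn accessors DS of a [Contour-class] against a given ellipse.
#' @export
setMethod("roughnessScore", "Contour",
    function(object, ellipse, tol = 1e-12, ...)
        roughnessScore(object@points, ellipse, tol = tol))
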
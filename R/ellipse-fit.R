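#' Configuration of the penalized ellipse fit
#'
#' @param r_max eccentricity bound on `|log(b/a)|`; the default `log(3)`
#'   admits axis ratios up to 3:1, matching the mild eccentricity of
#'   vertebral endplates.
#' @param w_tan,w_curv,w_ecc non-negative weights of the tangential,
#'   curvature and eccentricity penalty residuals.
#' @param max_iter maximum optimizer iterations.
#' @param tol convergence tolerance on the relative objective/step change.
#' @param distance_tol nearest-point solver tolerance.
#' @return A validated list of class `"FitConfig"`.
#' @seealso [fitEllipse()]
#' @export
fitConfig <- function(r_max = log(3), w_tan = 0.1, w_curv = 0.1,
                      w_ecc = 10, max_iter = 200, tol = 1e-10,
                      distance_tol = 1e-9) {
    if (r_max <= 0) stop("r_max must be positive")
    if (any(c(w_tan, w_curv, w_ecc) < 0)) stop("weights must be >= 0")
    if (tol <= 0 || distance_tol <= 0) stop("tolerances must be positive")
    structure(list(r_max = r_max, w_tan = w_tan, w_curv = w_curv,
                   w_ecc = w_ecc, max_iter = as.integer(max_iter),
                   tol = tol, distance_tol = distance_tol),
              class = "FitConfig")
}

#' PCA initial ellipse estimate
#'
#' Centers the point set at its centroid and eigendecomposes the coordinate
#' covariance: with eigenvalues `lambda1 >= lambda2`, the initial semi-axes
#' are `sqrt(2 * lambda)` (for points uniformly sampled in parameter,
#' `Var(a cos t) = a^2 / 2`), and the initial rotation is the leading
#' eigenvector's angle canonicalized to `[0, pi)`.
#'
#' @param points numeric n x 2 matrix, n >= 5, not all collinear.
#' @return An [EllipseParams-class] initial estimate.
#' @export
pcaInitialEllipse <- function(points) {
    points <- asPointMatrix(points)
    if (nrow(points) < 5L) stop("need at least 5 points")
    ctr <- colMeans(points)
    cv <- crossprod(sweep(points, 2L, ctr)) / nrow(points)
    eg <- eigen(cv, symmetric = TRUE)
    if (eg$values[2L] <= 1e-12 * max(eg$values[1L], 1e-300))
        stop("degenerate geometry: points are (nearly) collinear")
    phi0 <- atan2(eg$vectors[2L, 1L], eg$vectors[1L, 1L])
    EllipseParams(ctr[1L], ctr[2L], a = sqrt(2 * eg$values[1L]),
                  b = sqrt(2 * eg$values[2L]), phi = phi0)
}

asPointMatrix <- function(points) {
    if (is(points, "Contour")) points <- points@points
    if (is.data.frame(points)) points <- as.matrix(points)
    storage.mode(points) <- "double"
    points
}

# Internal parameter vector q = (xc, yc, log a, log b, phi) -> EllipseParams
# without canonicalization (used inside the optimizer where a < b transients
# are legal).
qToEllipseRaw <- function(q)
    list(xc = q[1L], yc = q[2L], a = exp(q[3L]), b = exp(q[4L]),
         phi = q[5L])

#' Algebraic ellipse-equation residuals
#'
#' For each point, the implicit ellipse equation value minus one:
#' `((dx cos phi + dy sin phi) / a)^2 + ((-dx sin phi + dy cos phi) / b)^2
#' - 1`, with the semi-axes taken as `exp(log_a)`, `exp(log_b)` from the
#' internal parameter vector.
#'
#' @param q numeric length-5 internal parameter vector
#'   `(xc, yc, log_a, log_b, phi)`.
#' @param points numeric n x 2 coordinate matrix.
#' @return Numeric vector of n residuals (0 for points on the ellipse, -1 at
#'   the center).
#' @export
algebraicResiduals <- function(q, points) {
    points <- asPointMatrix(points)
    e <- qToEllipseRaw(q)
    dx <- points[, 1L] - e$xc
    dy <- points[, 2L] - e$yc
    cp <- cos(e$phi); sp <- sin(e$phi)
    as.numeric(((dx * cp + dy * sp) / e$a)^2 +
               ((-dx * sp + dy * cp) / e$b)^2 - 1)
}

# Menger curvature of three points: 4 * area / product of side lengths.
mengerCurvature <- function(p1, p2, p3) {
    a <- sqrt(sum((p1 - p2)^2))
    b <- sqrt(sum((p2 - p3)^2))
    cc <- sqrt(sum((p3 - p1)^2))
    if (a * b * cc == 0) return(0)
    area2 <- abs((p2[1] - p1[1]) * (p3[2] - p1[2]) -
                 (p3[1] - p1[1]) * (p2[2] - p1[2]))
    2 * area2 / (a * b * cc)
}

# Analytic ellipse curvature at boundary parameter t.
ellipseCurvature <- function(a, b, t)
    a * b / (a^2 * sin(t)^2 + b^2 * cos(t)^2)^1.5

#' Penalty residuals of the composite ellipse objective
#'
#' Appends to the algebraic residuals: (i) tangential penalties at the two
#' contour endpoints, `w_tan` times the sine of the angle between the
#' end-segment direction and the chord joining the nearest-point
#' projections of the segment's endpoints onto the ellipse (falling back to
#' the analytic tangent at the midpoint's projection when both feet
#' coincide); (ii) curvature penalties at the endpoints and midpoint,
#' `w_curv * tanh()` of the relative difference between the discrete Menger
#' curvature of a contour stencil and the Menger curvature of the stencil's
#' projected feet on the ellipse; and (iii) an eccentricity hinge,
#' `w_ecc * max(0, |log(b/a)| - r_max)`. Comparing discrete curvature
#' against the discretely-sampled ellipse (rather than its analytic
#' curvature) makes every penalty vanish exactly when the contour lies on
#' the ellipse, at any sampling density.
#'
#' @inheritParams algebraicResiduals
#' @param config a [fitConfig()] object.
#' @return Numeric vector of penalty residuals (length 6 for n >= 3; the
#'   curvature terms are skipped with a warning for shorter contours).
#' @export
penaltyResiduals <- function(q, points, config = fitConfig()) {
    points <- asPointMatrix(points)
    e <- qToEllipseRaw(q)
    # work with canonicalized params for the geometric terms
    ep <- EllipseParams(e$xc, e$yc, max(e$a, e$b), min(e$a, e$b),
                        if (e$a >= e$b) e$phi else e$phi + pi / 2)
    n <- nrow(points)
    out <- numeric(0)
    scale0 <- max(ep@a, 1e-12)
    foot <- function(p)
        nearestPointOnEllipse(p, ep, tol = config$distance_tol)
    tangentAt <- function(t) {
        # unit tangent of the canonical ellipse at parameter t, world frame
        cp <- cos(ep@phi); sp <- sin(ep@phi)
        v <- c(-ep@a * sin(t), ep@b * cos(t))
        w <- c(cp * v[1] - sp * v[2], sp * v[1] + cp * v[2])
        w / sqrt(sum(w^2))
    }
    if (config$w_tan > 0 && n >= 2L) {
        for (idx in list(c(1L, 2L), c(n - 1L, n))) {
            seg <- points[idx[2L], ] - points[idx[1L], ]
            len <- sqrt(sum(seg^2))
            if (len == 0) next
            f1 <- foot(points[idx[1L], ])$foot
            f2 <- foot(points[idx[2L], ])$foot
            ref <- f2 - f1
            refLen <- sqrt(sum(ref^2))
            if (refLen < 1e-9 * scale0) {
                # both endpoints project to the same foot (e.g. a radial
                # segment): use the analytic tangent there
                mid <- (points[idx[1L], ] + points[idx[2L], ]) / 2
                ref <- tangentAt(foot(mid)$t)
                refLen <- 1
            }
            sinAngle <- abs(seg[1L] * ref[2L] - seg[2L] * ref[1L]) /
                (len * refLen)
            out <- c(out, config$w_tan * sinAngle)
        }
    }
    if (config$w_curv > 0) {
        if (n < 3L) {
            warning("fewer than 3 points: curvature penalties skipped")
        } else {
            # stencil arms span ~n/16 samples so the discrete curvature is
            # not dominated by point-level noise on dense contours; the
            # relative difference is squashed through tanh to stay bounded
            # while keeping the zero-at-truth, locally linear behavior
            s <- max(1L, min(as.integer(floor(n / 16)),
                             as.integer(floor((n - 1L) / 2))))
            m <- max(s + 1L, min(n - s, as.integer(floor(n / 2))))
            stencils <- unique(list(c(1L, 1L + s, 1L + 2L * s),
                                    c(m - s, m, m + s),
                                    c(n - 2L * s, n - s, n)))
            for (st in stencils) {
                kM <- mengerCurvature(points[st[1L], ], points[st[2L], ],
                                      points[st[3L], ])
                feet <- lapply(st, function(i) foot(points[i, ])$foot)
                kE <- mengerCurvature(feet[[1L]], feet[[2L]], feet[[3L]])
                if (kE < 1e-12 / scale0)
                    kE <- ellipseCurvature(ep@a, ep@b,
                                           foot(points[st[2L], ])$t)
                out <- c(out, config$w_curv * tanh((kM - kE) / kE))
            }
        }
    }
    out <- c(out, config$w_ecc * max(0, abs(q[4L] - q[3L]) - config$r_max))
    as.numeric(out)
}

#' Fit a penalized least-squares ellipse and score surface roughness
#'
#' Minimizes the stacked residual vector (algebraic ellipse-equation
#' residuals plus tangential, curvature and eccentricity penalties) over the
#' internal parameter vector `(xc, yc, log_a, log_b, phi)` using bounded
#' Levenberg-Marquardt least squares, starting from the PCA estimate. The
#' center is bounded within the contour bounding box dilated by one diameter
#' and the log-axes within brackets derived from centroid distances; the
#' rotation is free and canonicalized afterwards. The per-point
#' nearest-point distances to the optimized ellipse are then computed and
#' their mean reported as the DS roughness score.
#'
#' @param points n x 2 coordinate matrix, [Contour-class] or data.frame,
#'   n >= 5. Open contours (e.g. after baseline removal) are fitted as-is;
#'   closure is never forced.
#' @param config a [fitConfig()] object.
#' @return An [EllipseFit-class] object.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 201)[-201]
#' pts <- cbind(10 * cos(th), 5 * sin(th))
#' fit <- fitEllipse(pts)
#' roughnessScore(fit)  # ~0
#' @export
fitEllipse <- function(points, config = fitConfig()) {
    points <- asPointMatrix(if (is(points, "Contour")) points else points)
    if (nrow(points) < 5L) stop("need at least 5 points to fit an ellipse")
    init <- pcaInitialEllipse(points)
    q0 <- c(init@xc, init@yc, log(init@a), log(init@b), init@phi)
    rngX <- range(points[, 1L]); rngY <- range(points[, 2L])
    diam <- max(diff(rngX), diff(rngY))
    ctr <- colMeans(points)
    rCent <- sqrt(rowSums(sweep(points, 2L, ctr)^2))
    rMax <- max(rCent)
    lower <- c(rngX[1L] - diam, rngY[1L] - diam,
               rep(log(rMax / 50), 2L), -Inf)
    upper <- c(rngX[2L] + diam, rngY[2L] + diam,
               rep(log(rMax * 50), 2L), Inf)
    q0 <- pmin(pmax(q0, lower), upper)
    resFun <- function(q)
        c(algebraicResiduals(q, points),
          suppressWarnings(penaltyResiduals(q, points, config)))
    fit <- minpack.lm::nls.lm(
        par = q0, lower = lower, upper = upper, fn = resFun,
        control = minpack.lm::nls.lm.control(
            maxiter = min(config$max_iter, 1024L),
            ftol = config$tol, ptol = config$tol, maxfev = 100000L))
    converged <- fit$info %in% 1:4
    if (!converged)
        warning("ellipse fit did not converge: ", fit$message)
    q <- fit$par
    e <- qToEllipseRaw(q)
    ellipse <- EllipseParams(e$xc, e$yc,
                             a = max(e$a, e$b), b = min(e$a, e$b),
                             phi = if (e$a >= e$b) e$phi else e$phi + pi / 2)
    d <- distancesToEllipse(points, ellipse, tol = config$distance_tol)
    new("EllipseFit", ellipse = ellipse, distances = d, ds = mean(d),
        residualNorm = fit$deviance, converged = converged,
        nPoints = nrow(points))
}

#' Fit an ellipse to a contour CSV and write a result record
#'
#' Convenience wrapper composing [readContourCSV()], [fitEllipse()] and a
#' JSON result record `{xc, yc, a, b, phi, ds, n_points, converged}`.
#'
#' @param contour_csv path of a two-column `x,y` contour file.
#' @param config a [fitConfig()] object.
#' @param out optional path for the JSON record.
#' @param units units of the stored coordinates.
#' @return The [EllipseFit-class], invisibly when `out` is given.
#' @export
fitContourFile <- function(contour_csv, config = fitConfig(), out = NULL,
                           units = "mm") {
    contour <- readContourCSV(contour_csv, units = units)
    fit <- fitEllipse(contour, config = config)
    if (!is.null(out)) {
        rec <- list(xc = fit@ellipse@xc, yc = fit@ellipse@yc,
                    a = fit@ellipse@a, b = fit@ellipse@b,
                    phi = fit@ellipse@phi, ds = fit@ds,
                    n_points = fit@nPoints, converged = fit@converged)
        jsonlite::write_json(rec, out, auto_unbox = TRUE, digits = NA)
        return(invisible(fit))
    }
    fit
}
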
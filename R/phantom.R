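#' Specification of a synthetic endplate phantom
#'
#' Describes an elliptical endplate outline with controlled radial Gaussian
#' roughness, optional localized bumps/pits (emulating osteophytic ridges and
#' resorption pits), and an optional straight horizontal chord emulating the
#' posterior cut line that baseline removal must eliminate.
#'
#' @param a_mm,b_mm semi-major and semi-minor axes in mm (`a_mm >= b_mm > 0`).
#' @param phi_rad rotation of the major axis in radians.
#' @param n_points number of boundary samples (>= 16).
#' @param sigma_radial_mm SD of the zero-mean Gaussian radial perturbation
#'   applied along the local radial direction, in mm (>= 0).
#' @param bumps list of numeric triples `c(center_angle_rad,
#'   angular_width_rad, amplitude_mm)`; positive amplitudes protrude, negative
#'   ones indent. Angular widths must lie in (0, pi).
#' @param include_baseline logical; append a straight horizontal chord of
#'   `ceiling(n_points / 4)` points at the outline's minimum y.
#' @param seed integer RNG seed; the phantom is deterministic given the spec.
#' @return A validated list of class `"PhantomSpec"`.
#' @seealso [makePhantomContour()], [rasterizePhantom()]
#' @examples
#' spec <- phantomSpec(a_mm = 15, b_mm = 10, sigma_radial_mm = 0.2, seed = 7)
#' contour <- makePhantomContour(spec)
#' @export
phantomSpec <- function(a_mm = 15, b_mm = 10, phi_rad = 0, n_points = 400,
                        sigma_radial_mm = 0.15, bumps = list(),
                        include_baseline = FALSE, seed = 1) {
    if (!(is.numeric(a_mm) && is.numeric(b_mm) && b_mm > 0 && a_mm >= b_mm))
        stop("invalid phantom spec: need a_mm >= b_mm > 0")
    if (n_points < 16) stop("invalid phantom spec: n_points must be >= 16")
    if (sigma_radial_mm < 0)
        stop("invalid phantom spec: sigma_radial_mm must be >= 0")
    bumps <- lapply(bumps, as.numeric)
    for (b in bumps) {
        if (length(b) != 3 || !all(is.finite(b)))
            stop("each bump must be c(center_angle, width, amplitude)")
        if (b[2] <= 0 || b[2] >= pi)
            stop("bump angular widths must lie in (0, pi)")
    }
    structure(list(a_mm = a_mm, b_mm = b_mm, phi_rad = phi_rad,
                   n_points = as.integer(n_points),
                   sigma_radial_mm = sigma_radial_mm, bumps = bumps,
                   include_baseline = isTRUE(include_baseline),
                   seed = as.integer(seed)),
              class = "PhantomSpec")
}

# Raised-cosine bump profile at parameter angles t (radians), wrapped.
bumpDelta <- function(t, bumps) {
    delta <- numeric(length(t))
    for (b in bumps) {
        d <- (t - b[1] + pi) %% (2 * pi) - pi
        inside <- abs(d) < b[2] / 2
        delta[inside] <- delta[inside] +
            b[3] * cos(pi * d[inside] / b[2])^2
    }
    delta
}

#' Generate a synthetic endplate contour
#'
#' Samples `n_points` parameter angles equally spaced on `[0, 2*pi)` and
#' perturbs the base ellipse radially: point i is
#' `R(phi) %*% c((a + delta_i) * cos(t_i), (b + delta_i) * sin(t_i))`, where
#' `delta_i` combines Gaussian radial noise and bump contributions. With
#' `include_baseline`, a horizontal chord of `ceiling(n_points / 4)` collinear
#' points at the outline's minimum y is appended, emulating the posterior cut
#' line.
#'
#' @param spec a [phantomSpec()] object.
#' @return A closed [Contour-class] in mm units.
#' @examples
#' ctr <- makePhantomContour(phantomSpec(a_mm = 10, b_mm = 10,
#'                                       sigma_radial_mm = 0, n_points = 64))
#' range(sqrt(rowSums(contourPoints(ctr)^2)))  # all radii 10
#' @export
makePhantomContour <- function(spec) {
    if (!inherits(spec, "PhantomSpec")) spec <- do.call(phantomSpec, spec)
    n <- spec$n_points
    t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    delta <- withSeed(spec$seed, rnorm(n, 0, spec$sigma_radial_mm)) +
        bumpDelta(t, spec$bumps)
    px <- (spec$a_mm + delta) * cos(t)
    py <- (spec$b_mm + delta) * sin(t)
    cp <- cos(spec$phi_rad); sp <- sin(spec$phi_rad)
    pts <- cbind(x = cp * px - sp * py, y = sp * px + cp * py)
    if (spec$include_baseline) {
        m <- max(2L, as.integer(ceiling(n / 4)))
        y0 <- min(pts[, 2])
        xmid <- mean(range(pts[, 1]))
        halfspan <- diff(range(pts[, 1])) / 4
        chord <- cbind(x = seq(xmid - halfspan, xmid + halfspan,
                               length.out = m),
                       y = rep(y0, m))
        pts <- rbind(pts, chord)
    }
    Contour(pts, units = "mm", closed = TRUE)
}

# Bresenham line between integer pixel coordinates; returns matrix of
# (col, row) pairs including both endpoints.
bresenham <- function(x0, y0, x1, y1) {
    dx <- abs(x1 - x0); dy <- abs(y1 - y0)
    sx <- if (x0 < x1) 1L else -1L
    sy <- if (y0 < y1) 1L else -1L
    err <- dx - dy
    npix <- dx + dy + 1L
    out <- matrix(0L, npix, 2L)
    i <- 0L
    repeat {
        i <- i + 1L
        out[i, ] <- c(x0, y0)
        if (x0 == x1 && y0 == y1) break
        e2 <- 2L * err
        if (e2 > -dy) { err <- err - dy; x0 <- x0 + sx }
        if (e2 < dx)  { err <- err + dx; y0 <- y0 + sy }
    }
    out[seq_len(i), , drop = FALSE]
}

#' Rasterize a contour into an 8-bit grayscale image
#'
#' Draws the boundary as 255-valued pixels on a 0 background by joining
#' consecutive contour points with Bresenham line segments (closing the
#' polygon for closed contours). The image covers the contour bounding box
#' plus `pad_px` padding on every side; the true mm-per-pixel factor is
#' recorded in the `"pixelSizeMM"` attribute for round-trip tests.
#'
#' @param contour a [Contour-class] in mm units.
#' @param pixel_size_mm physical size of one pixel in mm (> 0).
#' @param pad_px integer padding in pixels around the bounding box.
#' @return Integer matrix in \{0, 255\} (rows = image y, top-left origin,
#'   columns = image x) with attributes `pixelSizeMM` and `originMM`.
#' @examples
#' img <- rasterizePhantom(makePhantomContour(phantomSpec(
#'     a_mm = 10, b_mm = 10, sigma_radial_mm = 0, n_points = 180)),
#'     pixel_size_mm = 0.2)
#' dim(img)
#' @export
rasterizePhantom <- function(contour, pixel_size_mm = 0.1, pad_px = 4L) {
    stopifnot(is(contour, "Contour"))
    if (nrow(contour@points) < 2L)
        stop("cannot rasterize a contour with fewer than 2 points")
    if (pixel_size_mm <= 0) stop("pixel_size_mm must be positive")
    pad_px <- as.integer(pad_px)
    pts <- contour@points
    xmin <- min(pts[, 1]); ymax <- max(pts[, 2])
    # image frame: x right, y down
    col <- as.integer(round((pts[, 1] - xmin) / pixel_size_mm)) + 1L + pad_px
    row <- as.integer(round((ymax - pts[, 2]) / pixel_size_mm)) + 1L + pad_px
    ncolI <- max(col) + pad_px
    nrowI <- max(row) + pad_px
    img <- matrix(0L, nrowI, ncolI)
    n <- length(col)
    idx <- if (contour@closed) c(seq_len(n), 1L) else seq_len(n)
    for (i in seq_len(length(idx) - 1L)) {
        seg <- bresenham(col[idx[i]], row[idx[i]],
                         col[idx[i + 1L]], row[idx[i + 1L]])
        img[cbind(seg[, 2L], seg[, 1L])] <- 255L
    }
    attr(img, "pixelSizeMM") <- pixel_size_mm
    attr(img, "originMM") <- c(x = xmin - pad_px * pixel_size_mm,
                               y = ymax + pad_px * pixel_size_mm)
    img
}
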
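#' Otsu threshold of an 8-bit grayscale image
#'
#' Finds the intensity threshold maximizing the between-class variance of the
#' image histogram and returns the binary mask under the convention
#' `mask = 1` where `I >= theta`, 0 otherwise. Intensities are binned at
#' integer values 0--255 (non-integer inputs are rounded for the histogram).
#'
#' @param image numeric/integer matrix of intensities in \[0, 255\]
#'   (rows = image y from the top, columns = image x).
#' @return list with elements `threshold` (numeric theta) and `mask`
#'   (integer matrix in \{0, 1\}, same shape as `image`).
#' @examples
#' img <- matrix(c(rep(0, 8), rep(255, 8)), 4, 4)
#' otsuThreshold(img)$threshold
#' @export
otsuThreshold <- function(image) {
    if (!is.matrix(image) || length(image) == 0L)
        stop("image must be a non-empty matrix")
    v <- as.integer(round(image))
    if (min(v) < 0L || max(v) > 255L)
        stop("intensities must lie in [0, 255]")
    if (min(v) == max(v))
        stop("degenerate histogram: image has a single intensity value")
    counts <- tabulate(v + 1L, nbins = 256L)
    n <- length(v)
    vals <- 0:255
    # threshold theta = t: class0 = {I < t} (bins 0..t-1), class1 = {I >= t}
    c0 <- cumsum(counts)          # c0[i] = #pixels with I <= i-1
    s0 <- cumsum(counts * vals)   # intensity sum of the same
    t <- 1:255
    w0 <- c0[t] / n
    w1 <- 1 - w0
    ok <- w0 > 0 & w1 > 0
    mu0 <- s0[t] / pmax(c0[t], 1L)
    mu1 <- (s0[256L] - s0[t]) / pmax(n - c0[t], 1L)
    sigmaB <- ifelse(ok, w0 * w1 * (mu0 - mu1)^2, -Inf)
    theta <- t[which.max(sigmaB)]
    mask <- matrix(as.integer(image >= theta), nrow(image), ncol(image))
    list(threshold = as.numeric(theta), mask = mask)
}

# Label 8-connected foreground components by BFS.
# Returns an integer matrix of labels (0 = background), labels assigned in
# row-major scan order of each component's first pixel.
labelComponents <- function(mask) {
    nr <- nrow(mask); nc <- ncol(mask)
    lab <- matrix(0L, nr, nc)
    fg <- mask != 0
    nextLab <- 0L
    # row-major scan: rows within columns is R default; we scan by row
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
        if (!fg[r, cc] || lab[r, cc] != 0L) next
        nextLab <- nextLab + 1L
        queue <- c(r + (cc - 1L) * nr)
        lab[r, cc] <- nextLab
        while (length(queue)) {
            newq <- integer(0)
            rr <- (queue - 1L) %% nr + 1L
            ccc <- (queue - 1L) %/% nr + 1L
            for (dr in -1:1) for (dc in -1:1) {
                if (dr == 0L && dc == 0L) next
                r2 <- rr + dr; c2 <- ccc + dc
                keep <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
                if (!any(keep)) next
                idx <- r2[keep] + (c2[keep] - 1L) * nr
                idx <- idx[fg[idx] & lab[idx] == 0L]
                if (length(idx)) {
                    lab[idx] <- nextLab
                    newq <- c(newq, idx)
                }
            }
            queue <- unique(newq)
        }
    }
    lab
}

# Moore-neighbor boundary tracing (8-connectivity, clockwise in image
# coordinates with y down) of one labeled component. Returns the full outer
# boundary pixel chain as an (x = col, y = row) matrix; holes are never
# visited. Stopping uses Jacob's criterion (revisit of the start pixel with
# the same backtrack state).
traceBoundary <- function(isfg, startRow, startCol) {
    # clockwise neighbor order starting at W: (drow, dcol)
    dirs <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
                  c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
    nr <- nrow(isfg); nc <- ncol(isfg)
    inb <- function(r, cc) r >= 1L && r <= nr && cc >= 1L && cc <= nc
    path <- matrix(0L, 0L, 2L)
    pr <- startRow; pc <- startCol
    # backtrack starts at the W neighbor (background for a topmost-leftmost
    # start pixel)
    bdir <- 1L
    firstState <- NULL
    maxSteps <- 8L * (nr * nc + 1L)
    chain <- vector("list", 0L)
    step <- 0L
    repeat {
        step <- step + 1L
        if (step > maxSteps) stop("boundary tracing failed to terminate")
        chain[[length(chain) + 1L]] <- c(pc, pr)
        # scan clockwise starting just after the backtrack direction
        found <- FALSE
        for (k in 1:8) {
            d <- ((bdir - 1L + k - 1L) %% 8L) + 1L
            r2 <- pr + dirs[d, 1L]; c2 <- pc + dirs[d, 2L]
            if (inb(r2, c2) && isfg[r2, c2]) {
                # new backtrack: direction pointing from new pixel to the
                # previously examined (background) position
                prevd <- ((d - 2L) %% 8L) + 1L
                br <- pr + dirs[prevd, 1L]; bc <- pc + dirs[prevd, 2L]
                pr <- r2; pc <- c2
                # direction index from new pixel toward backtrack position
                ddr <- br - pr; ddc <- bc - pc
                bdir <- which(dirs[, 1L] == ddr & dirs[, 2L] == ddc)
                found <- TRUE
                break
            }
        }
        if (!found) break  # isolated pixel
        state <- c(pr, pc, bdir)
        if (is.null(firstState)) firstState <- state
        else if (all(state == firstState)) break
    }
    do.call(rbind, chain)
}

#' Extract external contours of a binary mask
#'
#' Returns the outer boundary of every 8-connected foreground component as an
#' ordered pixel chain (no polygonal simplification); inner hole boundaries
#' are not returned. Components are reported in row-major scan order of their
#' topmost-leftmost pixel.
#'
#' @param mask matrix; non-zero entries are foreground.
#' @return list of [Contour-class] objects in px units.
#' @examples
#' m <- matrix(0L, 12, 12); m[2:11, 2:11] <- 1L
#' length(extractExternalContours(m))
#' @export
extractExternalContours <- function(mask) {
    if (!is.matrix(mask)) stop("mask must be a matrix")
    if (!any(mask != 0)) stop("empty mask: no foreground pixels")
    lab <- labelComponents(mask)
    nlab <- max(lab)
    out <- vector("list", nlab)
    for (l in seq_len(nlab)) {
        isfg <- lab == l
        # topmost row, then leftmost column
        rows <- row(isfg)[isfg]; cols <- col(isfg)[isfg]
        r0 <- min(rows)
        c0 <- min(cols[rows == r0])
        chain <- traceBoundary(isfg, r0, c0)
        # drop the duplicated closing vertex if tracing re-listed the start
        if (nrow(chain) > 1L && all(chain[1L, ] == chain[nrow(chain), ]))
            chain <- chain[-nrow(chain), , drop = FALSE]
        # collapse any consecutive duplicates defensively
        if (nrow(chain) > 1L) {
            dup <- c(FALSE, rowSums(abs(diff(chain))) == 0)
            chain <- chain[!dup, , drop = FALSE]
        }
        out[[l]] <- Contour(chain, units = "px", closed = TRUE)
    }
    out
}

#' Select the largest contour by enclosed polygon area
#'
#' Ties are broken deterministically toward the first contour in scan order;
#' a tie is reported with a warning.
#'
#' @param contours non-empty list of [Contour-class] objects.
#' @return The contour with maximal shoelace area.
#' @export
selectLargestContour <- function(contours) {
    if (!length(contours)) stop("empty contour list")
    areas <- vapply(contours, function(ct) polygonArea(ct@points), 0)
    best <- which.max(areas)
    if (sum(areas == areas[best]) > 1L)
        warning("area tie between contours; keeping the first in scan order")
    contours[[best]]
}

#' Remove the straight baseline from a pixel contour
#'
#' Computes the modal integer-rounded y-coordinate `y*` of the contour points
#' and removes every point within `tau_px` of it, eliminating the horizontal
#' posterior cut line while preserving true surface undulations. Modal ties
#' are broken toward the candidate with more points within `tau_px`, then
#' toward the smaller y.
#'
#' @param contour a [Contour-class] in px units.
#' @param tau_px non-negative tolerance in pixels (default 2).
#' @return A [Contour-class] (open) containing exactly the points with
#'   `|y - y*| > tau_px`, in their original order.
#' @export
removeBaseline <- function(contour, tau_px = 2) {
    stopifnot(is(contour, "Contour"))
    if (contour@units != "px") stop("baseline removal expects a px contour")
    if (tau_px < 0) stop("tau_px must be >= 0")
    y <- contour@points[, 2L]
    yr <- round(y)
    tabY <- table(yr)
    cand <- as.numeric(names(tabY))[tabY == max(tabY)]
    if (length(cand) > 1L) {
        nearby <- vapply(cand, function(y0) sum(abs(y - y0) <= tau_px), 0L)
        cand <- cand[nearby == max(nearby)]
        yStar <- min(cand)
    } else yStar <- cand
    keep <- abs(y - yStar) > tau_px
    if (!any(keep))
        stop(sprintf(paste0("baseline removal left no points ",
                            "(y* = %g, tau = %g, y range [%g, %g])"),
                     yStar, tau_px, min(y), max(y)))
    out <- Contour(contour@points[keep, , drop = FALSE], units = "px",
                   closed = FALSE)
    attr(out, "yStar") <- yStar
    out
}

#' Scale a pixel contour to millimetres
#'
#' Multiplies coordinates by `ref_len_mm / ref_len_px` (the mm-per-pixel
#' factor measured from the reference scale line), flips the y axis to
#' mathematical orientation (y up) and recenters the origin at the contour
#' centroid.
#'
#' @param contour a [Contour-class] in px units.
#' @param ref_len_mm,ref_len_px physical and pixel lengths of the reference
#'   line (> 0).
#' @return A [Contour-class] in mm units.
#' @export
scaleContour <- function(contour, ref_len_mm, ref_len_px) {
    stopifnot(is(contour, "Contour"))
    if (contour@units != "px") stop("contour is already scaled")
    if (ref_len_mm <= 0 || ref_len_px <= 0)
        stop("reference lengths must be positive")
    f <- ref_len_mm / ref_len_px
    pts <- cbind(x = contour@points[, 1L] * f,
                 y = -contour@points[, 2L] * f)
    pts <- sweep(pts, 2L, colMeans(pts))
    Contour(pts, units = "mm", closed = contour@closed)
}

# 3x3 median filter (edge pixels keep enough neighbors via clamping).
medianFilter3 <- function(image) {
    nr <- nrow(image); nc <- ncol(image)
    stacks <- array(NA_real_, c(nr, nc, 9L))
    k <- 0L
    for (dr in -1:1) for (dc in -1:1) {
        k <- k + 1L
        rs <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
        cs <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
        stacks[, , k] <- image[rs, cs]
    }
    matrix(apply(stacks, c(1, 2), stats::median), nr, nc)
}

#' Full image-to-contour pipeline
#'
#' Composition of the extraction stages: Otsu thresholding, external contour
#' tracing, largest-contour selection, baseline removal and mm scaling.
#' Optionally applies a 3x3 median pre-filter and writes the resulting
#' coordinates to a two-column CSV.
#'
#' @param image intensity matrix in \[0, 255\] (see [otsuThreshold()]), or a
#'   path readable by [readGrayImage()].
#' @param ref_len_mm,ref_len_px reference-line lengths for mm scaling.
#' @param tau_px baseline-removal tolerance in pixels (default 2).
#' @param median_filter apply a 3x3 median pre-filter (default `FALSE`).
#' @param csv_out optional path; when given, the contour is written as a
#'   CSV with header `x,y`.
#' @return A [Contour-class] in mm units.
#' @seealso [removeBaseline()], [scaleContour()], [fitEllipse()]
#' @export
imageToContour <- function(image, ref_len_mm, ref_len_px, tau_px = 2,
                           median_filter = FALSE, csv_out = NULL) {
    if (is.character(image)) image <- readGrayImage(image)
    if (median_filter) image <- medianFilter3(image)
    ot <- otsuThreshold(image)
    contour <- selectLargestContour(extractExternalContours(ot$mask))
    contour <- removeBaseline(contour, tau_px = tau_px)
    contour <- scaleContour(contour, ref_len_mm, ref_len_px)
    if (!is.null(csv_out)) writeContourCSV(contour, csv_out)
    contour
}
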
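# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures are stored.

# Points on an ellipse boundary, optionally an open arc and with radial
# Gaussian noise.
ellipsePoints <- function(a, b, phi = 0, center = c(0, 0), n = 200,
                          tRange = c(0, 2 * pi), noise = 0, closed = TRUE) {
    t <- if (closed && abs(diff(tRange) - 2 * pi) < 1e-12)
        seq(tRange[1], tRange[2], length.out = n + 1)[-(n + 1)]
    else seq(tRange[1], tRange[2], length.out = n)
    d <- if (noise > 0) stats::rnorm(n, 0, noise) else 0
    px <- (a + d) * cos(t); py <- (b + d) * sin(t)
    cbind(x = center[1] + cos(phi) * px - sin(phi) * py,
          y = center[2] + sin(phi) * px + cos(phi) * py)
}

# Parametric brute-force nearest distance to an ellipse boundary.
bruteForceDistance <- function(point, ellipse, nGrid = 2e5,
                               grid = NULL) {
    if (is.null(grid)) {
        t <- seq(0, 2 * pi, length.out = nGrid + 1)[-(nGrid + 1)]
        grid <- list(ct = cos(t), st = sin(t))
    }
    cp <- cos(ellipse@phi); sp <- sin(ellipse@phi)
    ex <- ellipse@xc + cp * ellipse@a * grid$ct - sp * ellipse@b * grid$st
    ey <- ellipse@yc + sp * ellipse@a * grid$ct + cp * ellipse@b * grid$st
    sqrt(min((ex - point[1])^2 + (ey - point[2])^2))
}

# Exhaustive-search Otsu oracle: maximal between-class variance over all
# 256 candidate thresholds, computed by a naive per-threshold loop.
bruteForceOtsu <- function(image) {
    v <- as.integer(round(image))
    best <- -Inf; bestT <- NA_integer_
    for (t in 1:255) {
        lo <- v[v < t]; hi <- v[v >= t]
        if (!length(lo) || !length(hi)) next
        w0 <- length(lo) / length(v); w1 <- 1 - w0
        sB <- w0 * w1 * (mean(lo) - mean(hi))^2
        if (sB > best) { best <- sB; bestT <- t }
    }
    list(threshold = bestT, sigmaB = best)
}

# Between-class variance at a given threshold (for tie-robust comparison).
sigmaBAt <- function(image, t) {
    v <- as.integer(round(image))
    lo <- v[v < t]; hi <- v[v >= t]
    if (!length(lo) || !length(hi)) return(-Inf)
    w0 <- length(lo) / length(v)
    w0 * (1 - w0) * (mean(lo) - mean(hi))^2
}

# Small deterministic synthetic cohort reused across statistics tests.
smallCohort <- function(seed = 11, n_male = 94, n_female = 82)
    makeSyntheticCohort(cohortSimSpec(n_male = n_male, n_female = n_female,
                                      seed = seed))

# Generator spec under which the linear DS-age model is exactly true:
# intercepts far from the positivity floor, so no truncation occurs and
# OLS confidence intervals have their nominal coverage.
recoverySpec <- function(seed, n_male = 500, n_female = 500) {
    lab <- vertebraLabels()
    sl <- stats::setNames(seq(0.004, 0.012, length.out = 19), lab)
    cohortSimSpec(
        n_male = n_male, n_female = n_female,
        slopes = list(M = sl, F = rev(sl)),
        intercepts = list(M = stats::setNames(rep(1.5, 19), lab),
                          F = stats::setNames(rep(1.8, 19), lab)),
        noise_sd = list(M = stats::setNames(rep(0.2, 19), lab),
                        F = stats::setNames(rep(0.25, 19), lab)),
        seed = seed)
}
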
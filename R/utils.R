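#' Vertebra labels used throughout the package
#'
#' The 19 vertebral levels scored for endplate roughness, in cranio-caudal
#' order: C7, T1--T12, L1--L5, S1.
#'
#' @return Character vector of length 19.
#' @examples
#' vertebraLabels()
#' @export
vertebraLabels <- function()
    c("C7", paste0("T", 1:12), paste0("L", 1:5), "S1")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit({
        if (had) assign(".Random.seed", old, envir = genv)
        else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
    })
    set.seed(seed)
    code
}

# Derive a child seed from a master seed and a stream index, staying < 2^31.
childSeed <- function(seed, stream)
    (as.numeric(seed) * 1000003 + 7919 * as.numeric(stream)) %% 2147483629

# Shoelace area of a polygon given an n x 2 coordinate matrix (closed
# implicitly). Positive regardless of orientation.
polygonArea <- function(points) {
    n <- nrow(points)
    if (n < 3L) return(0)
    x <- points[, 1L]; y <- points[, 2L]
    xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
    abs(sum(x * yn - xn * y)) / 2
}

# R-squared of predictions against observed values.
rSquared <- function(truth, pred) {
    sst <- sum((truth - mean(truth))^2)
    if (sst == 0) return(NA_real_)
    1 - sum((truth - pred)^2) / sst
}

# Standard error of the estimate (Eq.-style): sqrt(SSR / (n - k - 1)).
seeFromResiduals <- function(residuals, k, warnSmall = TRUE) {
    n <- length(residuals)
    dfree <- n - k - 1
    if (dfree < 1) {
        if (warnSmall)
            warning("n - k - 1 < 1; SEE computed with divisor max(1, n-k-1)")
        dfree <- max(1, dfree)
    }
    sqrt(sum(residuals^2) / dfree)
}
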
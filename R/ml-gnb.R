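#' Discretized Gaussian naive-Bayes pseudo-regressor
#'
#' Discretizes the continuous response into equal-frequency bins (edges at
#' empirical quantiles), fits a Gaussian naive-Bayes classifier to the
#' binned labels (per-bin, per-feature Gaussian likelihoods with a shared
#' variance floor of `1e-9` times the largest overall feature variance, as
#' a numerical smoother), and projects the posterior back to the continuous
#' scale: the prediction is the posterior-weighted mean of the bin
#' mid-points, `sum_b P(b | x) * (lower_b + upper_b) / 2`.
#'
#' @param x numeric feature matrix (n x p).
#' @param y numeric response (ages).
#' @param n_bins number of equal-frequency bins (>= 1; must not exceed the
#'   number of distinct response values).
#' @return An object of class `"gnbReg"` with a [predict.gnbReg()] method.
#' @examples
#' x <- matrix(rnorm(40), 20, 2)
#' y <- seq(20, 90, length.out = 20)
#' m <- gnbRegressor(x, y, n_bins = 4)
#' range(predict(m, x))
#' @export
gnbRegressor <- function(x, y, n_bins = 5) {
    x <- as.matrix(x)
    n_bins <- as.integer(n_bins)
    if (n_bins < 1L) stop("n_bins must be >= 1")
    if (n_bins > length(unique(y)))
        stop("n_bins exceeds the number of distinct response values")
    edges <- stats::quantile(y, probs = seq(0, 1, length.out = n_bins + 1L),
                             names = FALSE)
    if (anyDuplicated(edges))
        stop("duplicated quantile edges: too few distinct response values ",
             "for ", n_bins, " equal-frequency bins")
    bin <- cut(y, breaks = edges, include.lowest = TRUE, labels = FALSE)
    mid <- (edges[-length(edges)] + edges[-1L]) / 2
    p <- ncol(x)
    varFloor <- 1e-9 * max(apply(x, 2L, stats::var), 1e-300)
    mu <- matrix(NA_real_, n_bins, p)
    s2 <- matrix(NA_real_, n_bins, p)
    prior <- numeric(n_bins)
    for (b in seq_len(n_bins)) {
        rows <- bin == b
        prior[b] <- mean(rows)
        xb <- x[rows, , drop = FALSE]
        mu[b, ] <- colMeans(xb)
        vb <- if (nrow(xb) > 1L)
            apply(xb, 2L, function(col) mean((col - mean(col))^2))
        else rep(0, p)
        s2[b, ] <- vb + varFloor
    }
    structure(list(edges = edges, midpoints = mid, prior = prior, mu = mu,
                   s2 = s2, n_bins = n_bins, p = p),
              class = "gnbReg")
}

#' @rdname gnbRegressor
#' @param object a fitted `"gnbReg"` model.
#' @param newdata numeric feature matrix.
#' @param ... ignored.
#' @return `predict.gnbReg`: numeric vector of posterior-expected ages,
#'   always within `[min(midpoints), max(midpoints)]`.
#' @export
predict.gnbReg <- function(object, newdata, ...) {
    xs <- as.matrix(newdata)
    if (ncol(xs) != object$p) stop("feature count mismatch")
    n <- nrow(xs)
    logpost <- matrix(NA_real_, n, object$n_bins)
    for (b in seq_len(object$n_bins)) {
        ll <- rowSums(stats::dnorm(
            xs, mean = matrix(object$mu[b, ], n, object$p, byrow = TRUE),
            sd = matrix(sqrt(object$s2[b, ]), n, object$p, byrow = TRUE),
            log = TRUE))
        logpost[, b] <- log(object$prior[b]) + ll
    }
    logpost <- logpost - apply(logpost, 1L, max)
    post <- exp(logpost)
    post <- post / rowSums(post)
    as.numeric(post %*% object$midpoints)
}
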
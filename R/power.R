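#' Cohen's f2 effect size
#'
#' Converts a coefficient of determination to Cohen's effect-size index
#' `f2 = r2 / (1 - r2)` for the overall regression F-test.
#'
#' @param r2 coefficient of determination in \[0, 1).
#' @return Non-negative effect size.
#' @examples
#' cohensF2(0.399)  # ~0.66
#' @export
cohensF2 <- function(r2) {
    if (any(r2 < 0) || any(r2 >= 1)) stop("r2 must lie in [0, 1)")
    r2 / (1 - r2)
}

#' Non-centrality parameter of the regression F-test
#'
#' `lambda = f2 * df2`, parameterizing the non-central F distribution of the
#' overall test statistic under the observed effect size.
#'
#' @param f2 Cohen's effect size (>= 0).
#' @param df2 denominator degrees of freedom `n - k - 1` (> 0).
#' @return Non-centrality parameter.
#' @export
noncentrality <- function(f2, df2) {
    if (any(f2 < 0)) stop("f2 must be >= 0")
    if (any(df2 <= 0)) stop("df2 must be positive")
    f2 * df2
}

#' Achieved power of the overall regression F-test
#'
#' Computes the central-F upper-`alpha` critical value and evaluates the
#' non-central F survival function there:
#' `power = 1 - pf(f_crit, df1, df2, ncp = lambda)`.
#'
#' @param df1,df2 numerator and denominator degrees of freedom (> 0).
#' @param lambda_nc non-centrality parameter (>= 0).
#' @param alpha significance level in (0, 1).
#' @return list with `f_crit` and `power`.
#' @examples
#' achievedPower(19, 74, 49.1)$power  # ~0.992
#' @export
achievedPower <- function(df1, df2, lambda_nc, alpha = 0.05) {
    if (df1 <= 0 || df2 <= 0) stop("degrees of freedom must be positive")
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
    if (lambda_nc < 0) stop("lambda must be >= 0")
    fCrit <- stats::qf(1 - alpha, df1, df2)
    list(f_crit = fCrit,
         power = 1 - stats::pf(fCrit, df1, df2, ncp = lambda_nc))
}

#' Post hoc power report for a fitted regression
#'
#' Chains [cohensF2()], [noncentrality()] and [achievedPower()] from an
#' observed R-squared, sample size and predictor count.
#'
#' @param r2 observed coefficient of determination.
#' @param n sample size.
#' @param k number of predictors.
#' @param alpha significance level.
#' @return A [PowerReport-class] object.
#' @examples
#' powerReport(r2 = 0.399, n = 94, k = 19)
#' @export
powerReport <- function(r2, n, k, alpha = 0.05) {
    df1 <- k
    df2 <- n - k - 1
    if (df2 <= 0) stop("n - k - 1 must be positive")
    f2 <- cohensF2(r2)
    lambda <- noncentrality(f2, df2)
    pw <- achievedPower(df1, df2, lambda, alpha)
    new("PowerReport", r2 = as.numeric(r2), f2 = f2, df1 = as.numeric(df1),
        df2 = as.numeric(df2), alpha = alpha, lambda = lambda,
        fCrit = pw$f_crit, power = pw$power)
}
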
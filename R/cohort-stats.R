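dsFormula <- function()
    stats::reformulate(sprintf("`%s`", vertebraLabels()), response = "age")

#' Sex-specific descriptive statistics of the DS panel
#'
#' Mean, SD, median, range and the t-based 95% confidence interval of the
#' mean (`mean +/- t_{0.975, n-1} * SD / sqrt(n)`) per vertebra and sex.
#'
#' @param cohort validated cohort data.frame (see [validateCohort()]).
#' @param conf confidence level (default 0.95).
#' @return data.frame with one row per (sex, vertebra).
#' @export
descriptiveStats <- function(cohort, conf = 0.95) {
    cohort <- validateCohort(cohort, min_age = -Inf)
    out <- list()
    for (s in c("M", "F")) {
        sub <- cohort[cohort$sex == s, , drop = FALSE]
        n <- nrow(sub)
        if (n < 2L) {
            warning("fewer than 2 subjects for sex ", s,
                    "; confidence intervals omitted")
        }
        for (v in vertebraLabels()) {
            x <- sub[[v]]
            half <- if (n >= 2L)
                stats::qt(1 - (1 - conf) / 2, n - 1L) *
                    stats::sd(x) / sqrt(n)
            else NA_real_
            out[[length(out) + 1L]] <- data.frame(
                sex = s, vertebra = v, n = n, mean = mean(x),
                sd = if (n >= 2L) stats::sd(x) else NA_real_,
                median = stats::median(x), min = min(x), max = max(x),
                ci_lo = mean(x) - half, ci_hi = mean(x) + half)
        }
    }
    do.call(rbind, out)
}

#' Sex-difference test for one DS variable
#'
#' Two-sided Mann-Whitney U test of the male versus female distributions
#' (exact when both groups have fewer than 20 subjects and no ties, normal
#' approximation with tie correction otherwise). A Welch t-test is available
#' as an alternative.
#'
#' @param cohort validated cohort data.frame.
#' @param variable one of [vertebraLabels()] (or `"age"`).
#' @param method `"wilcoxon"` (default) or `"welch"`.
#' @return Two-sided p-value.
#' @export
sexDifferenceTest <- function(cohort, variable,
                              method = c("wilcoxon", "welch")) {
    method <- match.arg(method)
    xm <- cohort[cohort$sex == "M", variable]
    xf <- cohort[cohort$sex == "F", variable]
    if (!length(xm) || !length(xf)) stop("both sexes must be present")
    if (method == "welch")
        return(stats::t.test(xm, xf)$p.value)
    exact <- length(xm) < 20L && length(xf) < 20L &&
        !anyDuplicated(c(xm, xf))
    suppressWarnings(
        stats::wilcox.test(xm, xf, exact = exact, correct = !exact)$p.value)
}

#' Per-sex age correlations of every DS variable
#'
#' Rank (Spearman, default) or Pearson correlation between chronological age
#' and each vertebral DS value, fitted separately per sex. Spearman p-values
#' use the t approximation with mid-ranked ties.
#'
#' @param cohort validated cohort data.frame.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return data.frame with columns sex, vertebra, r, p (r is `NA` and
#'   flagged `degenerate` for constant variables).
#' @export
ageCorrelations <- function(cohort, method = c("spearman", "pearson")) {
    method <- match.arg(method)
    out <- list()
    for (s in c("M", "F")) {
        sub <- cohort[cohort$sex == s, , drop = FALSE]
        if (nrow(sub) < 4L) stop("need >= 4 subjects per sex")
        for (v in vertebraLabels()) {
            if (stats::sd(sub[[v]]) == 0 || stats::sd(sub$age) == 0) {
                out[[length(out) + 1L]] <- data.frame(
                    sex = s, vertebra = v, r = NA_real_, p = NA_real_,
                    degenerate = TRUE)
                next
            }
            ct <- suppressWarnings(stats::cor.test(
                sub$age, sub[[v]], method = method, exact = FALSE))
            out[[length(out) + 1L]] <- data.frame(
                sex = s, vertebra = v, r = unname(ct$estimate),
                p = ct$p.value, degenerate = FALSE)
        }
    }
    do.call(rbind, out)
}

#' ANCOVA screen for sex-specific age--DS relations
#'
#' Fits `age ~ sex + DS metrics + sex:metrics` by ordinary least squares on
#' the pooled cohort and jointly tests the 20 sex-related coefficients (sex
#' main effect plus the 19 interactions) with a Wald F test (equivalently,
#' the extra-sum-of-squares comparison against the metrics-only model). A
#' significant joint test motivates fitting all downstream models separately
#' per sex.
#'
#' @param cohort validated cohort data.frame with both sexes.
#' @return list with `f_stat`, `df1`, `df2`, `p_value` (joint), and
#'   `min_term_p`, `min_term` over the individual sex-related coefficients.
#' @export
ancovaInteractionScreen <- function(cohort) {
    cohort <- validateCohort(cohort, min_age = -Inf)
    if (length(unique(cohort$sex)) < 2L) stop("both sexes must be present")
    dat <- cohort
    dat$sex <- factor(dat$sex, levels = c("F", "M"))
    labs <- sprintf("`%s`", vertebraLabels())
    fullF <- stats::as.formula(paste(
        "age ~ sex +", paste(labs, collapse = " + "), "+",
        paste(paste0("sex:", labs), collapse = " + ")))
    redF <- stats::as.formula(paste(
        "age ~", paste(labs, collapse = " + ")))
    full <- stats::lm(fullF, data = dat)
    if (anyNA(stats::coef(full))) {
        bad <- names(stats::coef(full))[is.na(stats::coef(full))]
        stop("singular design; aliased columns: ",
             paste(bad, collapse = ", "))
    }
    red <- stats::lm(redF, data = dat)
    av <- stats::anova(red, full)
    co <- summary(full)$coefficients
    sexRows <- grepl("^sex", rownames(co))
    list(f_stat = av$F[2L], df1 = av$Df[2L], df2 = av$Res.Df[2L],
         p_value = av$`Pr(>F)`[2L],
         min_term_p = min(co[sexRows, 4L]),
         min_term = rownames(co)[sexRows][which.min(co[sexRows, 4L])])
}

# SPSS-style condition indices: columns of the intercept-included design
# scaled to unit length, sqrt(lambda_max / lambda_j) of crossprod.
conditionIndices <- function(X) {
    Xs <- sweep(X, 2L, sqrt(colSums(X^2)), "/")
    ev <- eigen(crossprod(Xs), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    sqrt(max(ev) / ev)
}

#' Sex-specific multiple linear regression benchmark
#'
#' Ordinary least squares of age on the 19 DS values for one sex, with the
#' classical report: R, R-squared, adjusted R-squared, the standard error of
#' the estimate `sqrt(SSR / (n - k - 1))` with k = 19, the overall F test,
#' per-coefficient tests, and collinearity diagnostics (VIF from auxiliary
#' regressions, tolerance = 1/VIF, SPSS-style condition indices of the
#' unit-length-scaled design including the intercept).
#'
#' @param cohort validated cohort data.frame.
#' @param sex `"M"` or `"F"`.
#' @return list of class `"RegressionReport"`.
#' @export
mlrFit <- function(cohort, sex = c("M", "F")) {
    sex <- match.arg(sex)
    sub <- cohort[cohort$sex == sex, , drop = FALSE]
    k <- length(vertebraLabels())
    n <- nrow(sub)
    if (n <= k + 1L)
        stop("need n > k + 1 = ", k + 1L, " subjects; got ", n)
    X <- as.matrix(sub[, vertebraLabels()])
    qrX <- qr(cbind(1, X))
    if (qrX$rank < k + 1L) {
        bad <- colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]]
        stop("aliased (perfectly collinear) predictors: ",
             paste(bad, collapse = ", "))
    }
    fit <- stats::lm(dsFormula(), data = sub)
    sm <- summary(fit)
    see <- seeFromResiduals(stats::residuals(fit), k)
    vif <- vapply(seq_len(k), function(j) {
        r2j <- summary(stats::lm(X[, j] ~ X[, -j]))$r.squared
        1 / (1 - r2j)
    }, 0)
    names(vif) <- vertebraLabels()
    structure(list(
        sex = sex, n = n, k = k,
        r = sqrt(sm$r.squared), r2 = sm$r.squared,
        adj_r2 = sm$adj.r.squared, see_years = see,
        f_stat = unname(sm$fstatistic[1L]),
        df1 = unname(sm$fstatistic[2L]), df2 = unname(sm$fstatistic[3L]),
        p_value = unname(stats::pf(sm$fstatistic[1L], sm$fstatistic[2L],
                                   sm$fstatistic[3L], lower.tail = FALSE)),
        coefficients = sm$coefficients,
        vif = vif, tolerance = 1 / vif,
        condition_indices = conditionIndices(cbind(1, X)),
        model = fit), class = "RegressionReport")
}

#' Flag extreme outliers in the DS panel
#'
#' Marks, per sex and vertebra, values more than `threshold` SDs from the
#' sex mean. Records are flagged, not removed, unless `remove = TRUE`.
#'
#' @param cohort validated cohort data.frame.
#' @param threshold SD multiple (default 3).
#' @param remove drop flagged subjects (default `FALSE`).
#' @return The cohort with a logical `outlier` column (or with flagged rows
#'   removed when `remove = TRUE`).
#' @export
flagOutliers <- function(cohort, threshold = 3, remove = FALSE) {
    cohort <- validateCohort(cohort, min_age = -Inf)
    flag <- rep(FALSE, nrow(cohort))
    for (s in c("M", "F")) {
        idx <- which(cohort$sex == s)
        for (v in vertebraLabels()) {
            x <- cohort[[v]][idx]
            if (stats::sd(x) == 0) next
            flag[idx] <- flag[idx] |
                abs(x - mean(x)) > threshold * stats::sd(x)
        }
    }
    cohort$outlier <- flag
    if (remove) cohort[!flag, , drop = FALSE] else cohort
}

#' LASSO age model with cross-validated penalty selection
#'
#' Splits one sex's data 80/20, selects the L1 penalty `alpha` (the
#' `1/(2n)`-scaled least-squares convention, glmnet's lambda) from a
#' log-spaced grid by 10-fold cross-validated mean absolute error inside the
#' training split (predictors standardized within the training folds),
#' refits at the selected penalty, and reports the surviving coefficients on
#' the original scale together with hold-out R-squared and SEE (k = number
#' of nonzero coefficients) and the SEE of a full-sample refit.
#'
#' @param cohort validated cohort data.frame.
#' @param sex `"M"` or `"F"`.
#' @param alphas decreasing-sortable penalty grid; default 50 log-spaced
#'   points in `[1e-3, 10]`.
#' @param cv_folds number of CV folds (>= 2, default 10).
#' @param seed RNG seed for split and folds.
#' @param test_fraction hold-out fraction (default 0.2).
#' @return list of class `"LassoReport"` with `alpha`, `nonzero` (named
#'   coefficients), `intercept`, `test_r2`, `test_see`, `full_see`,
#'   `k_nonzero`.
#' @export
lassoFit <- function(cohort, sex = c("M", "F"),
                     alphas = 10^seq(-3, 1, length.out = 50),
                     cv_folds = 10, seed = 42, test_fraction = 0.2) {
    sex <- match.arg(sex)
    if (!length(alphas) || any(alphas <= 0))
        stop("degenerate penalty grid")
    if (cv_folds < 2L) stop("need at least 2 folds")
    sub <- cohort[cohort$sex == sex, , drop = FALSE]
    sp <- makeSplit(sub, splitSpec(test_fraction = test_fraction,
                                   cv_folds = cv_folds, seed = seed))
    xTr <- as.matrix(sp$train[, vertebraLabels()])
    yTr <- sp$train$age
    xTe <- as.matrix(sp$test[, vertebraLabels()])
    yTe <- sp$test$age
    lam <- sort(unique(as.numeric(alphas)), decreasing = TRUE)
    foldid <- withSeed(childSeed(seed, 1L),
                       sample(rep(seq_len(cv_folds),
                                  length.out = nrow(xTr))))
    cvf <- glmnet::cv.glmnet(xTr, yTr, lambda = lam, foldid = foldid,
                             type.measure = "mae", standardize = TRUE)
    alpha <- cvf$lambda.min
    beta <- as.matrix(stats::coef(cvf, s = "lambda.min"))[, 1L]
    nz <- beta[-1L][beta[-1L] != 0]
    k <- length(nz)
    predTe <- as.numeric(stats::predict(cvf, newx = xTe, s = "lambda.min"))
    xAll <- as.matrix(sub[, vertebraLabels()])
    fullFit <- glmnet::glmnet(xAll, sub$age, lambda = lam,
                              standardize = TRUE)
    predAll <- as.numeric(stats::predict(fullFit, newx = xAll, s = alpha))
    structure(list(
        sex = sex, alpha = alpha, nonzero = nz,
        intercept = unname(beta[1L]),
        k_nonzero = k,
        test_r2 = rSquared(yTe, predTe),
        test_see = seeFromResiduals(yTe - predTe, k, warnSmall = FALSE),
        full_see = seeFromResiduals(sub$age - predAll, k,
                                    warnSmall = FALSE),
        cv_mae = min(cvf$cvm)), class = "LassoReport")
}
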
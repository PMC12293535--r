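#' Evaluate a tuned model on the hold-out test set
#'
#' Computes MAE, RMSE and R-squared on the unseen test rows, the standard
#' error of the estimate `sqrt(SSR / (n - k - 1))` with `n = nrow(test)` and
#' `k = k_predictors`, and two-sided percentile bootstrap confidence
#' intervals for R-squared and SEE from `n_boot` resamples of the test set.
#' When `n <= k + 1` the SEE divisor falls back to `max(1, n - k - 1)` with
#' a warning. The out-of-bag R-squared is carried through for random
#' forests.
#'
#' @param model a `"dsModel"` from [tuneModel()].
#' @param test hold-out data.frame with `age` and the feature columns.
#' @param k_predictors number of retained predictors for the SEE divisor
#'   (default: the model's feature count).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return list of class `"EvalReport"`.
#' @export
evaluateModel <- function(model, test, k_predictors = NULL, n_boot = 1000,
                          seed = model$seed) {
    if (!nrow(test)) stop("empty test set")
    if (is.null(k_predictors)) k_predictors <- length(model$features)
    truth <- test$age
    pred <- stats::predict(model, test)
    res <- truth - pred
    n <- length(truth)
    if (n <= k_predictors + 1L)
        warning("test set has n <= k + 1; SEE uses divisor max(1, n-k-1)")
    see <- seeFromResiduals(res, k_predictors, warnSmall = FALSE)
    boot <- withSeed(childSeed(seed, 3L), {
        t(vapply(seq_len(n_boot), function(i) {
            idx <- sample(n, n, replace = TRUE)
            c(r2 = rSquared(truth[idx], pred[idx]),
              see = seeFromResiduals(res[idx], k_predictors,
                                     warnSmall = FALSE))
        }, c(r2 = 0, see = 0)))
    })
    ci <- function(v) unname(stats::quantile(v[is.finite(v)],
                                             c(0.025, 0.975)))
    r2ci <- ci(boot[, "r2"]); seeci <- ci(boot[, "see"])
    structure(list(
        model_name = model$kind,
        holdout_r2 = rSquared(truth, pred),
        r2_ci_lo = r2ci[1L], r2_ci_hi = r2ci[2L],
        see_years = see, see_ci_lo = seeci[1L], see_ci_hi = seeci[2L],
        mae_years = mean(abs(res)), rmse_years = sqrt(mean(res^2)),
        cv_r2 = model$cv_r2, oob_r2 = model$oob_r2,
        n_test = n, k = k_predictors, seed = seed),
        class = "EvalReport")
}

#' Permutation importance on the hold-out set
#'
#' Importance of each feature is the mean drop in hold-out R-squared over
#' `n_repeats` random shuffles of that feature column.
#'
#' @param model a `"dsModel"`.
#' @param test hold-out data.frame.
#' @param n_repeats shuffles per feature (default 20).
#' @param seed RNG seed.
#' @return Named numeric vector of importances (one per feature).
#' @export
permutationImportance <- function(model, test, n_repeats = 20,
                                  seed = model$seed) {
    base <- rSquared(test$age, stats::predict(model, test))
    feats <- model$features
    withSeed(childSeed(seed, 4L), {
        imp <- vapply(feats, function(f) {
            drops <- vapply(seq_len(n_repeats), function(r) {
                shuffled <- test
                shuffled[[f]] <- sample(shuffled[[f]])
                base - rSquared(test$age, stats::predict(model, shuffled))
            }, 0)
            mean(drops)
        }, 0)
        imp
    })
}

#' Bland-Altman agreement of predictions with truth
#'
#' @param predictions,truths equal-length numeric vectors.
#' @return list with `bias` (mean of prediction - truth), `sd_diff`, and
#'   the 95% limits of agreement `bias +/- 1.96 * sd_diff`.
#' @export
blandAltman <- function(predictions, truths) {
    if (length(predictions) != length(truths))
        stop("vectors must have equal length")
    if (length(predictions) < 2L) stop("need at least 2 pairs")
    d <- predictions - truths
    bias <- mean(d)
    s <- stats::sd(d)
    list(bias = bias, sd_diff = s,
         loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s)
}

#' Learning curve of a learner over training-set fractions
#'
#' For each fraction, refits (with full tuning) on a seeded subsample of the
#' training set and records the training R-squared and the tuned
#' cross-validated R-squared. Fraction 1 reproduces [tuneModel()] on the
#' full training set. Subsamples smaller than the fold count are skipped
#' with a warning.
#'
#' @param model_name one of the learner names (see [tuneModel()]).
#' @param train training data.frame.
#' @param fractions numeric vector in (0, 1\] (default `seq(0.4, 1, 0.2)`).
#' @param grid a [modelGrid()].
#' @param spec a [splitSpec()].
#' @return data.frame with columns `fraction`, `n`, `train_r2`, `cv_r2`.
#' @export
learningCurve <- function(model_name, train,
                          fractions = seq(0.4, 1, by = 0.2),
                          grid = modelGrid(), spec = splitSpec()) {
    if (any(fractions <= 0 | fractions > 1))
        stop("fractions must lie in (0, 1]")
    n <- nrow(train)
    rows <- list()
    for (f in fractions) {
        m <- round(f * n)
        if (m < spec$cv_folds) {
            warning(sprintf("fraction %.2f gives %d rows < %d folds; skipped",
                            f, m, spec$cv_folds))
            next
        }
        idx <- sort(withSeed(childSeed(spec$seed, round(1000 * f)),
                             sample(n, m)))
        sub <- train[idx, , drop = FALSE]
        mod <- tuneModel(sub, model_name, grid = grid, spec = spec)
        rows[[length(rows) + 1L]] <- data.frame(
            fraction = f, n = m,
            train_r2 = rSquared(sub$age, stats::predict(mod, sub)),
            cv_r2 = mod$cv_r2)
    }
    do.call(rbind, rows)
}
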
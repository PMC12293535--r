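#' Hold-out split and cross-validation settings
#'
#' @param test_fraction hold-out fraction in (0, 1) (default 0.2).
#' @param cv_folds number of in-training CV folds (>= 2, default 10).
#' @param shuffle shuffle before splitting (default `TRUE`).
#' @param seed master RNG seed; all model randomness derives from it.
#' @return A validated list of class `"SplitSpec"`.
#' @export
splitSpec <- function(test_fraction = 0.2, cv_folds = 10, shuffle = TRUE,
                      seed = 42) {
    if (test_fraction <= 0 || test_fraction >= 1)
        stop("test_fraction must lie in (0, 1)")
    if (cv_folds < 2L) stop("cv_folds must be >= 2")
    structure(list(test_fraction = test_fraction,
                   cv_folds = as.integer(cv_folds),
                   shuffle = isTRUE(shuffle), seed = as.integer(seed)),
              class = "SplitSpec")
}

#' Single shuffled hold-out split
#'
#' Shuffles the rows deterministically under the spec seed and assigns
#' `round(test_fraction * n)` of them to the hold-out test set; the split is
#' disjoint and exhaustive.
#'
#' @param data data.frame of one sex's subjects.
#' @param spec a [splitSpec()] object.
#' @return list with `train` and `test` data.frames.
#' @export
makeSplit <- function(data, spec = splitSpec()) {
    n <- nrow(data)
    if (n < 10L) stop("cohort too small to split (n < 10)")
    idx <- if (spec$shuffle) withSeed(spec$seed, sample(n)) else seq_len(n)
    nTest <- round(spec$test_fraction * n)
    list(test = data[idx[seq_len(nTest)], , drop = FALSE],
         train = data[idx[-seq_len(nTest)], , drop = FALSE])
}

#' Hyper-parameter grids for the four learners
#'
#' @param svr list with candidate `C`, `gamma` and `epsilon` values.
#' @param rf list with `n_trees` and `max_depth` candidates (`NA` = grown to
#'   purity; depth d is enforced as a `2^d` leaf budget).
#' @param knn list with neighbor counts `k` (3--7 by default).
#' @param gnb list with equal-frequency bin counts `n_bins`.
#' @return A list of class `"ModelGrid"`.
#' @export
modelGrid <- function(svr = list(C = c(1, 10, 100),
                                 gamma = c(0.01, 0.1),
                                 epsilon = c(0.1, 1)),
                      rf = list(n_trees = 200,
                                max_depth = c(3, 5, 10, NA)),
                      knn = list(k = 3:7),
                      gnb = list(n_bins = 5)) {
    for (g in list(svr$C, svr$gamma, svr$epsilon, rf$n_trees, knn$k,
                   gnb$n_bins))
        if (!length(g)) stop("empty candidate list in model grid")
    if (any(knn$k < 1)) stop("knn k must be >= 1")
    structure(list(svr = svr, rf = rf, knn = knn, gnb = gnb),
              class = "ModelGrid")
}

dsModelNames <- function() c("svr_rbf", "svr_lin", "rf", "knn", "gnb_reg")

# Standardization helper: returns center/scale estimated on `x` (constant
# columns get scale 1 so they map to 0).
zParams <- function(x) {
    ctr <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    list(center = ctr, scale = scl)
}
zApply <- function(x, zp) scale(x, center = zp$center, scale = zp$scale)

# Fit one learner configuration on (already standardized) predictors.
fitEngine <- function(kind, xs, y, cfg, seed) {
    switch(kind,
        svr_rbf = e1071::svm(x = xs, y = y, type = "eps-regression",
                             kernel = "radial", cost = cfg$C,
                             gamma = cfg$gamma, epsilon = cfg$epsilon,
                             scale = FALSE),
        svr_lin = e1071::svm(x = xs, y = y, type = "eps-regression",
                             kernel = "linear", cost = cfg$C,
                             epsilon = cfg$epsilon, scale = FALSE),
        rf = withSeed(seed, randomForest::randomForest(
                 x = xs, y = y, ntree = cfg$n_trees,
                 maxnodes = if (is.na(cfg$max_depth)) NULL
                            else min(2^cfg$max_depth, nrow(xs)))),
        knn = caret::knnreg(xs, y, k = cfg$k),
        gnb_reg = gnbRegressor(xs, y, n_bins = cfg$n_bins),
        stop("unknown model: ", kind))
}

predictEngine <- function(kind, fit, xs) {
    xs <- as.matrix(xs)
    as.numeric(switch(kind,
        svr_rbf = ,
        svr_lin = stats::predict(fit, xs),
        rf = stats::predict(fit, xs),
        knn = stats::predict(fit, as.data.frame(xs)),
        gnb_reg = stats::predict(fit, xs)))
}

gridConfigs <- function(model_name, grid) {
    g <- switch(model_name,
        svr_rbf = expand.grid(C = grid$svr$C, gamma = grid$svr$gamma,
                              epsilon = grid$svr$epsilon),
        svr_lin = expand.grid(C = grid$svr$C, epsilon = grid$svr$epsilon),
        rf = expand.grid(n_trees = grid$rf$n_trees,
                         max_depth = grid$rf$max_depth),
        knn = expand.grid(k = grid$knn$k),
        gnb_reg = expand.grid(n_bins = grid$gnb$n_bins),
        stop("unknown model: ", model_name))
    lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

#' Tune a learner by leakage-free cross-validation
#'
#' Grid search by k-fold cross-validation inside the training set. Within
#' every fold, continuous predictors are z-standardized using the fold's
#' training part only (the test fold is transformed with those parameters),
#' so no information leaks from held-out rows; tree ensembles, although
#' scale-invariant, run through the same pipeline for consistency. The best
#' configuration (highest mean fold R-squared, first on ties) is refitted on
#' the full training set.
#'
#' @param train data.frame with `age` and the DS columns.
#' @param model_name one of `"svr_rbf"`, `"svr_lin"`, `"rf"`, `"knn"`,
#'   `"gnb_reg"`.
#' @param grid a [modelGrid()] object.
#' @param spec a [splitSpec()] object (folds and master seed).
#' @param features predictor column names (default the 19 vertebrae).
#' @return list of class `"dsModel"` with the fitted engine, the
#'   standardization parameters, the winning configuration and `cv_r2`
#'   (mean fold R-squared of the winner).
#' @export
tuneModel <- function(train, model_name, grid = modelGrid(),
                      spec = splitSpec(), features = vertebraLabels()) {
    if (!model_name %in% dsModelNames())
        stop("unknown model: ", model_name)
    x <- as.matrix(train[, features, drop = FALSE])
    y <- train$age
    n <- nrow(x)
    folds <- withSeed(childSeed(spec$seed, 2L),
                      sample(rep(seq_len(spec$cv_folds), length.out = n)))
    configs <- gridConfigs(model_name, grid)
    cvScores <- vapply(seq_along(configs), function(ci) {
        cfg <- configs[[ci]]
        foldR2 <- vapply(seq_len(spec$cv_folds), function(f) {
            tr <- folds != f
            if (sum(tr) < 2L || sum(!tr) < 1L) return(NA_real_)
            zp <- zParams(x[tr, , drop = FALSE])
            fit <- fitEngine(model_name, zApply(x[tr, , drop = FALSE], zp),
                             y[tr], cfg,
                             seed = childSeed(spec$seed, 100L * ci + f))
            pred <- predictEngine(model_name, fit,
                                  zApply(x[!tr, , drop = FALSE], zp))
            rSquared(y[!tr], pred)
        }, 0)
        mean(foldR2, na.rm = TRUE)
    }, 0)
    best <- which.max(cvScores)
    zp <- zParams(x)
    fit <- fitEngine(model_name, zApply(x, zp), y, configs[[best]],
                     seed = childSeed(spec$seed, 99L))
    oob <- if (model_name == "rf")
        rSquared(y, fit$predicted) else NA_real_
    structure(list(kind = model_name, fit = fit, center = zp$center,
                   scale = zp$scale, features = features,
                   config = configs[[best]], cv_r2 = cvScores[best],
                   cv_scores = cvScores, oob_r2 = oob,
                   seed = spec$seed, train_y = y),
              class = "dsModel")
}

#' Predict ages with a tuned model
#'
#' @param object a `"dsModel"` from [tuneModel()].
#' @param newdata data.frame containing the model's feature columns.
#' @param ... ignored.
#' @return Numeric vector of predicted ages.
#' @export
predict.dsModel <- function(object, newdata, ...) {
    xs <- zApply(as.matrix(newdata[, object$features, drop = FALSE]),
                 list(center = object$center, scale = object$scale))
    predictEngine(object$kind, object$fit, xs)
}
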
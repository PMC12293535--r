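test_that("hold-out split has the stated sizes and is seed-deterministic", {
    cohort <- smallCohort(seed = 40)
    sub <- cohort[cohort$sex == "M", ]
    sp <- makeSplit(sub, splitSpec(seed = 42))
    expect_equal(nrow(sp$test), 19L)   # round(0.2 * 94)
    expect_equal(nrow(sp$train), 75L)
    expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0L)
    expect_setequal(c(sp$train$subject_id, sp$test$subject_id),
                    sub$subject_id)
    sp2 <- makeSplit(sub, splitSpec(seed = 42))
    expect_identical(sp$test$subject_id, sp2$test$subject_id)
    sp3 <- makeSplit(sub, splitSpec(seed = 43))
    expect_false(identical(sp$test$subject_id, sp3$test$subject_id))
    expect_error(makeSplit(sub[1:5, ], splitSpec()), "too small")
})

test_that("tuning selects the single candidate and the degenerate kNN", {
    cohort <- smallCohort(seed = 41)
    train <- cohort[cohort$sex == "F", ][1:40, ]
    g <- modelGrid(knn = list(k = 5))
    mod <- tuneModel(train, "knn", grid = g,
                     spec = splitSpec(cv_folds = 5))
    expect_equal(mod$config$k, 5)
    # duplicated rows: each fold neighbor is an exact copy, k = 3 wins
    base <- train[1:12, ]
    dup <- base[rep(1:12, each = 6), ]
    g2 <- modelGrid(knn = list(k = c(3, 7)))
    mod2 <- tuneModel(dup, "knn", grid = g2,
                      spec = splitSpec(cv_folds = 6, seed = 1))
    expect_equal(mod2$config$k, 3)
    expect_gt(mod2$cv_r2, 0.9)
    expect_error(tuneModel(train, "not_a_model"), "unknown model")
})

test_that("standardization happens inside folds, not before splitting", {
    # heteroscedastic blocks make fold-train scale estimates differ from
    # the global ones; the RBF kernel is scale-sensitive (its effective
    # width changes with the scaling), so CV scores must differ between
    # fold-wise and whole-data standardization. (kNN with one feature is
    # affine-invariant and cannot expose this.)
    set.seed(3)
    n <- 60
    age <- stats::runif(n, 21, 90)
    feat <- age + stats::rnorm(n, 0, 3)
    feat[1:20] <- feat[1:20] * 50  # scale shift in one block
    df <- data.frame(age = age, F1 = feat)
    spec <- splitSpec(cv_folds = 5, seed = 2)
    cfg <- list(C = 10, gamma = 0.5, epsilon = 0.1)
    folds <- vertebraDS:::withSeed(vertebraDS:::childSeed(2L, 2L),
                                   sample(rep(1:5, length.out = n)))
    svrFold <- function(xsTr, yTr, xsTe)
        as.numeric(stats::predict(e1071::svm(
            x = xsTr, y = yTr, type = "eps-regression", kernel = "radial",
            cost = cfg$C, gamma = cfg$gamma, epsilon = cfg$epsilon,
            scale = FALSE), xsTe))
    inFold <- vapply(1:5, function(f) {
        tr <- folds != f
        zp <- vertebraDS:::zParams(as.matrix(df[tr, "F1", drop = FALSE]))
        pred <- svrFold(
            vertebraDS:::zApply(as.matrix(df[tr, "F1", drop = FALSE]), zp),
            df$age[tr],
            vertebraDS:::zApply(as.matrix(df[!tr, "F1", drop = FALSE]),
                                zp))
        vertebraDS:::rSquared(df$age[!tr], pred)
    }, 0)
    zg <- vertebraDS:::zParams(as.matrix(df[, "F1", drop = FALSE]))
    global <- vapply(1:5, function(f) {
        tr <- folds != f
        xs <- vertebraDS:::zApply(as.matrix(df[, "F1", drop = FALSE]), zg)
        pred <- svrFold(xs[tr, , drop = FALSE], df$age[tr],
                        xs[!tr, , drop = FALSE])
        vertebraDS:::rSquared(df$age[!tr], pred)
    }, 0)
    expect_false(isTRUE(all.equal(mean(inFold), mean(global))))
    # and tuneModel reproduces the leakage-free variant exactly
    mod <- tuneModel(df, "svr_rbf",
                     grid = modelGrid(svr = list(C = 10, gamma = 0.5,
                                                 epsilon = 0.1)),
                     spec = spec, features = "F1")
    expect_equal(mod$cv_r2, mean(inFold), tolerance = 1e-10)
})

test_that("GNB pseudo-regressor honors its bin-midpoint contracts", {
    set.seed(10)
    x <- matrix(stats::rnorm(60), 30, 2)
    y <- stats::runif(30, 20, 90)
    # single bin: constant prediction at (min + max) / 2
    m1 <- gnbRegressor(x, y, n_bins = 1)
    expect_equal(unique(round(predict(m1, x), 10)),
                 round((min(y) + max(y)) / 2, 10))
    # symmetric two-bin posteriors average the two midpoints
    xs <- matrix(c(rep(-1, 10), rep(1, 10)), ncol = 1)
    ys <- c(seq(20, 29, length.out = 10), seq(70, 79, length.out = 10))
    m2 <- gnbRegressor(xs, ys, n_bins = 2)
    predMid <- predict(m2, matrix(0, 1, 1))
    expect_equal(predMid, mean(m2$midpoints), tolerance = 1e-6)
    # separable clusters predict near their own midpoints
    predLo <- predict(m2, matrix(-1, 1, 1))
    predHi <- predict(m2, matrix(1, 1, 1))
    expect_lt(abs(predLo - m2$midpoints[1]), 1)
    expect_lt(abs(predHi - m2$midpoints[2]), 1)
    # predictions always stay within the midpoint range
    rnd <- predict(m2, matrix(stats::rnorm(50, 0, 5), ncol = 1))
    expect_true(all(rnd >= min(m2$midpoints) - 1e-9 &
                    rnd <= max(m2$midpoints) + 1e-9))
    expect_error(gnbRegressor(x, rep(c(30, 60), 15), n_bins = 5),
                 "distinct")
})

test_that("evaluation metrics satisfy their identities", {
    # k = 1 nearest neighbor on the training points gives known residuals
    train <- data.frame(age = c(10, 20, 30, 40),
                        F1 = c(1, 2, 3, 4) * 10)
    mod <- tuneModel(train, "knn", grid = modelGrid(knn = list(k = 1)),
                     spec = splitSpec(cv_folds = 2, seed = 1),
                     features = "F1")
    test <- data.frame(age = c(11, 19, 32, 38), F1 = c(1, 2, 3, 4) * 10)
    ev <- evaluateModel(mod, test, k_predictors = 1, n_boot = 200)
    expect_equal(ev$mae_years, 1.5)
    expect_equal(ev$rmse_years, sqrt(2.5))
    expect_equal(ev$see_years, sqrt(10 / 2))  # n = 4, k = 1
    expect_gte(ev$rmse_years, ev$mae_years)
    # perfect predictions
    perfect <- data.frame(age = c(10, 20, 30, 40), F1 = c(1, 2, 3, 4) * 10)
    evP <- evaluateModel(mod, perfect, k_predictors = 1, n_boot = 100)
    expect_equal(evP$mae_years, 0)
    expect_equal(evP$rmse_years, 0)
    expect_equal(evP$holdout_r2, 1)
    # constant predictor never beats the test mean
    constTrain <- data.frame(age = stats::runif(30, 20, 90),
                             F1 = stats::rnorm(30))
    constMod <- tuneModel(constTrain, "gnb_reg",
                          grid = modelGrid(gnb = list(n_bins = 1)),
                          spec = splitSpec(cv_folds = 3, seed = 2),
                          features = "F1")
    constTest <- data.frame(age = c(25, 50, 80), F1 = stats::rnorm(3))
    expect_warning(
        evC <- evaluateModel(constMod, constTest, k_predictors = 3,
                             n_boot = 50),
        "n <= k \\+ 1")
    expect_lte(evC$holdout_r2, 0)
})

test_that("bootstrap CIs cover the point estimate and RMSE >= MAE", {
    cohort <- smallCohort(seed = 44)
    sub <- cohort[cohort$sex == "M", ]
    sp <- makeSplit(sub, splitSpec(seed = 7))
    for (m in c("knn", "gnb_reg")) {
        mod <- tuneModel(sp$train, m, spec = splitSpec(seed = 7))
        ev <- evaluateModel(mod, sp$test, n_boot = 400)
        expect_gte(ev$rmse_years, ev$mae_years)
        expect_lte(ev$r2_ci_lo, ev$holdout_r2 + 1e-9)
        expect_gte(ev$r2_ci_hi, ev$holdout_r2 - 1e-9)
        expect_lte(ev$see_ci_lo, ev$see_years + 1e-9)
        expect_gte(ev$see_ci_hi, ev$see_years - 1e-9)
    }
})

test_that("random forest reports an out-of-bag R2 and others do not", {
    cohort <- smallCohort(seed = 45)
    sp <- makeSplit(cohort[cohort$sex == "F", ], splitSpec(seed = 5))
    rf <- tuneModel(sp$train, "rf",
                    grid = modelGrid(rf = list(n_trees = 100,
                                               max_depth = 5)),
                    spec = splitSpec(seed = 5))
    expect_true(is.finite(rf$oob_r2))
    kn <- tuneModel(sp$train, "knn", spec = splitSpec(seed = 5))
    expect_true(is.na(kn$oob_r2))
})

test_that("permutation importance isolates the informative feature", {
    set.seed(12)
    n <- 80
    df <- data.frame(age = stats::runif(n, 20, 90))
    df$INF <- df$age + stats::rnorm(n, 0, 2)
    df$NOISE <- stats::rnorm(n)
    df$CONST <- 1
    mod <- tuneModel(df, "knn", grid = modelGrid(knn = list(k = 3)),
                     spec = splitSpec(cv_folds = 5, seed = 3),
                     features = c("INF", "NOISE", "CONST"))
    imp <- permutationImportance(mod, df, n_repeats = 10, seed = 3)
    expect_equal(names(which.max(imp)), "INF")
    expect_equal(unname(imp["CONST"]), 0)  # shuffling a constant is a no-op
    expect_gt(imp[["INF"]], 10 * abs(imp[["NOISE"]]))
})

test_that("Bland-Altman agreement has the textbook arithmetic", {
    expect_equal(blandAltman(1:5, 1:5),
                 list(bias = 0, sd_diff = 0, loa_lower = 0, loa_upper = 0))
    ba <- blandAltman(1:5 + 5, 1:5)
    expect_equal(ba$bias, 5)
    expect_equal(ba$loa_lower, 5)
    ba2 <- blandAltman(c(-2, 0, 2) + 10, c(10, 10, 10))
    expect_equal(ba2$bias, 0)
    expect_equal(ba2$loa_upper, 1.96 * 2)
    expect_error(blandAltman(1, 1:2), "equal length")
    expect_error(blandAltman(1, 1), "at least 2")
})

test_that("learning curve reproduces full-data tuning and flags tiny folds", {
    cohort <- smallCohort(seed = 46)
    train <- makeSplit(cohort[cohort$sex == "M", ],
                       splitSpec(seed = 4))$train
    spec <- splitSpec(cv_folds = 5, seed = 4)
    g <- modelGrid(knn = list(k = 5))
    lc <- learningCurve("knn", train, fractions = c(0.5, 1), grid = g,
                        spec = spec)
    ref <- tuneModel(train, "knn", grid = g, spec = spec)
    expect_equal(lc$cv_r2[lc$fraction == 1], ref$cv_r2)
    expect_warning(
        learningCurve("knn", train, fractions = 0.01, grid = g,
                      spec = spec),
        "skipped")
    # memorizing forest: training score dominates CV score everywhere
    gRF <- modelGrid(rf = list(n_trees = 100, max_depth = NA))
    lcRF <- learningCurve("rf", train, fractions = c(0.5, 1), grid = gRF,
                          spec = spec)
    expect_true(all(lcRF$train_r2 >= lcRF$cv_r2))
})
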
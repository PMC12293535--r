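test_that("descriptive statistics use the t-based confidence interval", {
    lab <- vertebraLabels()
    cohort <- smallCohort(seed = 3)
    d <- descriptiveStats(cohort)
    expect_equal(nrow(d), 38L)
    m <- d[d$sex == "M" & d$vertebra == "L3", ]
    x <- cohort$L3[cohort$sex == "M"]
    expect_equal(m$mean, mean(x))
    expect_equal(m$median, stats::median(x))
    half <- stats::qt(0.975, 93) * stats::sd(x) / sqrt(94)
    expect_equal(m$ci_hi - m$mean, half)
    # the trivial {1,2,3} case (three subjects per sex)
    tiny <- cohort[c(1:3, 95:97), ]
    tiny$C7 <- rep(c(1, 2, 3), 2)
    t6 <- descriptiveStats(tiny)
    row <- t6[t6$vertebra == "C7" & t6$sex == "M", ]
    expect_equal(row$mean[1], 2)
    expect_equal(row$sd[1], 1)
    expect_equal(row$median[1], 2)
})

test_that("Mann-Whitney sex test: null, separation, and shift power", {
    cohort <- smallCohort(seed = 6)
    # identical samples: no evidence of a difference
    same <- cohort[1:40, ]
    same$sex <- rep(c("M", "F"), 20)
    same$T3[same$sex == "M"] <- 1:20 / 10
    same$T3[same$sex == "F"] <- 1:20 / 10
    expect_gt(sexDifferenceTest(same, "T3"), 0.9)
    # complete separation at n = 10/10: exact p = 2 / C(20, 10)
    sep <- same[1:20, ]
    sep$sex <- rep(c("M", "F"), each = 10)
    sep$T4 <- c(1:10, 101:110) / 1000
    expect_equal(sexDifferenceTest(sep, "T4"), 2 / choose(20, 10),
                 tolerance = 1e-12)
    # a 0.5 SD shift at n = 90/80 is detected most of the time
    hits <- 0L
    for (i in 1:60) {
        x <- stats::rnorm(90); y <- stats::rnorm(80, mean = 0.5)
        df <- data.frame(subject_id = 1:170,
                         sex = rep(c("M", "F"), c(90, 80)), age = 50,
                         check.names = FALSE)
        for (v in vertebraLabels()) df[[v]] <- 1
        df$T5 <- exp(c(x, y))  # positive, monotone transform keeps ranks
        if (sexDifferenceTest(df, "T5") < 0.05) hits <- hits + 1L
    }
    expect_gte(hits / 60, 0.8)
})

test_that("age correlations behave on monotone, tied and constant data", {
    base <- smallCohort(seed = 2)[1:24, ]
    base$sex <- rep(c("M", "F"), each = 12)
    base$age <- c(1:12 * 5 + 15, 1:12 * 5 + 15)
    for (s in c("M", "F")) {
        base$L1[base$sex == s] <- 1:12 / 10          # increasing
        base$L2[base$sex == s] <- 12:1 / 10          # decreasing
        base$L4[base$sex == s] <- 1                  # constant
    }
    ac <- ageCorrelations(base)
    expect_equal(ac$r[ac$vertebra == "L1"], c(1, 1))
    expect_equal(ac$r[ac$vertebra == "L2"], c(-1, -1))
    expect_true(all(is.na(ac$r[ac$vertebra == "L4"])))
    expect_true(all(ac$degenerate[ac$vertebra == "L4"]))
    # tied example equals Pearson on mid-ranks
    tied <- base
    tied$age[tied$sex == "M"] <- c(30, 30, 40, 50, 50, 60, 61:66)
    tied$L5[tied$sex == "M"] <-
        c(0.2, 0.3, 0.3, 0.5, 0.4, 0.6, 0.7, 0.7, 0.8, 0.9, 1, 1.1)
    acT <- ageCorrelations(tied)
    oracle <- stats::cor(rank(tied$age[tied$sex == "M"]),
                         rank(tied$L5[tied$sex == "M"]))
    expect_equal(acT$r[acT$sex == "M" & acT$vertebra == "L5"], oracle)
    # invariance under strictly monotone transforms
    mono <- base
    mono$L1 <- exp(mono$L1)
    expect_equal(ageCorrelations(mono)$r[ac$vertebra == "L1"], c(1, 1))
})

test_that("ANCOVA interaction screen detects sex-specific slopes", {
    # same generating process in both sexes: joint p is not tiny most runs
    lab <- vertebraLabels()
    eqSpec <- function(seed) {
        sl <- stats::setNames(rep(0.004, 19), lab)
        ns <- stats::setNames(rep(0.2, 19), lab)
        ic <- stats::setNames(rep(0.2, 19), lab)
        cohortSimSpec(n_male = 88, n_female = 88,
                      slopes = list(M = sl, F = sl),
                      intercepts = list(M = ic, F = ic),
                      noise_sd = list(M = ns, F = ns), seed = seed)
    }
    pNull <- vapply(1:40, function(i)
        ancovaInteractionScreen(makeSyntheticCohort(eqSpec(i)))$p_value, 0)
    # null p-values are roughly uniform: no mass collapse at 0
    expect_gt(mean(pNull > 0.05), 0.75)
    expect_gt(stats::ks.test(pNull, "punif")$p.value, 0.01)
    # one strongly sex-specific slope is detected
    hits <- 0L
    for (i in 1:25) {
        sl2 <- stats::setNames(rep(0.004, 19), lab)
        slM <- sl2; slM[["L3"]] <- 0.016
        spec <- cohortSimSpec(n_male = 88, n_female = 88,
                              slopes = list(M = slM, F = sl2),
                              intercepts = list(
                                  M = stats::setNames(rep(0.2, 19), lab),
                                  F = stats::setNames(rep(0.2, 19), lab)),
                              noise_sd = list(
                                  M = stats::setNames(rep(0.15, 19), lab),
                                  F = stats::setNames(rep(0.15, 19), lab)),
                              seed = 1000 + i)
        if (ancovaInteractionScreen(
                makeSyntheticCohort(spec))$p_value < 0.05)
            hits <- hits + 1L
    }
    expect_gte(hits / 25, 0.8)
    # duplicated interaction column: singularity reported
    dup <- smallCohort(seed = 9)
    dup$T2 <- dup$T1
    expect_error(ancovaInteractionScreen(dup), "aliased|singular")
})

test_that("MLR report satisfies the SEE and adjusted-R2 identities", {
    cohort <- smallCohort(seed = 12)
    rep <- mlrFit(cohort, "M")
    res <- stats::residuals(rep$model)
    expect_equal(rep$see_years^2 * (rep$n - rep$k - 1), sum(res^2))
    expect_equal(rep$adj_r2,
                 1 - (1 - rep$r2) * (rep$n - 1) / (rep$n - rep$k - 1))
    expect_equal(rep$df2, rep$n - rep$k - 1)
    expect_equal(rep$r, sqrt(rep$r2))
    expect_equal(unname(rep$tolerance), unname(1 / rep$vif))
    expect_gte(min(rep$condition_indices), 1)
    # optional cross-check against car's VIF implementation
    if (requireNamespace("car", quietly = TRUE)) {
        cv <- car::vif(rep$model)
        expect_equal(unname(rep$vif), unname(cv), tolerance = 1e-8)
    }
})

test_that("MLR handles noise-free data and perfect collinearity", {
    cohort <- smallCohort(seed = 13)
    # noise-free linear age signal
    clean <- cohort
    clean$age <- 30 + 5 * clean$L3 + 2 * clean$T8
    repC <- mlrFit(clean, "F")
    expect_equal(repC$r2, 1)
    expect_lt(repC$see_years, 1e-8)
    dup <- cohort
    dup$L4 <- dup$L3
    expect_error(mlrFit(dup, "M"), "aliased")
    expect_error(mlrFit(cohort[1:15, ], "M"), "n > k")
})

test_that("MLR F-test has nominal type-I error under the null", {
    # age independent of all DS values
    rejections <- 0L
    reps <- 300L
    set.seed(99)
    for (i in seq_len(reps)) {
        n <- 94
        X <- matrix(stats::rnorm(n * 19), n, 19)
        y <- stats::rnorm(n, 50, 10)
        sm <- summary(stats::lm(y ~ X))
        p <- stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                       sm$fstatistic[3], lower.tail = FALSE)
        if (p < 0.05) rejections <- rejections + 1L
    }
    expect_lt(abs(rejections / reps - 0.05), 0.035)
})

test_that("LASSO limits: full shrinkage, vanishing penalty, soft threshold", {
    cohort <- smallCohort(seed = 20)
    # alpha forced huge: everything shrinks to zero, prediction = mean age
    big <- lassoFit(cohort, "M", alphas = c(1e6, 9.9e5), seed = 42)
    expect_equal(big$k_nonzero, 0L)
    sub <- cohort[cohort$sex == "M", ]
    sp <- makeSplit(sub, splitSpec(seed = 42))
    expect_equal(big$intercept, mean(sp$train$age), tolerance = 1e-6)
    # vanishing penalty approaches OLS on the training split
    tinyA <- lassoFit(cohort, "M", alphas = c(1e-6, 1e-5), seed = 42)
    ols <- stats::lm(vertebraDS:::dsFormula(), data = sp$train)
    bOls <- stats::coef(ols)[-1]
    expect_equal(unname(tinyA$nonzero[names(bOls)]), unname(bOls),
                 tolerance = 0.01)
    expect_error(lassoFit(cohort, "M", alphas = numeric(0)), "grid")
    # orthonormalized single predictor: glmnet equals soft thresholding
    set.seed(7)
    n <- 200
    x <- scale(stats::rnorm(n)); x <- x / sqrt(mean(x^2))
    beta <- 3
    y <- beta * x + stats::rnorm(n, 0, 0.5)
    lam <- 0.8
    g <- glmnet::glmnet(cbind(x, 0 * x + stats::rnorm(n, 0, 1e-8)), y,
                        lambda = lam, standardize = FALSE)
    bHat <- as.numeric(stats::coef(g))[2]
    rho <- mean(x * (y - mean(y)))
    oracle <- sign(rho) * max(0, abs(rho) - lam)
    expect_equal(bHat, oracle, tolerance = 0.01)
})

test_that("outlier screening flags but does not remove by default", {
    cohort <- smallCohort(seed = 30)
    cohort$L3[1] <- cohort$L3[1] + 50  # gross outlier
    flagged <- flagOutliers(cohort)
    expect_true(flagged$outlier[1])
    expect_equal(nrow(flagged), nrow(cohort))
    removed <- flagOutliers(cohort, remove = TRUE)
    expect_lt(nrow(removed), nrow(cohort))
    expect_false("TRUE" %in% as.character(removed$outlier))
})
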
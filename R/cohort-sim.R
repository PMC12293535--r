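# Per-sex, per-vertebra calibration used for the default synthetic cohort:
# DS mean/SD and age--DS rank correlation magnitudes typical of adult
# thoraco-lumbar endplate roughness panels (DS in mm, ages in years).
dsCalibration <- function() {
    lab <- vertebraLabels()
    data.frame(
        vertebra = lab,
        mean_M = c(0.33, 0.30, 0.33, 0.33, 0.35, 0.33, 0.35, 0.30, 0.32,
                   0.31, 0.39, 0.48, 0.46, 0.41, 0.57, 0.62, 0.74, 0.61,
                   0.56),
        sd_M   = c(0.34, 0.15, 0.22, 0.16, 0.16, 0.18, 0.20, 0.19, 0.22,
                   0.17, 0.29, 0.30, 0.31, 0.25, 0.39, 0.40, 0.55, 0.36,
                   0.31),
        r_M    = c(0.089, -0.108, -0.039, 0.078, 0.014, 0.059, 0.129,
                   0.279, 0.324, 0.322, 0.352, 0.284, 0.175, 0.280, 0.424,
                   0.600, 0.448, 0.395, 0.403),
        mean_F = c(0.35, 0.34, 0.30, 0.27, 0.27, 0.32, 0.29, 0.27, 0.28,
                   0.33, 0.33, 0.36, 0.41, 0.31, 0.49, 0.62, 0.68, 0.65,
                   0.66),
        sd_F   = c(0.34, 0.28, 0.20, 0.15, 0.18, 0.47, 0.23, 0.17, 0.21,
                   0.25, 0.22, 0.30, 0.46, 0.16, 0.38, 1.13, 0.47, 0.56,
                   0.43),
        r_F    = c(0.194, 0.096, 0.355, 0.334, 0.362, 0.314, 0.287, 0.352,
                   0.522, 0.459, 0.471, 0.367, 0.324, 0.495, 0.553, 0.509,
                   0.538, 0.588, 0.074),
        row.names = lab)
}

#' Specification of a synthetic DS cohort
#'
#' Describes a cohort of subjects with uniformly distributed ages and
#' per-vertebra DS values following sex-specific linear age trends plus
#' Gaussian noise. Defaults are calibrated so that per-vertebra DS means,
#' SDs and age correlations match the magnitudes observed in adult
#' thoraco-lumbar roughness panels (strongest signal in the lumbar levels):
#' `slope = r * sd_DS / sd_age`, `noise_sd = sd_DS * sqrt(1 - r^2)` and the
#' intercept anchors the DS mean at the mid-range age, where `sd_age` is the
#' SD of the generating uniform age distribution.
#'
#' @param n_male,n_female subject counts (>= 0).
#' @param age_low,age_high uniform age range in years (`age_low < age_high`).
#' @param slopes,intercepts,noise_sd lists with elements `M` and `F`, each a
#'   named numeric vector over [vertebraLabels()] (DS mm per year, DS mm,
#'   and residual SD in mm respectively). `NULL` uses the calibrated
#'   defaults.
#' @param seed integer RNG seed.
#' @return A validated list of class `"CohortSimSpec"`.
#' @seealso [makeSyntheticCohort()]
#' @export
cohortSimSpec <- function(n_male = 94, n_female = 82, age_low = 21,
                          age_high = 94, slopes = NULL, intercepts = NULL,
                          noise_sd = NULL, seed = 1) {
    if (n_male < 0 || n_female < 0) stop("subject counts must be >= 0")
    if (!(age_low < age_high)) stop("age_low must be < age_high")
    lab <- vertebraLabels()
    cal <- dsCalibration()
    sdAge <- (age_high - age_low) / sqrt(12)
    meanAge <- (age_low + age_high) / 2
    defaultFor <- function(sex) {
        r <- cal[[paste0("r_", sex)]]
        s <- cal[[paste0("sd_", sex)]]
        m <- cal[[paste0("mean_", sex)]]
        slope <- r * s / sdAge
        list(slope = stats::setNames(slope, lab),
             intercept = stats::setNames(m - slope * meanAge, lab),
             noise = stats::setNames(s * sqrt(1 - r^2), lab))
    }
    dM <- defaultFor("M"); dF <- defaultFor("F")
    pick <- function(user, defM, defF) {
        if (is.null(user)) return(list(M = defM, F = defF))
        for (s in c("M", "F")) {
            if (is.null(user[[s]]) || !all(lab %in% names(user[[s]])))
                stop("per-sex vectors must name all 19 vertebra labels")
            user[[s]] <- user[[s]][lab]
        }
        user
    }
    slopes <- pick(slopes, dM$slope, dF$slope)
    intercepts <- pick(intercepts, dM$intercept, dF$intercept)
    noise_sd <- pick(noise_sd, dM$noise, dF$noise)
    if (any(unlist(noise_sd) < 0)) stop("noise_sd must be >= 0")
    structure(list(n_male = as.integer(n_male),
                   n_female = as.integer(n_female),
                   age_low = age_low, age_high = age_high, slopes = slopes,
                   intercepts = intercepts, noise_sd = noise_sd,
                   seed = as.integer(seed)),
              class = "CohortSimSpec")
}

#' Simulate a cohort of subjects with age-dependent DS panels
#'
#' Ages are drawn uniform on `[age_low, age_high]`; each vertebra's DS value
#' is `intercept + slope * age + N(0, noise_sd)`, truncated below at a small
#' positive floor (1e-6 mm) since observed roughness scores are strictly
#' positive. Column order matches the cohort CSV schema.
#'
#' @param spec a [cohortSimSpec()] object.
#' @return data.frame with columns `subject_id`, `sex` (`"M"`/`"F"`), `age`
#'   and the 19 DS columns named by [vertebraLabels()].
#' @examples
#' cohort <- makeSyntheticCohort(cohortSimSpec(n_male = 10, n_female = 10))
#' dim(cohort)  # 20 x 22
#' @export
makeSyntheticCohort <- function(spec) {
    if (!inherits(spec, "CohortSimSpec")) spec <- do.call(cohortSimSpec, spec)
    lab <- vertebraLabels()
    n <- spec$n_male + spec$n_female
    sex <- rep(c("M", "F"), c(spec$n_male, spec$n_female))
    withSeed(spec$seed, {
        age <- stats::runif(n, spec$age_low, spec$age_high)
        ds <- matrix(NA_real_, n, length(lab), dimnames = list(NULL, lab))
        for (v in lab) {
            mu <- ifelse(sex == "M",
                         spec$intercepts$M[[v]] + spec$slopes$M[[v]] * age,
                         spec$intercepts$F[[v]] + spec$slopes$F[[v]] * age)
            sdv <- ifelse(sex == "M", spec$noise_sd$M[[v]],
                          spec$noise_sd$F[[v]])
            ds[, v] <- pmax(mu + stats::rnorm(n, 0, sdv), 1e-6)
        }
        data.frame(subject_id = sprintf("S%03d", seq_len(n)), sex = sex,
                   age = age, ds, check.names = FALSE)
    })
}

#' Validate a cohort table
#'
#' Checks the cohort CSV schema: `subject_id`, `sex` in \{M, F\}, numeric
#' `age` and the 19 DS columns, strictly positive DS, and (configurably)
#' a minimum age reflecting ring-apophysis fusion.
#'
#' @param cohort data.frame to validate.
#' @param min_age minimum admissible age in years (default 21; use `-Inf`
#'   to disable).
#' @return The cohort, invisibly, with `sex` as character.
#' @export
validateCohort <- function(cohort, min_age = 21) {
    need <- c("subject_id", "sex", "age", vertebraLabels())
    miss <- setdiff(need, names(cohort))
    if (length(miss))
        stop("cohort is missing columns: ", paste(miss, collapse = ", "))
    cohort$sex <- as.character(cohort$sex)
    if (!all(cohort$sex %in% c("M", "F")))
        stop("sex must be coded M/F")
    if (any(!is.finite(cohort$age)) || any(cohort$age < min_age))
        stop("ages must be finite and >= ", min_age)
    dsm <- as.matrix(cohort[, vertebraLabels()])
    if (any(!is.finite(dsm)) || any(dsm <= 0))
        stop("DS values must be finite and > 0")
    invisible(cohort)
}
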
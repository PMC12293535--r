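#' Run configuration for batch processing
#'
#' Exactly one entry-point input kind must be given: an image directory
#' (files named `subjectID_vertebra.png`/`.tif`), a contour directory
#' (files named `subjectID_vertebra.csv`), or a cohort CSV. The seed is
#' recorded in every output.
#'
#' @param image_dir,contour_dir,cohort_csv entry-point inputs (give one).
#' @param out_dir output directory (created if needed).
#' @param ref_len_mm,ref_len_px reference-line lengths for mm scaling of
#'   images.
#' @param tau_px baseline-removal tolerance in pixels.
#' @param fit a [fitConfig()].
#' @param split a [splitSpec()].
#' @param models learner names for the ML stage.
#' @param metadata_csv subject metadata file (`subject_id,sex,age`) used
#'   when assembling a cohort from contours.
#' @param strict drop subjects missing any vertebra (default `TRUE`,
#'   mirroring whole-column inclusion criteria); `FALSE` keeps them flagged.
#' @param seed master seed.
#' @param log_level `"info"` or `"quiet"`.
#' @return A validated list of class `"RunConfig"` carrying a `config_hash`.
#' @export
runConfig <- function(image_dir = NULL, contour_dir = NULL,
                      cohort_csv = NULL, out_dir = tempfile("dsrun"),
                      ref_len_mm = 1, ref_len_px = 1, tau_px = 2,
                      fit = fitConfig(), split = splitSpec(),
                      models = dsModelNames(), metadata_csv = NULL,
                      strict = TRUE, seed = 42, log_level = "info") {
    kinds <- !vapply(list(image_dir, contour_dir, cohort_csv), is.null,
                     TRUE)
    if (sum(kinds) != 1L)
        stop("give exactly one of image_dir, contour_dir, cohort_csv")
    cfg <- list(image_dir = image_dir, contour_dir = contour_dir,
                cohort_csv = cohort_csv, out_dir = out_dir,
                ref_len_mm = ref_len_mm, ref_len_px = ref_len_px,
                tau_px = tau_px, fit = fit, split = split, models = models,
                metadata_csv = metadata_csv, strict = isTRUE(strict),
                seed = as.integer(seed), log_level = log_level)
    cfg$config_hash <- configHash(cfg)
    structure(cfg, class = "RunConfig")
}

# Stable hash of the configuration content (paths excluded from the digest
# would churn; they are part of the run identity, so they stay in).
configHash <- function(cfg) {
    cfg$config_hash <- NULL
    f <- tempfile()
    on.exit(unlink(f))
    # version 2 serialization is byte-stable across sessions
    saveRDS(cfg, f, version = 2L, compress = FALSE)
    unname(tools::md5sum(f))
}

#' Read a YAML run configuration
#'
#' Flat key-value YAML; keys mirror the [runConfig()] arguments, with
#' `fit.*` and `split.*` prefixes for the nested configurations.
#'
#' @param path YAML file path.
#' @return A `"RunConfig"`.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    pickPrefix <- function(prefix, ctor) {
        keys <- grep(paste0("^", prefix, "\\."), names(y), value = TRUE)
        args <- y[keys]
        names(args) <- sub(paste0("^", prefix, "\\."), "", keys)
        do.call(ctor, args)
    }
    args <- y[!grepl("^(fit|split)\\.", names(y))]
    args$fit <- pickPrefix("fit", fitConfig)
    args$split <- pickPrefix("split", splitSpec)
    do.call(runConfig, args)
}

logMsg <- function(cfg, stage, ...) {
    if (identical(cfg$log_level, "quiet")) return(invisible())
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                    sprintf(...)))
}

parseUnitName <- function(files) {
    base <- tools::file_path_sans_ext(basename(files))
    parts <- regmatches(base, regexec("^(.+)_([^_]+)$", base))
    data.frame(file = files,
               subject_id = vapply(parts, function(p)
                   if (length(p) == 3L) p[2L] else NA_character_, ""),
               vertebra = vapply(parts, function(p)
                   if (length(p) == 3L) p[3L] else NA_character_, ""))
}

#' Batch contour extraction from endplate images
#'
#' Runs [imageToContour()] on every `subject_vertebra.{png,tif,tiff}` file
#' in the configured image directory, writing one contour CSV per image to
#' `out_dir/contours` and a manifest of per-unit status. Failures are
#' logged and the run continues.
#'
#' @param config a [runConfig()] with `image_dir` set.
#' @return data.frame manifest (one row per attempted image) with columns
#'   `subject_id`, `vertebra`, `status`, `reason`, `contour_csv`,
#'   `config_hash`, invisibly also written to `out_dir/extract_manifest.csv`.
#' @export
runExtractBatch <- function(config) {
    if (is.null(config$image_dir)) stop("config has no image_dir")
    if (!dir.exists(config$image_dir))
        stop("unreadable image directory: ", config$image_dir)
    files <- list.files(config$image_dir,
                        pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                        full.names = TRUE)
    units <- parseUnitName(files)
    bad <- is.na(units$vertebra) | !units$vertebra %in% vertebraLabels()
    if (any(bad))
        warning("skipping files without a subject_vertebra name: ",
                paste(basename(units$file[bad]), collapse = ", "))
    units <- units[!bad, , drop = FALSE]
    dir.create(file.path(config$out_dir, "contours"), recursive = TRUE,
               showWarnings = FALSE)
    rows <- lapply(seq_len(nrow(units)), function(i) {
        u <- units[i, ]
        csv <- file.path(config$out_dir, "contours",
                         sprintf("%s_%s.csv", u$subject_id, u$vertebra))
        status <- "ok"; reason <- ""
        res <- tryCatch(
            imageToContour(u$file, ref_len_mm = config$ref_len_mm,
                           ref_len_px = config$ref_len_px,
                           tau_px = config$tau_px, csv_out = csv),
            error = function(e) e)
        if (inherits(res, "error")) {
            status <- "failed"; reason <- conditionMessage(res)
            csv <- NA_character_
            logMsg(config, "extract", "%s_%s failed: %s", u$subject_id,
                   u$vertebra, reason)
        }
        data.frame(subject_id = u$subject_id, vertebra = u$vertebra,
                   status = status, reason = reason, contour_csv = csv,
                   config_hash = config$config_hash)
    })
    manifest <- do.call(rbind, rows)
    utils::write.csv(manifest,
                     file.path(config$out_dir, "extract_manifest.csv"),
                     row.names = FALSE)
    manifest
}

#' Assemble a cohort table from per-vertebra contour fits
#'
#' Fits an ellipse to every contour CSV in the configured contour directory
#' (or the output of [runExtractBatch()]), collects the DS scores into the
#' 19-column cohort layout, and joins subject metadata (`subject_id, sex,
#' age`). Subjects missing any vertebra are flagged; in strict mode they
#' are dropped (the analogue of whole-column inclusion criteria).
#'
#' @param config a [runConfig()] with `contour_dir` (or after an extract
#'   run, `out_dir/contours`) and `metadata_csv` set.
#' @return list with `cohort` (data.frame), `flagged` (subject ids missing
#'   vertebrae) and `manifest`.
#' @export
runDSBatch <- function(config) {
    cdir <- config$contour_dir
    if (is.null(cdir)) cdir <- file.path(config$out_dir, "contours")
    if (!dir.exists(cdir)) stop("unreadable contour directory: ", cdir)
    if (is.null(config$metadata_csv))
        stop("metadata_csv (subject_id,sex,age) is required")
    meta <- utils::read.csv(config$metadata_csv)
    need <- c("subject_id", "sex", "age")
    if (!all(need %in% names(meta)))
        stop("metadata must have columns subject_id,sex,age")
    files <- list.files(cdir, pattern = "\\.csv$", full.names = TRUE)
    units <- parseUnitName(files)
    units <- units[units$vertebra %in% vertebraLabels(), , drop = FALSE]
    orphans <- setdiff(unique(units$subject_id), meta$subject_id)
    if (length(orphans))
        stop("contours without metadata for subjects: ",
             paste(orphans, collapse = ", "))
    rows <- lapply(seq_len(nrow(units)), function(i) {
        u <- units[i, ]
        ds <- tryCatch({
            fit <- fitContourFile(u$file, config = config$fit)
            if (!fit@converged)
                logMsg(config, "fit", "%s_%s did not converge",
                       u$subject_id, u$vertebra)
            fit@ds
        }, error = function(e) {
            logMsg(config, "fit", "%s_%s failed: %s", u$subject_id,
                   u$vertebra, conditionMessage(e))
            NA_real_
        })
        data.frame(subject_id = u$subject_id, vertebra = u$vertebra,
                   ds = ds)
    })
    long <- do.call(rbind, rows)
    wide <- stats::reshape(long, idvar = "subject_id",
                           timevar = "vertebra", direction = "wide")
    names(wide) <- sub("^ds\\.", "", names(wide))
    for (v in setdiff(vertebraLabels(), names(wide)))
        wide[[v]] <- NA_real_
    cohort <- merge(meta[, need], wide, by = "subject_id", sort = TRUE)
    cohort <- cohort[, c(need, vertebraLabels())]
    complete <- stats::complete.cases(cohort[, vertebraLabels()])
    flagged <- cohort$subject_id[!complete]
    if (length(flagged))
        logMsg(config, "assemble", "subjects missing vertebrae: %s",
               paste(flagged, collapse = ", "))
    if (config$strict) cohort <- cohort[complete, , drop = FALSE]
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(config$out_dir, "cohort.csv")
    utils::write.csv(cohort, path, row.names = FALSE)
    list(cohort = cohort, flagged = flagged, cohort_csv = path,
         manifest = data.frame(long, config_hash = config$config_hash))
}

#' Full statistical report from a cohort table
#'
#' Executes the cohort-statistics, machine-learning and power-analysis
#' stages on a cohort CSV under one seeded manifest: descriptives, sex
#' comparisons, age correlations, ANCOVA interaction screen, per-sex MLR
#' (with post hoc power) and LASSO, then the tuned learners with hold-out
#' evaluation. Tables are written as CSV/JSON under `out_dir`.
#'
#' @param config a [runConfig()] with `cohort_csv` set (or a cohort
#'   data.frame in `cohort`).
#' @param cohort optional in-memory cohort overriding `cohort_csv`.
#' @return list with elements `descriptives`, `sex_tests`, `correlations`,
#'   `ancova`, `mlr` (per sex), `power` (per sex), `lasso` (per sex),
#'   `ml` (per sex, per model [evaluateModel()] reports) and `manifest`.
#' @export
runFullReport <- function(config, cohort = NULL) {
    if (is.null(cohort)) {
        if (is.null(config$cohort_csv)) stop("config has no cohort_csv")
        cohort <- readCohortCSV(config$cohort_csv, min_age = -Inf)
    }
    cohort <- validateCohort(cohort, min_age = -Inf)
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    logMsg(config, "stats", "descriptives and correlations")
    desc <- descriptiveStats(cohort)
    sexTests <- data.frame(
        vertebra = vertebraLabels(),
        p = vapply(vertebraLabels(),
                   function(v) sexDifferenceTest(cohort, v), 0))
    corr <- ageCorrelations(cohort)
    anc <- ancovaInteractionScreen(cohort)
    mlr <- list(); pw <- list(); lasso <- list(); ml <- list()
    for (s in c("M", "F")) {
        logMsg(config, "model", "sex %s: MLR/LASSO", s)
        mlr[[s]] <- mlrFit(cohort, s)
        pw[[s]] <- powerReport(mlr[[s]]$r2, mlr[[s]]$n, mlr[[s]]$k)
        lasso[[s]] <- lassoFit(cohort, s, seed = config$seed)
        sub <- cohort[cohort$sex == s, , drop = FALSE]
        sp <- makeSplit(sub, config$split)
        ml[[s]] <- lapply(stats::setNames(config$models, config$models),
            function(m) {
                logMsg(config, "ml", "sex %s: %s", s, m)
                mod <- tuneModel(sp$train, m, spec = config$split)
                evaluateModel(mod, sp$test, seed = config$split$seed)
            })
    }
    mlTable <- do.call(rbind, lapply(names(ml), function(s)
        do.call(rbind, lapply(ml[[s]], function(e)
            data.frame(sex = s, model = e$model_name,
                       holdout_r2 = e$holdout_r2, r2_ci_lo = e$r2_ci_lo,
                       r2_ci_hi = e$r2_ci_hi, see_years = e$see_years,
                       see_ci_lo = e$see_ci_lo, see_ci_hi = e$see_ci_hi,
                       mae_years = e$mae_years, rmse_years = e$rmse_years,
                       cv_r2 = e$cv_r2, oob_r2 = e$oob_r2)))))
    utils::write.csv(desc, file.path(config$out_dir, "descriptives.csv"),
                     row.names = FALSE)
    utils::write.csv(corr, file.path(config$out_dir, "correlations.csv"),
                     row.names = FALSE)
    utils::write.csv(mlTable, file.path(config$out_dir, "ml_report.csv"),
                     row.names = FALSE)
    powerTab <- do.call(rbind, lapply(names(pw), function(s)
        data.frame(sex = s, r2 = pw[[s]]@r2, f2 = pw[[s]]@f2,
                   df1 = pw[[s]]@df1, df2 = pw[[s]]@df2,
                   lambda = pw[[s]]@lambda, f_crit = pw[[s]]@fCrit,
                   power = pw[[s]]@power)))
    utils::write.csv(powerTab, file.path(config$out_dir, "power.csv"),
                     row.names = FALSE)
    manifest <- list(seed = config$seed, config_hash = config$config_hash,
                     timestamp = format(Sys.time()),
                     n_subjects = nrow(cohort))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE)
    list(descriptives = desc, sex_tests = sexTests, correlations = corr,
         ancova = anc, mlr = mlr, power = pw, lasso = lasso, ml = ml,
         ml_table = mlTable, manifest = manifest)
}
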
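#' Read an 8-bit grayscale image
#'
#' Reads PNG or TIFF images and returns an intensity matrix in \[0, 255\]
#' (rows = image y from the top). Multi-channel images are reduced to their
#' first channel with a warning if channels differ.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return Numeric matrix of intensities in \[0, 255\].
#' @export
readGrayImage <- function(path) {
    ext <- tolower(tools::file_ext(path))
    arr <- switch(ext,
        png = png::readPNG(path),
        tif = ,
        tiff = tiff::readTIFF(path),
        stop("unsupported image format: .", ext))
    if (length(dim(arr)) == 3L) {
        if (dim(arr)[3L] > 1L) {
            chans <- dim(arr)[3L]
            same <- all(vapply(seq_len(chans - 1L), function(k)
                isTRUE(all.equal(arr[, , k], arr[, , k + 1L])), TRUE))
            if (!same) warning("multi-channel image; using first channel")
        }
        arr <- arr[, , 1L]
    }
    round(arr * 255)
}

#' Write an 8-bit grayscale PNG image
#'
#' @param image intensity matrix in \[0, 255\].
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
writeGrayImage <- function(image, path) {
    png::writePNG(matrix(as.numeric(image) / 255, nrow(image), ncol(image)),
                  path)
    invisible(path)
}

#' Read and write contour coordinate CSV files
#'
#' The on-disk format is a two-column CSV with header `x,y`, one file per
#' vertebra.
#'
#' @param contour a [Contour-class] object.
#' @param path file path.
#' @param units coordinate units of the file content (`"mm"` or `"px"`).
#' @param closed whether the stored boundary is closed.
#' @return `writeContourCSV` returns `path` invisibly; `readContourCSV`
#'   returns a [Contour-class].
#' @export
writeContourCSV <- function(contour, path) {
    stopifnot(is(contour, "Contour"))
    df <- data.frame(x = contour@points[, 1L], y = contour@points[, 2L])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeContourCSV
#' @export
readContourCSV <- function(path, units = "mm", closed = FALSE) {
    df <- utils::read.csv(path)
    if (!all(c("x", "y") %in% names(df)))
        stop("contour CSV must have columns x,y")
    Contour(as.matrix(df[, c("x", "y")]), units = units, closed = closed)
}

#' Read and write cohort CSV files
#'
#' Schema: `subject_id, sex, age, C7, T1, ..., T12, L1, ..., L5, S1` with
#' sex coded M/F.
#'
#' @param cohort a cohort data.frame (see [makeSyntheticCohort()]).
#' @param path file path.
#' @param min_age validation lower bound on age (see [validateCohort()]).
#' @return `writeCohortCSV` returns `path` invisibly; `readCohortCSV`
#'   returns a validated data.frame.
#' @export
writeCohortCSV <- function(cohort, path) {
    validateCohort(cohort, min_age = -Inf)
    utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeCohortCSV
#' @export
readCohortCSV <- function(path, min_age = 21) {
    df <- utils::read.csv(path, check.names = FALSE)
    validateCohort(df, min_age = min_age)
    df
}
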
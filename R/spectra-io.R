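#' Read a spectra / design CSV pair
#'
#' Reads the wide-format export convention used throughout the package: the
#' spectra file is a comma-separated matrix with one header row of
#' wavelengths in nm (dot decimal, UTF-8) and one row per acquisition; the
#' design file has a header of factor names and one row of categorical
#' levels per acquisition, aligned with the spectra by row order.
#'
#' @param spectraPath path to the wide spectra CSV.
#' @param designPath path to the design CSV.
#' @return a [SpectraSet-class].
#' @seealso [writeSpectraCSV()]
#' @export
readSpectraCSV <- function(spectraPath, designPath) {
    header <- strsplit(readLines(spectraPath, n = 1L), ",", fixed = TRUE)[[1]]
    wl <- suppressWarnings(as.numeric(header))
    if (anyNA(wl))
        stop("spectra header could not be parsed as wavelengths: ",
             paste(sQuote(utils::head(header[is.na(wl)], 3)),
                   collapse = ", "))
    if (any(diff(wl) <= 0))
        stop("wavelength header is not strictly increasing")
    raw <- utils::read.csv(spectraPath, header = TRUE,
                           check.names = FALSE, colClasses = "character")
    m <- suppressWarnings(
        matrix(as.numeric(as.matrix(raw)), nrow(raw), ncol(raw)))
    bad <- which(!is.finite(m), arr.ind = TRUE)
    if (nrow(bad))
        stop("non-numeric or non-finite spectra value at row ", bad[1, 1],
             ", column ", bad[1, 2])
    design <- utils::read.csv(designPath, header = TRUE,
                              check.names = FALSE,
                              colClasses = "character",
                              stringsAsFactors = FALSE)
    if (nrow(design) != nrow(m))
        stop("design table has ", nrow(design),
             " rows but spectra matrix has ", nrow(m),
             " rows; the files must align one-to-one")
    SpectraSet(m, wl, design)
}

#' Write a SpectraSet as a spectra / design CSV pair
#'
#' Inverse of [readSpectraCSV()]: writing then reading reproduces the
#' object's matrix, grid and design (factor levels are serialised as
#' character).
#'
#' @param x a [SpectraSet-class].
#' @param spectraPath,designPath output file paths.
#' @return invisibly, the two paths.
#' @export
writeSpectraCSV <- function(x, spectraPath, designPath) {
    m <- spectraMatrix(x)
    # %.17g round-trips IEEE doubles exactly
    fmt <- function(v) sprintf("%.17g", v)
    lines <- c(paste(fmt(wavelengths(x)), collapse = ","),
               apply(m, 1L, function(r) paste(fmt(r), collapse = ",")))
    writeLines(lines, spectraPath)
    dt <- designTable(x)
    dt[] <- lapply(dt, as.character)
    utils::write.csv(dt, designPath, row.names = FALSE, quote = FALSE)
    invisible(c(spectraPath, designPath))
}
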
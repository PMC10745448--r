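#' Wavelength grid of a SpectraSet
#'
#' @param x a [SpectraSet-class].
#' @return numeric vector of channel centers in nm.
#' @export
#' @name wavelengths
#' @aliases wavelengths,SpectraSet-method
setMethod("wavelengths", "SpectraSet", function(x)
    as.numeric(rowData(x)$wavelength))

#' Design table of a SpectraSet
#'
#' @param x a [SpectraSet-class].
#' @return data.frame of categorical design factors, one row per
#'   acquisition.
#' @export
#' @name designTable
#' @aliases designTable,SpectraSet-method
setMethod("designTable", "SpectraSet", function(x) {
    df <- as.data.frame(colData(x))
    rownames(df) <- NULL
    df
})

#' Reflectance matrix of a SpectraSet
#'
#' @param x a [SpectraSet-class].
#' @return numeric matrix, acquisitions in rows and wavelength channels in
#'   columns (column names are the wavelengths in nm).
#' @export
#' @name spectraMatrix
#' @aliases spectraMatrix,SpectraSet-method
setMethod("spectraMatrix", "SpectraSet", function(x) {
    m <- t(assay(x, "reflectance"))
    colnames(m) <- format(wavelengths(x), trim = TRUE)
    rownames(m) <- NULL
    m
})

setMethod("show", "SpectraSet", function(object) {
    wl <- wavelengths(object)
    cat("SpectraSet with", ncol(object), "acquisitions x",
        nrow(object), "channels\n")
    cat(sprintf("  wavelengths: %.1f-%.1f nm\n", min(wl), max(wl)))
    dt <- designTable(object)
    if (ncol(dt)) {
        lv <- vapply(dt, function(col) length(unique(col)), integer(1))
        cat("  design factors:",
            paste(sprintf("%s (%d)", names(lv), lv), collapse = ", "), "\n")
    }
    pp <- metadata(object)$preprocess
    if (length(pp))
        cat("  preprocessing:", paste(vapply(pp, `[[`, "", "step"),
                                      collapse = " -> "), "\n")
})

#' Subset acquisitions by design-factor levels
#'
#' Selects the rows (acquisitions) whose design entries match every
#' `factor = level(s)` clause, keeping the design aligned. Unused factor
#' levels are dropped from the subset's design.
#'
#' @param x a [SpectraSet-class].
#' @param ... named clauses, e.g. `session = "2"` or
#'   `sample = c("s1", "s2")`.
#' @param drop unused; present for symmetry with `[`.
#' @return a [SpectraSet-class] with the matching acquisitions.
#' @examples
#' cfg <- simConfig(channels = 16, samples = 2, sessions = 2,
#'                  replicates = 3)
#' s <- simulateSpectra(buildDesign(cfg), cfg)
#' nrow(designTable(subsetSpectra(s, session = "1")))
#' @export
subsetSpectra <- function(x, ..., drop = FALSE) {
    clauses <- list(...)
    if (length(clauses) == 0L) return(x)
    if (is.null(names(clauses)) || any(names(clauses) == ""))
        stop("all selector clauses must be named by a design factor")
    dt <- designTable(x)
    keep <- rep(TRUE, nrow(dt))
    for (f in names(clauses)) {
        if (!f %in% names(dt))
            stop("unknown design factor '", f, "'; available: ",
                 paste(names(dt), collapse = ", "))
        lv <- as.character(clauses[[f]])
        have <- unique(as.character(dt[[f]]))
        bad <- setdiff(lv, have)
        if (length(bad))
            stop("unknown level(s) ", paste(sQuote(bad), collapse = ", "),
                 " for factor '", f, "'; available: ",
                 paste(sQuote(have), collapse = ", "))
        keep <- keep & as.character(dt[[f]]) %in% lv
    }
    if (!any(keep))
        warning("selection matches no acquisitions; returning an empty set")
    out <- x[, keep]
    cd <- colData(out)
    for (j in seq_along(cd))
        if (is.factor(cd[[j]])) cd[[j]] <- droplevels(cd[[j]])
    colData(out) <- cd
    out
}
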
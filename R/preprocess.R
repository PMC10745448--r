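.recordStep <- function(x, step, ...) {
    pp <- metadata(x)$preprocess
    metadata(x)$preprocess <- c(pp, list(c(list(step = step), list(...))))
    x
}

.replaceMatrix <- function(x, m, wl = wavelengths(x)) {
    out <- SpectraSet(m, wl, designTable(x))
    metadata(out) <- metadata(x)
    out
}

#' Column mean-centering
#'
#' Subtracts the mean spectrum from every acquisition. Applied internally
#' by [ascaDecompose()]; exposed for explicit pipelines.
#'
#' @param x a [SpectraSet-class].
#' @return a [SpectraSet-class] with zero column means.
#' @export
meanCenter <- function(x) {
    m <- spectraMatrix(x)
    out <- .replaceMatrix(x, sweep(m, 2L, colMeans(m)))
    .recordStep(out, "mean_center")
}

#' Standard normal variate (SNV)
#'
#' Centers every spectrum to mean 0 and scales it to unit sample standard
#' deviation (n - 1 denominator), removing additive and multiplicative
#' scatter row-wise.
#'
#' @param x a [SpectraSet-class].
#' @return a transformed [SpectraSet-class].
#' @export
snv <- function(x) {
    m <- spectraMatrix(x)
    mu <- rowMeans(m)
    sd <- apply(m, 1L, stats::sd)
    if (any(sd == 0))
        stop("constant spectrum (zero sd) in row(s) ",
             paste(which(sd == 0), collapse = ", "),
             "; SNV is undefined there")
    out <- .replaceMatrix(x, (m - mu) / sd)
    .recordStep(out, "snv")
}

#' Multiplicative scatter correction (MSC)
#'
#' Regresses every spectrum on a reference spectrum,
#' `x = a + b * ref + e`, and returns `(x - a) / b`, inverting the fitted
#' additive and multiplicative scatter.
#'
#' @param x a [SpectraSet-class].
#' @param reference `"mean"` (the mean spectrum, the usual choice) or a
#'   numeric spectrum of matching length.
#' @param tol smallest admissible `|b|`.
#' @return a transformed [SpectraSet-class].
#' @export
msc <- function(x, reference = "mean", tol = 1e-10) {
    m <- spectraMatrix(x)
    ref <- if (identical(reference, "mean")) colMeans(m) else
        as.numeric(reference)
    if (length(ref) != ncol(m))
        stop("reference length (", length(ref),
             ") must equal the channel count (", ncol(m), ")")
    refc <- ref - mean(ref)
    den <- sum(refc^2)
    if (den == 0) stop("reference spectrum has zero variance")
    b <- as.numeric(m %*% refc) / den          # least-squares slope
    a <- rowMeans(m) - b * mean(ref)
    if (any(abs(b) < tol))
        stop("fitted scatter slope below tolerance in row(s) ",
             paste(which(abs(b) < tol), collapse = ", "))
    out <- .replaceMatrix(x, (m - a) / b)
    .recordStep(out, "msc", reference = if (identical(reference, "mean"))
        "mean" else "custom")
}

#' Savitzky-Golay derivative filtering
#'
#' Applies a Savitzky-Golay local-polynomial derivative filter to every
#' spectrum. The `(window - 1)/2` edge channels on each side, where the
#' centered filter is undefined, are removed from both the matrix and the
#' wavelength grid (edge truncation).
#'
#' @param x a [SpectraSet-class].
#' @param window odd filter width in channels (default 7).
#' @param polyorder polynomial order (default 2), `< window`.
#' @param derivorder derivative order (default 1), `<= polyorder`;
#'   0 gives pure smoothing.
#' @param perNm logical; if `TRUE`, derivatives are scaled per nm using the
#'   mean channel spacing instead of per channel step.
#' @return a transformed [SpectraSet-class] with
#'   `p - window + 1` channels.
#' @export
savgolDerivative <- function(x, window = 7, polyorder = 2, derivorder = 1,
                             perNm = FALSE) {
    if (window %% 2 != 1) stop("window must be odd (got ", window, ")")
    if (polyorder >= window)
        stop("polyorder must be smaller than window")
    if (derivorder > polyorder)
        stop("derivorder must not exceed polyorder")
    m <- spectraMatrix(x)
    p <- ncol(m)
    if (p < window)
        stop("spectra have ", p, " channels but the filter window is ",
             window)
    half <- (window - 1L) %/% 2L
    coef <- signal::sgolay(p = polyorder, n = window, m = derivorder)
    cen <- as.numeric(coef[half + 1L, ])       # centered FIR filter
    keep <- seq.int(half + 1L, p - half)
    filt <- matrix(0, nrow(m), length(keep))
    for (k in seq_len(window))
        filt <- filt + cen[k] * m[, keep - half - 1L + k, drop = FALSE]
    if (perNm) filt <- filt / mean(diff(wavelengths(x)))^derivorder
    out <- .replaceMatrix(x, filt, wavelengths(x)[keep])
    .recordStep(out, "savgol", window = window, polyorder = polyorder,
                derivorder = derivorder, perNm = perNm)
}

#' Apply a named preprocessing variant or step list
#'
#' Convenience dispatcher used by the workflow: `"none"` returns the input
#' unchanged, `"snv"` applies [snv()], `"savgol"` applies the
#' first-derivative Savitzky-Golay filter with window 7 and polynomial
#' order 2, `"msc"` applies [msc()] against the mean spectrum,
#' `"mean_center"` applies [meanCenter()]. A list
#' `list(step = "savgol", window = , polyorder = , derivorder = )` selects
#' parameters explicitly; a list of such elements is applied in order.
#'
#' @param x a [SpectraSet-class].
#' @param spec character name or list as above.
#' @return a transformed [SpectraSet-class]; every applied step is recorded
#'   in `metadata(x)$preprocess`.
#' @export
applyPreprocess <- function(x, spec) {
    one <- function(x, s) {
        if (is.character(s)) s <- list(step = s)
        switch(s$step,
               none = x,
               mean_center = meanCenter(x),
               snv = snv(x),
               msc = msc(x, reference = s$reference %||% "mean"),
               savgol = savgolDerivative(
                   x,
                   window = s$window %||% 7,
                   polyorder = s$polyorder %||% 2,
                   derivorder = s$derivorder %||% 1),
               stop("unknown preprocessing step '", s$step, "'"))
    }
    if (is.character(spec) && length(spec) == 1L) return(one(x, spec))
    if (is.list(spec) && !is.null(spec$step)) return(one(x, spec))
    for (s in spec) x <- one(x, s)
    x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
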
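## K redundancy index of a correlation matrix: with eigenvalues lambda_m
## of Sigma_cor and explained variances EV_m = lambda_m / sum(lambda),
##
##     K = sum_m |EV_m - 1/p|  /  (2 (p - 1) / p)
##
## K = 0 when all variables are uncorrelated (all EV equal 1/p) and K = 1
## under perfect correlation (a single nonzero eigenvalue). When the
## correlation matrix comes from an error matrix of rank r < p, K cannot
## fall below the "imbedded" minimum (p - r)/(p - 1), attained when the r
## nonzero eigenvalues are equal.

.kFromEigen <- function(lambda, p) {
    lambda <- pmax(lambda, 0)
    ev <- lambda / sum(lambda)
    sum(abs(ev - 1 / p)) / (2 * (p - 1) / p)
}

#' K redundancy index of a correlation matrix
#'
#' Eigendecomposes the correlation matrix (negative numerical eigenvalues
#' clipped at 0 — exact-arithmetic correlation matrices are PSD), computes
#' the explained variances and the K index, and, when the effective rank of
#' the underlying error matrix is supplied, the imbedded minimum and the
#' distance to it. A small distance means the preprocessing has removed
#' nearly all experiment-dependent channel correlation.
#'
#' @param corr square symmetric correlation matrix (unit diagonal).
#' @param rank optional effective rank `r` of the error matrix the
#'   correlation was estimated from (typically `n - g`); enables the
#'   imbedded-minimum comparison. Values above `p` are capped at `p`
#'   (the imbedded minimum is then 0).
#' @param symTol symmetry tolerance.
#' @return a [KIndexResult-class].
#' @examples
#' kIndex(diag(10))@k            # 0: uncorrelated
#' kIndex(matrix(1, 5, 5))@k     # 1: perfectly correlated
#' @export
kIndex <- function(corr, rank = NULL, symTol = 1e-8) {
    corr <- as.matrix(corr)
    if (nrow(corr) != ncol(corr))
        stop("correlation matrix must be square (got ", nrow(corr), " x ",
             ncol(corr), ")")
    if (max(abs(corr - t(corr))) > symTol)
        stop("correlation matrix is not symmetric")
    p <- nrow(corr)
    if (max(abs(diag(corr) - 1)) > 1e-6)
        warning("correlation matrix diagonal deviates from 1")
    lambda <- sort(eigen((corr + t(corr)) / 2, symmetric = TRUE,
                         only.values = TRUE)$values, decreasing = TRUE)
    lambda <- pmax(lambda, 0)
    k <- .kFromEigen(lambda, p)
    if (!is.null(rank)) {
        # a p-variable correlation matrix cannot exceed rank p: when the
        # replicate-derived bound n - g is larger, the imbedded minimum is 0
        rank <- min(rank, p)
        kmin <- imbeddedK(p, rank)
        new("KIndexResult", eigenvalues = lambda,
            explainedVariance = lambda / sum(lambda), k = k,
            p = as.integer(p), kMin = kmin, rank = as.integer(rank),
            distance = k - kmin)
    } else {
        new("KIndexResult", eigenvalues = lambda,
            explainedVariance = lambda / sum(lambda), k = k,
            p = as.integer(p), kMin = NA_real_, rank = NA_integer_,
            distance = NA_real_)
    }
}

#' Imbedded (minimum attainable) K index
#'
#' A correlation matrix estimated from an error matrix of rank `r < p`
#' cannot have K below `(p - r)/(p - 1)`: the best case spreads the total
#' variance equally over the `r` nonzero components. The closed form is
#' cross-checked internally against the K-index summation evaluated on that
#' equal-eigenvalue spectrum (`r` eigenvalues of `p / r`, the rest 0); the
#' two routes must agree to 1e-12.
#'
#' @param p number of variables (channels).
#' @param r effective rank, `1 <= r <= p` (typically replicates minus the
#'   number of pooled group means, `n - g`).
#' @return the imbedded minimum K, a number in `[0, 1]`.
#' @examples
#' imbeddedK(236, 42)  # 0.826
#' imbeddedK(74, 45)   # 0.397
#' @export
imbeddedK <- function(p, r) {
    if (length(p) != 1L || length(r) != 1L || p < 2 || r < 1 || r > p)
        stop("need 1 <= r <= p with p >= 2 (got p = ", p, ", r = ", r, ")")
    closed <- (p - r) / (p - 1)
    spectral <- .kFromEigen(c(rep(p / r, r), rep(0, p - r)), p)
    if (abs(closed - spectral) > 1e-12)
        stop("internal inconsistency between closed form and spectral ",
             "evaluation of the imbedded K")
    closed
}

setMethod("show", "KIndexResult", function(object) {
    cat(sprintf("KIndexResult: K = %.3f (p = %d)", object@k, object@p))
    if (!is.na(object@kMin))
        cat(sprintf("; imbedded minimum %.3f at rank %d (distance %.3f)",
                    object@kMin, object@rank, object@distance))
    cat("\n")
})

#' Image histogram of an error-correlation matrix
#'
#' Maps every correlation to a gray level `g = (rho + 1)/2` (-1 -> 0,
#' 0 -> 0.5, 1 -> 1) and bins the resulting "image" over `[0, 1]`. An ideal
#' unstructured error yields a symmetric distribution centred at 0.5;
#' mass piled towards 1 signals correlated errors. Bins are left-closed,
#' with the last bin right-inclusive so that `g = 1` is counted.
#'
#' @param corr correlation matrix with entries in `[-1, 1]`.
#' @param nBins number of equal-width bins (default 256, the 8-bit image
#'   convention).
#' @param includeDiagonal logical; the default (`TRUE`) histograms the full
#'   matrix including the unit-diagonal spike at gray 1.
#' @param tailThresholds numeric length-2 `c(low, high)` gray thresholds
#'   for the reported tail masses.
#' @param tol tolerance for entries slightly outside `[-1, 1]`.
#' @return a [HistogramSummary-class].
#' @export
imageHistogram <- function(corr, nBins = 256, includeDiagonal = TRUE,
                           tailThresholds = c(0.05, 0.95), tol = 1e-8) {
    corr <- as.matrix(corr)
    vals <- if (includeDiagonal) as.numeric(corr) else
        as.numeric(corr[row(corr) != col(corr)])
    if (any(vals < -1 - tol | vals > 1 + tol))
        stop("correlation entries outside [-1, 1]")
    vals <- pmin(pmax(vals, -1), 1)
    g <- (vals + 1) / 2
    idx <- pmin(floor(g * nBins) + 1L, as.integer(nBins))
    counts <- tabulate(idx, nbins = nBins)
    breaks <- seq(0, 1, length.out = nBins + 1)
    mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
    mu <- mean(g); s <- stats::sd(g)
    skew <- if (is.na(s) || s == 0) 0 else mean((g - mu)^3) / s^3
    new("HistogramSummary", breaks = breaks, counts = as.integer(counts),
        totalPixels = length(g), mode = mids[which.max(counts)],
        skewness = skew,
        tailMass = c(low = mean(g <= tailThresholds[1]),
                     high = mean(g >= tailThresholds[2])),
        includeDiagonal = includeDiagonal)
}

setMethod("show", "HistogramSummary", function(object) {
    cat(sprintf(paste0("HistogramSummary: %d pixels in %d bins; mode at ",
                       "gray %.3f, skewness %.3f\n"),
                object@totalPixels, length(object@counts), object@mode,
                object@skewness))
})
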
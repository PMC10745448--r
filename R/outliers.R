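#' Flag gross outlier spectra by PCA screening
#'
#' Fits a PCA to the mean-centered reflectance matrix and flags acquisitions
#' exceeding either the Hotelling-T2 limit (F-distribution) or the
#' Q-residual limit (Jackson-Mudholkar approximation) at confidence
#' `1 - alpha`. Flags are returned, never applied: removal is a separate,
#' explicit step ([dropOutliers()]) so that design-balance bookkeeping stays
#' under the user's control.
#'
#' @param x a [SpectraSet-class].
#' @param nComponents number of principal components retained; the default
#'   (`NULL`) takes the smallest number explaining at least 90% of the
#'   variance.
#' @param alpha significance level of the limits (default 0.01).
#' @return logical vector, one flag per acquisition, with attributes `t2`,
#'   `q`, `t2Limit`, `qLimit` and `nComponents` carrying the underlying
#'   statistics.
#' @export
flagGrossOutliers <- function(x, nComponents = NULL, alpha = 0.01) {
    m <- spectraMatrix(x)
    n <- nrow(m)
    p <- ncol(m)
    mc <- sweep(m, 2L, colMeans(m))
    sv <- svd(mc)
    ev <- sv$d^2 / (n - 1)                    # PC variances
    rk <- sum(sv$d > sv$d[1] * 1e-10)
    if (is.null(nComponents)) {
        nComponents <- which(cumsum(ev) / sum(ev) >= 0.9)[1]
        nComponents <- min(nComponents, rk - 1L)
        nComponents <- max(nComponents, 1L)
    }
    if (n < nComponents + 2L)
        stop("need at least nComponents + 2 acquisitions (n = ", n, ")")
    if (nComponents >= min(n - 1L, p))
        stop("nComponents = ", nComponents,
             " must be below min(n - 1, p) = ", min(n - 1L, p))
    a <- as.integer(nComponents)
    scores <- sv$u[, seq_len(a), drop = FALSE] %*% diag(sv$d[seq_len(a)], a)
    t2 <- rowSums(sweep(scores^2, 2L, ev[seq_len(a)], "/"))
    t2Limit <- a * (n - 1) / (n - a) * stats::qf(1 - alpha, a, n - a)
    recon <- scores %*% t(sv$v[, seq_len(a), drop = FALSE])
    q <- rowSums((mc - recon)^2)
    resEv <- ev[-seq_len(a)]
    th1 <- sum(resEv); th2 <- sum(resEv^2); th3 <- sum(resEv^3)
    if (th1 > max(ev) * 1e-12) {
        h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
        if (!is.finite(h0) || h0 < 1e-3) h0 <- 1e-3
        z <- stats::qnorm(1 - alpha)
        qLimit <- th1 * (z * sqrt(2 * th2 * h0^2) / th1 +
                         1 + th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
    } else {
        qLimit <- Inf                          # no residual subspace
    }
    flags <- t2 > t2Limit | q > qLimit
    structure(flags, t2 = t2, q = q, t2Limit = t2Limit, qLimit = qLimit,
              nComponents = a)
}

#' Drop flagged acquisitions
#'
#' @param x a [SpectraSet-class].
#' @param flags logical vector as returned by [flagGrossOutliers()].
#' @return `x` without the flagged acquisitions.
#' @export
dropOutliers <- function(x, flags) {
    if (length(flags) != ncol(x))
        stop("flags length (", length(flags),
             ") must equal the number of acquisitions (", ncol(x), ")")
    if (!any(flags)) return(x)
    x[, !flags]
}
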
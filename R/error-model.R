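#' Replicate-mean-subtracted error matrix
#'
#' Subtracts from every spectrum the mean of its replicate group — by
#' default the sample x session x background-timing cell — so systematic
#' between-group differences do not enter the error estimate. Each group
#' spends one degree of freedom on its mean, so the numerical rank of the
#' result is at most `n - g`.
#'
#' @param x a [SpectraSet-class].
#' @param replicateGroup character vector of design factors defining the
#'   replicate groups; the default uses every design factor except
#'   `replicate_order` and `instrument_config`.
#' @return an [ErrorMatrix-class].
#' @examples
#' cfg <- simConfig(channels = 16, samples = 1, sessions = 3,
#'                  replicates = 15, backgroundTimings = "per-sample")
#' e <- errorMatrix(simulateSpectra(buildDesign(cfg), cfg))
#' e@rankBound  # 45 - 3
#' @export
errorMatrix <- function(x, replicateGroup = NULL) {
    design <- designTable(x)
    if (is.null(replicateGroup))
        replicateGroup <- setdiff(names(design),
                                  c("replicate_order", "instrument_config"))
    miss <- setdiff(replicateGroup, names(design))
    if (length(miss))
        stop("grouping factor(s) not in the design: ",
             paste(miss, collapse = ", "))
    g <- if (length(replicateGroup))
        droplevels(interaction(design[replicateGroup], drop = TRUE,
                               sep = ":"))
    else factor(rep("all", nrow(design)))
    sizes <- table(g)
    if (any(sizes < 2L))
        stop("replicate cell(s) with a single acquisition: ",
             paste(names(sizes)[sizes < 2L], collapse = ", "),
             "; at least 2 replicates per cell are required")
    m <- spectraMatrix(x)
    means <- (rowsum(m, g, reorder = TRUE) / as.integer(sizes))
    E <- m - means[as.integer(g), , drop = FALSE]
    new("ErrorMatrix", E = E, grouping = replicateGroup, groups = g,
        groupSizes = as.integer(sizes),
        rankBound = nrow(m) - nlevels(g), wavelengths = wavelengths(x))
}

setMethod("show", "ErrorMatrix", function(object) {
    cat("ErrorMatrix:", nrow(object@E), "rows x", ncol(object@E),
        "channels;", nlevels(object@groups), "replicate groups (",
        paste(object@grouping, collapse = " x "), "); rank bound",
        object@rankBound, "\n")
})

#' Pooled error covariance
#'
#' Classical pooled estimator over the within-group-centered residuals:
#' `Sigma_cov = t(E) %*% E / (n - g)`. With a single group this reduces to
#' the ordinary sample covariance with `n - 1` degrees of freedom; with
#' several groups (e.g. sessions) it averages the per-group covariance
#' estimates weighted by their degrees of freedom.
#'
#' @param e an [ErrorMatrix-class].
#' @return an [ErrorSurfaces-class] with the covariance part filled in
#'   (apply [correlationMatrix()] for the correlation part).
#' @export
pooledCovariance <- function(e) {
    stopifnot(is(e, "ErrorMatrix"))
    dof <- nrow(e@E) - nlevels(e@groups)
    if (dof < 1L)
        stop("pooled degrees of freedom n - g = ", dof, " < 1")
    S <- crossprod(e@E) / dof
    S <- (S + t(S)) / 2
    new("ErrorSurfaces", sigmaCov = S,
        sigmaCor = matrix(numeric(0), 0, 0), dof = as.integer(dof),
        excluded = integer(0), wavelengths = e@wavelengths)
}

#' Error correlation matrix
#'
#' Scales the pooled covariance to correlations,
#' `Sigma_cor(i, j) = Sigma_cov(i, j) / sqrt(Sigma_cov(i,i) Sigma_cov(j,j))`.
#' Channels whose error variance is below `tol` times the maximum variance
#' are excluded from the correlation surface and listed in the `excluded`
#' slot (this happens e.g. for degenerate channels after derivative edge
#' truncation).
#'
#' @param x an [ErrorSurfaces-class] holding a covariance.
#' @param tol relative variance tolerance (default 1e-12).
#' @return the [ErrorSurfaces-class] with `sigmaCor` filled in.
#' @export
#' @name correlationMatrix
#' @aliases correlationMatrix,ErrorSurfaces-method
setMethod("correlationMatrix", "ErrorSurfaces", function(x, tol = 1e-12) {
    S <- x@sigmaCov
    if (length(S) == 0L) stop("no covariance surface present")
    v <- diag(S)
    if (all(v <= 0)) stop("all channels have zero error variance")
    keep <- v >= tol * max(v)
    Sk <- S[keep, keep, drop = FALSE]
    d <- 1 / sqrt(diag(Sk))
    C <- Sk * tcrossprod(d)
    diag(C) <- 1
    C[C > 1] <- 1
    C[C < -1] <- -1
    dimnames(C) <- NULL
    x@sigmaCor <- C
    x@excluded <- unname(which(!keep))
    x
})

setMethod("show", "ErrorSurfaces", function(object) {
    p <- nrow(object@sigmaCov)
    cat("ErrorSurfaces:", p, "x", p, "pooled covariance, dof =",
        object@dof, "\n")
    if (length(object@sigmaCor))
        cat("  correlation over", nrow(object@sigmaCor), "channels (",
            length(object@excluded), "excluded for near-zero variance)\n")
})

#' Diagonal variance profile of an error surface
#'
#' @param surfaces an [ErrorSurfaces-class].
#' @return data.frame with columns `wavelength` and `variance`.
#' @export
varianceProfile <- function(surfaces) {
    data.frame(wavelength = surfaces@wavelengths,
               variance = diag(surfaces@sigmaCov))
}
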
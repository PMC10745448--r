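## ANOVA-simultaneous component analysis: the centered data matrix is
## decomposed into additive effect matrices (one per design factor and
## requested two-way interaction) plus residuals; effect importance is the
## Frobenius sum of squares of the corresponding matrix.

# level-mean expansion: row i gets the mean of the rows sharing g[i]
.levelMeans <- function(Xc, g) {
    g <- droplevels(as.factor(g))
    sums <- rowsum(Xc, g, reorder = TRUE)
    counts <- as.integer(table(g))
    out <- (sums / counts)[as.integer(g), , drop = FALSE]
    dimnames(out) <- NULL
    out
}

.ssq <- function(m) sum(m * m)

# effect matrix of one term under the cell-mean scheme; `term` is a single
# factor name or a character pair (two-way interaction)
.effectMatrixFor <- function(Xc, design, term) {
    if (length(term) == 1L)
        return(.levelMeans(Xc, design[[term]]))
    f <- design[[term[1]]]
    g <- design[[term[2]]]
    cell <- interaction(f, g, drop = TRUE)
    .levelMeans(Xc, cell) - .levelMeans(Xc, f) - .levelMeans(Xc, g)
}

.termLabel <- function(term) paste(term, collapse = ":")

#' ASCA decomposition of a design-annotated spectra set
#'
#' Mean-centers the reflectance matrix (the package-wide default
#' preprocessing for analysis), assigns each factor its level means as an
#' effect matrix, each requested two-way interaction its cell means minus
#' the two main effects, and what remains to the residual matrix. Effect
#' importance is reported as the percentage contribution of each effect's
#' sum of squares to the total; on balanced designs the effect matrices are
#' mutually orthogonal and percentages sum to 100.
#'
#' @param x a [SpectraSet-class].
#' @param factors character vector of design-factor names to decompose on.
#' @param interactions `"all"` (every two-way pair of `factors`, the
#'   default), `"none"`, or a list of character pairs.
#' @return an [AscaDecomposition-class].
#' @examples
#' cfg <- simConfig(channels = 16, samples = 1, sessions = 3,
#'                  replicates = 5)
#' s <- simulateSpectra(buildDesign(cfg), cfg)
#' d <- ascaDecompose(s, c("session", "background_timing"))
#' ascaPercentages(d)
#' @export
ascaDecompose <- function(x, factors, interactions = "all") {
    design <- designTable(x)
    miss <- setdiff(factors, names(design))
    if (length(miss))
        stop("factor(s) not in the design: ", paste(miss, collapse = ", "))
    for (f in factors) {
        lev <- unique(as.character(design[[f]]))
        if (length(lev) < 2L)
            stop("factor '", f, "' has a single level; ",
                 "a degenerate factor cannot be decomposed")
    }
    # confounding: two factors inducing the identical row partition
    if (length(factors) > 1L) {
        for (i in seq_len(length(factors) - 1L))
            for (j in seq.int(i + 1L, length(factors))) {
                tb <- table(design[[factors[i]]], design[[factors[j]]])
                if (all(rowSums(tb > 0) == 1L) && all(colSums(tb > 0) == 1L))
                    stop("factors '", factors[i], "' and '", factors[j],
                         "' are confounded (identical row partitions)")
            }
    }
    if (identical(interactions, "all")) {
        interactions <- if (length(factors) > 1L)
            utils::combn(factors, 2L, simplify = FALSE) else list()
    } else if (identical(interactions, "none")) {
        interactions <- list()
    }
    for (pair in interactions)
        if (length(pair) != 2L || !all(pair %in% factors))
            stop("interactions must be pairs of decomposed factors")

    cells <- interaction(design[factors], drop = TRUE)
    balanced <- length(unique(table(cells))) == 1L
    if (!balanced)
        warning("design is unbalanced across ",
                paste(factors, collapse = " x "),
                "; cell-mean estimators used, SS additivity is only ",
                "approximate")

    X <- spectraMatrix(x)
    grandMean <- colMeans(X)
    Xc <- sweep(X, 2L, grandMean)
    terms <- c(as.list(factors), interactions)
    effects <- lapply(terms, function(tm) .effectMatrixFor(Xc, design, tm))
    names(effects) <- vapply(terms, .termLabel, "")
    resid <- Xc - Reduce(`+`, effects)
    ss <- vapply(effects, .ssq, numeric(1))
    ssResidual <- .ssq(resid)
    ssTotal <- .ssq(Xc)
    pct <- 100 * c(ss, residuals = ssResidual) / ssTotal
    new("AscaDecomposition", grandMean = grandMean, effects = effects,
        residuals = resid, ss = ss, ssResidual = ssResidual,
        ssTotal = ssTotal, percentages = pct,
        design = design[unique(c(factors))], factors = factors,
        interactions = interactions, balanced = balanced)
}

#' Effect-percentage table of an ASCA decomposition
#'
#' @param decomp an [AscaDecomposition-class].
#' @return named numeric: percentage contribution of every effect and the
#'   residuals to the total sum of squares.
#' @export
ascaPercentages <- function(decomp) decomp@percentages

setMethod("show", "AscaDecomposition", function(object) {
    cat("AscaDecomposition:", nrow(object@residuals), "acquisitions x",
        ncol(object@residuals), "channels\n")
    cat("  factors:", paste(object@factors, collapse = ", "), "\n")
    if (length(object@interactions))
        cat("  interactions:",
            paste(vapply(object@interactions, .termLabel, ""),
                  collapse = ", "), "\n")
    pct <- object@percentages
    cat("  % of SS:",
        paste(sprintf("%s %.2f", names(pct), pct), collapse = ", "), "\n")
    if (!object@balanced)
        cat("  (unbalanced design: SS additivity approximate)\n")
})

#' Permutation significance test of one ASCA effect
#'
#' Permutes the tested factor's level labels across rows (for an
#' interaction, the two label columns are permuted jointly), recomputes the
#' effect's sum of squares under the same cell-mean scheme each time, and
#' reports `p = (#\{null SS >= observed SS\} + 1) / (nPerm + 1)`.
#'
#' @param x the [SpectraSet-class] the decomposition was computed from.
#' @param decomp the matching [AscaDecomposition-class].
#' @param effect effect name: a factor or `"f1:f2"` interaction label.
#' @param nPerm permutation count (default 2000).
#' @param seed RNG seed.
#' @return a [PermutationResult-class].
#' @export
ascaPermutationTest <- function(x, decomp, effect, nPerm = 2000,
                                seed = NULL) {
    if (!effect %in% names(decomp@effects))
        stop("effect '", effect, "' is not in the decomposition; have: ",
             paste(names(decomp@effects), collapse = ", "))
    if (nPerm < 1) stop("nPerm must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    design <- designTable(x)
    X <- spectraMatrix(x)
    Xc <- sweep(X, 2L, colMeans(X))
    term <- strsplit(effect, ":", fixed = TRUE)[[1]]
    observed <- .ssq(.effectMatrixFor(Xc, design, term))
    n <- nrow(Xc)
    nullSS <- vapply(seq_len(nPerm), function(b) {
        idx <- sample.int(n)
        pd <- design
        pd[term] <- design[term][idx, , drop = FALSE]
        .ssq(.effectMatrixFor(Xc, pd, term))
    }, numeric(1))
    pval <- (sum(nullSS >= observed) + 1) / (nPerm + 1)
    new("PermutationResult", effect = effect, observedSS = observed,
        nullSS = nullSS, nPerm = as.integer(nPerm), pValue = pval,
        scheme = paste("free permutation of the tested term's labels",
                       "across rows"))
}

setMethod("show", "PermutationResult", function(object) {
    cat(sprintf(
        "PermutationResult: effect '%s', SS = %.4g, p = %.4g (%d perms)\n",
        object@effect, object@observedSS, object@pValue, object@nPerm))
})

#' Simultaneous-component sub-model of one ASCA effect
#'
#' SVD of the effect matrix: loadings are right singular vectors, effect
#' scores the projection of the effect matrix, and residual-augmented
#' scores the projection of effect + residuals — the recommended
#' visualization, since pure effect scores collapse onto one point per
#' level.
#'
#' @param decomp an [AscaDecomposition-class].
#' @param effect effect name.
#' @param nComponents number of components; default (`NULL`) keeps the full
#'   numerical rank of the effect matrix.
#' @return an [AscaSubmodel-class].
#' @export
ascaSubmodel <- function(decomp, effect, nComponents = NULL) {
    if (!effect %in% names(decomp@effects))
        stop("effect '", effect, "' is not in the decomposition")
    M <- decomp@effects[[effect]]
    sv <- svd(M)
    rk <- sum(sv$d > max(sv$d[1], 0) * 1e-10)
    if (rk == 0L) stop("effect matrix '", effect, "' is numerically zero")
    if (is.null(nComponents)) nComponents <- rk
    if (nComponents > rk)
        stop("nComponents = ", nComponents, " exceeds the effect-matrix ",
             "rank (", rk, ")")
    c0 <- seq_len(nComponents)
    loadings <- sv$v[, c0, drop = FALSE]
    scores <- M %*% loadings
    aug <- (M + decomp@residuals) %*% loadings
    term <- strsplit(effect, ":", fixed = TRUE)[[1]]
    lv <- droplevels(interaction(decomp@design[term], drop = TRUE,
                                 sep = ":"))
    cent <- rowsum(aug, lv) / as.integer(table(lv))
    new("AscaSubmodel", effect = effect, loadings = loadings,
        scores = scores, augmentedScores = aug,
        explainedVariance = sv$d[c0]^2 / sum(sv$d^2), levels = lv,
        centroids = cent)
}

setMethod("show", "AscaSubmodel", function(object) {
    cat(sprintf(
        "AscaSubmodel: effect '%s', %d component(s), EV = %s\n",
        object@effect, ncol(object@loadings),
        paste(sprintf("%.1f%%", 100 * object@explainedVariance),
              collapse = ", ")))
})

#' Consolidated ASCA effect table with permutation p-values
#'
#' Runs [ascaPermutationTest()] for every effect in a decomposition and
#' assembles the familiar effect-percentage table with a significance
#' marker.
#'
#' @param x the [SpectraSet-class] the decomposition came from.
#' @param decomp an [AscaDecomposition-class].
#' @param nPerm permutation count.
#' @param seed RNG seed.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame with columns `effect`, `percent`, `pValue`,
#'   `significant`, plus a final `residuals` row with `NA` p-value.
#' @export
ascaEffectTable <- function(x, decomp, nPerm = 2000, seed = NULL,
                            alpha = 0.05) {
    if (!is.null(seed)) set.seed(seed)
    effs <- names(decomp@effects)
    pv <- vapply(effs, function(e)
        ascaPermutationTest(x, decomp, e, nPerm = nPerm)@pValue, numeric(1))
    data.frame(
        effect = c(effs, "residuals"),
        percent = as.numeric(decomp@percentages[c(effs, "residuals")]),
        pValue = c(pv, NA_real_),
        significant = c(pv < alpha, NA),
        row.names = NULL)
}
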
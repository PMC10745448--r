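#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData colData<-
NULL

#' SpectraSet: design-annotated replicate spectra
#'
#' The central data container of the package: a reflectance matrix over a
#' wavelength grid, paired row-for-row with a table of categorical design
#' factors (sample, session, replicate order, background timing, power
#' supply, ...). `SpectraSet` extends
#' [SummarizedExperiment::SummarizedExperiment] with wavelength channels as
#' features (rows of the assay) and acquisitions as columns; the design
#' table lives in `colData` and the wavelength grid in `rowData$wavelength`.
#'
#' Validity requires a finite `"reflectance"` assay, a strictly increasing
#' finite wavelength grid of length at least 2, and at least one
#' acquisition.
#'
#' @slot .. inherited from `SummarizedExperiment`.
#' @seealso [SpectraSet()] the constructor, [spectraMatrix()],
#'   [wavelengths()], [designTable()]
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

.validSpectraSet <- function(object) {
    msg <- character()
    if (!"reflectance" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'reflectance' is required")
    wl <- rowData(object)$wavelength
    if (is.null(wl)) {
        msg <- c(msg, "rowData must contain a 'wavelength' column (nm)")
    } else {
        if (length(wl) < 2L)
            msg <- c(msg, "wavelength grid must have length >= 2")
        if (anyNA(wl) || any(!is.finite(wl)))
            msg <- c(msg, "wavelengths must be finite")
        else if (any(diff(wl) <= 0))
            msg <- c(msg, "wavelengths must be strictly increasing")
    }
    if (ncol(object) < 1L)
        msg <- c(msg, "at least one acquisition (column) is required")
    if (length(msg) == 0L) {
        m <- assay(object, "reflectance")
        if (anyNA(m) || any(!is.finite(m)))
            msg <- c(msg, "reflectance matrix must be finite")
    }
    if (length(msg)) msg else TRUE
}
setValidity("SpectraSet", .validSpectraSet)

#' Construct a SpectraSet
#'
#' @param spectra numeric matrix of reflectance values, one row per
#'   acquisition and one column per wavelength channel (the conventional
#'   chemometrics orientation; it is transposed internally to the
#'   features-by-samples layout of `SummarizedExperiment`).
#' @param wavelengths numeric vector of channel centers in nm, strictly
#'   increasing, length `ncol(spectra)`.
#' @param design data.frame of categorical design factors, one row per
#'   acquisition. Character columns are converted to factors.
#' @return a [SpectraSet-class] object.
#' @examples
#' s <- SpectraSet(matrix(rnorm(6), 2, 3), c(1000, 1100, 1200),
#'                 data.frame(sample = c("a", "b")))
#' dim(spectraMatrix(s))
#' @export
SpectraSet <- function(spectra, wavelengths, design) {
    spectra <- as.matrix(spectra)
    storage.mode(spectra) <- "double"
    if (length(wavelengths) != ncol(spectra))
        stop("length(wavelengths) [", length(wavelengths),
             "] must equal ncol(spectra) [", ncol(spectra), "]")
    design <- as.data.frame(design, stringsAsFactors = FALSE)
    if (nrow(design) != nrow(spectra))
        stop("design table has ", nrow(design),
             " rows but spectra matrix has ", nrow(spectra),
             " rows; they must align one-to-one")
    design[] <- lapply(design, function(col)
        if (is.character(col) || is.logical(col)) factor(col) else col)
    a <- t(spectra)
    dimnames(a) <- list(NULL, NULL)
    se <- SummarizedExperiment(
        assays = SimpleList(reflectance = a),
        rowData = DataFrame(wavelength = as.numeric(wavelengths)),
        colData = DataFrame(design, check.names = FALSE))
    new("SpectraSet", se)
}

#' AscaDecomposition: ANOVA-simultaneous component analysis of a spectra set
#'
#' Result of [ascaDecompose()]: the grand-mean spectrum, one n-by-p effect
#' matrix per design factor and requested two-way interaction, the residual
#' matrix, and the sum-of-squares bookkeeping (absolute and as percentage of
#' the total).
#'
#' @slot grandMean numeric, length p.
#' @slot effects named list of n-by-p effect matrices.
#' @slot residuals n-by-p residual matrix.
#' @slot ss named numeric, per-effect sum of squares.
#' @slot ssResidual,ssTotal numeric scalars.
#' @slot percentages named numeric, per-effect and residual percentage
#'   contributions to `ssTotal` (sums to 100 on balanced designs).
#' @slot design data.frame of the factors used, aligned with rows.
#' @slot factors,interactions character / list bookkeeping of what was fit.
#' @slot balanced logical; `FALSE` when cell-mean estimators were used on an
#'   unbalanced design (SS additivity then only approximate).
#' @export
setClass("AscaDecomposition", representation(
    grandMean = "numeric",
    effects = "list",
    residuals = "matrix",
    ss = "numeric",
    ssResidual = "numeric",
    ssTotal = "numeric",
    percentages = "numeric",
    design = "data.frame",
    factors = "character",
    interactions = "list",
    balanced = "logical"))

#' AscaSubmodel: simultaneous-component (PCA) view of one effect matrix
#'
#' @slot effect character, the effect analysed.
#' @slot loadings p-by-c orthonormal loading matrix.
#' @slot scores n-by-c effect scores (effect matrix projected on loadings).
#' @slot augmentedScores n-by-c residual-augmented scores
#'   ((effect + residual) projected on loadings), the default visualization.
#' @slot explainedVariance numeric, per-component fraction of the effect SS.
#' @slot levels factor of length n, the level labels of the effect.
#' @slot centroids levels-by-c matrix of mean augmented scores per level.
#' @export
setClass("AscaSubmodel", representation(
    effect = "character",
    loadings = "matrix",
    scores = "matrix",
    augmentedScores = "matrix",
    explainedVariance = "numeric",
    levels = "factor",
    centroids = "matrix"))

#' PermutationResult: permutation significance test of one ASCA effect
#'
#' @slot effect character.
#' @slot observedSS numeric, SS of the effect on the observed labels.
#' @slot nullSS numeric vector of permuted-label SS values.
#' @slot nPerm integer.
#' @slot pValue numeric, `(#\{null >= observed\} + 1) / (nPerm + 1)`.
#' @slot scheme character, description of the permutation scheme used.
#' @export
setClass("PermutationResult", representation(
    effect = "character",
    observedSS = "numeric",
    nullSS = "numeric",
    nPerm = "integer",
    pValue = "numeric",
    scheme = "character"))

#' ErrorMatrix: replicate-mean-subtracted residual spectra
#'
#' Result of [errorMatrix()]: each row is the difference between an acquired
#' spectrum and the mean of its replicate group, so between-group effects
#' (sample, session, background timing) do not inflate the error estimate.
#'
#' @slot E n-by-p residual matrix (columns labelled by wavelength).
#' @slot grouping character, the factor names defining replicate groups.
#' @slot groups factor of length n, the group of each row.
#' @slot groupSizes integer table of rows per group.
#' @slot rankBound integer, `n - g` with `g` the number of groups: an upper
#'   bound on the rank of `E` (each group loses one dimension to its mean).
#' @slot wavelengths numeric, length p.
#' @export
setClass("ErrorMatrix", representation(
    E = "matrix",
    grouping = "character",
    groups = "factor",
    groupSizes = "integer",
    rankBound = "integer",
    wavelengths = "numeric"))

#' ErrorSurfaces: pooled error covariance and correlation matrices
#'
#' @slot sigmaCov p-by-p pooled error variance-covariance matrix
#'   (reflectance^2 units), `t(E) %*% E / (n - g)`.
#' @slot sigmaCor p-by-p error correlation matrix, or a 0-by-0 matrix before
#'   [correlationMatrix()] is applied.
#' @slot dof integer, pooled degrees of freedom `n - g`.
#' @slot excluded integer indices of channels excluded from `sigmaCor` for
#'   near-zero variance.
#' @slot wavelengths numeric, length p.
#' @export
setClass("ErrorSurfaces", representation(
    sigmaCov = "matrix",
    sigmaCor = "matrix",
    dof = "integer",
    excluded = "integer",
    wavelengths = "numeric"))

#' KIndexResult: eigenvalue-based redundancy of an error-correlation matrix
#'
#' @slot eigenvalues numeric, descending eigenvalues of the correlation
#'   matrix (negative numerical eigenvalues clipped at 0).
#' @slot explainedVariance numeric, eigenvalues normalised to sum 1.
#' @slot k numeric in \[0, 1\]: 0 when all variables are uncorrelated, 1
#'   when perfectly correlated.
#' @slot p integer, number of variables.
#' @slot kMin numeric, the imbedded minimum `(p - r)/(p - 1)` for the stated
#'   rank `r` (NA when no rank was supplied).
#' @slot rank integer, the rank used for `kMin` (NA when not supplied).
#' @slot distance numeric, `k - kMin` (NA when no rank was supplied).
#' @export
setClass("KIndexResult", representation(
    eigenvalues = "numeric",
    explainedVariance = "numeric",
    k = "numeric",
    p = "integer",
    kMin = "numeric",
    rank = "integer",
    distance = "numeric"))

#' HistogramSummary: image histogram of a correlation matrix
#'
#' Correlations are mapped to gray levels `g = (rho + 1)/2` and binned over
#' \[0, 1\]; an ideal unstructured error gives a symmetric distribution
#' centred at 0.5 (plus the unit-diagonal spike at 1 when the diagonal is
#' included).
#'
#' @slot breaks numeric, `nBins + 1` bin edges covering \[0, 1\].
#' @slot counts integer per bin; sums to the pixel count.
#' @slot totalPixels integer, `p^2` (or `p^2 - p` without the diagonal).
#' @slot mode numeric, midpoint of the fullest bin.
#' @slot skewness numeric, sample skewness of the gray values.
#' @slot tailMass named numeric, fraction of pixels beyond the configured
#'   gray thresholds.
#' @slot includeDiagonal logical.
#' @export
setClass("HistogramSummary", representation(
    breaks = "numeric",
    counts = "integer",
    totalPixels = "integer",
    mode = "numeric",
    skewness = "numeric",
    tailMass = "numeric",
    includeDiagonal = "logical"))
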
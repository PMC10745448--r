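#' Per-channel replicate statistics
#'
#' For each replicate group (rows sharing the levels of `groupBy`) computes
#' the per-channel mean spectrum, sample standard deviation (n - 1
#' denominator), relative standard deviation `RSD = 100 * sd / mean` (%) and
#' signal-to-noise ratio `S/N = mean / sd`. Channels where a ratio is
#' undefined (zero sd or zero mean) are flagged rather than reported as
#' infinities.
#'
#' @param x a [SpectraSet-class].
#' @param groupBy character vector of design-factor names defining the
#'   replicate groups; the default, `character()`, treats all acquisitions
#'   as one group.
#' @return a data.frame with one row per group x channel and columns
#'   `group`, `wavelength`, `mean`, `sd`, `rsd`, `snr`, `undefined`. `rsd`
#'   and `snr` are `NA` where `undefined` is `TRUE`.
#' @examples
#' s <- SpectraSet(rbind(c(1, 1), c(3, 3)), c(1000, 1100),
#'                 data.frame(sample = c("a", "a")))
#' replicateStats(s)
#' @export
replicateStats <- function(x, groupBy = character()) {
    dt <- designTable(x)
    bad <- setdiff(groupBy, names(dt))
    if (length(bad))
        stop("unknown design factor(s): ", paste(bad, collapse = ", "))
    m <- spectraMatrix(x)
    g <- if (length(groupBy))
        interaction(dt[groupBy], drop = TRUE, sep = ":")
    else
        factor(rep("all", nrow(m)))
    sizes <- table(g)
    if (any(sizes < 2L))
        stop("replicate group(s) with fewer than 2 acquisitions: ",
             paste(names(sizes)[sizes < 2L], collapse = ", "))
    wl <- wavelengths(x)
    out <- lapply(levels(g), function(lev) {
        sub <- m[g == lev, , drop = FALSE]
        mu <- colMeans(sub)
        sd <- apply(sub, 2L, stats::sd)
        undef <- sd == 0 | mu == 0
        data.frame(group = lev, wavelength = wl, mean = mu, sd = sd,
                   rsd = ifelse(undef, NA_real_, 100 * sd / mu),
                   snr = ifelse(undef, NA_real_, mu / sd),
                   undefined = undef, row.names = NULL)
    })
    do.call(rbind, out)
}
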
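# small in-code fixtures shared across test files

# SpectraSet from a plain matrix, with an evenly spaced grid and a
# one-factor design unless given
makeSet <- function(m, design = NULL, wl = NULL) {
    m <- as.matrix(m)
    if (is.null(wl)) wl <- seq(1000, 1000 + 10 * (ncol(m) - 1), by = 10)
    if (is.null(design)) design <- data.frame(id = paste0("r", seq_len(nrow(m))))
    SpectraSet(m, wl, design)
}

# balanced two-factor replicate design (f1 x f2 x reps rows)
makeTwoFactorSet <- function(nl1 = 2, nl2 = 3, reps = 1, p = 4,
                             noise = 1, seed = 1) {
    set.seed(seed)
    design <- expand.grid(rep = seq_len(reps),
                          f1 = paste0("a", seq_len(nl1)),
                          f2 = paste0("b", seq_len(nl2)),
                          stringsAsFactors = FALSE)[c("f1", "f2", "rep")]
    n <- nrow(design)
    makeSet(matrix(rnorm(n * p, sd = noise), n, p),
            design = data.frame(f1 = design$f1, f2 = design$f2))
}

# independent elementwise ANOVA decomposition oracle: loops over level
# means, no matrix shortcuts shared with the implementation
oracleAnova <- function(X, f1, f2, interaction = TRUE) {
    grand <- colMeans(X)
    Xc <- sweep(X, 2, grand)
    eff <- function(g) {
        out <- matrix(0, nrow(X), ncol(X))
        for (lev in unique(g))
            out[g == lev, ] <- matrix(colMeans(Xc[g == lev, , drop = FALSE]),
                                      sum(g == lev), ncol(X), byrow = TRUE)
        out
    }
    A <- eff(f1); B <- eff(f2)
    res <- list(A = A, B = B)
    if (interaction) {
        cells <- paste(f1, f2)
        AB <- matrix(0, nrow(X), ncol(X))
        for (cl in unique(cells)) {
            idx <- cells == cl
            AB[idx, ] <- matrix(colMeans(Xc[idx, , drop = FALSE]),
                                sum(idx), ncol(X), byrow = TRUE)
        }
        res$AB <- AB - A - B
    }
    res$E <- Xc - Reduce(`+`, res[names(res) != "E"])
    res$ss <- vapply(res[setdiff(names(res), "ss")],
                     function(m) sum(m^2), numeric(1))
    res$ssTotal <- sum(Xc^2)
    res
}

# fast noiseless-effects config for simulator tests
quietConfig <- function(...) {
    defaults <- list(sessionOffsetScale = 0, backgroundDriftSlope = 0,
                     powerSupplyOffset = 0, scatterLogSd = 0,
                     additiveOffsetSd = 0, noiseSd = 0)
    do.call(simConfig, utils::modifyList(defaults, list(...)))
}
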
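test_that("error matrix subtracts replicate-group means", {
    # identical replicates -> all-zero error matrix
    m <- rbind(c(1, 2), c(1, 2), c(3, 4), c(3, 4))
    s <- makeSet(m, design = data.frame(sample = c("a", "a", "b", "b")))
    e <- errorMatrix(s, "sample")
    expect_equal(unname(e@E), matrix(0, 4, 2))
    # 45 rows in 3 sessions of 15 -> rank bound 42
    cfg <- simConfig(channels = 10, samples = 1, sessions = 3,
                     replicates = 15, backgroundTimings = "per-sample",
                     seed = 2)
    s2 <- simulateSpectra(buildDesign(cfg), cfg)
    e2 <- errorMatrix(s2, c("sample", "session"))
    expect_equal(e2@rankBound, 42L)
    # within-group column sums vanish
    for (lev in levels(e2@groups))
        expect_lte(max(abs(colSums(e2@E[e2@groups == lev, , drop = FALSE]))),
                   1e-10)
    # singleton cells are refused, naming the cell
    bad <- makeSet(matrix(rnorm(6), 3),
                   design = data.frame(sample = c("a", "a", "b")))
    expect_error(errorMatrix(bad, "sample"), "b")
})

test_that("pooled covariance reduces to the sample covariance for one group", {
    set.seed(4)
    m <- matrix(rnorm(30), 10, 3)
    s <- makeSet(m, design = data.frame(sample = rep("a", 10)))
    S <- pooledCovariance(errorMatrix(s, "sample"))@sigmaCov
    expect_equal(S, cov(m), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("two equal-size groups pool to the average of per-group covariances", {
    set.seed(5)
    m <- matrix(rnorm(6 * 3), 6, 3)
    g <- rep(c("a", "b"), each = 3)
    s <- makeSet(m, design = data.frame(session = g))
    surf <- pooledCovariance(errorMatrix(s, "session"))
    oracle <- (cov(m[g == "a", ]) + cov(m[g == "b", ])) / 2
    expect_equal(surf@sigmaCov, oracle, ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_equal(surf@dof, 4L)
})

test_that("pooling removes group-constant offsets", {
    set.seed(6)
    m <- matrix(rnorm(8 * 4), 8, 4)
    g <- rep(c("a", "b"), each = 4)
    s1 <- makeSet(m, design = data.frame(session = g))
    m2 <- m; m2[g == "b", ] <- sweep(m2[g == "b", ], 2, c(5, -3, 2, 100), "+")
    s2 <- makeSet(m2, design = data.frame(session = g))
    expect_equal(pooledCovariance(errorMatrix(s1, "session"))@sigmaCov,
                 pooledCovariance(errorMatrix(s2, "session"))@sigmaCov,
                 tolerance = 1e-12)
})

test_that("covariance rank respects the n - g bound", {
    set.seed(7)
    # 9 rows, 3 groups -> rank <= 6 although p = 12
    m <- matrix(rnorm(9 * 12), 9, 12)
    s <- makeSet(m, design = data.frame(session = rep(c("a", "b", "c"), 3)))
    e <- errorMatrix(s, "session")
    expect_equal(e@rankBound, 6L)
    ev <- eigen(pooledCovariance(e)@sigmaCov, symmetric = TRUE,
                only.values = TRUE)$values
    expect_lte(max(ev[-(1:6)]) / ev[1], 1e-8)
})

test_that("correlation surface is unit-diagonal and matches a direct oracle", {
    set.seed(8)
    m <- matrix(rnorm(5 * 3), 5, 3)
    s <- makeSet(m, design = data.frame(sample = rep("a", 5)))
    surf <- correlationMatrix(pooledCovariance(errorMatrix(s, "sample")))
    C <- surf@sigmaCor
    expect_equal(unname(diag(C)), rep(1, 3))
    expect_true(all(C >= -1 & C <= 1))
    # brute-force two-channel correlation oracle
    for (i in 1:3) for (j in 1:3)
        expect_equal(C[i, j], cor(m[, i], m[, j]), tolerance = 1e-12)
    # diagonal covariance -> identity correlation
    d <- new("ErrorSurfaces", sigmaCov = diag(c(1, 2, 3)),
             sigmaCor = matrix(numeric(0), 0, 0), dof = 5L,
             excluded = integer(0), wavelengths = c(1000, 1100, 1200))
    expect_equal(correlationMatrix(d)@sigmaCor, diag(3),
                 ignore_attr = TRUE)
})

test_that("near-zero-variance channels are excluded and listed", {
    set.seed(9)
    m <- matrix(rnorm(20 * 4), 20, 4)
    m[, 3] <- 7                       # constant channel: zero error variance
    s <- makeSet(m, design = data.frame(sample = rep("a", 20)))
    surf <- correlationMatrix(pooledCovariance(errorMatrix(s, "sample")))
    expect_equal(surf@excluded, 3L)
    expect_equal(dim(surf@sigmaCor), c(3, 3))
    zero <- new("ErrorSurfaces", sigmaCov = matrix(0, 2, 2),
                sigmaCor = matrix(numeric(0), 0, 0), dof = 1L,
                excluded = integer(0), wavelengths = c(1, 2))
    expect_error(correlationMatrix(zero), "zero")
})

test_that("SNV reduces the pooled error variance under multiplicative scatter", {
    cfg <- simConfig(channels = 30, samples = 1, sessions = 3,
                     replicates = 15, backgroundTimings = "per-sample",
                     scatterLogSd = 0.05, seed = 12)
    s <- simulateSpectra(buildDesign(cfg), cfg)
    trRaw <- sum(diag(pooledCovariance(errorMatrix(s))@sigmaCov))
    ssnv <- snv(s)
    trSnv <- sum(diag(pooledCovariance(errorMatrix(ssnv))@sigmaCov))
    # compare on a common scale: relative to the total signal variance
    relRaw <- trRaw / sum(apply(spectraMatrix(s), 2, var))
    relSnv <- trSnv / sum(apply(spectraMatrix(ssnv), 2, var))
    expect_lt(relSnv, relRaw)
})

test_that("the variance profile pairs wavelengths with diagonal variances", {
    set.seed(10)
    s <- makeSet(matrix(rnorm(30), 10, 3),
                 design = data.frame(sample = rep("a", 10)))
    surf <- pooledCovariance(errorMatrix(s, "sample"))
    vp <- varianceProfile(surf)
    expect_equal(vp$variance, unname(diag(surf@sigmaCov)))
    expect_equal(vp$wavelength, wavelengths(s))
})
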
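test_that("noiseless level-mean data put 100% of the SS on the factor", {
    design <- data.frame(g = rep(c("lo", "hi"), each = 3))
    m <- rbind(matrix(1, 3, 4), matrix(5, 3, 4))
    dec <- ascaDecompose(makeSet(m, design = design), "g")
    expect_equal(dec@ssResidual, 0)
    expect_equal(unname(dec@percentages[["g"]]), 100)
})

test_that("decomposition agrees with the elementwise ANOVA oracle", {
    for (seed in 1:5) {
        s <- makeTwoFactorSet(2, 3, reps = 2, p = 4, seed = seed)
        X <- spectraMatrix(s)
        d <- designTable(s)
        dec <- ascaDecompose(s, c("f1", "f2"))
        orc <- oracleAnova(X, as.character(d$f1), as.character(d$f2))
        expect_equal(unname(dec@effects[["f1"]]), unname(orc$A),
                     tolerance = 1e-12)
        expect_equal(unname(dec@effects[["f2"]]), unname(orc$B),
                     tolerance = 1e-12)
        expect_equal(unname(dec@effects[["f1:f2"]]), unname(orc$AB),
                     tolerance = 1e-12)
        expect_equal(unname(dec@residuals), unname(orc$E),
                     tolerance = 1e-12)
        # SS additivity and percentage closure
        expect_lte(abs(sum(dec@ss) + dec@ssResidual - dec@ssTotal),
                   1e-8 * dec@ssTotal)
        expect_equal(sum(dec@percentages), 100, tolerance = 1e-6)
    }
})

test_that("effect matrices have zero column means and are mutually orthogonal", {
    s <- makeTwoFactorSet(3, 4, reps = 2, p = 5, seed = 11)
    dec <- ascaDecompose(s, c("f1", "f2"))
    for (eff in dec@effects)
        expect_lte(max(abs(colMeans(eff))), 1e-10)
    cross <- sum(dec@effects[["f1"]] * dec@effects[["f2"]])
    expect_lte(abs(cross), 1e-8 * dec@ssTotal)
})

test_that("decomposition is invariant to row permutation", {
    s <- makeTwoFactorSet(2, 3, reps = 3, p = 4, seed = 21)
    set.seed(1); idx <- sample(ncol(s))
    sp <- s[, idx]
    dec1 <- ascaDecompose(s, c("f1", "f2"))
    dec2 <- ascaDecompose(sp, c("f1", "f2"))
    expect_equal(dec2@ss, dec1@ss, tolerance = 1e-12)
    expect_equal(dec2@ssResidual, dec1@ssResidual, tolerance = 1e-12)
})

test_that("degenerate and confounded factors are rejected", {
    s <- makeSet(matrix(rnorm(20), 5, 4),
                 design = data.frame(a = rep("x", 5),
                                     b = c("u", "u", "v", "v", "v"),
                                     c = c("p", "p", "q", "q", "q")))
    expect_error(ascaDecompose(s, "a"), "single level")
    expect_error(ascaDecompose(s, c("b", "c")), "confounded")
    expect_error(ascaDecompose(s, "nope"), "not in the design")
})

test_that("unbalanced designs proceed with a warning", {
    s <- makeTwoFactorSet(2, 2, reps = 3, p = 4, seed = 31)
    s <- s[, -1]
    expect_warning(dec <- ascaDecompose(s, c("f1", "f2")), "unbalanced")
    expect_false(dec@balanced)
})

test_that("a dominant effect reaches the smallest attainable p-value", {
    # three groups: the chance a permutation reproduces the partition
    # (which would tie the observed SS) is negligible
    design <- data.frame(g = rep(c("lo", "mid", "hi"), each = 5))
    set.seed(3)
    m <- matrix(rnorm(15 * 6, sd = 0.01), 15, 6)
    m[design$g == "mid", ] <- m[design$g == "mid", ] + 2
    m[design$g == "hi", ] <- m[design$g == "hi", ] + 5   # 50x noise scale
    s <- makeSet(m, design = design)
    dec <- ascaDecompose(s, "g")
    pt <- ascaPermutationTest(s, dec, "g", nPerm = 199, seed = 1)
    expect_equal(pt@pValue, 1 / 200)
    expect_equal(pt@nPerm, 199L)
    expect_length(pt@nullSS, 199)
    expect_error(ascaPermutationTest(s, dec, "nope", 10), "not in")
})

test_that("the permutation count defaults to 2000", {
    expect_equal(formals(ascaPermutationTest)$nPerm, 2000)
    expect_equal(formals(ascaEffectTable)$nPerm, 2000)
})

test_that("two-level submodel has the expected one-component geometry", {
    design <- data.frame(g = rep(c("lo", "hi"), each = 4))
    set.seed(5)
    m <- matrix(rnorm(8 * 5, sd = 0.1), 8, 5)
    m[design$g == "hi", ] <- m[design$g == "hi", ] + 2
    s <- makeSet(m, design = design)
    dec <- ascaDecompose(s, "g")
    sub <- ascaSubmodel(dec, "g")
    expect_equal(ncol(sub@loadings), 1)
    expect_equal(sum(sub@loadings^2), 1, tolerance = 1e-12)
    # loadings parallel to the difference of level means
    dmu <- colMeans(m[design$g == "hi", ]) - colMeans(m[design$g == "lo", ])
    cosang <- abs(sum(sub@loadings * dmu)) /
        sqrt(sum(dmu^2) * sum(sub@loadings^2))
    expect_equal(cosang, 1, tolerance = 1e-10)
    # effect scores take exactly two values of opposite sign
    sc <- round(as.numeric(sub@scores), 10)
    expect_equal(length(unique(sc)), 2)
    expect_equal(sum(unique(sc)), 0, tolerance = 1e-8)
})

test_that("augmented scores equal effect scores plus projected residuals", {
    s <- makeTwoFactorSet(2, 3, reps = 2, p = 4, seed = 41)
    dec <- ascaDecompose(s, c("f1", "f2"))
    sub <- ascaSubmodel(dec, "f2", nComponents = 2)
    expect_equal(sub@augmentedScores - sub@scores,
                 dec@residuals %*% sub@loadings, tolerance = 1e-12)
    expect_error(ascaSubmodel(dec, "f2", nComponents = 5), "rank")
    # explained variances: in [0, 1], decreasing, summing to <= 1
    ev <- sub@explainedVariance
    expect_true(all(diff(ev) <= 1e-12))
    expect_lte(sum(ev), 1 + 1e-12)
})

test_that("null-factor centroids scatter around zero", {
    set.seed(13)
    s <- makeSet(matrix(rnorm(60 * 8), 60, 8),
                 design = data.frame(g = rep(c("a", "b", "c"), each = 20)))
    dec <- ascaDecompose(s, "g")
    sub <- ascaSubmodel(dec, "g", nComponents = 1)
    # augmented-score centroids stay within a few standard errors of 0
    spread <- sd(sub@augmentedScores[, 1]) / sqrt(20)
    expect_lte(max(abs(sub@centroids[, 1])), 4 * spread)
})

test_that("the consolidated effect table marks significance at 0.05", {
    design <- data.frame(g = rep(c("lo", "hi"), each = 5))
    set.seed(9)
    m <- matrix(rnorm(10 * 6, sd = 0.01), 10, 6)
    m[design$g == "hi", ] <- m[design$g == "hi", ] + 1
    s <- makeSet(m, design = design)
    dec <- ascaDecompose(s, "g")
    tab <- ascaEffectTable(s, dec, nPerm = 99, seed = 2)
    expect_equal(tab$effect, c("g", "residuals"))
    expect_true(tab$significant[1])
    expect_true(is.na(tab$pValue[2]))
    expect_equal(sum(tab$percent), 100, tolerance = 1e-6)
})
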
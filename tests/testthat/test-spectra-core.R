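test_that("CSV write-then-read round-trips matrix, grid and design exactly", {
    m <- matrix(c(0.11, 0.22, 1/3, 0.44, 0.55, sqrt(2)), 2, 3)
    s <- makeSet(m, design = data.frame(sample = c("s1", "s2"),
                                        session = c("1", "1")))
    sp <- tempfile(fileext = ".csv"); dp <- tempfile(fileext = ".csv")
    writeSpectraCSV(s, sp, dp)
    s2 <- readSpectraCSV(sp, dp)
    expect_identical(unname(spectraMatrix(s2)), unname(spectraMatrix(s)))
    expect_identical(wavelengths(s2), wavelengths(s))
    expect_equal(designTable(s2), designTable(s))
})

test_that("a 236-column wavelength header parses into a 236-channel grid", {
    wl <- seq(972, 1701, length.out = 236)
    s <- makeSet(matrix(runif(3 * 236), 3), wl = wl,
                 design = data.frame(sample = rep("s1", 3)))
    sp <- tempfile(); dp <- tempfile()
    writeSpectraCSV(s, sp, dp)
    expect_length(wavelengths(readSpectraCSV(sp, dp)), 236)
})

test_that("misaligned or malformed CSV input is rejected with a located error", {
    s <- makeSet(matrix(1:12 / 7, 4, 3))
    sp <- tempfile(); dp <- tempfile()
    writeSpectraCSV(s, sp, dp)
    d5 <- rbind(read.csv(dp, colClasses = "character"),
                data.frame(id = "extra"))
    dp5 <- tempfile(); write.csv(d5, dp5, row.names = FALSE)
    expect_error(readSpectraCSV(sp, dp5), "5.*4|4.*5")

    bad <- readLines(sp)
    bad[3] <- sub(",[^,]*$", ",not_a_number", bad[3])
    spb <- tempfile(); writeLines(bad, spb)
    expect_error(readSpectraCSV(spb, dp), "row|column")

    nonmono <- readLines(sp)
    nonmono[1] <- "1000,990,1010"
    spn <- tempfile(); writeLines(nonmono, spn)
    expect_error(readSpectraCSV(spn, dp), "increasing")
})

test_that("constructor enforces grid and design invariants", {
    expect_error(SpectraSet(matrix(1:4, 2), c(1100, 1000),
                            data.frame(a = c("x", "y"))), "increasing")
    expect_error(SpectraSet(matrix(1:4, 2), c(1000, 1100),
                            data.frame(a = "x")), "rows")
    expect_error(SpectraSet(matrix(c(1, NA, 3, 4), 2), c(1000, 1100),
                            data.frame(a = c("x", "y"))), "finite")
})

test_that("subsetting selects matching rows and partitions the set", {
    cfg <- quietConfig(channels = 8, samples = 1, sessions = 3,
                       replicates = 15, backgroundTimings = "per-sample")
    s <- simulateSpectra(buildDesign(cfg), cfg)
    expect_equal(dim(subsetSpectra(s)), dim(s))
    one <- subsetSpectra(s, session = "1")
    expect_equal(ncol(one), 15)
    rest <- subsetSpectra(s, session = c("2", "3"))
    expect_equal(ncol(one) + ncol(rest), ncol(s))
    expect_error(subsetSpectra(s, session = "99"), "level")
    expect_error(subsetSpectra(s, no_such_factor = "1"), "factor")
})

test_that("replicate statistics match hand computation and flag degenerate channels", {
    s <- makeSet(rbind(c(1, 5, 0), c(3, 5, 0)),
                 design = data.frame(sample = c("a", "a")))
    st <- replicateStats(s)
    expect_equal(st$mean[1], 2)
    expect_equal(st$sd[1], sqrt(2))            # n - 1 denominator
    expect_equal(st$rsd[1], 100 * sqrt(2) / 2)
    expect_equal(st$snr[1], sqrt(2))
    # identical replicates: sd = 0 -> flagged, not infinite
    expect_true(st$undefined[2])
    expect_true(is.na(st$rsd[2]) && is.na(st$snr[2]))
    # zero mean channel
    expect_true(st$undefined[3])
})

test_that("replicate statistics are grouped, complete, and scale invariant", {
    cfg <- quietConfig(channels = 11, samples = 2, sessions = 3,
                       replicates = 15, backgroundTimings = "per-sample",
                       noiseSd = 0.01)
    s <- simulateSpectra(buildDesign(cfg), cfg)
    st <- replicateStats(s, groupBy = "sample")
    expect_equal(nrow(st), 2 * 11)
    expect_setequal(unique(st$group), c("sample1", "sample2"))
    # scaling the data by c > 0 scales mean/sd, leaves RSD and S/N fixed
    s3 <- SpectraSet(3 * spectraMatrix(s), wavelengths(s), designTable(s))
    st3 <- replicateStats(s3, groupBy = "sample")
    expect_equal(st3$mean, 3 * st$mean)
    expect_equal(st3$sd, 3 * st$sd)
    expect_equal(st3$rsd, st$rsd)
    expect_equal(st3$snr, st$snr)
    # singleton groups are refused
    tiny <- makeSet(matrix(1:4 / 3, 2), design = data.frame(g = c("a", "b")))
    expect_error(replicateStats(tiny, "g"), "fewer than 2")
})

test_that("PCA screening flags a planted gross outlier", {
    set.seed(42)
    n <- 60; p <- 12
    base <- sin(seq(0, 3, length.out = p))
    m <- matrix(rep(base, each = n), n, p) + matrix(rnorm(n * p, sd = 0.01), n, p)
    m[17, ] <- m[17, ] + 1                     # 100x the noise sd
    s <- makeSet(m, design = data.frame(sample = rep("a", n)))
    # oracle: the planted row is the farthest from the mean spectrum
    d2 <- rowSums(sweep(m, 2, colMeans(m))^2)
    expect_equal(which.max(d2), 17L)
    flags <- flagGrossOutliers(s, alpha = 0.01)
    expect_true(flags[17])
    expect_error(flagGrossOutliers(makeSet(matrix(rnorm(9), 3)),
                                   nComponents = 3), "nComponents")
})

test_that("null-data flag rate stays near the nominal level", {
    set.seed(7)
    n <- 500; p <- 6
    s <- makeSet(matrix(rnorm(n * p), n, p),
                 design = data.frame(sample = rep("a", n)))
    flags <- flagGrossOutliers(s, nComponents = 2, alpha = 0.001)
    # two limits at alpha each; allow Monte-Carlo slack around <= 2*alpha
    expect_lte(mean(flags), 0.008)
    flags2 <- flagGrossOutliers(s, nComponents = 2, alpha = 0.01)
    expect_lte(mean(flags2), 0.04)
})

test_that("dropOutliers removes exactly the flagged acquisitions", {
    s <- makeSet(matrix(rnorm(40), 10, 4))
    fl <- rep(FALSE, 10); fl[c(2, 9)] <- TRUE
    expect_equal(ncol(dropOutliers(s, fl)), 8)
    expect_identical(dropOutliers(s, rep(FALSE, 10)), s)
    expect_error(dropOutliers(s, TRUE), "length")
})
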
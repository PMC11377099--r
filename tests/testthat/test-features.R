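test_that("equilibration trimming keeps exactly the windowed frames", {
    r <- makeRecord(L = 5L, n = 1000L,
                    times = seq(0, by = 0.1, length.out = 1000L))
    r10 <- trimEquilibration(r, windowSpec(10))
    expect_equal(length(seriesTimes(trajectorySeries(r10, "twist"))), 900L)
    ## identity window
    r0 <- trimEquilibration(r, windowSpec(0))
    expect_equal(r0, r)
    ## 101 frames at 1 ns spacing, start 10 -> 91 frames (10..100 ns)
    r2 <- makeRecord(L = 5L, n = 101L, times = 0:100)
    r2t <- trimEquilibration(r2, windowSpec(10))
    tt <- seriesTimes(trajectorySeries(r2t, "rise"))
    expect_equal(length(tt), 91L)
    expect_equal(range(tt), c(10, 100))
    expect_error(trimEquilibration(r2, windowSpec(1000)),
                 "excludes all frames")
})

test_that("terminus trimming keeps interior levels with original labels", {
    r <- makeRecord(L = 25L, n = 10L)
    rt <- trimTermini(r, 2L)
    expect_equal(seriesLevels(trajectorySeries(rt, "shear")), 3:23)
    r5 <- trimTermini(makeRecord(L = 5L, n = 10L), 2L)
    expect_equal(seriesLevels(trajectorySeries(r5, "shear")), 3L)
    expect_error(trimTermini(makeRecord(L = 4L, n = 10L), 2L), "trim")
    ## n_trim = 0 is the identity
    expect_equal(trimTermini(r, 0L), r)
})

test_that("level-count law 17*(L-4) holds across duplex lengths", {
    for (L in seq(5L, 40L, by = 5L)) {
        r <- trimTermini(makeRecord(L = L, n = 5L), 2L)
        v <- aggregateRecord(r)
        expect_length(v, 17L * (L - 4L))
    }
})

test_that("aggregation matches a direct two-pass oracle", {
    r <- makeRecord(L = 6L, n = 40L, noise_sd = 2, seed = 9L)
    for (agg in c("mean", "sd")) {
        v <- aggregateRecord(r, agg)
        ## brute-force oracle on a few named cells
        for (p in c("twist", "shear", "axisbend")) {
            vals <- seriesValues(trajectorySeries(r, p))
            for (lv in c(1L, 4L)) {
                col <- vals[, lv]
                expected <- if (agg == "mean") sum(col) / length(col) else {
                    mu <- sum(col) / length(col)
                    sqrt(sum((col - mu)^2) / (length(col) - 1L))
                }
                expect_equal(unname(v[paste0(lv, "—", p)]), expected,
                             tolerance = 1e-10)
            }
        }
    }
    ## constant series: mean = c, sd = 0
    const <- makeRecord(L = 3L, n = 12L,
                        override = list(twist = matrix(34, 12L, 3L)))
    expect_equal(unname(aggregateRecord(const, "mean")["2—twist"]), 34)
    expect_equal(unname(aggregateRecord(const, "sd")["2—twist"]), 0)
})

test_that("masked frames are excluded and empty cells are errors", {
    vals <- matrix(1, 10L, 3L); vals[1:5, 2L] <- 99
    defined <- matrix(TRUE, 10L, 3L); defined[1:5, 2L] <- FALSE
    r <- makeRecord(L = 3L, n = 10L,
                    override = list(rise = vals))
    r@series[["rise"]]@defined <- defined
    v <- aggregateRecord(r)
    expect_equal(unname(v["2—rise"]), 1)
    defined[, 2L] <- FALSE
    r@series[["rise"]]@defined <- defined
    expect_error(aggregateRecord(r), "rise at base 2")
})

test_that("a 25-mer record yields the 357-feature vector", {
    r <- trimTermini(makeRecord(L = 25L, n = 5L), 2L)
    v <- aggregateRecord(r)
    expect_length(v, 357L)
    expect_equal(names(v)[1L], "3—shear")
    expect_equal(names(v)[357L], "23—axisbend")
})

test_that("feature names parse with both separators", {
    info <- parseFeatureName(c("14—propeller", "10-tip"))
    expect_equal(info$base, c(14L, 10L))
    expect_equal(info$nature, c("rotational", "rotational"))
    expect_error(parseFeatureName("propeller14"), "unparseable")
})

test_that("buildFeatureMatrix lays out rows, columns and labels correctly", {
    cfg <- syntheticConfig(n_hotspot_sites = 1L, n_nonhotspot_sites = 1L,
                           replicates = 1L, n_frames = 30L)
    b <- generateBundle(cfg, seed = 2L)
    x <- buildFeatureMatrix(b)
    expect_s4_class(x, "HelicalFeatureSet")
    expect_equal(dim(x), c(357L, 4L))
    cd <- SummarizedExperiment::colData(x)
    expect_equal(cd$class4,
                 paste0(ifelse(cd$hotspot, "hotspot", "nonhotspot"),
                        ifelse(cd$adducted, "_adduct", "_control")))
    ## determinism: two builds are bit-identical
    x2 <- buildFeatureMatrix(b)
    expect_identical(featureMatrix(x), featureMatrix(x2))
})

test_that("shifting one series by c shifts only its mean features by c", {
    r <- makeRecord(L = 8L, n = 20L, seed = 4L)
    b1 <- TrajectoryBundle(list(r))
    r2 <- r
    r2@series[["roll"]]@values <- r2@series[["roll"]]@values + 5
    b2 <- TrajectoryBundle(list(r2))
    f1 <- featureMatrix(buildFeatureMatrix(b1, window = windowSpec(0)))
    f2 <- featureMatrix(buildFeatureMatrix(b2, window = windowSpec(0)))
    rollCols <- grepl("roll", colnames(f1))
    expect_equal(f2[, rollCols], f1[, rollCols] + 5)
    expect_equal(f2[, !rollCols], f1[, !rollCols])
})

test_that("mixed level counts across records are rejected", {
    b <- TrajectoryBundle(list(makeRecord(L = 25L, n = 5L),
                               makeRecord(L = 21L, n = 5L, seed = 2L,
                                          meta = SampleMeta(
                                              gene = "TP53", site = "s2",
                                              sequence = seq25(),
                                              adducted = TRUE,
                                              hotspot = FALSE,
                                              replicate = 1L))))
    expect_error(buildFeatureMatrix(b), "mixed")
})
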
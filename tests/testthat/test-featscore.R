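test_that("the adducted subset keeps only adducted rows with binary labels", {
    x <- makeSeparableSet(n_per_class = 6L, p = 8L)   # 24 samples
    xa <- subsetAdductedBinary(x)
    expect_equal(ncol(xa), 12L)
    expect_true(all(isAdducted(xa)))
    expect_setequal(unique(ifelse(isHotspot(xa), "hotspot", "nonhotspot")),
                    c("hotspot", "nonhotspot"))
    ## all-control input is an error
    xc <- x[, !isAdducted(x)]
    expect_error(subsetAdductedBinary(xc), "no adducted")
    ## single hotspot class after subsetting is an error
    xh <- x[, isHotspot(x) | !isAdducted(x)]
    expect_error(subsetAdductedBinary(xh), "single hotspot class")
})

test_that("cross-validated RF importance recovers a planted feature", {
    x <- makeBinarySet(n_per_class = 15L, p = 20L, signal_cols = 1L,
                       effect = 5, seed = 2L)
    r <- rankRFImportanceCV(x, folds = 5L, seed = 1L)
    expect_equal(r$features[1L], colnames(featureMatrix(x))[1L])
    expect_equal(r$method, "rf_importance_cv")
    ## a constant feature gets zero importance
    X <- featureMatrix(x)
    X[, 5L] <- 1
    x2 <- makeFeatureSet(X, isHotspot(x), isAdducted(x))
    r2 <- rankRFImportanceCV(x2, folds = 5L, seed = 1L)
    expect_equal(unname(r2$values[colnames(X)[5L]]), 0)
})

test_that("RFE elimination order ranks the planted feature last-eliminated", {
    x <- makeBinarySet(n_per_class = 12L, p = 10L, signal_cols = 1L,
                       effect = 5, seed = 3L)
    r <- rankRFECV(x, folds = 4L, seed = 1L, step = 1L)
    expect_equal(attr(r, "n_rounds"), 10L)
    expect_equal(r$features[1L], colnames(featureMatrix(x))[1L])
    ## duplicated informative feature: both in the top ranks
    X <- featureMatrix(x)
    X[, 2L] <- X[, 1L]
    xd <- makeFeatureSet(X, isHotspot(x), isAdducted(x))
    rd <- rankRFECV(xd, folds = 4L, seed = 1L, step = 1L)
    expect_true(all(colnames(X)[1:2] %in% head(rd$features, 4L)))
    ## CV scores recorded for every subset size
    expect_equal(attr(r, "cv_scores")$n_features, 10:1)
})

test_that("lasso ranking is standardised and scale-invariant", {
    x <- makeBinarySet(n_per_class = 15L, p = 12L, signal_cols = 2L,
                       effect = 5, seed = 4L)
    r <- rankLasso(x, seed = 1L)
    expect_equal(r$features[1L], colnames(featureMatrix(x))[2L])
    ## rescaling a noise column must not change the leader
    X <- featureMatrix(x)
    X[, 7L] <- X[, 7L] * 1000
    xs <- makeFeatureSet(X, isHotspot(x), isAdducted(x))
    rs <- rankLasso(xs, seed = 1L)
    expect_equal(rs$features[1L], r$features[1L])
    ## zero-coefficient features keep column order after nonzero ones
    nz <- sum(r$values > 0)
    expect_identical(r$features[seq.int(nz + 1L, length(r$features))],
                     setdiff(r$universe, r$features[seq_len(nz)]))
    ## all-constant input is an error
    Xc <- matrix(1, 20L, 4L)
    xc <- makeFeatureSet(Xc, rep(c(TRUE, FALSE), each = 10L),
                         rep(TRUE, 20L))
    expect_error(rankLasso(xc), "constant")
})

test_that("consolidation scores follow the top-10% rank scheme", {
    feats <- paste0(rep(3:23, each = 17L), "—",
                    rep(helicalParameters()$name, 21L))  # 357 features
    mk <- function(ord) {
        structure(list(method = "rf_importance_cv", features = feats[ord],
                       values = setNames(rev(seq_along(ord)), feats[ord]),
                       universe = feats),
                  class = "FeatureRanking")
    }
    ord <- seq_along(feats)
    cs <- consolidateScores(list(mk(ord), mk(ord), mk(ord)),
                            top_frac = 0.10)
    expect_equal(attr(cs, "top_n"), 36L)
    expect_equal(cs$total[1L], 108L)                     # 3 x 36
    expect_equal(cs$total[36L], 3L)                      # 3 x 1
    expect_equal(sum(cs$total > 0L), 36L)
    ## each method marks exactly top_n features nonzero
    expect_equal(colSums(cs[, 5:7] > 0L), rep(36L, 3L),
                 ignore_attr = TRUE)
})

test_that("consolidation matches hand arithmetic on the 5-feature case", {
    feats <- paste0(10:14, "—tip")
    mk <- function(method, top) {
        ord <- c(top, setdiff(feats, top))
        structure(list(method = method, features = ord,
                       values = setNames(rev(seq_along(ord)), ord),
                       universe = feats),
                  class = "FeatureRanking")
    }
    cs <- consolidateScores(
        list(mk("rf_importance_cv", feats[c(1L, 2L)]),
             mk("rfecv", feats[c(1L, 3L)]),
             mk("lasso", feats[c(2L, 1L)])),
        top_frac = 0.4)   # top_n = 2
    tot <- setNames(cs$total, cs$feature)
    expect_equal(unname(tot[feats[1:3]]), c(5L, 3L, 1L))
    expect_equal(unname(tot[feats[4:5]]), c(0L, 0L))
    expect_error(consolidateScores(
        list(mk("a", feats[1:2]),
             structure(list(method = "b", features = feats[-1L],
                            values = NULL, universe = feats[-1L]),
                       class = "FeatureRanking"))),
        "different feature universes")
})

test_that("consolidation totals equal brute-force recomputation", {
    feats <- paste0(rep(3:12, each = 3L), "—",
                    c("tip", "roll", "shear"))[1:30]
    for (trial in 1:50) {
        set.seed(trial)
        rks <- lapply(c("rf_importance_cv", "rfecv", "lasso"),
                      function(m) {
            ord <- sample(feats)
            structure(list(method = m, features = ord,
                           values = setNames(rev(seq_along(ord)), ord),
                           universe = feats),
                      class = "FeatureRanking")
        })
        top_frac <- sample(c(0.1, 0.2, 0.34), 1L)
        cs <- consolidateScores(rks, top_frac = top_frac)
        ## independent brute force
        top_n <- ceiling(top_frac * length(feats))
        brute <- setNames(rep(0L, length(feats)), feats)
        for (r in rks)
            for (i in seq_len(top_n))
                brute[r$features[i]] <- brute[r$features[i]] +
                    (top_n - i + 1L)
        expect_equal(setNames(cs$total, cs$feature)[feats], brute)
        sel <- attr(cs, "selected")
        expect_gte(length(sel), top_n)
        expect_lte(length(sel), 3L * top_n)
    }
})

test_that("consolidation is permutation-equivariant", {
    feats <- paste0(3:22, "—tip")
    set.seed(8)
    mk <- function() {
        ord <- sample(feats)
        structure(list(method = "lasso", features = ord,
                       values = setNames(rev(seq_along(ord)), ord),
                       universe = feats),
                  class = "FeatureRanking")
    }
    rks <- list(mk(), mk(), mk())
    cs1 <- consolidateScores(rks, top_frac = 0.2)
    perm <- sample(feats)
    rks2 <- lapply(rks, function(r) { r$universe <- perm; r })
    cs2 <- consolidateScores(rks2, top_frac = 0.2)
    t1 <- setNames(cs1$total, cs1$feature)
    t2 <- setNames(cs2$total, cs2$feature)
    expect_equal(t1[feats], t2[feats])
})

test_that("nature summaries count rotational parameters correctly", {
    s <- natureSummary(c("10—tip", "11—shift", "14—propeller"))
    expect_equal(s$rotational_fraction, 2 / 3)
    s2 <- natureSummary(c("10—tip", "12—tip", "20—tip"))
    expect_equal(unname(s2$parameter_share["tip"]), 1)
    expect_error(natureSummary(character(0)), "empty")
    expect_error(natureSummary("tip10"), "unparseable")
    ## random sets match a direct counting oracle
    feats <- paste0(rep(3:23, each = 17L), "—",
                    rep(helicalParameters()$name, 21L))
    for (trial in 1:5) {
        set.seed(trial)
        sel <- sample(feats, 40L)
        s3 <- natureSummary(sel)
        rot <- helicalParameters()$name[
            helicalParameters()$nature == "rotational"]
        expect_equal(s3$rotational_fraction,
                     mean(sub("^[0-9]+—", "", sel) %in% rot))
    }
})

test_that("tri-method scoring recovers planted features end to end", {
    x <- makeBinarySet(n_per_class = 18L, p = 40L,
                       signal_cols = c(1L, 2L, 3L), effect = 4, seed = 6L)
    full <- makeFeatureSet(
        rbind(featureMatrix(x),
              featureMatrix(x) + matrix(rnorm(prod(dim(featureMatrix(x))),
                                              0, 1), nrow = ncol(x))),
        hotspot = rep(isHotspot(x), 2L),
        adducted = rep(c(TRUE, FALSE), each = ncol(x)))
    sc <- scoreFeatures(full, top_frac = 0.10, seed = 1L, rfe_step = 1L,
                        folds = 5L)
    planted <- colnames(featureMatrix(x))[1:3]
    expect_true(all(planted %in% attr(sc, "selected")))
    expect_equal(attr(sc, "top_n"), 4L)   # ceiling(0.1 * 40)
})
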
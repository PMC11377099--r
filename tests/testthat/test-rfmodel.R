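test_that("a one-point grid returns that point", {
    x <- makeSeparableSet(n_per_class = 8L, p = 6L)
    g <- list(n_estimators = 25L, max_depth = 4L, max_features = "sqrt",
              min_samples_leaf = 1L, min_samples_split = 2L,
              bootstrap = FALSE)
    gs <- gridSearch(x, grid = g, folds = 3L, seed = 1L)
    expect_equal(gs$best, do.call(rfParams, g))
    expect_error(gridSearch(x, grid = list(), folds = 3L), "empty")
})

test_that("grid search picks the exhaustive-CV argmax with first-wins ties", {
    x <- makeSeparableSet(n_per_class = 8L, p = 6L, effect = 2,
                          noise_sd = 1.5)
    g <- list(n_estimators = c(10L, 40L), max_depth = c(1L, 6L),
              max_features = "sqrt", min_samples_leaf = 1L,
              min_samples_split = 2L, bootstrap = FALSE)
    gs <- gridSearch(x, grid = g, folds = 3L, seed = 2L)
    sc <- gs$scores
    expect_equal(nrow(sc), 4L)
    best_row <- which.max(sc$cv_accuracy)  # first maximum
    expect_equal(gs$best,
                 do.call(rfParams,
                         as.list(sc[best_row,
                                    setdiff(names(sc), "cv_accuracy")])))
})

test_that("a depth-limited grid prefers depth when a stump cannot separate", {
    ## class = XOR of two features: depth-1 trees are at chance, deeper
    ## trees solve it, so the exhaustive CV optimum must be max_depth 4
    set.seed(5)
    n <- 80L
    a <- rep(c(0, 1), each = n / 2)
    b <- rep(c(0, 1), times = n / 2)
    X <- cbind(a + rnorm(n, 0, 0.05), b + rnorm(n, 0, 0.05),
               matrix(rnorm(2 * n), n, 2L))
    hot <- xor(a == 1, b == 1)
    x <- makeFeatureSet(X, hotspot = hot, adducted = rep(TRUE, n))
    g <- list(n_estimators = 30L, max_depth = c(1L, 4L),
              max_features = "all", min_samples_leaf = 1L,
              min_samples_split = 2L, bootstrap = FALSE)
    gs <- gridSearch(x, label = "hotspot", grid = g, folds = 4L, seed = 3L)
    expect_equal(gs$best$max_depth, 4L)
})

test_that("the shipped grid reaches the optimised configuration", {
    g <- defaultGrid()
    opt <- rfParams(n_estimators = 89L, max_depth = 4L,
                    max_features = "sqrt", min_samples_leaf = 1L,
                    min_samples_split = 2L, bootstrap = FALSE)
    for (nm in names(g))
        expect_true(opt[[nm]] %in% g[[nm]])
})

test_that("the forest is deterministic and exposes normalised importances", {
    x <- makeSeparableSet(n_per_class = 8L, p = 10L)
    m1 <- fitRF(x, seed = 7L)
    m2 <- fitRF(x, seed = 7L)
    Xt <- featureMatrix(x)
    expect_identical(predict(m1, Xt)$pred, predict(m2, Xt)$pred)
    expect_identical(predict(m1, Xt)$scores, predict(m2, Xt)$scores)
    imp <- rfImportance(m1)
    expect_equal(sum(imp), 1, tolerance = 1e-9)
    ## separable training data is predicted perfectly
    expect_equal(mean(predict(m1, Xt)$pred == as.character(classLabels(x))),
                 1)
    ## single-class input is an error
    xa <- x[, classLabels(x) == "hotspot_adduct"]
    expect_error(fitRF(xa), "single class")
})

test_that("deployment samples the stratified ceiling of the test fraction", {
    x <- makeSeparableSet(n_per_class = 10L, p = 6L)   # 40 samples
    m <- fitRF(x, seed = 0L)
    r <- deployModel(m, x, test_fraction = 0.95, seed = 1L)
    expect_equal(r$n_evaluated, 38L)                   # ceiling(0.95*40)
    expect_equal(sum(r$confusion), 38L)
    r1 <- deployModel(m, x, test_fraction = 1, seed = 1L)
    expect_equal(r1$n_evaluated, 40L)
    ## class proportions preserved within +-1
    cls <- table(classLabels(x))
    per_class <- rowSums(r$confusion)
    expect_true(all(abs(per_class - 0.95 * cls) <= 1))
})

test_that("deployment is invariant to row order of the unseen matrix", {
    x <- makeSeparableSet(n_per_class = 10L, p = 6L)
    m <- fitRF(x, seed = 0L)
    set.seed(99)
    xp <- x[, sample(ncol(x))]
    r1 <- deployModel(m, x, test_fraction = 0.9, seed = 5L)
    r2 <- deployModel(m, xp, test_fraction = 0.9, seed = 5L)
    expect_equal(r1$metrics$accuracy, r2$metrics$accuracy)
    expect_equal(r1$confusion, r2$confusion)
})

test_that("feature-column mismatch is reported with the offending names", {
    x <- makeSeparableSet(n_per_class = 6L, p = 6L)
    m <- fitRF(x, seed = 0L)
    Xt <- featureMatrix(x)
    colnames(Xt)[1L] <- "99—tip"
    expect_error(predict(m, Xt), "missing")
})

test_that("window robustness: zero reduction gives exactly zero deltas", {
    cfg <- tp53Config(n_hotspot_sites = 2L, n_nonhotspot_sites = 2L,
                      n_frames = 60L,
                      site_labels = c("h1", "h2", "n1", "n2"))
    b <- generateBundle(cfg, seed = 1L)
    bu <- generateBundle(tp53Config(n_hotspot_sites = 2L,
                                    n_nonhotspot_sites = 2L,
                                    n_frames = 60L, dataset_tag = "Val",
                                    site_labels = c("h1", "h2", "n1",
                                                    "n2")),
                         seed = 2L)
    wr0 <- windowRobustness(b, bu, reduced_fraction = 0,
                            train_fraction = 0.75, seed = 3L,
                            params = rfParams(n_estimators = 30L))
    expect_true(all(wr0$deltas == 0))
    ## strongly separable data: truncating the window barely moves metrics
    wr <- windowRobustness(b, bu, reduced_fraction = 0.10,
                           train_fraction = 0.75, seed = 3L,
                           params = rfParams(n_estimators = 30L))
    expect_lt(max(abs(wr$deltas)), 0.05)
    expect_error(windowRobustness(b, bu, reduced_fraction = 0.95),
                 "excludes all frames")
})
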
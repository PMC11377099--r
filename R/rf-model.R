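## Random-forest model: hyperparameter container, grid-search optimisation,
## fitting (ranger engine), deployment to unseen gene contexts, and the
## truncated-window robustness check.

#' Random-forest hyperparameters
#'
#' @param n_estimators Number of trees (>= 1).
#' @param max_depth Maximum tree depth, or \code{NA} for unlimited.
#' @param max_features \code{"sqrt"}, \code{"log2"} or \code{"all"}:
#'   candidate features per split.
#' @param min_samples_leaf Minimum samples in a terminal node (>= 1).
#' @param min_samples_split Minimum samples required to split (>= 2).
#' @param bootstrap Resample with replacement per tree; when \code{FALSE}
#'   every tree sees the full training set.
#' @return List of class \code{RFParams}.
#' @export
rfParams <- function(n_estimators = 89L, max_depth = 4L,
                     max_features = "sqrt", min_samples_leaf = 1L,
                     min_samples_split = 2L, bootstrap = FALSE) {
    stopifnot(n_estimators >= 1L, min_samples_leaf >= 1L,
              min_samples_split >= 2L,
              max_features %in% c("sqrt", "log2", "all"))
    structure(list(n_estimators = as.integer(n_estimators),
                   max_depth = if (is.na(max_depth)) NA_integer_ else
                       as.integer(max_depth),
                   max_features = max_features,
                   min_samples_leaf = as.integer(min_samples_leaf),
                   min_samples_split = as.integer(min_samples_split),
                   bootstrap = isTRUE(bootstrap)),
              class = "RFParams")
}

.mtryOf <- function(max_features, p) {
    switch(max_features,
           sqrt = max(1L, floor(sqrt(p))),
           log2 = max(1L, floor(log2(p))),
           all = p)
}

.rangerFit <- function(X, y, params, seed, probability = TRUE) {
    ranger::ranger(
        x = X, y = y, probability = probability,
        num.trees = params$n_estimators,
        max.depth = if (is.na(params$max_depth)) 0L else params$max_depth,
        mtry = .mtryOf(params$max_features, ncol(X)),
        min.bucket = params$min_samples_leaf,
        min.node.size = params$min_samples_split,
        replace = params$bootstrap,
        sample.fraction = 1,
        importance = "impurity",
        num.threads = 1L, seed = seed)
}

#' Fit the random-forest classifier
#'
#' @param x A \linkS4class{HelicalFeatureSet}, or a samples-x-features
#'   matrix (then supply \code{y}).
#' @param label \code{"class4"} or \code{"hotspot"} when \code{x} is a
#'   HelicalFeatureSet.
#' @param params An \code{\link{rfParams}} configuration.
#' @param seed Integer seed; fits are deterministic given it.
#' @param y Factor of labels when \code{x} is a plain matrix.
#' @return List of class \code{RFModel} with elements \code{fit} (ranger
#'   probability forest), \code{params}, \code{classes}, \code{features}
#'   (training column names), \code{seed}.
#' @export
fitRF <- function(x, label = "class4", params = rfParams(), seed = 0L,
                  y = NULL) {
    if (is(x, "HelicalFeatureSet")) {
        d <- .resolveLabels(x, label)
        X <- d$X; y <- d$y
    } else {
        X <- as.matrix(x)
        stopifnot(!is.null(y))
        y <- droplevels(as.factor(y))
    }
    if (nlevels(droplevels(y)) < 2L)
        stop("training labels contain a single class")
    fit <- .rangerFit(X, droplevels(y), params, seed)
    structure(list(fit = fit, params = params,
                   classes = levels(droplevels(y)),
                   features = colnames(X), seed = as.integer(seed),
                   label = label),
              class = "RFModel")
}

#' Predict with a fitted RFModel
#'
#' @param object An \code{RFModel}.
#' @param newdata Samples-x-features matrix with the training columns.
#' @param ... Unused.
#' @return List with \code{pred} (character labels) and \code{scores}
#'   (per-class probability matrix).
#' @export
predict.RFModel <- function(object, newdata, ...) {
    newdata <- as.matrix(newdata)
    miss <- setdiff(object$features, colnames(newdata))
    extra <- setdiff(colnames(newdata), object$features)
    if (length(miss) || length(extra))
        stop("feature columns do not match the training matrix; missing: ",
             paste(head(miss, 5L), collapse = ", "),
             if (length(miss) > 5L) " ..." else "",
             "; extra: ", paste(head(extra, 5L), collapse = ", "),
             if (length(extra) > 5L) " ..." else "")
    sc <- predict(object$fit, newdata[, object$features, drop = FALSE],
                  num.threads = 1L)$predictions
    list(pred = colnames(sc)[max.col(sc, ties.method = "first")],
         scores = sc)
}

#' Normalised impurity importances of an RFModel
#'
#' @param model An \code{RFModel}.
#' @return Named numeric vector summing to 1 (all-zero importances are
#'   returned unnormalised).
#' @export
rfImportance <- function(model) {
    imp <- ranger::importance(model$fit)
    s <- sum(imp)
    if (s > 0) imp / s else imp
}

#' The shipped hyperparameter grid
#'
#' @return Named list of candidate values whose cartesian product is
#'   searched by \code{\link{gridSearch}}; it contains the optimised
#'   configuration of 89 trees, depth 4, sqrt features, one sample per
#'   leaf, two to split, bootstrap off.
#' @export
defaultGrid <- function() {
    list(n_estimators = c(50L, 89L, 100L, 200L),
         max_depth = c(2L, 4L, 8L, NA_integer_),
         max_features = c("sqrt", "log2"),
         min_samples_leaf = c(1L, 2L),
         min_samples_split = c(2L, 4L),
         bootstrap = c(TRUE, FALSE))
}

#' Grid-search optimisation of the random-forest hyperparameters
#'
#' Every point of the cartesian product of the grid is scored by stratified
#' k-fold cross-validated accuracy (mean over folds) on the supplied data;
#' the maximising point wins, ties broken by enumeration order (first
#' listed value varies fastest).
#'
#' @param x A \linkS4class{HelicalFeatureSet} or samples-x-features matrix.
#' @param label Label selector (see \code{\link{fitRF}}).
#' @param grid Named list of candidate values (see
#'   \code{\link{defaultGrid}}).
#' @param folds CV folds (default 10).
#' @param seed Integer seed controlling fold assignment and tree fits.
#' @param y Labels when \code{x} is a matrix.
#' @return List of class \code{GridSearchResult}: \code{best}
#'   (\code{RFParams}), \code{scores} (per-point mean CV accuracy, in
#'   enumeration order).
#' @export
gridSearch <- function(x, label = "class4", grid = defaultGrid(),
                       folds = 10L, seed = 0L, y = NULL) {
    if (!length(grid) || any(!lengths(grid)))
        stop("empty hyperparameter grid")
    if (is(x, "HelicalFeatureSet")) {
        d <- .resolveLabels(x, label)
        X <- d$X; y <- d$y
    } else {
        X <- as.matrix(x); y <- droplevels(as.factor(y))
    }
    pts <- expand.grid(grid, stringsAsFactors = FALSE)
    set.seed(seed)
    fold <- .stratifiedFolds(as.character(y), folds)
    acc <- numeric(nrow(pts))
    for (i in seq_len(nrow(pts))) {
        p <- do.call(rfParams, as.list(pts[i, , drop = FALSE]))
        fold_acc <- numeric(folds)
        for (k in seq_len(folds)) {
            hold <- fold == k
            fit <- .rangerFit(X[!hold, , drop = FALSE],
                              droplevels(y[!hold]), p,
                              seed = seed * 1000L + k)
            sc <- predict(fit, X[hold, , drop = FALSE],
                          num.threads = 1L)$predictions
            pred <- colnames(sc)[max.col(sc, ties.method = "first")]
            fold_acc[k] <- mean(pred == as.character(y[hold]))
        }
        acc[i] <- mean(fold_acc)
    }
    best <- which.max(acc)   # first maximum = enumeration-order tie-break
    structure(list(best = do.call(rfParams,
                                  as.list(pts[best, , drop = FALSE])),
                   scores = cbind(pts, cv_accuracy = acc),
                   folds = folds, seed = seed),
              class = "GridSearchResult")
}

## Stratified sample of ceiling(fraction * n) rows: floor per class, then
## largest fractional parts, keeping each class within +-1 of its
## proportion. Candidates are canonicalised by 'key' (sample names) so the
## selected identities are invariant to row order of the input.
.stratifiedSample <- function(y, fraction, key = NULL) {
    y <- as.character(y)
    if (is.null(key)) key <- seq_along(y)
    n_take <- ceiling(fraction * length(y))
    classes <- sort(unique(y))
    n_c <- vapply(classes, function(cl) sum(y == cl), 1L)
    want <- fraction * n_c
    base <- pmin(floor(want), n_c)
    rem <- n_take - sum(base)
    if (rem > 0) {
        ord <- order(want - floor(want), decreasing = TRUE)
        i <- 0L
        while (rem > 0) {
            i <- i %% length(classes) + 1L
            cl <- ord[i]
            if (base[cl] < n_c[cl]) { base[cl] <- base[cl] + 1L
                                      rem <- rem - 1L }
        }
    }
    take <- integer(0)
    for (j in seq_along(classes)) {
        cand <- which(y == classes[j])
        cand <- cand[order(key[cand])]
        take <- c(take, cand[sample(seq_along(cand), base[j])])
    }
    sort(take)
}

#' Deploy a fitted model on an unseen dataset
#'
#' Evaluates the model on a stratified random sample of
#' \code{ceiling(test_fraction * n)} rows of the unseen feature set; the
#' remainder plays no role.
#'
#' @param model An \code{RFModel}.
#' @param unseen A \linkS4class{HelicalFeatureSet} with the same feature
#'   columns as training.
#' @param test_fraction Fraction of unseen rows evaluated (default 0.95).
#' @param seed Integer seed for the stratified sample.
#' @return List of class \code{DeployReport}: \code{dataset_tag},
#'   \code{test_fraction}, \code{n_evaluated}, \code{metrics},
#'   \code{confusion}.
#' @export
deployModel <- function(model, unseen, test_fraction = 0.95, seed = 0L) {
    stopifnot(inherits(model, "RFModel"), is(unseen, "HelicalFeatureSet"))
    d <- .resolveLabels(unseen, model$label)
    set.seed(seed)
    take <- .stratifiedSample(as.character(d$y), test_fraction,
                              key = rownames(d$X))
    res <- predict(model, d$X[take, , drop = FALSE])
    m <- computeMetrics(as.character(d$y[take]), res$pred,
                        scores = res$scores)
    structure(list(
        dataset_tag = paste(unique(
            SummarizedExperiment::colData(unseen)$dataset_tag),
            collapse = "+"),
        test_fraction = test_fraction, n_evaluated = length(take),
        metrics = m, confusion = m$confusion),
        class = "DeployReport")
}

#' @export
print.DeployReport <- function(x, ...) {
    cat(sprintf(
        "DeployReport [%s]: %d samples (fraction %.2f)\n",
        x$dataset_tag, x$n_evaluated, x$test_fraction))
    cat(sprintf(
        "  accuracy %.3f  precision %.3f  recall %.3f  f1 %.3f\n",
        x$metrics$accuracy, x$metrics$precision, x$metrics$recall,
        x$metrics$f1))
    invisible(x)
}

#' Truncated-window robustness check
#'
#' Rebuilds the training features with the analysis window shortened by an
#' additional fraction of the simulation span (emulating the exclusion of
#' part of the sampled time), retrains the model, redeploys it on the same
#' unseen dataset, and reports metric deltas against the full-window run.
#' A convergence diagnostic: for well-sampled trajectories the deltas are
#' small.
#'
#' @param bundle Training \linkS4class{TrajectoryBundle}.
#' @param unseen_bundle Unseen \linkS4class{TrajectoryBundle} (deployed at
#'   the standard window in both runs).
#' @param params \code{\link{rfParams}} configuration.
#' @param reduced_fraction Additional fraction of the span excluded from
#'   the start of the window (default 0.10; 0 reproduces the base run).
#' @param label,train_fraction,test_fraction,seed As in
#'   \code{\link{fitRF}} / \code{\link{deployModel}}.
#' @param window_fraction Baseline equilibration fraction (default 0.10).
#' @return List with \code{base} and \code{reduced} \code{DeployReport}s
#'   and \code{deltas} (reduced minus base for accuracy, precision, recall,
#'   f1).
#' @export
windowRobustness <- function(bundle, unseen_bundle, params = rfParams(),
                             reduced_fraction = 0.10, label = "class4",
                             train_fraction = 0.8, test_fraction = 0.95,
                             seed = 0L, window_fraction = 0.10) {
    if (window_fraction + reduced_fraction >= 1)
        stop("reduced window excludes all frames")
    unseen_x <- buildFeatureMatrix(unseen_bundle,
                                   window_fraction = window_fraction)
    runOne <- function(frac) {
        x <- buildFeatureMatrix(bundle, window_fraction = frac)
        d <- .resolveLabels(x, label)
        set.seed(seed)
        train <- .stratifiedSplit(as.character(d$y), train_fraction)
        model <- fitRF(d$X[train, , drop = FALSE], label = label,
                       params = params, seed = seed,
                       y = d$y[train])
        deployModel(model, unseen_x, test_fraction = test_fraction,
                    seed = seed)
    }
    base <- runOne(window_fraction)
    reduced <- runOne(window_fraction + reduced_fraction)
    deltas <- vapply(c("accuracy", "precision", "recall", "f1"),
                     function(m) reduced$metrics[[m]] - base$metrics[[m]],
                     0)
    list(base = base, reduced = reduced, deltas = deltas)
}
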
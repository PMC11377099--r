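## Multi-classifier benchmark harness: per-seed stratified 80/20 split,
## stratified k-fold cross-validation on the training portion, held-out
## test metrics and the train-test gap, for the 15-classifier panel.

.stratifiedSplit <- function(y, train_fraction) {
    train <- integer(0)
    for (cl in unique(y)) {
        idx <- which(y == cl)
        n_tr <- max(1L, round(train_fraction * length(idx)))
        n_tr <- min(n_tr, length(idx) - 1L)
        train <- c(train, sample(idx, n_tr))
    }
    sort(train)
}

.stratifiedFolds <- function(y, folds) {
    fold <- integer(length(y))
    for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
}

.resolveLabels <- function(x, label = c("class4", "hotspot")) {
    label <- match.arg(label)
    stopifnot(is(x, "HelicalFeatureSet"))
    X <- featureMatrix(x)
    y <- if (label == "class4") classLabels(x) else
        factor(ifelse(isHotspot(x), "hotspot", "nonhotspot"),
               levels = c("hotspot", "nonhotspot"))
    list(X = X, y = y)
}

#' Benchmark the 15-classifier panel
#'
#' For each seed: a stratified split reserves \code{train_fraction} of the
#' samples for training; each panel classifier is fitted on the training
#' portion and evaluated (a) by pooled stratified k-fold cross-validation
#' within the training portion, (b) on the held-out test portion, and (c)
#' on the training portion itself, from which the train-test gap
#' (train accuracy minus test accuracy) is derived. A classifier that fails
#' on the given data (e.g. QDA when features outnumber per-class samples)
#' is recorded as missing with a warning rather than aborting the run.
#'
#' @param x A \linkS4class{HelicalFeatureSet}.
#' @param label \code{"class4"} (default) or binary \code{"hotspot"}.
#' @param seeds Integer vector of random seeds (default \code{0:9}).
#' @param folds Cross-validation folds on the training portion (default 10).
#' @param train_fraction Fraction of samples used for training (default 0.8).
#' @param panel Named list of classifiers (default
#'   \code{\link{classifierPanel}()}).
#' @return A list of class \code{BenchResult}: \code{$results} long-format
#'   data.frame (classifier, seed, split, metric, value) and
#'   \code{$aggregates} (per-classifier mean and sd of each test metric).
#' @export
compareClassifiers <- function(x, label = "class4", seeds = 0:9,
                               folds = 10L, train_fraction = 0.8,
                               panel = classifierPanel()) {
    d <- .resolveLabels(x, label)
    X <- d$X; y <- d$y
    tab <- table(y)
    if (any(tab < 2L))
        stop("every class needs at least 2 samples; got: ",
             paste(names(tab), tab, sep = "=", collapse = ", "))
    rows <- list()
    push <- function(clf, seed, split, m) {
        for (metric in c("accuracy", "precision", "recall", "f1",
                         "train_test_gap", "roc_auc"))
            rows[[length(rows) + 1L]] <<- data.frame(
                classifier = clf, seed = seed, split = split,
                metric = metric, value = m[[metric]],
                stringsAsFactors = FALSE)
    }
    for (seed in seeds) {
        set.seed(seed)
        train <- .stratifiedSplit(as.character(y), train_fraction)
        test <- setdiff(seq_along(y), train)
        y_tr <- y[train]
        if (min(table(droplevels(y_tr))) < folds)
            stop(sprintf(
                "smallest training class (%d) is below the fold count (%d)",
                min(table(droplevels(y_tr))), folds))
        set.seed(seed)
        fold <- .stratifiedFolds(as.character(y_tr), folds)
        for (clf_name in names(panel)) {
            clf <- panel[[clf_name]]
            ok <- TRUE
            ## pooled CV predictions on the training portion
            cv_pred <- character(length(train))
            for (k in seq_len(folds)) {
                hold <- which(fold == k)
                r <- tryCatch(
                    .fitEvalRaw(clf, X[train, , drop = FALSE], y_tr,
                                setdiff(seq_along(train), hold), hold,
                                fit_seed = seed * 1000L + k),
                    error = function(e) e)
                if (inherits(r, "error")) { ok <- FALSE; break }
                cv_pred[hold] <- r$pred
            }
            full <- if (ok) tryCatch({
                set.seed(seed * 1000L)
                clf(X[train, , drop = FALSE], droplevels(y_tr),
                    X[c(train, test), , drop = FALSE])
            }, error = function(e) e) else NULL
            if (!ok || inherits(full, "error")) {
                warning(sprintf("classifier '%s' failed (seed %d): %s",
                                clf_name, seed,
                                if (inherits(full, "error"))
                                    conditionMessage(full) else
                                    "cross-validation failure"),
                        call. = FALSE)
                na <- list(accuracy = NA_real_, precision = NA_real_,
                           recall = NA_real_, f1 = NA_real_,
                           train_test_gap = NA_real_, roc_auc = NA_real_)
                push(clf_name, seed, "cv", na)
                push(clf_name, seed, "train", na)
                push(clf_name, seed, "test", na)
                next
            }
            n_tr <- length(train)
            tr_idx <- seq_len(n_tr)
            te_idx <- n_tr + seq_along(test)
            m_train <- computeMetrics(
                as.character(y_tr), full$pred[tr_idx],
                scores = if (is.null(full$scores)) NULL else
                    full$scores[tr_idx, , drop = FALSE])
            m_test <- computeMetrics(
                as.character(y[test]), full$pred[te_idx],
                scores = if (is.null(full$scores)) NULL else
                    full$scores[te_idx, , drop = FALSE],
                train_accuracy = m_train$accuracy)
            m_cv <- computeMetrics(as.character(y_tr), cv_pred)
            push(clf_name, seed, "cv", m_cv)
            push(clf_name, seed, "train", m_train)
            push(clf_name, seed, "test", m_test)
        }
    }
    results <- do.call(rbind, rows)
    test_res <- results[results$split == "test", ]
    aggregates <- aggregate(value ~ classifier + metric, test_res,
                            function(v) c(mean = mean(v), sd = sd(v)),
                            na.action = stats::na.pass)
    aggregates <- data.frame(classifier = aggregates$classifier,
                             metric = aggregates$metric,
                             mean = aggregates$value[, "mean"],
                             sd = aggregates$value[, "sd"])
    structure(list(results = results, aggregates = aggregates,
                   seeds = seeds, folds = folds,
                   train_fraction = train_fraction, label = label),
              class = "BenchResult")
}

.fitEvalRaw <- function(clf, X, y, train, test, fit_seed) {
    set.seed(fit_seed)
    clf(X[train, , drop = FALSE], droplevels(y[train]),
        X[test, , drop = FALSE])
}

#' @export
print.BenchResult <- function(x, ...) {
    cat(sprintf("BenchResult: %d classifiers, %d seeds, %d-fold CV\n",
                length(unique(x$results$classifier)), length(x$seeds),
                x$folds))
    acc <- x$aggregates[x$aggregates$metric == "accuracy", ]
    acc <- acc[order(-acc$mean), ]
    print(acc, row.names = FALSE)
    invisible(x)
}

#' Two-sided binomial null band for chance-level accuracy
#'
#' @param n Number of evaluated samples.
#' @param p Chance accuracy (e.g. 0.25 for four balanced classes).
#' @param alpha Two-sided tail mass outside the band (default 0.01).
#' @return Numeric \code{c(lower, upper)} on the accuracy scale.
#' @export
binomialNullBand <- function(n, p, alpha = 0.01) {
    c(lower = qbinom(alpha / 2, n, p) / n,
      upper = qbinom(1 - alpha / 2, n, p) / n)
}
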
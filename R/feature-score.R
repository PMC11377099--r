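## Tri-method feature selection and rank-score consolidation: random-forest
## importance under cross-validation, recursive feature elimination with
## cross-validation, and L1-regularised (lasso) ranking, consolidated by
## assigning each method's top-10% features scores from top_n (best) down
## to 1 and summing across methods.

.newRanking <- function(method, features, values, universe) {
    structure(list(method = method, features = features, values = values,
                   universe = universe),
              class = "FeatureRanking")
}

#' @export
print.FeatureRanking <- function(x, ...) {
    cat(sprintf("FeatureRanking [%s]: %d features; top 5: %s\n", x$method,
                length(x$features),
                paste(head(x$features, 5L), collapse = ", ")))
    invisible(x)
}

#' Restrict a feature set to adduct-bound samples with a binary label
#'
#' Feature scoring targets the structural signal that separates hotspot
#' from nonhotspot duplexes in the presence of the lesion, so only
#' adducted samples are scored and the label collapses to hotspot status.
#'
#' @param x A \linkS4class{HelicalFeatureSet}.
#' @return The adducted-only \linkS4class{HelicalFeatureSet}.
#' @export
subsetAdductedBinary <- function(x) {
    stopifnot(is(x, "HelicalFeatureSet"))
    keep <- isAdducted(x)
    if (!any(keep)) stop("no adducted samples in the feature set")
    out <- x[, keep]
    if (length(unique(isHotspot(out))) < 2L)
        stop("adducted subset contains a single hotspot class")
    out
}

.rankOrder <- function(values) {
    ## descending by value, ties broken by column position (stable order)
    order(-values, seq_along(values))
}

#' Feature ranking by cross-validated random-forest importance
#'
#' Fits the random forest on each of k stratified training folds and
#' averages the impurity importances across folds; features are ranked by
#' descending average importance (ties by column order).
#'
#' @param x A \linkS4class{HelicalFeatureSet} (typically the adducted
#'   subset).
#' @param label \code{"hotspot"} (default) or \code{"class4"}.
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed.
#' @param params \code{\link{rfParams}} used for the fold fits.
#' @return A \code{FeatureRanking} (method \code{rf_importance_cv}).
#' @export
rankRFImportanceCV <- function(x, label = "hotspot", folds = 10L,
                               seed = 0L, params = rfParams()) {
    d <- .resolveLabels(x, label)
    set.seed(seed)
    fold <- .stratifiedFolds(as.character(d$y), folds)
    imp <- matrix(0, ncol(d$X), folds,
                  dimnames = list(colnames(d$X), NULL))
    for (k in seq_len(folds)) {
        keep <- fold != k
        fit <- .rangerFit(d$X[keep, , drop = FALSE],
                          droplevels(d$y[keep]), params,
                          seed = seed * 1000L + k)
        imp[, k] <- ranger::importance(fit)[colnames(d$X)]
    }
    avg <- rowMeans(imp)
    ord <- .rankOrder(avg)
    .newRanking("rf_importance_cv", colnames(d$X)[ord], avg[ord],
                colnames(d$X))
}

#' Feature ranking by recursive feature elimination with cross-validation
#'
#' Repeatedly fits the random forest on the surviving features, scores the
#' surviving subset by stratified cross-validated accuracy, and eliminates
#' the least important features (a configurable fraction per round; within
#' an eliminated batch, order follows importance). The elimination order
#' reversed gives the ranking: the last-surviving feature ranks first.
#'
#' @param x,label,folds,seed,params As \code{\link{rankRFImportanceCV}}.
#' @param step Features eliminated per round: an integer count, or a
#'   fraction in (0,1) of the surviving set (default 1, the classical
#'   one-per-round elimination).
#' @return A \code{FeatureRanking} (method \code{rfecv}) whose
#'   \code{cv_scores} attribute records mean CV accuracy per subset size
#'   and \code{n_rounds} the number of elimination rounds.
#' @export
rankRFECV <- function(x, label = "hotspot", folds = 10L, seed = 0L,
                      params = rfParams(), step = 1L) {
    d <- .resolveLabels(x, label)
    set.seed(seed)
    fold <- .stratifiedFolds(as.character(d$y), folds)
    surviving <- colnames(d$X)
    eliminated <- character(0)
    cv_scores <- data.frame(n_features = integer(0),
                            cv_accuracy = numeric(0))
    n_rounds <- 0L
    while (length(surviving) > 0L) {
        n_rounds <- n_rounds + 1L
        Xs <- d$X[, surviving, drop = FALSE]
        fold_acc <- numeric(folds)
        for (k in seq_len(folds)) {
            keep <- fold != k
            fit <- .rangerFit(Xs[keep, , drop = FALSE],
                              droplevels(d$y[keep]), params,
                              seed = seed * 1000L + k)
            sc <- predict(fit, Xs[!keep, , drop = FALSE],
                          num.threads = 1L)$predictions
            pred <- colnames(sc)[max.col(sc, ties.method = "first")]
            fold_acc[k] <- mean(pred == as.character(d$y[!keep]))
        }
        cv_scores <- rbind(cv_scores,
                           data.frame(n_features = length(surviving),
                                      cv_accuracy = mean(fold_acc)))
        full <- .rangerFit(Xs, droplevels(d$y), params,
                           seed = seed * 1000L)
        imp <- ranger::importance(full)[surviving]
        n_drop <- if (step < 1) max(1L, floor(step * length(surviving)))
                  else as.integer(step)
        n_drop <- min(n_drop, length(surviving))
        ## drop the least important, least important first
        drop_ord <- order(imp, -seq_along(imp))
        dropped <- surviving[drop_ord[seq_len(n_drop)]]
        eliminated <- c(eliminated, dropped)
        surviving <- setdiff(surviving, dropped)
    }
    ranked <- rev(eliminated)
    r <- .newRanking("rfecv", ranked,
                     setNames(rev(seq_along(ranked)), ranked),
                     colnames(d$X))
    attr(r, "cv_scores") <- cv_scores
    attr(r, "n_rounds") <- n_rounds
    r
}

#' Feature ranking by L1-regularised (lasso) linear classification
#'
#' Fits an L1-penalised logistic model on the binary label with internal
#' standardisation; the penalty is chosen by 10-fold cross-validation.
#' Features are ordered by descending absolute coefficient; features shrunk
#' to zero follow, in column order.
#'
#' @param x A \linkS4class{HelicalFeatureSet}.
#' @param label \code{"hotspot"} (default).
#' @param seed Integer seed (controls CV fold assignment).
#' @param nfolds CV folds for the penalty path (default 10).
#' @return A \code{FeatureRanking} (method \code{lasso}).
#' @export
rankLasso <- function(x, label = "hotspot", seed = 0L, nfolds = 10L) {
    d <- .resolveLabels(x, label)
    if (all(apply(d$X, 2L, function(v) length(unique(v)) == 1L)))
        stop("all features are constant; lasso ranking undefined")
    set.seed(seed)
    cvfit <- glmnet::cv.glmnet(d$X, d$y, family = "binomial", alpha = 1,
                               standardize = TRUE, nfolds = nfolds)
    beta <- as.numeric(coef(cvfit, s = "lambda.min"))[-1L]
    names(beta) <- colnames(d$X)
    ord <- order(-abs(beta), seq_along(beta))
    .newRanking("lasso", colnames(d$X)[ord], abs(beta)[ord],
                colnames(d$X))
}

#' Consolidate three feature rankings into a single score
#'
#' Per method, the top \code{ceiling(top_frac * n)} features receive
#' integer scores from \code{top_n} (rank 1) down to 1 (rank \code{top_n});
#' all other features score 0 and are excluded from that method's
#' selection. Totals are summed across methods; the selected set is every
#' feature with a nonzero total. For the 357-feature schema and the default
#' 10 percent rule, \code{top_n} is 36.
#'
#' @param rankings List of three \code{FeatureRanking}s over the same
#'   feature universe.
#' @param top_frac Fraction of features retained per method (default 0.10).
#' @return data.frame of class \code{ConsolidatedScores} with columns
#'   \code{feature}, \code{base}, \code{parameter}, \code{nature}, one
#'   score column per method, \code{total} and \code{rank}; attributes
#'   \code{top_n} and \code{selected} (features with total > 0, in rank
#'   order).
#' @export
consolidateScores <- function(rankings, top_frac = 0.10) {
    stopifnot(length(rankings) >= 1L)
    universe <- rankings[[1L]]$universe
    for (r in rankings) {
        if (!setequal(r$features, universe) ||
            !identical(sort(r$universe), sort(universe)))
            stop("rankings cover different feature universes")
    }
    n <- length(universe)
    top_n <- ceiling(top_frac * n)
    scores <- matrix(0L, n, length(rankings),
                     dimnames = list(universe,
                                     vapply(rankings, `[[`, "", "method")))
    for (j in seq_along(rankings)) {
        top <- head(rankings[[j]]$features, top_n)
        scores[top, j] <- top_n - seq_along(top) + 1L
    }
    total <- rowSums(scores)
    ord <- order(-total, seq_len(n))
    info <- parseFeatureName(universe)
    out <- data.frame(feature = universe, info,
                      scores, total = as.integer(total),
                      check.names = FALSE, stringsAsFactors = FALSE)
    out <- out[ord, ]
    out$rank <- seq_len(n)
    rownames(out) <- NULL
    class(out) <- c("ConsolidatedScores", "data.frame")
    attr(out, "top_n") <- top_n
    attr(out, "selected") <- out$feature[out$total > 0L]
    out
}

#' Selected-feature composition by parameter nature
#'
#' @param features Character vector of feature names
#'   (\code{<base>—<parameter>}), e.g. the \code{selected} attribute of
#'   \code{\link{consolidateScores}}.
#' @return List with \code{rotational_fraction},
#'   \code{translational_fraction}, and \code{parameter_share} (named
#'   fraction of the set contributed by each parameter).
#' @export
natureSummary <- function(features) {
    if (!length(features)) stop("empty feature set")
    info <- parseFeatureName(features)
    share <- table(info$parameter) / nrow(info)
    list(rotational_fraction = mean(info$nature == "rotational"),
         translational_fraction = mean(info$nature == "translational"),
         parameter_share = setNames(as.numeric(share), names(share)))
}

#' One-call tri-method feature scoring
#'
#' Runs the three selectors on the adducted subset with the hotspot label
#' and consolidates their rankings.
#'
#' @param x A \linkS4class{HelicalFeatureSet} (full four-class set; the
#'   adducted subset is taken internally).
#' @param top_frac Fraction retained per method (default 0.10).
#' @param seed Integer seed shared by the three selectors.
#' @param params \code{\link{rfParams}} for the forest-based selectors.
#' @param rfe_step Elimination step for \code{\link{rankRFECV}} (default
#'   0.1 of the surviving set per round, for tractable run time on the
#'   357-feature schema).
#' @param folds CV folds (default 10).
#' @return A \code{ConsolidatedScores} data.frame (see
#'   \code{\link{consolidateScores}}).
#' @export
scoreFeatures <- function(x, top_frac = 0.10, seed = 0L,
                          params = rfParams(), rfe_step = 0.1,
                          folds = 10L) {
    xa <- subsetAdductedBinary(x)
    rankings <- list(
        rankRFImportanceCV(xa, folds = folds, seed = seed,
                           params = params),
        rankRFECV(xa, folds = folds, seed = seed, params = params,
                  step = rfe_step),
        rankLasso(xa, seed = seed, nfolds = folds))
    consolidateScores(rankings, top_frac = top_frac)
}
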
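## The 15-classifier panel used by the benchmark. Every entry is a function
## (X_train, y_train, X_test) -> list(pred = character, scores = matrix or
## NULL). Fits are deterministic given the R RNG state; callers seed before
## each fit. Engines are the standard R implementations (e1071, kernlab,
## ranger, xgboost, rpart, nnet, MASS, class); AdaBoost (SAMME over
## decision stumps) and the SGD linear classifier are implemented here
## because no installed package provides them.

.predProb <- function(p, classes) {
    p <- as.matrix(p)
    missing <- setdiff(classes, colnames(p))
    if (length(missing)) {
        pad <- matrix(0, nrow(p), length(missing),
                      dimnames = list(NULL, missing))
        p <- cbind(p, pad)
    }
    p[, classes, drop = FALSE]
}

.clfKNN <- function(X, y, Xt) {
    pred <- class::knn(X, Xt, y, k = 5L)
    list(pred = as.character(pred), scores = NULL)
}

.clfSVM <- function(kernel) {
    force(kernel)
    function(X, y, Xt) {
        fit <- e1071::svm(X, y, kernel = kernel, probability = TRUE)
        pr <- predict(fit, Xt, probability = TRUE)
        sc <- attr(pr, "probabilities")
        list(pred = as.character(pr),
             scores = .predProb(sc, levels(y)))
    }
}

.clfGP <- function(X, y, Xt) {
    fit <- kernlab::gausspr(X, y, type = "classification")
    sc <- kernlab::predict(fit, Xt, type = "probabilities")
    colnames(sc) <- fit@lev
    sc <- .predProb(sc, levels(y))
    list(pred = colnames(sc)[max.col(sc, ties.method = "first")],
         scores = sc)
}

.clfXGB <- function(X, y, Xt) {
    classes <- levels(y)
    dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L,
                                   nthread = 1L)
    fit <- xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = length(classes), nthread = 1L,
                      max_depth = 3L, eta = 0.1),
        data = dtrain, nrounds = 100L, verbose = 0)
    sc <- predict(fit, xgboost::xgb.DMatrix(Xt, nthread = 1L))
    dimnames(sc) <- list(NULL, classes)
    list(pred = classes[max.col(sc, ties.method = "first")], scores = sc)
}

.clfTree <- function(X, y, Xt) {
    df <- data.frame(y = y, X, check.names = FALSE)
    ## fully grown tree (no pruning, no minimum node size), the common
    ## default for a standalone CART classifier
    fit <- rpart::rpart(y ~ ., df, method = "class",
                        control = rpart::rpart.control(
                            minsplit = 2L, minbucket = 1L, cp = 0,
                            xval = 0L))
    sc <- predict(fit, data.frame(Xt, check.names = FALSE), type = "prob")
    sc <- .predProb(sc, levels(y))
    list(pred = colnames(sc)[max.col(sc, ties.method = "first")],
         scores = sc)
}

.clfRanger <- function(extratrees = FALSE) {
    force(extratrees)
    function(X, y, Xt) {
        args <- list(x = X, y = y, probability = TRUE, num.trees = 100L,
                     num.threads = 1L,
                     seed = sample.int(.Machine$integer.max, 1L))
        if (extratrees) {
            args$splitrule <- "extratrees"
            args$replace <- FALSE
            args$sample.fraction <- 1
        }
        fit <- do.call(ranger::ranger, args)
        sc <- predict(fit, Xt, num.threads = 1L)$predictions
        sc <- .predProb(sc, levels(y))
        list(pred = colnames(sc)[max.col(sc, ties.method = "first")],
             scores = sc)
    }
}

.clfNNet <- function(X, y, Xt) {
    fit <- nnet::nnet(X, nnet::class.ind(y), size = 10L, decay = 1e-4,
                      maxit = 200L, MaxNWts = 100000L, trace = FALSE,
                      softmax = TRUE)
    sc <- predict(fit, Xt)
    colnames(sc) <- levels(y)
    list(pred = colnames(sc)[max.col(sc, ties.method = "first")],
         scores = sc)
}

## AdaBoost with the SAMME multiclass weight update over depth-1 rpart
## stumps (50 rounds, learning rate 1).
.clfAdaBoost <- function(X, y, Xt, n_rounds = 50L) {
    classes <- levels(y)
    K <- length(classes)
    n <- nrow(X)
    w <- rep(1 / n, n)
    votes <- matrix(0, nrow(Xt), K, dimnames = list(NULL, classes))
    df <- data.frame(y = y, X, check.names = FALSE)
    dft <- data.frame(Xt, check.names = FALSE)
    for (i in seq_len(n_rounds)) {
        fit <- rpart::rpart(y ~ ., df, weights = w, method = "class",
                            control = rpart::rpart.control(
                                maxdepth = 1L, cp = -1, minsplit = 2L,
                                xval = 0L))
        pred <- as.character(predict(fit, df, type = "class"))
        err <- sum(w * (pred != as.character(y))) / sum(w)
        if (err >= 1 - 1 / K) break
        err <- max(err, 1e-10)
        alpha <- log((1 - err) / err) + log(K - 1)
        w <- w * exp(alpha * (pred != as.character(y)))
        w <- w / sum(w)
        predt <- as.character(predict(fit, dft, type = "class"))
        votes <- votes + alpha * outer(predt, classes, "==")
        if (err <= 1e-10) break
    }
    sc <- votes / pmax(rowSums(votes), .Machine$double.eps)
    list(pred = classes[max.col(sc, ties.method = "first")], scores = sc)
}

.clfNB <- function(X, y, Xt) {
    fit <- e1071::naiveBayes(X, y)
    sc <- predict(fit, Xt, type = "raw")
    sc <- .predProb(sc, levels(y))
    list(pred = colnames(sc)[max.col(sc, ties.method = "first")],
         scores = sc)
}

.clfQDA <- function(X, y, Xt) {
    fit <- MASS::qda(X, y)
    pr <- predict(fit, Xt)
    sc <- .predProb(pr$posterior, levels(y))
    list(pred = as.character(pr$class), scores = sc)
}

.clfLDA <- function(X, y, Xt) {
    fit <- suppressWarnings(MASS::lda(X, y))
    pr <- predict(fit, Xt)
    sc <- .predProb(pr$posterior, levels(y))
    list(pred = as.character(pr$class), scores = sc)
}

## One-vs-rest linear classifier trained by stochastic gradient descent on
## the hinge loss with L2 regularisation (alpha 1e-4), features
## standardised internally.
.clfSGD <- function(X, y, Xt, epochs = 50L, alpha = 1e-4) {
    classes <- levels(y)
    mu <- colMeans(X)
    sdev <- apply(X, 2L, stats::sd); sdev[sdev == 0] <- 1
    Xs <- sweep(sweep(X, 2L, mu), 2L, sdev, "/")
    Xts <- sweep(sweep(Xt, 2L, mu), 2L, sdev, "/")
    n <- nrow(Xs); p <- ncol(Xs)
    sc <- matrix(0, nrow(Xt), length(classes),
                 dimnames = list(NULL, classes))
    for (cl in classes) {
        yy <- ifelse(y == cl, 1, -1)
        w <- numeric(p); b <- 0; t <- 0L
        for (ep in seq_len(epochs)) {
            for (i in sample.int(n)) {
                t <- t + 1L
                eta <- 1 / (alpha * (t + 1 / alpha))
                margin <- yy[i] * (sum(Xs[i, ] * w) + b)
                w <- (1 - eta * alpha) * w
                if (margin < 1) {
                    w <- w + eta * yy[i] * Xs[i, ]
                    b <- b + eta * yy[i]
                }
            }
        }
        sc[, cl] <- Xts %*% w + b
    }
    list(pred = classes[max.col(sc, ties.method = "first")], scores = sc)
}

#' The benchmark's classifier panel
#'
#' @return Named list of 15 fit/predict functions, each taking
#'   \code{(X_train, y_train, X_test)} and returning \code{list(pred,
#'   scores)}.
#' @export
classifierPanel <- function() {
    list(
        "Nearest Neighbours" = .clfKNN,
        "Linear SVM" = .clfSVM("linear"),
        "Polynomial SVM" = .clfSVM("polynomial"),
        "RBF SVM" = .clfSVM("radial"),
        "Gaussian Process" = .clfGP,
        "Gradient Boosting" = .clfXGB,
        "Decision Tree" = .clfTree,
        "Extra Trees" = .clfRanger(extratrees = TRUE),
        "Random Forest" = .clfRanger(extratrees = FALSE),
        "Neural Network" = .clfNNet,
        "AdaBoost" = .clfAdaBoost,
        "Naive Bayes" = .clfNB,
        "QDA" = .clfQDA,
        "SGD" = .clfSGD,
        "LDA" = .clfLDA
    )
}
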
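## Evaluation metrics for the classifier benchmark: accuracy, weighted
## precision/recall/f1, train-test gap, and one-vs-rest multiclass ROC AUC
## with thresholds at unique score values.

#' Classification metrics with class-support weighting
#'
#' Multiclass precision, recall and f1 are computed per class from the
#' confusion matrix and averaged with class-support weights, which makes
#' weighted recall algebraically equal to accuracy. A per-class f1 never
#' exceeds the larger of that class's precision and recall.
#'
#' @param y_true,y_pred Vectors of class labels (equal length). Predicted
#'   labels must be drawn from the true label universe (plus any levels
#'   supplied via factor levels).
#' @param scores Optional numeric matrix of per-class scores (columns named
#'   by class); enables \code{roc_auc}.
#' @param train_accuracy Optional training-set accuracy; when supplied,
#'   \code{train_test_gap = train_accuracy - accuracy}.
#' @return Named list: \code{accuracy}, \code{precision}, \code{recall},
#'   \code{f1}, \code{train_test_gap}, \code{roc_auc}, plus the per-class
#'   table in \code{per_class} and the \code{confusion} matrix.
#' @export
computeMetrics <- function(y_true, y_pred, scores = NULL,
                           train_accuracy = NULL) {
    if (length(y_true) == 0L) stop("empty label vectors")
    if (length(y_true) != length(y_pred))
        stop("y_true and y_pred lengths differ")
    classes <- if (is.factor(y_true)) levels(y_true) else
        sort(unique(as.character(y_true)))
    y_true <- as.character(y_true); y_pred <- as.character(y_pred)
    unknown <- setdiff(unique(y_pred), classes)
    if (length(unknown))
        stop("predicted label(s) outside the class universe: ",
             paste(unknown, collapse = ", "))
    cm <- table(factor(y_true, classes), factor(y_pred, classes))
    support <- rowSums(cm)
    tp <- diag(cm)
    prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
    rec <- ifelse(support > 0, tp / support, 0)
    f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
    w <- support / sum(support)
    acc <- sum(tp) / sum(cm)
    auc <- if (!is.null(scores)) rocAucMulticlass(y_true, scores) else
        NA_real_
    gap <- if (!is.null(train_accuracy)) train_accuracy - acc else NA_real_
    list(accuracy = acc,
         precision = sum(w * prec), recall = sum(w * rec),
         f1 = sum(w * f1), train_test_gap = gap, roc_auc = auc,
         per_class = data.frame(class = classes, support = as.integer(support),
                                precision = as.numeric(prec),
                                recall = as.numeric(rec),
                                f1 = as.numeric(f1)),
         confusion = unclass(cm))
}

#' One-vs-rest multiclass ROC AUC
#'
#' For each class, the ROC curve is traced over thresholds placed at the
#' unique values of that class's score column (every observed score is a
#' decision boundary) and the area computed by trapezoidal integration;
#' class AUCs are macro-averaged. Classes absent from \code{y_true} are
#' skipped with a warning.
#'
#' @param y_true Vector of class labels.
#' @param scores Numeric matrix, one column per class, columns named by
#'   class.
#' @return Macro-averaged AUC in [0, 1].
#' @export
rocAucMulticlass <- function(y_true, scores) {
    y_true <- as.character(y_true)
    scores <- as.matrix(scores)
    if (is.null(colnames(scores)))
        stop("score columns must be named by class")
    if (nrow(scores) != length(y_true))
        stop("scores and labels have different lengths")
    aucs <- numeric(0)
    for (cl in colnames(scores)) {
        pos <- y_true == cl
        if (!any(pos)) {
            warning("class absent from y_true, skipped in ROC AUC: ", cl)
            next
        }
        if (all(pos)) next   # no negatives: AUC undefined for this class
        aucs <- c(aucs, .binaryAuc(pos, scores[, cl]))
    }
    if (!length(aucs)) stop("no class with both positives and negatives")
    mean(aucs)
}

## ROC by explicit threshold sweep at unique score values, then trapezoid.
.binaryAuc <- function(pos, s) {
    thr <- sort(unique(s), decreasing = TRUE)
    nP <- sum(pos); nN <- sum(!pos)
    tpr <- vapply(thr, function(t) sum(s >= t & pos) / nP, 0)
    fpr <- vapply(thr, function(t) sum(s >= t & !pos) / nN, 0)
    fpr <- c(0, fpr); tpr <- c(0, tpr)
    if (tail(fpr, 1L) < 1 || tail(tpr, 1L) < 1) {
        fpr <- c(fpr, 1); tpr <- c(tpr, 1)
    }
    sum(diff(fpr) * (head(tpr, -1L) + tail(tpr, -1L)) / 2)
}
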
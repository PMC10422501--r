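# One-vs-all linear SVM and the evaluation metrics.
#
# Multi-class classification is assembled from one binary linear SVM per
# class (libsvm C-classification via e1071, linear kernel, no rescaling of
# the already L2-normalised inputs). Each binary fit is reduced to an
# explicit (w, b) scorer oriented so that larger decision values favour the
# target class; prediction is the argmax over classes, ties broken by class
# order.

#' Train a one-vs-all linear SVM
#'
#' @param x n x d numeric matrix, one row per clip descriptor (rows should
#'   be L2-normalised).
#' @param y class labels, length n.
#' @param cost misclassification cost C (default 1).
#' @param classes class order for the scorers; defaults to `sort(unique(y))`
#'   (the manifest convention). All observed labels must be included.
#' @param tolerance libsvm termination tolerance (default 1e-4).
#' @return an [OvRModel-class].
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, 2), 10), matrix(rnorm(40, -2), 10))
#' m <- trainOvr(x, rep(c("a", "b"), each = 10))
#' predict(m, x)
#' @export
trainOvr <- function(x, y, cost = 1, classes = NULL, tolerance = 1e-4) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("features contain non-finite values", call. = FALSE)
  y <- as.character(y)
  if (length(y) != nrow(x)) stop("labels do not match feature rows", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(y))
  if (!all(y %in% classes)) stop("labels outside the declared class set", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("training requires at least 2 classes; got ", length(unique(y)),
         call. = FALSE)
  W <- matrix(0, ncol(x), length(classes))
  b <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    yy <- factor(ifelse(y == classes[ci], "pos", "neg"), levels = c("pos", "neg"))
    fit <- e1071::svm(x, yy, type = "C-classification", kernel = "linear",
                      cost = cost, scale = FALSE, tolerance = tolerance)
    w <- as.vector(t(fit$coefs) %*% fit$SV)
    rho <- fit$rho
    # libsvm orients the decision value towards the label it saw first;
    # flip so positive always means the target class.
    sgn <- if (fit$levels[fit$labels[1]] == "pos") 1 else -1
    W[, ci] <- sgn * w
    b[ci] <- -sgn * rho
  }
  new("OvRModel", weights = W, bias = b, classes = classes, cost = cost)
}

#' Predict activity labels with a one-vs-all model
#'
#' The predicted label is the argmax of the per-class linear decision
#' values; exact ties are broken by class order (first class wins).
#'
#' @param object an [OvRModel-class].
#' @param newdata n x d matrix (or a single descriptor vector).
#' @param decisionValues if `TRUE`, return the n x Nc decision-value matrix
#'   instead of labels.
#' @return character vector of labels (or a decision matrix).
#' @export
setMethod("predict", "OvRModel", function(object, newdata, decisionValues = FALSE) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object@weights))
    stop("feature dimension ", ncol(newdata), " does not match model dimension ",
         nrow(object@weights), call. = FALSE)
  scores <- newdata %*% object@weights
  scores <- sweep(scores, 2L, object@bias, "+")
  if (decisionValues) {
    colnames(scores) <- object@classes
    return(scores)
  }
  object@classes[max.col(scores, ties.method = "first")]
})

#' Confusion matrix with rows = ground truth, columns = prediction
#'
#' @param truth,predicted label vectors of equal length.
#' @param classes class order for rows/columns; defaults to the sorted
#'   union of observed labels.
#' @return Nc x Nc integer matrix of counts.
#' @export
confusionMatrix <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted))
    stop("truth and predicted differ in length", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  tab <- table(factor(truth, levels = classes),
               factor(predicted, levels = classes))
  m <- matrix(as.integer(tab), length(classes), length(classes),
              dimnames = list(truth = classes, predicted = classes))
  m
}

#' Overall accuracy of a confusion matrix (percent)
#'
#' 100 times the trace over the total count.
#'
#' @param confusion square count matrix (rows = truth).
#' @return percent in [0, 100].
#' @examples
#' accuracy(matrix(c(3, 2, 1, 4), 2))   # 70
#' @export
accuracy <- function(confusion) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion))
  100 * sum(diag(confusion)) / sum(confusion)
}

#' Per-class precision of a confusion matrix (percent)
#'
#' Precision of class j is 100 C_jj over the j-th column sum (predictions
#' of class j). A class that is never predicted has an undefined 0/0
#' ratio; by convention it contributes 0, with a message, which penalises
#' degenerate classifiers.
#'
#' @inheritParams accuracy
#' @return named percent vector, one entry per class.
#' @export
classPrecision <- function(confusion) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion))
  colsum <- colSums(confusion)
  pre <- ifelse(colsum > 0, 100 * diag(confusion) / pmax(colsum, 1), 0)
  if (any(colsum == 0))
    message("class(es) never predicted, precision set to 0: ",
            paste(colnames(confusion)[colsum == 0], collapse = ", "))
  names(pre) <- colnames(confusion)
  pre
}

#' Average per-class precision (AP, percent)
#'
#' The unweighted mean of the per-class precisions.
#'
#' @inheritParams accuracy
#' @return percent in [0, 100].
#' @export
averagePrecision <- function(confusion) {
  mean(classPrecision(confusion))
}
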
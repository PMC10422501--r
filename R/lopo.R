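#' Leave-one-person-out (LOPO) evaluation
#'
#' Runs the LOPO protocol over a descriptor matrix aligned with a
#' manifest's records: each subject's clips form one test fold, all other
#' subjects' clips train a fresh one-vs-all linear SVM, every clip is
#' predicted exactly once, and the confusion matrix is pooled over folds.
#' Metrics (accuracy, per-class precision, AP) are computed from the pooled
#' matrix; per-fold accuracies are recorded in the fold log. Within every
#' fold it is asserted that the test subject contributes no training rows.
#'
#' @param manifest a [DatasetManifest-class] with at least two subjects.
#' @param descriptors n x d numeric matrix, row i describing clip i of
#'   `clipRecords(manifest)` (rows L2-normalised).
#' @param cost SVM misclassification cost C (default 1).
#' @param config optional configuration list echoed into the result.
#' @param skipBadFolds if a training fold contains fewer than two classes:
#'   `FALSE` (default) raise an error, `TRUE` log and skip the fold.
#' @return an [EvaluationResult-class].
#' @export
lopoEvaluate <- function(manifest, descriptors, cost = 1, config = list(),
                         skipBadFolds = FALSE) {
  stopifnot(is(manifest, "DatasetManifest"))
  records <- manifest@records
  descriptors <- as.matrix(descriptors)
  if (nrow(descriptors) != nrow(records))
    stop("descriptor rows (", nrow(descriptors),
         ") do not match manifest records (", nrow(records), ")", call. = FALSE)
  subjects <- manifest@subjects
  if (length(subjects) < 2)
    stop("LOPO requires at least 2 subjects; got ", length(subjects),
         call. = FALSE)
  if (length(manifest@classes) < 2)
    stop("classification requires at least 2 classes", call. = FALSE)
  truth <- character(0); predicted <- character(0)
  fold_log <- data.frame(subject = character(0), nTrain = integer(0),
                         nTest = integer(0), accuracy = numeric(0),
                         stringsAsFactors = FALSE)
  tested <- logical(nrow(records))
  for (s in subjects) {
    test_idx <- which(records$subject_id == s)
    train_idx <- which(records$subject_id != s)
    stopifnot(!any(records$subject_id[train_idx] == s))  # no subject leakage
    y_train <- records$label[train_idx]
    if (length(unique(y_train)) < 2) {
      msg <- paste0("fold '", s, "': training set has a single class")
      if (!skipBadFolds) stop(msg, call. = FALSE)
      warning(msg, "; fold skipped")
      next
    }
    model <- trainOvr(descriptors[train_idx, , drop = FALSE], y_train,
                      cost = cost, classes = manifest@classes)
    pred <- predict(model, descriptors[test_idx, , drop = FALSE])
    truth <- c(truth, records$label[test_idx])
    predicted <- c(predicted, pred)
    tested[test_idx] <- TRUE
    fold_log <- rbind(fold_log, data.frame(
      subject = s, nTrain = length(train_idx), nTest = length(test_idx),
      accuracy = 100 * mean(pred == records$label[test_idx]),
      stringsAsFactors = FALSE))
  }
  conf <- confusionMatrix(truth, predicted, classes = manifest@classes)
  pre <- suppressMessages(classPrecision(conf))
  new("EvaluationResult", confusion = conf, accuracy = accuracy(conf),
      classPrecision = pre, averagePrecision = mean(pre),
      foldLog = fold_log, config = config)
}

#' Serialise an EvaluationResult
#'
#' Writes `<prefix>.json` (confusion matrix, metrics, fold log, and the
#' full configuration echo including seeds and the backbone identifier) and
#' `<prefix>_confusion.csv`.
#'
#' @param result an [EvaluationResult-class].
#' @param prefix output path prefix.
#' @return character vector of the two paths written, invisibly.
#' @export
writeEvaluationResult <- function(result, prefix) {
  stopifnot(is(result, "EvaluationResult"))
  json_path <- paste0(prefix, ".json")
  csv_path <- paste0(prefix, "_confusion.csv")
  payload <- list(
    accuracy = result@accuracy,
    average_precision = result@averagePrecision,
    class_precision = as.list(result@classPrecision),
    confusion = unname(apply(result@confusion, 1, as.integer, simplify = FALSE)),
    classes = colnames(result@confusion),
    fold_log = result@foldLog,
    config = result@config)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(result@confusion, csv_path)
  invisible(c(json_path, csv_path))
}
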
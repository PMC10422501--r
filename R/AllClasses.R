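#' @import methods
NULL

#' FeatureMapStack: per-frame convolutional activation grid
#'
#' A three-dimensional activation array of shape cells x cells x channels,
#' as emitted by the last convolutional block of an image CNN for one frame
#' (7 x 7 x 512 for VGG16 pool5). This is the input to the regional spatial
#' pooling operators.
#'
#' @slot .Data numeric array (H_cells, W_cells, C); all values finite.
#' @export
setClass("FeatureMapStack", contains = "array", validity = function(object) {
  d <- dim(object@.Data)
  if (length(d) != 3) return("values must be a 3-d array (rows, cols, channels)")
  if (any(d < 1)) return("all dimensions must be positive")
  if (!all(is.finite(object@.Data))) return("all activations must be finite")
  TRUE
})

#' Construct a FeatureMapStack
#'
#' @param values numeric 3-d array (grid rows, grid cols, channels).
#' @return A [FeatureMapStack-class] object.
#' @examples
#' fm <- FeatureMapStack(array(runif(7 * 7 * 512), c(7, 7, 512)))
#' dim(fm)
#' @export
FeatureMapStack <- function(values) {
  new("FeatureMapStack", values)
}

#' @describeIn FeatureMapStack-class number of channels
#' @param x a FeatureMapStack
#' @export
nChannels <- function(x) dim(x)[3]

#' @describeIn FeatureMapStack-class spatial grid dimensions (rows, cols)
#' @export
gridDim <- function(x) dim(x)[1:2]

setMethod("show", "FeatureMapStack", function(object) {
  d <- dim(object)
  cat(sprintf("FeatureMapStack: %d x %d cells, %d channels\n", d[1], d[2], d[3]))
  cat(sprintf("  activation range [%.4g, %.4g]\n", min(object), max(object)))
})

#' DatasetManifest: clip records with subject and activity annotation
#'
#' Holds one row per pre-segmented video clip: an opaque clip identifier,
#' a file-system path (frame directory), the subject who recorded it, the
#' activity label, and the native frame rate. The class set is the sorted
#' distinct labels; the subject set is the distinct subject identifiers in
#' order of first appearance.
#'
#' @slot records data.frame with columns clip_id, path, subject_id, label,
#'   native_fps; row order is preserved from the source file.
#' @slot classes character, sorted distinct labels.
#' @slot subjects character, distinct subject identifiers.
#' @export
setClass("DatasetManifest",
  representation(records = "data.frame", classes = "character",
                 subjects = "character"),
  validity = function(object) {
    req <- c("clip_id", "path", "subject_id", "label", "native_fps")
    missing <- setdiff(req, names(object@records))
    if (length(missing)) return(paste("missing column(s):", paste(missing, collapse = ", ")))
    if (nrow(object@records) == 0) return("manifest has no records")
    if (anyDuplicated(object@records$clip_id))
      return("duplicate clip_id in manifest")
    if (!is.numeric(object@records$native_fps) ||
        any(!is.finite(object@records$native_fps)) ||
        any(object@records$native_fps <= 0))
      return("native_fps must be a positive finite number")
    if (!identical(object@classes, sort(unique(object@records$label))))
      return("classes must equal the sorted distinct labels")
    TRUE
  })

#' Construct a DatasetManifest from a record table
#'
#' @param records data.frame with columns clip_id, path, subject_id, label,
#'   native_fps.
#' @return A [DatasetManifest-class] object.
#' @export
DatasetManifest <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("clip_id", "path", "subject_id", "label"))
    if (col %in% names(records)) records[[col]] <- as.character(records[[col]])
  if ("native_fps" %in% names(records))
    records$native_fps <- as.numeric(records$native_fps)
  new("DatasetManifest", records = records,
      classes = sort(unique(as.character(records$label))),
      subjects = unique(as.character(records$subject_id)))
}

#' @describeIn DatasetManifest-class the per-clip record table
#' @param manifest a DatasetManifest
#' @export
clipRecords <- function(manifest) manifest@records

#' @describeIn DatasetManifest-class sorted distinct activity labels
#' @export
classLabels <- function(manifest) manifest@classes

#' @describeIn DatasetManifest-class distinct subject identifiers
#' @export
subjectIds <- function(manifest) manifest@subjects

setMethod("show", "DatasetManifest", function(object) {
  cat(sprintf("DatasetManifest: %d clips, %d subjects, %d classes\n",
              nrow(object@records), length(object@subjects), length(object@classes)))
  cat("  classes:", paste(object@classes, collapse = ", "), "\n")
})

setMethod("length", "DatasetManifest", function(x) nrow(x@records))

#' FlowField: dense per-pixel displacement field
#'
#' Horizontal (u, positive rightwards along columns) and vertical
#' (v, positive downwards along rows) displacement in pixels per frame
#' interval, one value per pixel.
#'
#' @slot u matrix of horizontal displacements.
#' @slot v matrix of vertical displacements.
#' @export
setClass("FlowField", representation(u = "matrix", v = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@u), dim(object@v)))
      return("u and v must have identical dimensions")
    if (!all(is.finite(object@u)) || !all(is.finite(object@v)))
      return("flow components must be finite")
    TRUE
  })

#' Construct a FlowField
#' @param u,v matrices of horizontal / vertical displacement (pixels).
#' @return A [FlowField-class] object.
#' @export
FlowField <- function(u, v) new("FlowField", u = u, v = v)

#' @describeIn FlowField-class horizontal displacement component
#' @param x a FlowField
#' @export
flowU <- function(x) x@u

#' @describeIn FlowField-class vertical displacement component
#' @export
flowV <- function(x) x@v

setMethod("show", "FlowField", function(object) {
  mag <- sqrt(object@u^2 + object@v^2)
  cat(sprintf("FlowField: %d x %d px, |flow| max %.3f median %.3f\n",
              nrow(object@u), ncol(object@u), max(mag), stats::median(mag)))
})

#' ClipDescriptor: fixed-length per-clip feature vector
#'
#' The result of temporal pooling of a clip's per-frame descriptors:
#' a two-level temporal pyramid ("tpmm", 3 x frame dimension), or plain
#' elementwise "max" / "mean" over frames (1 x frame dimension). Fused
#' descriptors concatenate the appearance and motion streams.
#'
#' @slot values numeric vector.
#' @slot poolingTag one of "tpmm", "max", "mean".
#' @slot modalityTag one of "appearance", "motion", "fused".
#' @slot nFrames number of frames pooled.
#' @export
setClass("ClipDescriptor",
  representation(values = "numeric", poolingTag = "character",
                 modalityTag = "character", nFrames = "integer"),
  validity = function(object) {
    if (!object@poolingTag %in% c("tpmm", "max", "mean"))
      return("poolingTag must be one of tpmm, max, mean")
    if (!object@modalityTag %in% c("appearance", "motion", "fused"))
      return("modalityTag must be one of appearance, motion, fused")
    if (!all(is.finite(object@values))) return("values must be finite")
    if (object@nFrames < 1L) return("nFrames must be >= 1")
    TRUE
  })

#' @describeIn ClipDescriptor-class the numeric feature vector
#' @param x a ClipDescriptor
#' @export
descriptorValues <- function(x) x@values

#' @describeIn ClipDescriptor-class the temporal pooling tag
#' @export
poolingTag <- function(x) x@poolingTag

#' @describeIn ClipDescriptor-class the modality tag
#' @export
modalityTag <- function(x) x@modalityTag

setMethod("show", "ClipDescriptor", function(object) {
  cat(sprintf("ClipDescriptor: %s/%s, length %d, %d frame(s), L2 norm %.4f\n",
              object@poolingTag, object@modalityTag, length(object@values),
              object@nFrames, sqrt(sum(object@values^2))))
})

setMethod("length", "ClipDescriptor", function(x) length(x@values))

#' OvRModel: one-vs-all linear SVM ensemble
#'
#' One binary linear scorer (weight vector plus bias) per activity class;
#' prediction is the argmax of the per-class decision values, with exact
#' ties broken by class order.
#'
#' @slot weights d x Nc matrix, one column per class.
#' @slot bias numeric vector of length Nc.
#' @slot classes character vector of class labels (column order).
#' @slot cost misclassification cost C used at training.
#' @export
setClass("OvRModel",
  representation(weights = "matrix", bias = "numeric", classes = "character",
                 cost = "numeric"),
  validity = function(object) {
    if (ncol(object@weights) != length(object@classes))
      return("one weight column per class required")
    if (length(object@bias) != length(object@classes))
      return("one bias per class required")
    TRUE
  })

#' @describeIn OvRModel-class class labels in scorer order
#' @param x an OvRModel
#' @export
modelClasses <- function(x) x@classes

setMethod("show", "OvRModel", function(object) {
  cat(sprintf("OvRModel: %d classes, feature dim %d, cost C = %g\n",
              length(object@classes), nrow(object@weights), object@cost))
})

#' EvaluationResult: pooled confusion matrix and summary metrics
#'
#' The outcome of leave-one-person-out evaluation: the confusion matrix
#' pooled over all folds (rows = ground truth, columns = prediction),
#' overall accuracy, per-class precision, average per-class precision (AP),
#' a per-fold log, and an echo of the run configuration.
#'
#' @slot confusion Nc x Nc integer matrix.
#' @slot accuracy percent in [0, 100].
#' @slot classPrecision named percent vector, one entry per class.
#' @slot averagePrecision percent in [0, 100].
#' @slot foldLog data.frame: subject, nTrain, nTest, accuracy per fold.
#' @slot config list, the configuration the result was computed under.
#' @export
setClass("EvaluationResult",
  representation(confusion = "matrix", accuracy = "numeric",
                 classPrecision = "numeric", averagePrecision = "numeric",
                 foldLog = "data.frame", config = "list"),
  validity = function(object) {
    if (nrow(object@confusion) != ncol(object@confusion))
      return("confusion matrix must be square")
    if (is.finite(object@accuracy) &&
        (object@accuracy < 0 || object@accuracy > 100))
      return("accuracy must be a percentage in [0, 100]")
    if (length(object@classPrecision) != nrow(object@confusion))
      return("one precision per class required")
    TRUE
  })

#' @describeIn EvaluationResult-class the pooled confusion matrix
#' @param x an EvaluationResult
#' @export
confusionCounts <- function(x) x@confusion

#' @describeIn EvaluationResult-class per-class precision (percent)
#' @export
classPrecisionOf <- function(x) x@classPrecision

#' @describeIn EvaluationResult-class the per-fold log
#' @export
foldLog <- function(x) x@foldLog

setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf("EvaluationResult: %d classes, N = %d clips, %d folds\n",
              nrow(object@confusion), sum(object@confusion), nrow(object@foldLog)))
  cat(sprintf("  accuracy %.2f%%   AP %.2f%%\n",
              object@accuracy, object@averagePrecision))
})
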
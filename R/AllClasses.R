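#' @import methods
#' @importFrom stats runif rnorm prcomp cor dist sd var t.test pf predict
#' @importFrom utils head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Labeled trial-by-feature matrix
#'
#' The universal input container: an \code{m} trials by \code{n} features
#' numeric matrix together with one integer class label per trial. Built on
#' \linkS4class{SummarizedExperiment}, with features stored as assay rows and
#' trials as columns, so the usual Bioconductor subsetting and metadata
#' machinery applies. Labels are zero-based (\code{0 .. k-1}) internally.
#'
#' @slot .Data inherited \code{SummarizedExperiment} structure: one assay
#'   named \code{"features"} (n features x m trials), \code{colData} column
#'   \code{label}, and \code{metadata} entries \code{classCount} and
#'   \code{splitTag}.
#'
#' @seealso [LabeledMatrix()] for construction, [features()], [labels()],
#'   [classCount()], [splitTag()] for access.
#' @export
setClass("LabeledMatrix", contains = "SummarizedExperiment")

setValidity("LabeledMatrix", function(object) {
  msg <- character()
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData column 'label' is required")
  md <- S4Vectors::metadata(object)
  if (is.null(md$classCount))
    msg <- c(msg, "metadata 'classCount' is required")
  if (is.null(md$splitTag) || !md$splitTag %in% c("train", "test"))
    msg <- c(msg, "metadata 'splitTag' must be 'train' or 'test'")
  if (!length(msg)) {
    x <- SummarizedExperiment::assay(object, "features")
    lab <- object$label
    k <- md$classCount
    if (!all(is.finite(x)))
      msg <- c(msg, "features contain non-finite values")
    if (anyNA(lab) || any(lab < 0L) || any(lab >= k))
      msg <- c(msg, sprintf("labels must lie in 0..%d", k - 1L))
  }
  if (length(msg)) msg else TRUE
})

#' Model architecture and training configuration
#'
#' Describes one model to be fitted: its family (\code{"TRACE"}, \code{"AE"},
#' \code{"VAE"} or \code{"PCA"}), layer widths, the classifier-loss weight
#' \code{alpha} (TRACE only) and the optimisation hyperparameters. PCA
#' ignores all training hyperparameters; \code{alpha} is ignored unless the
#' family is TRACE.
#'
#' @slot family character, one of TRACE, AE, VAE, PCA.
#' @slot inputDim integer n, number of input features.
#' @slot hiddenDim integer, width of the single hidden layer on each of the
#'   encoding and decoding arms (identical across TRACE/AE/VAE so the
#'   comparators are complexity-matched).
#' @slot bottleneckDim integer d, width of the bottleneck.
#' @slot classCount integer k; required for TRACE.
#' @slot alpha numeric >= 0, weight of the cross-entropy term.
#' @slot outputActivation "linear" or "logistic" reconstruction output.
#' @slot klWeight numeric, weight of the VAE KL term.
#' @slot epochs,batchSize,learningRate,patience,tol training hyperparameters
#'   (Adam optimiser; early stop once the full-data loss improves by less
#'   than \code{tol} relative over \code{patience} consecutive epochs).
#' @slot seed integer master seed for initialisation and batch order.
#' @export
setClass("ModelConfig",
  representation(
    family = "character",
    inputDim = "integer",
    hiddenDim = "integer",
    bottleneckDim = "integer",
    classCount = "integer",
    alpha = "numeric",
    outputActivation = "character",
    klWeight = "numeric",
    epochs = "integer",
    batchSize = "integer",
    learningRate = "numeric",
    patience = "integer",
    tol = "numeric",
    seed = "integer"
  )
)

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (!object@family %in% c("TRACE", "AE", "VAE", "PCA"))
    msg <- c(msg, "family must be one of TRACE, AE, VAE, PCA")
  if (object@bottleneckDim > object@inputDim)
    msg <- c(msg, "bottleneckDim must not exceed inputDim")
  if (object@bottleneckDim < 1L)
    msg <- c(msg, "bottleneckDim must be >= 1")
  if (object@alpha < 0)
    msg <- c(msg, "alpha must be >= 0")
  if (!object@outputActivation %in% c("linear", "logistic"))
    msg <- c(msg, "outputActivation must be 'linear' or 'logistic'")
  if (object@family == "TRACE" && object@classCount < 2L)
    msg <- c(msg, "TRACE requires classCount >= 2")
  if (length(msg)) msg else TRUE
})

#' Fitted model classes
#'
#' \code{TrainedModel} is the virtual parent of the four fitted-model
#' classes. Network families store their weights as a named list of matrices
#' and vectors; PCA stores the centering vector and rotation. All expose
#' [encode()] (to the bottleneck) and [reconstruct()] (back to input space),
#' and the network families carry the per-epoch training-loss trace.
#'
#' @slot config the \linkS4class{ModelConfig} used for fitting.
#' @slot lossTrace numeric, full-data training objective per epoch (empty for
#'   PCA).
#' @export
setClass("TrainedModel",
  representation("VIRTUAL",
    config = "ModelConfig",
    lossTrace = "numeric"
  )
)

#' @rdname TrainedModel-class
#' @slot params named list of weight matrices/bias vectors.
#' @export
setClass("TraceModel", contains = "TrainedModel",
  representation(params = "list"))

#' @rdname TrainedModel-class
#' @export
setClass("AEModel", contains = "TrainedModel",
  representation(params = "list"))

#' @rdname TrainedModel-class
#' @export
setClass("VAEModel", contains = "TrainedModel",
  representation(params = "list"))

#' @rdname TrainedModel-class
#' @slot center numeric length-n centering vector.
#' @slot rotation n x d loading matrix.
#' @export
setClass("PCAModel", contains = "TrainedModel",
  representation(center = "numeric", rotation = "matrix"))

#' Per-class cluster-separation effect sizes
#'
#' Cohen's d comparing mean pairwise within-class against between-class
#' Euclidean distances, per class, in one representation space. Tight
#' clusters give a negative signed value (within distances smaller than
#' between); the summary follows the magnitude convention, with the signed
#' per-class values retained.
#'
#' @slot perClass named numeric, signed d per class.
#' @slot meanAbs,sdAbs mean and SD of |d| across classes.
#' @slot meanSigned mean signed d across classes.
#' @slot space one of "bottleneck", "reconstruction", "input".
#' @export
setClass("EffectSizeReport",
  representation(
    perClass = "numeric",
    meanAbs = "numeric",
    sdAbs = "numeric",
    meanSigned = "numeric",
    space = "character"
  )
)

#' Sweep grid and result containers
#'
#' \code{SweepGrid} fixes everything a benchmark run needs: the bottleneck
#' dimensionalities, model families, truncation fractions with their
#' jack-knife replicate count, and the master seed. \code{SweepResult} holds
#' one row per grid cell in \code{metrics} (the four outcome metrics plus the
#' input-space baselines) and per cell and space in \code{effectSizes},
#' together with provenance (seeds, per-cell failures).
#'
#' @slot dims strictly increasing integer vector of bottleneck widths.
#' @slot families character subset of TRACE/AE/VAE/PCA.
#' @slot fractions truncation fractions removed, each in [0, 1).
#' @slot replicateCount jack-knife replicates used at the largest fraction.
#' @slot seed master seed; all per-cell seeds derive from it.
#' @export
setClass("SweepGrid",
  representation(
    dims = "integer",
    families = "character",
    fractions = "numeric",
    replicateCount = "integer",
    seed = "integer"
  )
)

setValidity("SweepGrid", function(object) {
  msg <- character()
  if (is.unsorted(object@dims, strictly = TRUE))
    msg <- c(msg, "dims must be strictly increasing")
  if (!all(object@families %in% c("TRACE", "AE", "VAE", "PCA")))
    msg <- c(msg, "unknown model family")
  if (any(object@fractions < 0 | object@fractions >= 1))
    msg <- c(msg, "fractions must lie in [0, 1)")
  if (object@replicateCount < 1L)
    msg <- c(msg, "replicateCount must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname SweepGrid-class
#' @slot metrics data.frame of outcome metrics, one row per cell.
#' @slot effectSizes data.frame of Cohen's d summaries, one row per cell and
#'   space.
#' @slot provenance list: grid settings, seeds, failures, timestamp.
#' @export
setClass("SweepResult",
  representation(
    metrics = "data.frame",
    effectSizes = "data.frame",
    provenance = "list"
  )
)
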
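#' Construct a LabeledMatrix
#'
#' @param features numeric matrix, m trials x n features.
#' @param labels integer vector of length m with class indices. Zero-based
#'   labels are kept as-is; a vector whose smallest value is 1 and largest is
#'   its class count is remapped to zero-based.
#' @param splitTag "train" or "test".
#' @param classCount integer k; defaults to the number of distinct labels
#'   observed (classes are assumed contiguous from 0).
#' @return a \linkS4class{LabeledMatrix}.
#' @examples
#' lm <- LabeledMatrix(matrix(rnorm(20), 5), labels = c(0, 0, 1, 1, 1))
#' features(lm)
#' labels(lm)
#' @export
LabeledMatrix <- function(features, labels,
                          splitTag = c("train", "test"),
                          classCount = NULL) {
  splitTag <- match.arg(splitTag)
  if (!is.matrix(features)) features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.integer(round(labels))
  if (length(labels) != nrow(features))
    stop("length(labels) must equal nrow(features)")
  if (length(labels) && min(labels) == 1L) # 1-based input remapped
    labels <- labels - 1L
  if (is.null(classCount)) classCount <- max(labels) + 1L
  classCount <- as.integer(classCount)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(features)),
    colData = S4Vectors::DataFrame(label = labels)
  )
  S4Vectors::metadata(se) <- list(classCount = classCount, splitTag = splitTag)
  new("LabeledMatrix", se)
}

#' @rdname features
#' @export
setMethod("features", "LabeledMatrix", function(x) {
  m <- t(SummarizedExperiment::assay(x, "features"))
  dimnames(m) <- NULL
  m
})

#' Per-trial class labels (zero-based)
#' @param object a \linkS4class{LabeledMatrix}.
#' @param ... unused.
#' @return integer vector of length m.
#' @export
setMethod("labels", "LabeledMatrix", function(object, ...) {
  as.integer(object$label)
})

#' @rdname classCount
#' @export
setMethod("classCount", "LabeledMatrix", function(x) {
  as.integer(S4Vectors::metadata(x)$classCount)
})

#' @rdname splitTag
#' @export
setMethod("splitTag", "LabeledMatrix", function(x) {
  S4Vectors::metadata(x)$splitTag
})

setMethod("show", "LabeledMatrix", function(object) {
  cat(sprintf(
    "LabeledMatrix: %d trials x %d features, %d classes (%s split)\n",
    ncol(object), nrow(object), classCount(object), splitTag(object)
  ))
  tab <- table(labels(object))
  cat("  trials per class:", paste(head(as.integer(tab), 10L), collapse = " "),
      if (length(tab) > 10L) "..." else "", "\n")
})

#' Subset trials of a LabeledMatrix
#'
#' @param x a \linkS4class{LabeledMatrix}.
#' @param i integer or logical trial index.
#' @return a \linkS4class{LabeledMatrix} with the selected trials.
#' @export
subsetTrials <- function(x, i) {
  out <- x[, i]
  S4Vectors::metadata(out) <- S4Vectors::metadata(x)
  new("LabeledMatrix", out)
}

#' Z-score features using training-split moments
#'
#' Standardizes each feature to mean 0, SD 1 using moments computed on the
#' training split only, then applies the same affine map to the test split —
#' the usual MVPA normalization for tabular voxel-pattern data. Constant
#' features are centered and left unscaled.
#'
#' @param train,test \linkS4class{LabeledMatrix} objects (test optional).
#' @return a list with standardized \code{train} and (if given) \code{test}.
#' @export
standardizeFeatures <- function(train, test = NULL) {
  X <- features(train)
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  scaleIt <- function(d) {
    M <- features(d)
    M <- .addBias(M, -mu) / rep(sdv, each = nrow(M))
    LabeledMatrix(M, labels(d), splitTag = splitTag(d),
                  classCount = classCount(d))
  }
  out <- list(train = scaleIt(train))
  if (!is.null(test)) out$test <- scaleIt(test)
  out
}
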
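#' Create a model configuration
#'
#' @param family "TRACE", "AE", "VAE" or "PCA".
#' @param inputDim n input features.
#' @param bottleneckDim d, bottleneck width (<= inputDim).
#' @param classCount k classes (required for TRACE).
#' @param hiddenDim hidden-layer width on each arm; default 512 for 784-dim
#'   inputs and \code{min(inputDim, 1024)} otherwise, identical across
#'   TRACE/AE/VAE so the comparison models are complexity-matched.
#' @param alpha classifier-loss weight (TRACE only), default 1.
#' @param outputActivation "linear" (z-scored tabular data) or "logistic"
#'   ([0,1] image data); matches the output range to the input range.
#' @param klWeight VAE KL-term weight, default 1.
#' @param epochs,batchSize,learningRate Adam training hyperparameters.
#' @param patience,tol early stopping: stop when the full-data loss improves
#'   by less than \code{tol} (relative) over \code{patience} epochs.
#' @param seed master seed for initialisation, batch order and VAE sampling.
#' @return a \linkS4class{ModelConfig}.
#' @examples
#' cfg <- modelConfig("TRACE", inputDim = 50, bottleneckDim = 2,
#'                    classCount = 4, epochs = 10)
#' @export
modelConfig <- function(family, inputDim, bottleneckDim,
                        classCount = 0L,
                        hiddenDim = NULL,
                        alpha = 1,
                        outputActivation = c("linear", "logistic"),
                        klWeight = 1,
                        epochs = 100L, batchSize = 128L,
                        learningRate = 1e-3,
                        patience = 10L, tol = 1e-5,
                        seed = 1L) {
  outputActivation <- match.arg(outputActivation)
  if (is.null(hiddenDim))
    hiddenDim <- if (inputDim == 784L) 512L else min(inputDim, 1024L)
  new("ModelConfig",
      family = family,
      inputDim = as.integer(inputDim),
      hiddenDim = as.integer(hiddenDim),
      bottleneckDim = as.integer(bottleneckDim),
      classCount = as.integer(classCount),
      alpha = alpha,
      outputActivation = outputActivation,
      klWeight = klWeight,
      epochs = as.integer(epochs),
      batchSize = as.integer(batchSize),
      learningRate = learningRate,
      patience = as.integer(patience),
      tol = tol,
      seed = as.integer(seed))
}

#' @rdname fitModel
#' @export
setMethod("fitModel", signature(config = "ModelConfig", train = "LabeledMatrix"),
  function(config, train, ...) {
    X <- features(train)
    if (ncol(X) != config@inputDim)
      stop("train has ", ncol(X), " features but config expects ",
           config@inputDim)
    if (config@family == "TRACE" &&
        classCount(train) != config@classCount)
      stop("train has ", classCount(train),
           " classes but config expects ", config@classCount)
    if (config@family == "PCA") {
      pc <- prcomp(X, center = TRUE, scale. = FALSE,
                   rank. = config@bottleneckDim)
      rot <- pc$rotation
      dimnames(rot) <- NULL
      if (ncol(rot) < config@bottleneckDim) { # rank-deficient data: pad
        pad <- matrix(0, nrow(rot), config@bottleneckDim - ncol(rot))
        rot <- cbind(rot, pad)
      }
      return(new("PCAModel", config = config, lossTrace = numeric(0),
                 center = unname(pc$center), rotation = rot))
    }
    Y <- if (config@family == "TRACE")
      .onehot(labels(train), config@classCount) else NULL
    fit <- .trainNetwork(config, X, Y)
    cls <- switch(config@family, TRACE = "TraceModel", AE = "AEModel",
                  VAE = "VAEModel")
    new(cls, config = config, lossTrace = fit$lossTrace,
        params = fit$params)
  })

.checkWidth <- function(model, X) {
  X <- .assertMatrix(X)
  if (ncol(X) != model@config@inputDim)
    stop("X has ", ncol(X), " columns but the model expects ",
         model@config@inputDim)
  X
}

#' @rdname encode
#' @export
setMethod("encode", "TraceModel", function(model, X) {
  .encodeNet(model@params, .checkWidth(model, X))
})

#' @rdname encode
#' @export
setMethod("encode", "AEModel", function(model, X) {
  .encodeNet(model@params, .checkWidth(model, X))
})

#' @rdname encode
#' @export
setMethod("encode", "VAEModel", function(model, X) {
  # posterior mean: the deterministic encoding used at evaluation time
  .encodeNet(model@params, .checkWidth(model, X))
})

#' @rdname encode
#' @export
setMethod("encode", "PCAModel", function(model, X) {
  X <- .checkWidth(model, X)
  .addBias(X, -model@center) %*% model@rotation
})

#' @rdname reconstruct
#' @export
setMethod("reconstruct", "TraceModel", function(model, X) {
  .decodeNet(model@params, encode(model, X),
             model@config@outputActivation)
})

#' @rdname reconstruct
#' @export
setMethod("reconstruct", "AEModel", function(model, X) {
  .decodeNet(model@params, encode(model, X),
             model@config@outputActivation)
})

#' @rdname reconstruct
#' @export
setMethod("reconstruct", "VAEModel", function(model, X) {
  .decodeNet(model@params, encode(model, X),
             model@config@outputActivation)
})

#' @rdname reconstruct
#' @export
setMethod("reconstruct", "PCAModel", function(model, X) {
  .addBias(tcrossprod(encode(model, X), model@rotation), model@center)
})

#' Bottleneck classifier probabilities (TRACE only)
#'
#' Softmax output of the classifier head attached to the bottleneck.
#'
#' @param model a fitted \linkS4class{TraceModel}.
#' @param X input matrix or \linkS4class{LabeledMatrix}.
#' @return m x k matrix of class probabilities (rows sum to 1).
#' @export
classProbabilities <- function(model, X) {
  if (!is(model, "TraceModel"))
    stop("classProbabilities is only defined for TRACE models")
  Z <- encode(model, X)
  .softmax(.addBias(Z %*% model@params$Wc, model@params$bc))
}

setMethod("show", "TrainedModel", function(object) {
  cfg <- object@config
  cat(sprintf("%s model: %d -> %d -> %d%s\n", cfg@family, cfg@inputDim,
              cfg@hiddenDim, cfg@bottleneckDim,
              if (cfg@family == "TRACE")
                sprintf(" (+%d-class head, alpha=%g)",
                        cfg@classCount, cfg@alpha) else ""))
  if (length(object@lossTrace))
    cat(sprintf("  trained %d epochs, final loss %.6g\n",
                length(object@lossTrace),
                object@lossTrace[length(object@lossTrace)]))
})

setMethod("show", "PCAModel", function(object) {
  cfg <- object@config
  cat(sprintf("PCA model: %d features -> %d components\n",
              cfg@inputDim, ncol(object@rotation)))
})

#' Save / load a fitted model
#'
#' Serializes a fitted model to a versioned plain-text container: a JSON
#' metadata file (family, configuration, seed) plus flat weight arrays.
#' Models reload without retraining.
#'
#' @param model a \linkS4class{TrainedModel}.
#' @param path output file (JSON).
#' @return \code{path} invisibly, or the reloaded model.
#' @export
saveModel <- function(model, path) {
  cfg <- model@config
  meta <- list(
    container = "TRACEkit-model", version = 1L,
    family = cfg@family,
    config = list(inputDim = cfg@inputDim, hiddenDim = cfg@hiddenDim,
                  bottleneckDim = cfg@bottleneckDim,
                  classCount = cfg@classCount, alpha = cfg@alpha,
                  outputActivation = cfg@outputActivation,
                  klWeight = cfg@klWeight, epochs = cfg@epochs,
                  batchSize = cfg@batchSize,
                  learningRate = cfg@learningRate,
                  patience = cfg@patience, tol = cfg@tol, seed = cfg@seed),
    lossTrace = model@lossTrace
  )
  if (is(model, "PCAModel")) {
    meta$center <- model@center
    meta$rotation <- list(dim = dim(model@rotation),
                          values = as.numeric(model@rotation))
  } else {
    meta$params <- lapply(model@params, function(w)
      list(dim = if (is.matrix(w)) dim(w) else length(w),
           values = as.numeric(w)))
  }
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(meta$container, "TRACEkit-model"))
    stop("not a TRACEkit model container: ", path)
  cf <- meta$config
  cfg <- modelConfig(meta$family, cf$inputDim, cf$bottleneckDim,
                     classCount = cf$classCount, hiddenDim = cf$hiddenDim,
                     alpha = cf$alpha,
                     outputActivation = cf$outputActivation,
                     klWeight = cf$klWeight, epochs = cf$epochs,
                     batchSize = cf$batchSize,
                     learningRate = cf$learningRate,
                     patience = cf$patience, tol = cf$tol, seed = cf$seed)
  lt <- as.numeric(meta$lossTrace)
  if (meta$family == "PCA") {
    rot <- matrix(meta$rotation$values, meta$rotation$dim[1],
                  meta$rotation$dim[2])
    return(new("PCAModel", config = cfg, lossTrace = lt,
               center = as.numeric(meta$center), rotation = rot))
  }
  params <- lapply(meta$params, function(w) {
    if (length(w$dim) == 2L) matrix(w$values, w$dim[1], w$dim[2])
    else as.numeric(w$values)
  })
  cls <- switch(meta$family, TRACE = "TraceModel", AE = "AEModel",
                VAE = "VAEModel")
  new(cls, config = cfg, lossTrace = lt, params = params)
}
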
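#' @name TRACEkit-generics
#' @title Generics for data containers and fitted models
NULL

#' Extract the trials-by-features matrix
#' @param x a \linkS4class{LabeledMatrix}.
#' @return numeric matrix, m trials x n features.
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' Number of classes
#' @param x a \linkS4class{LabeledMatrix}.
#' @return integer k.
#' @export
setGeneric("classCount", function(x) standardGeneric("classCount"))

#' Train/test split tag
#' @param x a \linkS4class{LabeledMatrix}.
#' @return "train" or "test".
#' @export
setGeneric("splitTag", function(x) standardGeneric("splitTag"))

#' Fit a model to labeled training data
#'
#' Dispatches on the family in \code{config}: the supervised autoencoder
#' (TRACE) minimises reconstruction MSE plus \code{alpha} times the
#' cross-entropy of its bottleneck classifier; AE minimises MSE alone with
#' identical layer sizes; VAE minimises MSE plus a KL term for its
#' diagonal-Gaussian bottleneck; PCA projects onto the top-d principal
#' components of the centered training data.
#'
#' @param config a \linkS4class{ModelConfig}.
#' @param train a \linkS4class{LabeledMatrix}.
#' @param ... unused.
#' @return a \linkS4class{TrainedModel} subclass.
#' @export
setGeneric("fitModel", function(config, train, ...) standardGeneric("fitModel"))

#' Map inputs to the bottleneck representation
#'
#' Deterministic given the fitted model: the VAE returns the posterior mean,
#' PCA the centered projection onto the retained components.
#'
#' @param model a fitted \linkS4class{TrainedModel}.
#' @param X numeric matrix (m x inputDim) or a \linkS4class{LabeledMatrix}.
#' @return numeric matrix, m x bottleneckDim.
#' @export
setGeneric("encode", function(model, X) standardGeneric("encode"))

#' Map inputs through the bottleneck back to input space
#'
#' \code{reconstruct(model, X)} equals decoding \code{encode(model, X)}.
#'
#' @inheritParams encode
#' @return numeric matrix, m x inputDim.
#' @export
setGeneric("reconstruct", function(model, X) standardGeneric("reconstruct"))
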
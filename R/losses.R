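#' Reconstruction mean squared error
#'
#' \deqn{L_R = \frac{1}{mn}\sum_{i=1}^m\sum_{j=1}^n (\hat X_{ij} - X_{ij})^2}
#'
#' @param X input matrix, m x n.
#' @param Xhat reconstruction, same shape.
#' @return non-negative scalar; symmetric in its arguments.
#' @export
reconstructionLoss <- function(X, Xhat) {
  X <- .assertMatrix(X); Xhat <- .assertMatrix(Xhat, "Xhat")
  if (!identical(dim(X), dim(Xhat)))
    stop("X and Xhat must have the same shape")
  mean((Xhat - X)^2)
}

#' Categorical cross-entropy
#'
#' \deqn{L_{CE} = -\frac{1}{m}\sum_{i=1}^m\sum_{c=1}^k y_{ci}\log \hat y_{ci}}
#' Predicted probabilities are clipped below at 1e-12 inside the log, so the
#' loss is never infinite.
#'
#' @param yOnehot m x k one-hot label matrix.
#' @param yHat m x k matrix of predicted class probabilities (rows sum to 1).
#' @return non-negative scalar; 0 iff predictions are exactly one-hot
#'   correct.
#' @export
crossEntropyLoss <- function(yOnehot, yHat) {
  if (!identical(dim(yOnehot), dim(yHat)))
    stop("yOnehot and yHat must have the same shape")
  rs <- rowSums(yHat)
  if (any(abs(rs - 1) > 1e-6))
    stop("each row of yHat must sum to 1")
  -sum(yOnehot * log(pmax(yHat, 1e-12))) / nrow(yOnehot)
}

#' Supervised-autoencoder objective
#'
#' The weighted sum \eqn{L_R + \alpha L_{CE}} minimised by the TRACE family:
#' reconstruction MSE plus \code{alpha} times the cross-entropy of the
#' bottleneck classifier. With \code{alpha = 0} it reduces exactly to the
#' standard autoencoder objective.
#'
#' @inheritParams reconstructionLoss
#' @inheritParams crossEntropyLoss
#' @param alpha classifier-loss weight, >= 0.
#' @return scalar objective value.
#' @export
traceObjective <- function(X, Xhat, yOnehot, yHat, alpha) {
  if (alpha < 0) stop("alpha must be >= 0")
  reconstructionLoss(X, Xhat) + alpha * crossEntropyLoss(yOnehot, yHat)
}
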
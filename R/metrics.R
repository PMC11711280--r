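#' Reconstruction fidelity
#'
#' Mean over trials of the Pearson correlation between each input row and
#' its reconstruction, computed across features. Trials with zero variance
#' in either row have no defined correlation and are excluded with a
#' warning.
#'
#' @param X input matrix, m x n (or a \linkS4class{LabeledMatrix}).
#' @param Xhat reconstruction, same shape.
#' @return scalar in [-1, 1].
#' @export
reconstructionFidelity <- function(X, Xhat) {
  X <- .assertMatrix(X); Xhat <- .assertMatrix(Xhat, "Xhat")
  if (!identical(dim(X), dim(Xhat)))
    stop("X and Xhat must have the same shape")
  ok <- apply(X, 1L, sd) > 0 & apply(Xhat, 1L, sd) > 0
  if (!all(ok))
    warning(sum(!ok), " zero-variance trial(s) excluded from fidelity")
  if (!any(ok)) return(NA_real_)
  rs <- vapply(which(ok), function(i) cor(X[i, ], Xhat[i, ]), numeric(1))
  mean(rs)
}

# All m x m pairwise between-trial Pearson correlations (trials correlated
# across features).
.trialCor <- function(X) cor(t(X))

#' Class specificity of a representation
#'
#' Builds all pairwise between-trial Pearson correlations, then returns the
#' mean over same-class pairs (self-pairs excluded) minus the mean over
#' different-class pairs. Applied to model reconstructions this is the
#' reconstruction class specificity used to pick the optimal bottleneck
#' width; applied to raw inputs it is the input-space baseline.
#'
#' @param X m x n matrix of trials (or a \linkS4class{LabeledMatrix}, whose
#'   labels are then used).
#' @param labelsVec integer class labels, length m (ignored when \code{X}
#'   carries its own).
#' @return scalar in [-2, 2].
#' @export
classSpecificity <- function(X, labelsVec = NULL) {
  if (is(X, "LabeledMatrix")) {
    if (is.null(labelsVec)) labelsVec <- labels(X)
    X <- features(X)
  }
  X <- .assertMatrix(X)
  m <- nrow(X)
  if (length(labelsVec) != m) stop("labels must match trial count")
  if (any(table(labelsVec) < 2L))
    stop("every class needs >= 2 trials")
  C <- .trialCor(X)
  same <- outer(labelsVec, labelsVec, "==")
  upper <- upper.tri(C)
  mean(C[upper & same]) - mean(C[upper & !same])
}

#' Post-hoc classifier configuration
#'
#' Settings for the L2-penalized multinomial logistic regression used as an
#' evaluation probe. The same fixed penalty is used for every model and
#' representation space so metric differences reflect the representations,
#' not classifier tuning.
#'
#' @param lambdaL2 L2 penalty weight on \eqn{\lambda \sum_r w_r^2} added to
#'   the per-sample negative log-likelihood; default 1.
#' @param maxIterations optimizer iteration cap.
#' @param tol convergence tolerance.
#' @return a list of class "PostHocClassifierConfig".
#' @export
postHocClassifierConfig <- function(lambdaL2 = 1, maxIterations = 1e5,
                                    tol = 1e-8) {
  stopifnot(lambdaL2 >= 0)
  structure(list(lambdaL2 = lambdaL2, maxIterations = maxIterations,
                 tol = tol),
            class = "PostHocClassifierConfig")
}

#' Post-hoc classifier accuracy
#'
#' Fits a multinomial logistic regression with ridge penalty on training
#' representations (strictly after, and independently of, the main model)
#' and returns top-1 accuracy on the held-out test representations. Serves
#' three roles: bottleneck classifier accuracy (representations =
#' \code{encode}), reconstruction classifier accuracy (representations =
#' \code{reconstruct}) and the input-space baseline (representations = raw
#' features).
#'
#' @param trainRepr,testRepr m x p representation matrices.
#' @param trainLabels,testLabels integer class labels (zero-based).
#' @param cfg a [postHocClassifierConfig()].
#' @return fraction correct in [0, 1].
#' @export
postHocClassifierAccuracy <- function(trainRepr, trainLabels,
                                      testRepr, testLabels,
                                      cfg = postHocClassifierConfig()) {
  trainRepr <- .assertMatrix(trainRepr, "trainRepr")
  testRepr <- .assertMatrix(testRepr, "testRepr")
  if (length(unique(trainLabels)) < 2L)
    stop("training labels contain a single class")
  pred <- .fitPosthocPredict(trainRepr, trainLabels, testRepr, cfg)$class
  mean(pred == testLabels)
}

# glmnet ridge multinomial behind the probe. glmnet minimises
# (1/m) NLL + lambda_g/2 * sum(w^2) for alpha = 0, so lambda_g = 2 * lambdaL2
# matches the lambda * sum(w^2) objective. Probe inputs are z-scored with
# training-representation moments (identically for every model and space):
# unconstrained bottlenecks can sit at arbitrary scale, and a fixed penalty
# is only comparable across representations on a common scale. glmnet needs
# >= 2 columns; a 1-column representation gets an all-zero companion column
# (its penalized weight stays 0, predictions unchanged).
.fitPosthocPredict <- function(trainRepr, trainLabels, testRepr, cfg) {
  mu <- colMeans(trainRepr)
  sdv <- apply(trainRepr, 2L, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  trainRepr <- .addBias(trainRepr, -mu) / rep(sdv, each = nrow(trainRepr))
  testRepr <- .addBias(testRepr, -mu) / rep(sdv, each = nrow(testRepr))
  if (ncol(trainRepr) < 2L) {
    trainRepr <- cbind(trainRepr, 0)
    testRepr <- cbind(testRepr, 0)
  }
  # warm-started decreasing lambda path ending at the target penalty;
  # single-lambda multinomial fits are numerically fragile in glmnet
  lamTarget <- max(2 * cfg$lambdaL2, 1e-8)
  lamSeq <- lamTarget * 10^seq(3, 0, length.out = 15L)
  fit <- glmnet::glmnet(trainRepr, factor(trainLabels),
                        family = "multinomial", alpha = 0,
                        lambda = lamSeq,
                        standardize = FALSE,
                        maxit = cfg$maxIterations, thresh = cfg$tol)
  link <- predict(fit, testRepr, type = "link", s = lamTarget)[, , 1L]
  if (is.null(dim(link))) link <- matrix(link, nrow = nrow(testRepr))
  cn <- colnames(link)
  prob <- .softmax(link) # overflow-safe
  colnames(prob) <- cn
  cls <- as.integer(colnames(prob)[max.col(prob, ties.method = "first")])
  list(class = cls, prob = prob)
}

#' Cluster-separation effect size (Cohen's d)
#'
#' For each class c, compares the mean pairwise Euclidean distance among
#' class-c trials (self-pairs excluded) with the mean distance between
#' class-c trials and all trials of other classes, standardized by the
#' pooled SD of the two distance samples:
#' \deqn{d_c = (\bar D_{w,c} - \bar D_b)/s.}
#' Tight clusters give negative \eqn{d_c}; the summary reports the mean and
#' SD of |d_c| across classes (the magnitude convention of the effect-size
#' tables) alongside the signed mean.
#'
#' @param X m x p representation matrix (or \linkS4class{LabeledMatrix}).
#' @param labelsVec integer labels (ignored if \code{X} carries its own).
#' @param space tag recorded in the report: "bottleneck", "reconstruction"
#'   or "input".
#' @return an \linkS4class{EffectSizeReport}.
#' @export
cohensD <- function(X, labelsVec = NULL, space = "bottleneck") {
  if (is(X, "LabeledMatrix")) {
    if (is.null(labelsVec)) labelsVec <- labels(X)
    X <- features(X)
  }
  X <- .assertMatrix(X)
  if (any(table(labelsVec) < 2L))
    stop("every class needs >= 2 trials")
  D <- as.matrix(dist(X))
  classes <- sort(unique(labelsVec))
  d <- vapply(classes, function(cls) {
    inC <- labelsVec == cls
    Dw <- D[inC, inC, drop = FALSE]
    within <- Dw[upper.tri(Dw)]
    between <- as.numeric(D[inC, !inC, drop = FALSE])
    s <- sqrt(((length(within) - 1) * var(within) +
               (length(between) - 1) * var(between)) /
              (length(within) + length(between) - 2))
    if (!is.finite(s) || s == 0) return(NA_real_)
    (mean(within) - mean(between)) / s
  }, numeric(1))
  names(d) <- as.character(classes)
  new("EffectSizeReport",
      perClass = d,
      meanAbs = mean(abs(d), na.rm = TRUE),
      sdAbs = sd(abs(d), na.rm = TRUE),
      meanSigned = mean(d, na.rm = TRUE),
      space = space)
}

setMethod("show", "EffectSizeReport", function(object) {
  cat(sprintf("EffectSizeReport (%s): |d| = %.3f ± %.3f over %d classes\n",
              object@space, object@meanAbs, object@sdAbs,
              length(object@perClass)))
})

#' Binary-equivalent (top-q) accuracy
#'
#' Counts a prediction as correct when the true class ranks within the
#' \code{topCount} highest predicted probabilities — the translation used to
#' compare 40-way accuracy with binary designs (top 20 of 40). Ties are
#' broken by class-index order.
#'
#' @param probabilities m x k matrix of predicted class probabilities;
#'   column c corresponds to class c-1 (or named columns with class labels).
#' @param labelsVec integer true classes (zero-based).
#' @param topCount number of top-ranked classes to accept, default 20.
#' @return fraction in [0, 1].
#' @export
binaryEquivalentAccuracy <- function(probabilities, labelsVec,
                                     topCount = 20L) {
  probabilities <- .assertMatrix(probabilities, "probabilities")
  if (topCount <= 0) stop("topCount must be positive")
  k <- ncol(probabilities)
  if (topCount > k) stop("topCount must not exceed the class count")
  cls <- if (!is.null(colnames(probabilities)))
    as.integer(colnames(probabilities)) else seq_len(k) - 1L
  hit <- vapply(seq_len(nrow(probabilities)), function(i) {
    ord <- order(probabilities[i, ], decreasing = TRUE) # ties: class order
    labelsVec[i] %in% cls[ord[seq_len(topCount)]]
  }, logical(1))
  mean(hit)
}
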
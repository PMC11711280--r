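# Hand-rolled fully-connected networks: one tanh hidden layer on each of the
# encoding and decoding arms, linear bottleneck, linear or logistic
# reconstruction output, optional softmax classifier head on the bottleneck
# (TRACE) or diagonal-Gaussian bottleneck (VAE). Trained with Adam on
# mini-batches. Every random draw (weight init, batch order, VAE noise) uses
# a sub-seed derived from the config seed and a fixed name, so the standard
# autoencoder and the supervised autoencoder share bit-identical
# initialisation and batch schedules.

.initParams <- function(cfg) {
  n <- cfg@inputDim; h <- cfg@hiddenDim
  d <- cfg@bottleneckDim; k <- cfg@classCount
  mk <- function(nr, nc, name) {
    lim <- 1 / sqrt(nr)  # symmetric uniform fan-in scaling
    matrix(withr::with_seed(.deriveSeed(cfg@seed, "init", name),
                            runif(nr * nc, -lim, lim)), nr, nc)
  }
  p <- list(
    W1 = mk(n, h, "W1"), b1 = numeric(h),
    W2 = mk(h, d, "W2"), b2 = numeric(d),
    W3 = mk(d, h, "W3"), b3 = numeric(h),
    W4 = mk(h, n, "W4"), b4 = numeric(n)
  )
  if (cfg@family == "TRACE") {
    p$Wc <- mk(d, k, "Wc"); p$bc <- numeric(k)
  }
  if (cfg@family == "VAE") {
    p$W2lv <- mk(h, d, "W2lv"); p$b2lv <- numeric(d)
  }
  p
}

.outAct <- function(Pre, kind) {
  if (kind == "logistic") 1 / (1 + exp(-Pre)) else Pre
}

# encoder: X -> tanh hidden -> linear bottleneck (mean path for VAE)
.encodeNet <- function(p, X) {
  H1 <- tanh(.addBias(X %*% p$W1, p$b1))
  .addBias(H1 %*% p$W2, p$b2)
}

.decodeNet <- function(p, Z, kind) {
  H2 <- tanh(.addBias(Z %*% p$W3, p$b3))
  .outAct(.addBias(H2 %*% p$W4, p$b4), kind)
}

# Shared backward pass for the reconstruction arm. Given dXhat (gradient at
# the activated output), returns gradients of all decoder/encoder weights
# plus the gradient arriving at the bottleneck.
.gradReconArm <- function(p, X, H1, Z, H2, Xhat, dXhat, kind) {
  dPre4 <- if (kind == "logistic") dXhat * Xhat * (1 - Xhat) else dXhat
  g <- list()
  g$W4 <- crossprod(H2, dPre4)
  g$b4 <- colSums(dPre4)
  dH2 <- tcrossprod(dPre4, p$W4)
  dPre3 <- dH2 * (1 - H2^2)
  g$W3 <- crossprod(Z, dPre3)
  g$b3 <- colSums(dPre3)
  g$dZ <- tcrossprod(dPre3, p$W3)
  g
}

.gradEncoderArm <- function(p, X, H1, dZ) {
  g <- list()
  g$W2 <- crossprod(H1, dZ)
  g$b2 <- colSums(dZ)
  dH1 <- tcrossprod(dZ, p$W2)
  dPre1 <- dH1 * (1 - H1^2)
  g$W1 <- crossprod(X, dPre1)
  g$b1 <- colSums(dPre1)
  g
}

# One mini-batch gradient for AE / TRACE. For TRACE the classifier-head
# gradient (alpha * (P - Y) / m at the logits) is added to the bottleneck
# gradient; with alpha = 0 those contributions are exact zeros, so the
# update sequence is bit-identical to the plain autoencoder's.
.gradAEBatch <- function(p, X, Y, cfg, withHead) {
  mB <- nrow(X); n <- ncol(X)
  H1 <- tanh(.addBias(X %*% p$W1, p$b1))
  Z <- .addBias(H1 %*% p$W2, p$b2)
  H2 <- tanh(.addBias(Z %*% p$W3, p$b3))
  Xhat <- .outAct(.addBias(H2 %*% p$W4, p$b4), cfg@outputActivation)
  dXhat <- 2 * (Xhat - X) / (mB * n)
  g <- .gradReconArm(p, X, H1, Z, H2, Xhat, dXhat, cfg@outputActivation)
  dZ <- g$dZ
  if (withHead) {
    P <- .softmax(.addBias(Z %*% p$Wc, p$bc))
    dLogit <- cfg@alpha * (P - Y) / mB
    g$Wc <- crossprod(Z, dLogit)
    g$bc <- colSums(dLogit)
    dZ <- dZ + tcrossprod(dLogit, p$Wc)
  }
  c(g[setdiff(names(g), "dZ")], .gradEncoderArm(p, X, H1, dZ))
}

# VAE mini-batch gradient: reparameterised sampling at the bottleneck, KL of
# the diagonal-Gaussian posterior against N(0, I), scaled by 1/(m*n) so the
# KL term lives on the same per-entry scale as the MSE term.
.gradVAEBatch <- function(p, X, cfg, eps) {
  mB <- nrow(X); n <- ncol(X)
  H1 <- tanh(.addBias(X %*% p$W1, p$b1))
  Mu <- .addBias(H1 %*% p$W2, p$b2)
  Lv <- .addBias(H1 %*% p$W2lv, p$b2lv)
  Sig <- exp(0.5 * Lv)
  Z <- Mu + Sig * eps
  H2 <- tanh(.addBias(Z %*% p$W3, p$b3))
  Xhat <- .outAct(.addBias(H2 %*% p$W4, p$b4), cfg@outputActivation)
  dXhat <- 2 * (Xhat - X) / (mB * n)
  g <- .gradReconArm(p, X, H1, Z, H2, Xhat, dXhat, cfg@outputActivation)
  dZ <- g$dZ
  klScale <- cfg@klWeight / (mB * n)
  dMu <- dZ + klScale * Mu
  dLv <- dZ * eps * 0.5 * Sig + klScale * 0.5 * (exp(Lv) - 1)
  gm <- .gradEncoderArm(p, X, H1, dMu)
  g$W2 <- gm$W2; g$b2 <- gm$b2
  g$W2lv <- crossprod(H1, dLv)
  g$b2lv <- colSums(dLv)
  dH1 <- tcrossprod(dMu, p$W2) + tcrossprod(dLv, p$W2lv)
  dPre1 <- dH1 * (1 - H1^2)
  g$W1 <- crossprod(X, dPre1)
  g$b1 <- colSums(dPre1)
  g$dZ <- NULL
  g
}

.fullLoss <- function(p, X, Y, cfg) {
  Z <- .encodeNet(p, X)
  Xhat <- .decodeNet(p, Z, cfg@outputActivation)
  lr <- mean((Xhat - X)^2)
  if (cfg@family == "TRACE") {
    P <- .softmax(.addBias(Z %*% p$Wc, p$bc))
    lr <- lr + cfg@alpha *
      (-sum(Y * log(pmax(P, 1e-12))) / nrow(X))
  } else if (cfg@family == "VAE") {
    H1 <- tanh(.addBias(X %*% p$W1, p$b1))
    Lv <- .addBias(H1 %*% p$W2lv, p$b2lv)
    kl <- 0.5 * sum(exp(Lv) + Z^2 - 1 - Lv)
    lr <- lr + cfg@klWeight * kl / (nrow(X) * ncol(X))
  }
  lr
}

.adamInit <- function(p) {
  list(m = lapply(p, function(x) x * 0),
       v = lapply(p, function(x) x * 0), t = 0L)
}

.adamStep <- function(p, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t; c2 <- 1 - beta2^st$t
  for (nm in names(p)) {
    gn <- g[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * gn
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * gn^2
    p[[nm]] <- p[[nm]] -
      lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(p = p, st = st)
}

.trainNetwork <- function(cfg, X, Y) {
  p <- .initParams(cfg)
  st <- .adamInit(p)
  m <- nrow(X)
  bs <- min(cfg@batchSize, m)
  lossTrace <- numeric(0)
  for (epoch in seq_len(cfg@epochs)) {
    ord <- withr::with_seed(.deriveSeed(cfg@seed, "order", epoch), sample(m))
    starts <- seq(1L, m, by = bs)
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + bs - 1L, m)]
      Xb <- X[idx, , drop = FALSE]
      g <- switch(cfg@family,
        TRACE = .gradAEBatch(p, Xb, Y[idx, , drop = FALSE], cfg, TRUE),
        AE = .gradAEBatch(p, Xb, NULL, cfg, FALSE),
        VAE = {
          eps <- matrix(withr::with_seed(
            .deriveSeed(cfg@seed, "vaeeps", epoch, bi),
            rnorm(length(idx) * cfg@bottleneckDim)),
            length(idx), cfg@bottleneckDim)
          .gradVAEBatch(p, Xb, cfg, eps)
        }
      )
      upd <- .adamStep(p, g, st, cfg@learningRate)
      p <- upd$p; st <- upd$st
    }
    loss <- .fullLoss(p, X, Y, cfg)
    if (!is.finite(loss))
      stop("training diverged (non-finite loss) at epoch ", epoch)
    lossTrace <- c(lossTrace, loss)
    # loss-plateau early stopping
    if (epoch > cfg@patience) {
      prev <- lossTrace[epoch - cfg@patience]
      if (abs(prev - loss) < cfg@tol * max(1, abs(loss))) break
    }
  }
  list(params = p, lossTrace = lossTrace)
}
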
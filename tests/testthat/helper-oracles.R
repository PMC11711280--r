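# Independent brute-force oracles: plain double loops over trial pairs,
# kept deliberately free of the package's vectorized implementations.

bruteMSE <- function(X, Xhat) {
  s <- 0
  for (i in seq_len(nrow(X)))
    for (j in seq_len(ncol(X)))
      s <- s + (Xhat[i, j] - X[i, j])^2
  s / (nrow(X) * ncol(X))
}

bruteCrossEntropy <- function(Y, P) {
  s <- 0
  for (i in seq_len(nrow(Y)))
    for (c in seq_len(ncol(Y)))
      if (Y[i, c] > 0) s <- s - Y[i, c] * log(P[i, c])
  s / nrow(Y)
}

bruteFidelity <- function(X, Xhat) {
  rs <- numeric(nrow(X))
  for (i in seq_len(nrow(X)))
    rs[i] <- cor(X[i, ], Xhat[i, ])
  mean(rs)
}

bruteClassSpecificity <- function(X, y) {
  within <- c(); between <- c()
  for (i in seq_len(nrow(X) - 1L))
    for (j in (i + 1L):nrow(X)) {
      r <- cor(X[i, ], X[j, ])
      if (y[i] == y[j]) within <- c(within, r) else between <- c(between, r)
    }
  mean(within) - mean(between)
}

bruteCohensD <- function(X, y) {
  euclid <- function(a, b) sqrt(sum((a - b)^2))
  classes <- sort(unique(y))
  d <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    cls <- classes[ci]
    within <- c(); between <- c()
    idx <- which(y == cls)
    for (i in idx) {
      for (j in idx) if (j > i)
        within <- c(within, euclid(X[i, ], X[j, ]))
      for (j in which(y != cls))
        between <- c(between, euclid(X[i, ], X[j, ]))
    }
    sp <- sqrt(((length(within) - 1) * var(within) +
                (length(between) - 1) * var(between)) /
               (length(within) + length(between) - 2))
    d[ci] <- (mean(within) - mean(between)) / sp
  }
  names(d) <- as.character(classes)
  d
}

# textbook one-way repeated-measures decomposition; Y is replicates x levels
bruteRmAnovaF <- function(Y) {
  k <- ncol(Y); n <- nrow(Y)
  grand <- mean(Y)
  ssModel <- n * sum((colMeans(Y) - grand)^2)
  ssSubj <- k * sum((rowMeans(Y) - grand)^2)
  ssErr <- sum((Y - grand)^2) - ssModel - ssSubj
  (ssModel / (k - 1)) / (ssErr / ((k - 1) * (n - 1)))
}

# small structured dataset shared by several tests
makeToyData <- function(k = 4L, n = 60L, perClass = 30L, seed = 2L,
                        standardize = TRUE, ...) {
  ds <- generateSynthetic(k, n, perClass, seed = seed, ...)
  if (standardize) {
    s <- standardizeFeatures(ds$train, ds$test)
    ds$train <- s$train; ds$test <- s$test
  }
  ds
}

.softmaxOracle <- function(L) {
  E <- exp(L - apply(L, 1L, max))
  E / rowSums(E)
}
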
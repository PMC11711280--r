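# Deterministic seed derivation so every grid cell, weight matrix and
# shuffle stream is independently reproducible from one master seed.
# Values stay strictly below 2^31 - 1 (R integers are 32-bit).
.deriveSeed <- function(master, ...) {
  parts <- c(...)
  s <- as.double(master) %% 2147483629
  for (p in parts) {
    inc <- if (is.character(p)) sum(utf8ToInt(p)) else as.double(p)
    s <- (s * 69069 + inc + 1) %% 2147483629
  }
  as.integer(s)
}

.assertMatrix <- function(X, what = "X") {
  if (is(X, "LabeledMatrix")) X <- features(X)
  if (!is.matrix(X) || !is.numeric(X))
    stop(what, " must be a numeric matrix", call. = FALSE)
  X
}

# Column-wise bias addition without sweep()'s overhead.
.addBias <- function(M, b) M + rep(b, each = nrow(M))

.onehot <- function(labels, k) {
  Y <- matrix(0, length(labels), k)
  Y[cbind(seq_along(labels), labels + 1L)] <- 1
  Y
}

.softmax <- function(L) {
  L <- L - apply(L, 1L, max)
  E <- exp(L)
  E / rowSums(E)
}
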
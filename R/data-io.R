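#' Read an IDX image/label file pair
#'
#' Reads the big-endian IDX binary layout used to distribute MNIST and
#' Fashion MNIST: an image file (magic 2051, unsigned bytes, dims
#' count x rows x cols) and a label file (magic 2049). Images are flattened
#' row-major to n = rows*cols features and scaled to [0, 1] by dividing by
#' 255.
#'
#' @param pathImages,pathLabels paths to the image and label files.
#' @param splitTag "train" or "test" tag for the returned object.
#' @return a \linkS4class{LabeledMatrix}.
#' @export
readIDX <- function(pathImages, pathLabels, splitTag = c("train", "test")) {
  splitTag <- match.arg(splitTag)
  readMagic <- function(con) readBin(con, "integer", 1L, 4L, endian = "big")
  imgCon <- file(pathImages, "rb"); on.exit(close(imgCon), add = TRUE)
  magic <- readMagic(imgCon)
  if (!identical(magic, 2051L))
    stop("bad magic number in image file (expected 2051, got ", magic, ")")
  m <- readMagic(imgCon)
  rows <- readMagic(imgCon)
  cols <- readMagic(imgCon)
  raw <- readBin(imgCon, "raw", m * rows * cols)
  if (length(raw) < m * rows * cols)
    stop("image file truncated: expected ", m * rows * cols, " pixels")
  labCon <- file(pathLabels, "rb"); on.exit(close(labCon), add = TRUE)
  magicL <- readMagic(labCon)
  if (!identical(magicL, 2049L))
    stop("bad magic number in label file (expected 2049, got ", magicL, ")")
  mL <- readMagic(labCon)
  if (!identical(m, mL))
    stop("image/label count mismatch: ", m, " images vs ", mL, " labels")
  lab <- as.integer(readBin(labCon, "raw", mL))
  # IDX stores each image's pixels consecutively (row-major); filling the
  # feature matrix by row keeps one image per row.
  X <- matrix(as.integer(raw), nrow = m, ncol = rows * cols,
              byrow = TRUE) / 255
  LabeledMatrix(X, lab, splitTag = splitTag, classCount = max(lab) + 1L)
}

#' Read a delimited trial-by-feature table
#'
#' @param path delimited text file (separator auto-detected), rectangular,
#'   header optional; one integer label column, all other columns numeric
#'   features in file order.
#' @param labelColumn column name or 1-based index of the label column.
#' @param splitTag "train" or "test".
#' @param standardize if TRUE, z-score each feature using this file's own
#'   moments (use [standardizeFeatures()] to share training moments across
#'   splits instead).
#' @return a \linkS4class{LabeledMatrix}.
#' @export
readDelimited <- function(path, labelColumn = "label",
                          splitTag = c("train", "test"),
                          standardize = FALSE) {
  splitTag <- match.arg(splitTag)
  dt <- data.table::fread(path, header = "auto", fill = FALSE,
                          blank.lines.skip = FALSE)
  if (is.character(labelColumn)) {
    if (!labelColumn %in% names(dt))
      stop("label column '", labelColumn, "' not found")
    labIdx <- match(labelColumn, names(dt))
  } else {
    labIdx <- as.integer(labelColumn)
  }
  lab <- dt[[labIdx]]
  if (!is.numeric(lab) || any(lab != round(lab)))
    stop("label column must be integer-valued")
  feat <- as.matrix(dt[, -labIdx, with = FALSE])
  if (!is.numeric(feat) || anyNA(feat))
    stop("non-numeric or missing feature cell in ", path)
  out <- LabeledMatrix(feat, as.integer(lab), splitTag = splitTag)
  if (standardize) out <- standardizeFeatures(out)$train
  out
}

#' Write a LabeledMatrix to delimited text
#'
#' Inverse of [readDelimited()]: features in column order \code{f1..fn} plus
#' a final \code{label} column. Values round-trip at full precision.
#'
#' @param x a \linkS4class{LabeledMatrix}.
#' @param path output file; separator chosen by extension (.csv/.tsv).
#' @return \code{path}, invisibly.
#' @export
writeDelimited <- function(x, path) {
  X <- features(x)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  dt <- data.table::as.data.table(X)
  dt$label <- labels(x)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  data.table::fwrite(dt, path, sep = sep)
  invisible(path)
}

#' Generate class-structured synthetic data
#'
#' Emulates the structure the supervised autoencoder targets: each trial is a
#' class prototype plus a shared low-rank task-irrelevant component plus
#' i.i.d. Gaussian noise,
#' \deqn{x = s_p \mu_{c} + s_u B u + \epsilon,}
#' where the prototypes \eqn{\mu_c} and the loading matrix \eqn{B} (rank
#' \code{irrelevantRank}) have standard-Gaussian entries drawn once, the
#' per-trial latent \eqn{u} is standard Gaussian, and
#' \eqn{\epsilon \sim N(0, \sigma^2 I)}. Train and test splits share the
#' generative parameters; labels are exactly balanced. The defaults put most
#' of the variance into the shared task-irrelevant component, the regime in
#' which purely unsupervised compression latches onto nuisance structure.
#'
#' @param classCount k classes.
#' @param featureCount n features.
#' @param exemplarsPerClass trials per class in each split (>= 2).
#' @param prototypeScale separation of class means (default 1).
#' @param irrelevantRank dimensionality of the shared nuisance subspace;
#'   default \code{min(10, featureCount - 1)}.
#' @param irrelevantScale scale of the nuisance component (default 3, so the
#'   nuisance dominates the leading variance directions).
#' @param noiseSd i.i.d. noise SD (default 1).
#' @param testExemplarsPerClass trials per class in the test split (defaults
#'   to \code{exemplarsPerClass}).
#' @param seed integer; identical seeds give bit-identical output.
#' @return list with \code{train} and \code{test}
#'   \linkS4class{LabeledMatrix} objects.
#' @export
generateSynthetic <- function(classCount, featureCount, exemplarsPerClass,
                              prototypeScale = 1, irrelevantRank = NULL,
                              irrelevantScale = 3, noiseSd = 1,
                              testExemplarsPerClass = exemplarsPerClass,
                              seed = 1L) {
  if (is.null(irrelevantRank))
    irrelevantRank <- min(10L, as.integer(featureCount) - 1L)
  stopifnot(prototypeScale >= 0, irrelevantScale >= 0, noiseSd >= 0,
            irrelevantRank < featureCount, irrelevantRank >= 1)
  if (exemplarsPerClass < 2L)
    stop("exemplarsPerClass must be >= 2 (within-class statistics undefined)")
  k <- as.integer(classCount); n <- as.integer(featureCount)
  r <- as.integer(irrelevantRank)
  proto <- matrix(withr::with_seed(.deriveSeed(seed, "proto"),
                                   rnorm(k * n)), k, n)
  B <- matrix(withr::with_seed(.deriveSeed(seed, "loadings"),
                               rnorm(r * n)), r, n)
  draw <- function(perClass, tag) {
    m <- k * perClass
    lab <- rep(seq_len(k) - 1L, each = perClass)
    U <- matrix(withr::with_seed(.deriveSeed(seed, tag, "latent"),
                                 rnorm(m * r)), m, r)
    E <- matrix(withr::with_seed(.deriveSeed(seed, tag, "noise"),
                                 rnorm(m * n, sd = max(noiseSd, 0))), m, n)
    if (noiseSd == 0) E[] <- 0
    X <- prototypeScale * proto[lab + 1L, , drop = FALSE] +
      irrelevantScale * (U %*% B) + E
    LabeledMatrix(X, lab, splitTag = tag, classCount = k)
  }
  list(train = draw(as.integer(exemplarsPerClass), "train"),
       test = draw(as.integer(testExemplarsPerClass), "test"))
}

#' Class-stratified dataset truncation
#'
#' Removes a fraction of the training trials by class-stratified uniform
#' sampling, so class balance is preserved to within one exemplar and the
#' chance level of downstream classifiers is unchanged. For a given
#' \code{(fraction, seed, replicate)} the retained index set is
#' deterministic, so every model family trains on the identical sub-sample;
#' distinct replicates give independent sub-samples (the jack-knife
#' resamplings of the sparsity protocol).
#'
#' @param data a \linkS4class{LabeledMatrix}.
#' @param fractionRemoved fraction of trials to remove, in [0, 1). The
#'   sparsity protocol uses 0.10, 0.30, 0.50, 0.70, 0.90, 0.95, 0.98.
#' @param replicate 1-based replicate index.
#' @param seed integer master seed.
#' @return a \linkS4class{LabeledMatrix} with \code{round((1 - fraction) *
#'   m)} trials (computed per class).
#' @export
truncateData <- function(data, fractionRemoved, replicate = 1L, seed = 1L) {
  stopifnot(fractionRemoved >= 0, fractionRemoved < 1)
  if (fractionRemoved == 0) return(data)
  lab <- labels(data)
  keep <- integer(0)
  for (cls in sort(unique(lab))) {
    idx <- which(lab == cls)
    nKeep <- round(length(idx) * (1 - fractionRemoved))
    if (nKeep < 1L)
      stop("truncation would empty class ", cls)
    sel <- withr::with_seed(
      .deriveSeed(seed, "truncate", fractionRemoved * 1e6, replicate, cls),
      sample(idx, nKeep)
    )
    keep <- c(keep, sel)
  }
  subsetTrials(data, sort(keep))
}

#' Shuffle class labels
#'
#' Applies a uniform random permutation to the labels, leaving features
#' untouched; the label marginal is preserved exactly. Used by the
#' shuffled-label null control.
#'
#' @param data a \linkS4class{LabeledMatrix}.
#' @param seed integer.
#' @return a \linkS4class{LabeledMatrix} with permuted labels.
#' @export
shuffleLabels <- function(data, seed = 1L) {
  lab <- labels(data)
  perm <- withr::with_seed(.deriveSeed(seed, "shuffle"),
                           sample(length(lab)))
  LabeledMatrix(features(data), lab[perm], splitTag = splitTag(data),
                classCount = classCount(data))
}
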
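#' Construct a sweep grid
#'
#' @param dims bottleneck widths, strictly increasing; defaults to the
#'   standard grid 2, 5, 10, 15, 20, 30, 50, 60, 100, 150, 200, 250, 500,
#'   784, capped at \code{inputDim} when given.
#' @param families model families to run.
#' @param fractions truncation fractions removed (default none).
#' @param replicateCount jack-knife replicates at the largest fraction.
#' @param seed master seed; every cell's seed derives deterministically from
#'   (seed, family, dim, fraction, replicate).
#' @param inputDim optional feature count used to cap \code{dims} (cells
#'   exceeding it are dropped with a message).
#' @return a \linkS4class{SweepGrid}.
#' @export
sweepGrid <- function(dims = c(2L, 5L, 10L, 15L, 20L, 30L, 50L, 60L, 100L,
                               150L, 200L, 250L, 500L, 784L),
                      families = c("TRACE", "AE", "VAE", "PCA"),
                      fractions = numeric(0),
                      replicateCount = 1L,
                      seed = 1L,
                      inputDim = NULL) {
  dims <- as.integer(dims)
  if (!is.null(inputDim) && any(dims > inputDim)) {
    message("dropping bottleneck dims exceeding inputDim: ",
            paste(dims[dims > inputDim], collapse = ", "))
    dims <- dims[dims <= inputDim]
  }
  new("SweepGrid", dims = dims, families = families,
      fractions = as.numeric(fractions),
      replicateCount = as.integer(replicateCount),
      seed = as.integer(seed))
}

# Fit one family at one width and compute the full metric battery.
.evalCell <- function(family, d, train, test, seed, alpha, hiddenDim,
                      outputActivation, epochs, batchSize, learningRate,
                      posthocCfg) {
  cfg <- modelConfig(family,
                     inputDim = ncol(features(train)),
                     bottleneckDim = d,
                     classCount = classCount(train),
                     hiddenDim = hiddenDim,
                     alpha = alpha,
                     outputActivation = outputActivation,
                     epochs = epochs, batchSize = batchSize,
                     learningRate = learningRate,
                     seed = seed)
  model <- fitModel(cfg, train)
  Xte <- features(test); yte <- labels(test)
  Xtr <- features(train); ytr <- labels(train)
  Zte <- encode(model, Xte); Ztr <- encode(model, Xtr)
  Rte <- reconstruct(model, Xte); Rtr <- reconstruct(model, Xtr)
  list(
    model = model,
    fidelity = reconstructionFidelity(Xte, Rte),
    bottleneckAccuracy =
      postHocClassifierAccuracy(Ztr, ytr, Zte, yte, posthocCfg),
    reconstructionSpecificity = classSpecificity(Rte, yte),
    reconstructionAccuracy =
      postHocClassifierAccuracy(Rtr, ytr, Rte, yte, posthocCfg),
    bottleneckEffect = cohensD(Zte, yte, space = "bottleneck"),
    reconstructionEffect = cohensD(Rte, yte, space = "reconstruction")
  )
}

#' Run a bottleneck-dimensionality sweep
#'
#' Fits every (family, bottleneck width) cell of the grid on the training
#' split and computes the four outcome metrics on the held-out test split,
#' plus the d-independent input-space baselines (computed once per dataset)
#' and the Cohen's d effect-size summaries for bottleneck and
#' reconstruction. Cell failures are isolated: the sweep continues and the
#' failure is recorded in the provenance.
#'
#' @param grid a \linkS4class{SweepGrid}.
#' @param train,test \linkS4class{LabeledMatrix} splits (disjoint).
#' @param alpha classifier-loss weight for TRACE cells.
#' @param hiddenDim,epochs,batchSize,learningRate network training settings
#'   shared by all network families.
#' @param outputActivation "linear" or "logistic" reconstruction output.
#' @param posthocCfg a [postHocClassifierConfig()].
#' @return a \linkS4class{SweepResult}.
#' @export
runSweep <- function(grid, train, test,
                     alpha = 1, hiddenDim = NULL,
                     outputActivation = c("linear", "logistic"),
                     epochs = 100L, batchSize = 128L, learningRate = 1e-3,
                     posthocCfg = postHocClassifierConfig()) {
  outputActivation <- match.arg(outputActivation)
  Xtr <- features(train); ytr <- labels(train)
  Xte <- features(test); yte <- labels(test)
  inputSpec <- classSpecificity(Xte, yte)
  inputAcc <- postHocClassifierAccuracy(Xtr, ytr, Xte, yte, posthocCfg)
  rows <- list(); esRows <- list(); failures <- list()
  for (family in grid@families) {
    for (d in grid@dims) {
      cellSeed <- .deriveSeed(grid@seed, family, d, 0, 1)
      cell <- tryCatch(
        .evalCell(family, d, train, test, cellSeed, alpha, hiddenDim,
                  outputActivation, epochs, batchSize, learningRate,
                  posthocCfg),
        error = function(e) e)
      if (inherits(cell, "error")) {
        failures[[paste(family, d, sep = ":")]] <- conditionMessage(cell)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        family = family, dim = d, fraction = 0, replicate = 1L,
        reconstruction_fidelity = cell$fidelity,
        bottleneck_accuracy = cell$bottleneckAccuracy,
        reconstruction_specificity = cell$reconstructionSpecificity,
        reconstruction_accuracy = cell$reconstructionAccuracy,
        input_specificity = inputSpec,
        input_accuracy = inputAcc)
      for (es in list(cell$bottleneckEffect, cell$reconstructionEffect))
        esRows[[length(esRows) + 1L]] <- data.frame(
          family = family, dim = d, fraction = 0, replicate = 1L,
          space = es@space, mean_abs_d = es@meanAbs, sd_abs_d = es@sdAbs,
          mean_signed_d = es@meanSigned)
    }
  }
  new("SweepResult",
      metrics = do.call(rbind, rows),
      effectSizes = do.call(rbind, esRows),
      provenance = list(seed = grid@seed, dims = grid@dims,
                        families = grid@families, alpha = alpha,
                        failures = failures,
                        timestamp = format(Sys.time(), tz = "UTC")))
}

#' Select the optimal bottleneck width
#'
#' Returns the width maximizing reconstruction class specificity for the
#' given family — the criterion balancing task-relevant information
#' extraction against compression. Ties break toward the smaller width
#' (more compression).
#'
#' @param result a \linkS4class{SweepResult}.
#' @param family model family, default "TRACE".
#' @return integer bottleneck width.
#' @export
selectOptimalDim <- function(result, family = "TRACE") {
  df <- result@metrics
  df <- df[df$family == family & df$fraction == 0, ]
  if (nrow(df) < 2L) stop("need >= 2 dims to select an optimum")
  if (anyNA(df$reconstruction_specificity))
    stop("missing reconstruction specificity in at least one cell")
  df <- df[order(df$dim), ]
  df$dim[which.max(df$reconstruction_specificity)]
}

#' Run the data-sparsity (truncation) study
#'
#' At a fixed bottleneck width, trains every family on progressively
#' truncated training data and evaluates on the standard test split. At the
#' largest fraction, \code{grid@replicateCount} independent jack-knife
#' sub-samples are drawn and every metric is summarised by its mean and SD
#' across replicates; other fractions run one replicate. Within a
#' (fraction, replicate) cell all families train on the identical retained
#' sample.
#'
#' @inheritParams runSweep
#' @param dim the fixed bottleneck width (typically [selectOptimalDim()]).
#' @return a \linkS4class{SweepResult} with one metrics row per
#'   (family, fraction, replicate).
#' @export
runTruncationStudy <- function(grid, train, test, dim,
                               alpha = 1, hiddenDim = NULL,
                               outputActivation = c("linear", "logistic"),
                               epochs = 100L, batchSize = 128L,
                               learningRate = 1e-3,
                               posthocCfg = postHocClassifierConfig()) {
  outputActivation <- match.arg(outputActivation)
  if (!length(grid@fractions)) stop("grid has no truncation fractions")
  Xte <- features(test); yte <- labels(test)
  inputSpec <- classSpecificity(Xte, yte)
  inputAcc <- postHocClassifierAccuracy(features(train), labels(train),
                                        Xte, yte, posthocCfg)
  maxFrac <- max(grid@fractions)
  rows <- list(); esRows <- list(); failures <- list()
  for (frac in grid@fractions) {
    nRep <- if (frac == maxFrac) grid@replicateCount else 1L
    for (rep in seq_len(nRep)) {
      sub <- if (frac == 0) train else
        truncateData(train, frac, replicate = rep, seed = grid@seed)
      for (family in grid@families) {
        cellSeed <- .deriveSeed(grid@seed, family, dim, frac * 1e6, rep)
        cell <- tryCatch(
          .evalCell(family, dim, sub, test, cellSeed, alpha, hiddenDim,
                    outputActivation, epochs, batchSize, learningRate,
                    posthocCfg),
          error = function(e) e)
        if (inherits(cell, "error")) {
          failures[[paste(family, frac, rep, sep = ":")]] <-
            conditionMessage(cell)
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          family = family, dim = dim, fraction = frac, replicate = rep,
          reconstruction_fidelity = cell$fidelity,
          bottleneck_accuracy = cell$bottleneckAccuracy,
          reconstruction_specificity = cell$reconstructionSpecificity,
          reconstruction_accuracy = cell$reconstructionAccuracy,
          input_specificity = inputSpec,
          input_accuracy = inputAcc)
        for (es in list(cell$bottleneckEffect, cell$reconstructionEffect))
          esRows[[length(esRows) + 1L]] <- data.frame(
            family = family, dim = dim, fraction = frac, replicate = rep,
            space = es@space, mean_abs_d = es@meanAbs,
            sd_abs_d = es@sdAbs, mean_signed_d = es@meanSigned)
      }
    }
  }
  new("SweepResult",
      metrics = do.call(rbind, rows),
      effectSizes = do.call(rbind, esRows),
      provenance = list(seed = grid@seed, dim = dim,
                        fractions = grid@fractions,
                        replicateCount = grid@replicateCount,
                        families = grid@families, alpha = alpha,
                        failures = failures,
                        timestamp = format(Sys.time(), tz = "UTC")))
}

#' Shuffled-label null control
#'
#' Trains the supervised autoencoder on label-shuffled training data and
#' evaluates the Cohen's d cluster-separation metrics against independently
#' shuffled test labels. Because no other family uses labels in its loss,
#' the control is defined for TRACE only; requesting it for another family
#' is an error. With shuffled labels the expected effect size is zero: a
#' larger value would mean the model imposes class structure where none
#' exists.
#'
#' @param train,test \linkS4class{LabeledMatrix} splits.
#' @param dim bottleneck width.
#' @param family must be "TRACE".
#' @param alpha,hiddenDim,outputActivation,epochs,batchSize,learningRate
#'   training settings.
#' @param seed master seed (controls both shuffles and training).
#' @return list with \code{bottleneck} and \code{reconstruction}
#'   \linkS4class{EffectSizeReport}s.
#' @export
runShuffleControl <- function(train, test, dim, family = "TRACE",
                              alpha = 1, hiddenDim = NULL,
                              outputActivation = c("linear", "logistic"),
                              epochs = 100L, batchSize = 128L,
                              learningRate = 1e-3, seed = 1L) {
  if (family != "TRACE")
    stop("the shuffled-label control is only defined for TRACE; other ",
         "families ignore labels, so shuffling them has no effect")
  outputActivation <- match.arg(outputActivation)
  shTrain <- shuffleLabels(train, seed = .deriveSeed(seed, "ctrl-train"))
  shTest <- shuffleLabels(test, seed = .deriveSeed(seed, "ctrl-test"))
  cfg <- modelConfig("TRACE",
                     inputDim = ncol(features(train)),
                     bottleneckDim = dim,
                     classCount = classCount(train),
                     hiddenDim = hiddenDim, alpha = alpha,
                     outputActivation = outputActivation,
                     epochs = epochs, batchSize = batchSize,
                     learningRate = learningRate,
                     seed = .deriveSeed(seed, "ctrl-fit"))
  model <- fitModel(cfg, shTrain)
  Xte <- features(shTest); yte <- labels(shTest)
  list(
    bottleneck = cohensD(encode(model, Xte), yte, space = "bottleneck"),
    reconstruction = cohensD(reconstruct(model, Xte), yte,
                             space = "reconstruction")
  )
}

#' One-way repeated-measures ANOVA across model families
#'
#' Omnibus repeated-measures ANOVA of one outcome metric with within factor
#' model family (replicates are the repeated units: each jack-knife
#' replicate trains every family on the identical retained sample),
#' followed by planned paired contrasts comparing TRACE to each other
#' family. Greenhouse-Geisser sphericity correction is applied and both the
#' corrected and uncorrected p-values are returned.
#'
#' @param df data.frame with columns \code{replicate}, \code{family} and
#'   \code{value}; must be balanced (every family observed at every
#'   replicate).
#' @return list with \code{F}, \code{df1}, \code{df2}, \code{p},
#'   \code{ggEpsilon}, \code{pGG} and a \code{contrasts} data.frame
#'   (one row per family compared against TRACE).
#' @export
compareModelsRmAnova <- function(df) {
  stopifnot(all(c("replicate", "family", "value") %in% names(df)))
  tab <- table(df$replicate, df$family)
  if (any(tab != 1L))
    stop("unbalanced table: each (replicate, family) must appear once")
  wide <- stats::reshape(df[, c("replicate", "family", "value")],
                         idvar = "replicate", timevar = "family",
                         direction = "wide")
  fams <- sub("^value\\.", "", names(wide)[-1L])
  Y <- as.matrix(wide[, -1L, drop = FALSE])
  colnames(Y) <- fams
  nFam <- length(fams); nRep <- nrow(Y)
  df1 <- nFam - 1L; df2 <- (nFam - 1L) * (nRep - 1L)
  anv <- tryCatch({
    mlm <- stats::lm(Y ~ 1)
    idata <- data.frame(family = factor(fams, levels = fams))
    av <- car::Anova(mlm, idata = idata, idesign = ~family, type = "III")
    s <- suppressWarnings(summary(av, multivariate = FALSE))
    ut <- s$univariate.tests
    adj <- s$pval.adjustments
    list(F = unname(ut["family", "F value"]),
         p = unname(ut["family", "Pr(>F)"]),
         eps = unname(adj["family", "GG eps"]),
         pGG = unname(adj["family", "Pr(>F[GG])"]))
  }, error = function(e) NULL)
  if (!is.null(anv)) {
    if (is.na(anv$eps)) { # 2-level factor: sphericity trivially holds
      anv$eps <- 1
      anv$pGG <- anv$p
    }
    if (!is.finite(anv$F) || anv$F < 0) anv <- NULL # zero error variance
  }
  if (is.null(anv)) {
    # degenerate data (e.g. zero error variance): fall back to the direct
    # within-subject decomposition
    grand <- mean(Y)
    ssModel <- nRep * sum((colMeans(Y) - grand)^2)
    ssSubj <- nFam * sum((rowMeans(Y) - grand)^2)
    ssErr <- sum((Y - grand)^2) - ssModel - ssSubj
    msErr <- ssErr / df2
    Fval <- if (msErr > 0) (ssModel / df1) / msErr else
      if (ssModel == 0) 0 else Inf
    anv <- list(F = Fval, p = pf(Fval, df1, df2, lower.tail = FALSE),
                eps = 1, pGG = pf(Fval, df1, df2, lower.tail = FALSE))
  }
  Fval <- anv$F; p <- anv$p; eps <- anv$eps; pGG <- anv$pGG
  contrasts <- NULL
  if ("TRACE" %in% fams) {
    others <- setdiff(fams, "TRACE")
    contrasts <- do.call(rbind, lapply(others, function(f) {
      diffs <- Y[, "TRACE"] - Y[, f]
      if (sd(diffs) == 0) {
        data.frame(comparison = paste0("TRACE-", f),
                   meanDiff = mean(diffs), t = NA_real_,
                   df = nRep - 1L, p = NA_real_)
      } else {
        tt <- t.test(Y[, "TRACE"], Y[, f], paired = TRUE)
        data.frame(comparison = paste0("TRACE-", f),
                   meanDiff = unname(tt$estimate), t = unname(tt$statistic),
                   df = unname(tt$parameter), p = tt$p.value)
      }
    }))
  }
  list(F = Fval, df1 = df1, df2 = df2, p = p,
       ggEpsilon = eps, pGG = pGG, contrasts = contrasts)
}

setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult: %d metric rows, %d effect-size rows\n",
              nrow(object@metrics), nrow(object@effectSizes)))
  nf <- length(object@provenance$failures)
  if (nf) cat("  failed cells:", nf, "\n")
})

#' Accessors for sweep results
#' @param result a \linkS4class{SweepResult}.
#' @return data.frame of per-cell metrics or effect sizes.
#' @export
sweepMetrics <- function(result) result@metrics

#' @rdname sweepMetrics
#' @export
sweepEffectSizes <- function(result) result@effectSizes
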
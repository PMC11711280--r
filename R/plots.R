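#' Scatter plot of a 2-D bottleneck
#'
#' Plots the two bottleneck activations against each other, colored by
#' class — the standard visual check of class clustering when the selected
#' bottleneck width is 2.
#'
#' @param model a fitted \linkS4class{TrainedModel} with
#'   \code{bottleneckDim == 2}.
#' @param data a \linkS4class{LabeledMatrix} (typically the test split).
#' @param maxPoints subsample cap for readability.
#' @return a ggplot object.
#' @export
plotBottleneck <- function(model, data, maxPoints = 2000L) {
  if (model@config@bottleneckDim != 2L)
    stop("bottleneck scatter requires bottleneckDim == 2")
  Z <- encode(model, features(data))
  df <- data.frame(z1 = Z[, 1L], z2 = Z[, 2L],
                   class = factor(labels(data)))
  if (nrow(df) > maxPoints) {
    keep <- withr::with_seed(1L, sample(nrow(df), maxPoints))
    df <- df[keep, ]
  }
  ggplot2::ggplot(df, ggplot2::aes(x = z1, y = z2, color = class)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::labs(x = "bottleneck 1", y = "bottleneck 2",
                  title = paste(model@config@family, "bottleneck")) +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("z1", "z2", "class"))
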
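# Base-graphics views of the optimizer trace, the MIV contributions and
# model predictions.

#' Plot a convergence trace
#'
#' Global-best fitness (training-set RMSE, normalized scale) against the
#' hybrid optimizer iteration.
#'
#' @param x A `convergence_trace`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.convergence_trace <- function(x, ...) {
  graphics::plot(seq_along(x), as.numeric(x), type = "b", pch = 19,
                 xlab = "PSO-GA iteration", ylab = "best fitness (RMSE)",
                 main = "Hybrid optimizer convergence", ...)
  invisible(x)
}

#' Plot a MIV contribution report
#'
#' Signed horizontal bars: bar length is the contribution rate (%), bar
#' direction and label carry the sign of the region's influence.
#'
#' @param x A `miv_result`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.miv_result <- function(x, ...) {
  df <- x[order(x$rank, decreasing = TRUE), ]
  val <- ifelse(df$sign == "+", df$contribution, -df$contribution)
  old <- graphics::par(mar = c(4, 9, 3, 2))
  on.exit(graphics::par(old))
  graphics::barplot(val, names.arg = paste0(df$region, " (", df$sign, ")"),
                    horiz = TRUE, las = 1,
                    col = ifelse(df$sign == "+", "steelblue", "firebrick"),
                    xlab = "contribution rate (%), signed by influence",
                    main = "Region contributions to stiffness", ...)
  graphics::abline(v = 0)
  invisible(x)
}

#' Predicted versus actual stiffness scatter plot
#'
#' @param model A [bp_model()].
#' @param split A [split_dataset()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_predictions <- function(model, split, ...) {
  y <- c(split$train$y, split$test$y)
  yhat <- c(predict(model, split$train), predict(model, split$test))
  grp <- rep(c("train", "test"), c(length(split$train$y), length(split$test$y)))
  graphics::plot(y, yhat, col = ifelse(grp == "train", "steelblue", "firebrick"),
                 pch = 19, xlab = "actual stiffness (N/m)",
                 ylab = "predicted stiffness (N/m)",
                 main = "Model prediction performance", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = c("train", "test"), pch = 19,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(NULL)
}
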
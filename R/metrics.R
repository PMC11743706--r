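# Evaluation metrics on inverse-normalized (N/m) predictions:
# mean bias error, root mean square error and relative error percentage.

check_pair <- function(y, yhat) {
  if (length(y) != length(yhat)) stopf("y and yhat lengths differ")
  if (length(y) < 1L) stopf("need at least one sample")
  if (anyNA(y) || anyNA(yhat)) stopf("missing values in y/yhat")
  invisible(NULL)
}

#' Mean bias error
#'
#' Signed mean of the residuals, \eqn{(1/n)\sum(y_m - \hat y_m)}; positive
#' when predictions fall below the truth on average.
#'
#' @param y True values (N/m).
#' @param yhat Predicted values (N/m).
#' @return MBE (N/m).
#' @export
mbe <- function(y, yhat) {
  check_pair(y, yhat)
  mean(y - yhat)
}

#' Root mean square error
#'
#' \eqn{\sqrt{(1/n)\sum(y_m - \hat y_m)^2}}.
#'
#' @inheritParams mbe
#' @return RMSE (N/m).
#' @export
rmse <- function(y, yhat) {
  check_pair(y, yhat)
  sqrt(mean((y - yhat)^2))
}

#' Relative error percentage
#'
#' Per-sample \eqn{|y_m - \hat y_m| / y_m \times 100}.  The absolute value
#' is applied per sample so the maximum and mean summaries are positive
#' magnitudes (reporting convention).
#'
#' @inheritParams mbe
#' @return List with `per_sample` (vector of %), `max` and `mean`.
#' @export
rep_errors <- function(y, yhat) {
  check_pair(y, yhat)
  if (any(y == 0)) stopf("REP undefined for zero-valued true values")
  r <- abs(y - yhat) / y * 100
  list(per_sample = r, max = max(r), mean = mean(r))
}

#' Evaluate a model on the training and test sets
#'
#' Predicts on raw-scale features through the model's stored normalization
#' (normalize, forward pass, inverse-normalize) and computes MBE, RMSE and
#' the REP max/mean per set, all in N/m or percent.
#'
#' @param model A [bp_model()].
#' @param split A [split_dataset()] result (raw scale).
#' @return A data frame of class `error_report` with one row per set and
#'   columns `set`, `n`, `mbe`, `rmse`, `rep_max`, `rep_mean`.
#' @export
evaluate_sets <- function(model, split) {
  one <- function(ds, label) {
    yhat <- predict(model, ds)
    r <- rep_errors(ds$y, yhat)
    data.frame(set = label, n = length(ds$y),
               mbe = mbe(ds$y, yhat), rmse = rmse(ds$y, yhat),
               rep_max = r$max, rep_mean = r$mean,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one(split$train, "train"), one(split$test, "test"))
  class(out) <- c("error_report", "data.frame")
  out
}

#' @export
print.error_report <- function(x, digits = 4, ...) {
  cat("Model error report (N/m; REP in %)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Write an error report to CSV
#'
#' Columns follow the conventional layout: MBE, RMSE, maximum REP and
#' average REP for the training and test sets.
#'
#' @param report An `error_report`.
#' @param path CSV path.
#' @return `path` invisibly.
#' @export
write_error_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
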
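#' Root mean square error
#'
#' @param measured,predicted Numeric vectors of equal length.
#' @return RMSE in the units of the inputs.
#' @export
rmse <- function(measured, predicted) {
  if (length(measured) != length(predicted)) {
    stop("rmse: length mismatch (", length(measured), " vs ",
         length(predicted), ")")
  }
  if (length(measured) < 1) stop("rmse: empty input")
  sqrt(mean((measured - predicted)^2))
}

#' Normalized (relative) root mean square error
#'
#' RMSE divided by the mean of the measured values, in percent.
#'
#' @inheritParams rmse
#' @return nRMSE in percent.
#' @export
nrmse <- function(measured, predicted) {
  m <- mean(measured)
  if (!is.finite(m) || m <= 0) stop("nrmse: mean of measured must be > 0")
  100 * rmse(measured, predicted) / m
}

#' Adjusted coefficient of determination
#'
#' 1 - [SSE/(n-p-1)] / [SST/(n-1)], penalizing for the number of predictors.
#'
#' @inheritParams rmse
#' @param p Number of predictors in the model that produced `predicted`.
#' @return Adjusted R-squared (can be negative).
#' @export
r2_adjusted <- function(measured, predicted, p) {
  n <- length(measured)
  if (n != length(predicted)) stop("r2_adjusted: length mismatch")
  if (n <= p + 1) stop("r2_adjusted: need n > p + 1")
  sst <- sum((measured - mean(measured))^2)
  if (sst <= 0) stop("r2_adjusted: zero variance in measured values")
  sse <- sum((measured - predicted)^2)
  1 - (sse / (n - p - 1)) / (sst / (n - 1))
}

#' Bundle the goodness-of-fit metrics into one report
#'
#' @inheritParams r2_adjusted
#' @return A `metrics_report` list: r2_adjusted, rmse, nrmse (%), n, p.
#' @export
metrics_report <- function(measured, predicted, p) {
  structure(list(r2_adjusted = r2_adjusted(measured, predicted, p),
                 rmse = rmse(measured, predicted),
                 nrmse = nrmse(measured, predicted),
                 n = length(measured), p = p),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n = %d, p = %d: adj. R2 = %.4f, RMSE = %.4f, nRMSE = %.2f%%\n",
              x$n, x$p, x$r2_adjusted, x$rmse, x$nrmse))
  invisible(x)
}
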
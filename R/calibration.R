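# Linear calibration of predicted against manually counted berries per
# bunch: least-squares fit actual ~ k * predicted + b, with RMSE of the raw
# predictions and the coefficient of determination of the fitted line.

as_count_pairs <- function(pairs) {
  if (!all(c("predicted", "actual") %in% names(pairs)))
    stop("count pairs need columns 'predicted' and 'actual'")
  if (nrow(pairs) == 0L) stop("count pairs are empty")
  pairs
}

#' Root mean square error between predicted and actual counts
#'
#' `sqrt(mean((predicted - actual)^2))`, in berries.
#'
#' @param pairs data.frame with columns `predicted` and `actual`.
#' @return non-negative scalar.
#' @export
count_rmse <- function(pairs) {
  pairs <- as_count_pairs(pairs)
  sqrt(mean((pairs$predicted - pairs$actual)^2))
}

#' Fit the count calibration line
#'
#' Closed-form least squares for `actual = k * predicted + b`, minimizing the
#' mean squared loss over bunches. The returned object also carries the RMSE
#' of the raw predictions and the R-squared of the fitted line.
#'
#' @param pairs data.frame with `predicted` (model counts per bunch) and
#'   `actual` (manual counts); at least 2 rows, non-constant predictor.
#' @return object of class `count_fit` with fields `k`, `b`, `rmse`, `r2`,
#'   `n`, and the `pairs` used.
#' @export
fit_count_regression <- function(pairs) {
  pairs <- as_count_pairs(pairs)
  x <- pairs$predicted; y <- pairs$actual
  if (length(x) < 2L) stop("fit_count_regression: need at least 2 bunches")
  if (stats::var(x) == 0) stop("fit_count_regression: constant predictor")
  k <- stats::cov(x, y) / stats::var(x)
  b <- mean(y) - k * mean(x)
  fit <- structure(list(k = k, b = b, rmse = count_rmse(pairs),
                        r2 = NA_real_, n = length(x), pairs = pairs),
                   class = "count_fit")
  fit$r2 <- if (stats::var(y) > 0) r_squared(pairs, fit) else NA_real_
  fit
}

#' Coefficient of determination of a calibration line
#'
#' Standard R-squared, `1 - SS_res / SS_tot`, of the line `k * predicted + b`
#' against the actual counts.
#'
#' @param pairs count pairs data.frame.
#' @param fit a `count_fit` (fitted from `pairs` when `NULL`).
#' @return R-squared in (-Inf, 1]; 1 exactly when all residuals vanish.
#' @export
r_squared <- function(pairs, fit = NULL) {
  pairs <- as_count_pairs(pairs)
  if (is.null(fit)) fit <- fit_count_regression(pairs)
  y <- pairs$actual
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("r_squared: zero variance in actual counts")
  f <- fit$k * pairs$predicted + fit$b
  1 - sum((y - f)^2) / ss_tot
}

#' Apply a fitted calibration to new predicted counts
#'
#' @param fit a `count_fit`.
#' @param predicted vector of raw predicted counts.
#' @return integer calibrated counts `round(k * predicted + b)`.
#' @export
calibrate_counts <- function(fit, predicted) {
  as.integer(round(fit$k * predicted + fit$b))
}

#' @export
print.count_fit <- function(x, ...) {
  cat(sprintf("count calibration: actual = %.4f * predicted + %.4f\n",
              x$k, x$b))
  cat(sprintf("  n = %d bunches, RMSE = %.3f berries, R^2 = %.4f\n",
              x$n, x$rmse, x$r2))
  invisible(x)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a count calibration fit
#'
#' @param x a `count_fit`.
#' @param ... unused.
#' @return data.frame with one row per model term.
#' @exportS3Method generics::tidy
tidy.count_fit <- function(x, ...) {
  data.frame(term = c("slope", "intercept"), estimate = c(x$k, x$b))
}

#' One-row summary of a count calibration fit
#'
#' @param x a `count_fit`.
#' @param ... unused.
#' @return data.frame with k, b, rmse, r2, n.
#' @exportS3Method generics::glance
glance.count_fit <- function(x, ...) {
  data.frame(k = x$k, b = x$b, rmse = x$rmse, r2 = x$r2, n = x$n)
}

#' Scatter-and-line plot of a count calibration
#'
#' @param object a `count_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.count_fit <- function(object, ...) {
  df <- object$pairs
  ggplot2::ggplot(df, ggplot2::aes(x = predicted, y = actual)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_point(colour = "#4a6fa5") +
    ggplot2::geom_abline(slope = object$k, intercept = object$b,
                         colour = "#b2444f") +
    ggplot2::labs(x = "predicted berries per bunch",
                  y = "actual berries per bunch",
                  title = sprintf("k = %.3f, b = %.2f, RMSE = %.2f, R² = %.3f",
                                  object$k, object$b, object$rmse,
                                  object$r2)) +
    ggplot2::theme_minimal()
}
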
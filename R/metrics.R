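#' Regression evaluation metrics
#'
#' Computes the three benchmark metrics: root mean squared logarithmic
#' error `RMSLE = sqrt(mean((log1p(pred) - log1p(obs))^2))`, the
#' coefficient of determination `R2 = 1 - SS_res / SS_tot`, and mean
#' absolute error. RMSLE measures relative error and is therefore
#' resistant to the impact of large outliers, which suits skewed
#' time-to-next-visit targets. Negative predictions are clipped to zero
#' (with a warning) before the logarithm.
#'
#' @param y_true observed non-negative targets.
#' @param y_pred predictions (same length).
#' @return named list `rmsle`, `r2`, `mae`. `r2` is `NaN` with a warning
#'   when `y_true` is constant.
#' @examples
#' regression_metrics(c(1, 2, 3), c(1, 2, 3))
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0L || length(y_true) != length(y_pred)) {
    abort("y_true and y_pred must be non-empty and equal length",
          "ohppfwa_data_error")
  }
  if (any(y_true < 0)) abort("y_true must be non-negative", "ohppfwa_data_error")
  if (any(y_pred < 0)) {
    warning("negative predictions clipped to 0 for RMSLE")
  }
  clipped <- pmax(y_pred, 0)
  rmsle <- sqrt(mean((log1p(clipped) - log1p(y_true))^2))
  mae <- mean(abs(y_true - y_pred))
  ss_tot <- sum((y_true - mean(y_true))^2)
  r2 <- if (ss_tot == 0) {
    warning("constant y_true: R2 undefined")
    NaN
  } else 1 - sum((y_true - y_pred)^2) / ss_tot
  list(rmsle = rmsle, r2 = r2, mae = mae)
}
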
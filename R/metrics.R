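#' Goodness-of-fit index (percent)
#'
#' `GFI = 100 * (1 - ||y - y_hat|| / ||y - mean(y)||)`: 100 for a perfect
#' fit, 0 for a predictor no better than the output mean, negative when
#' worse. The default uses Euclidean norms; `method = "abs"` uses sums of
#' absolute deviations instead.
#'
#' @param y Measured series (length >= 2, non-constant).
#' @param y_hat Predicted series, same length.
#' @param method `"norm"` (Euclidean, default) or `"abs"`.
#' @return GFI in percent (<= 100).
#' @export
gfi <- function(y, y_hat, method = c("norm", "abs")) {
  method <- match.arg(method)
  stopifnot(length(y) == length(y_hat), length(y) >= 2)
  centred <- y - mean(y)
  denom <- if (method == "norm") sqrt(sum(centred^2)) else sum(abs(centred))
  if (denom == 0) stop("GFI undefined for a constant measured series")
  num <- if (method == "norm") sqrt(sum((y - y_hat)^2)) else sum(abs(y - y_hat))
  100 * (1 - num / denom)
}

#' Root-mean-square tracking error
#'
#' @param y Output series.
#' @param r Reference series, same length.
#' @return `sqrt(mean((y - r)^2))`.
#' @export
rmse <- function(y, r) {
  stopifnot(length(y) == length(r), length(y) >= 1)
  sqrt(mean((y - r)^2))
}

#' Accumulated volume from a flow series
#'
#' Running sum of the flow times the sampling interval (rectangle rule,
#' matching hourly totalizer readings).
#'
#' @param flow Flow series (e.g. L/h).
#' @param dt Sampling interval (h), default 1.
#' @return Cumulative volume series, same length.
#' @export
accumulate_volume <- function(flow, dt = 1) cumsum(flow) * dt

#' Fit report for a prediction run
#'
#' @param y Measured flow series.
#' @param y_hat Predicted flow series.
#' @param r Optional reference series for tracking RMSE.
#' @param dt Sampling interval (h).
#' @return A list with `gfi_rate`, `gfi_cumulative` and (if `r` given)
#'   `rmse`.
#' @export
fit_report <- function(y, y_hat, r = NULL, dt = 1) {
  out <- list(gfi_rate = gfi(y, y_hat),
              gfi_cumulative = gfi(accumulate_volume(y, dt),
                                   accumulate_volume(y_hat, dt)))
  if (!is.null(r)) out$rmse <- rmse(y, r)
  out
}
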
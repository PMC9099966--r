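#' Calibration evaluation metrics
#'
#' The four standard figures of merit for spectroscopic calibration:
#' root mean square error (RMSE), coefficient of determination (R^2),
#' residual prediction deviation (RPD = SD of the measured values over
#' RMSE) and ratio of performance to interquartile distance
#' (RPIQ = (Q3 - Q1) / RMSE). RPD and RPIQ are unit-free: both are
#' invariant under a common positive rescaling of measured and predicted
#' values. RPD values above ~2 are conventionally read as good
#' quantitative capability; RPIQ is the robust analogue for skewed
#' attributes.
#'
#' Conventions: the standard deviation uses the `n - 1` denominator, and
#' quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7), so `rpiq(c(1, 2, 3, 4, 5), ...)` sees an
#' interquartile range of 2.
#'
#' @param y measured values.
#' @param y_hat predicted values (same length).
#' @return a single number.
#' @name metrics
NULL

check_pair <- function(y, y_hat) {
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  if (length(y) != length(y_hat)) {
    stop("y and y_hat lengths differ (", length(y), " vs ",
         length(y_hat), ")", call. = FALSE)
  }
  if (length(y) < 1L) stop("empty input", call. = FALSE)
  if (anyNA(y) || anyNA(y_hat)) stop("missing values not allowed",
                                     call. = FALSE)
  list(y = y, y_hat = y_hat)
}

#' @rdname metrics
#' @export
rmse <- function(y, y_hat) {
  p <- check_pair(y, y_hat)
  sqrt(mean((p$y - p$y_hat)^2))
}

#' @rdname metrics
#' @details `r_squared()` is `1 - SS_res / SS_tot` (perfect prediction
#'   scores 1); the complementary ratio `SS_res / SS_tot` is available as
#'   `residual_ratio()`, and the two always sum to 1.
#' @export
r_squared <- function(y, y_hat) {
  1 - residual_ratio(y, y_hat)
}

#' @rdname metrics
#' @export
residual_ratio <- function(y, y_hat) {
  p <- check_pair(y, y_hat)
  sstot <- sum((p$y - mean(p$y))^2)
  if (sstot == 0) stop("variance of y is zero; R^2 undefined", call. = FALSE)
  sum((p$y - p$y_hat)^2) / sstot
}

#' @rdname metrics
#' @export
rpd <- function(y, y_hat) {
  p <- check_pair(y, y_hat)
  if (length(p$y) < 2L) stop("need at least 2 observations", call. = FALSE)
  sdy <- stats::sd(p$y)
  if (sdy == 0) stop("SD of y is zero; RPD undefined", call. = FALSE)
  e <- rmse(p$y, p$y_hat)
  if (e == 0) {
    warning("zero RMSE; RPD reported as Inf", call. = FALSE)
    return(Inf)
  }
  sdy / e
}

#' @rdname metrics
#' @export
rpiq <- function(y, y_hat) {
  p <- check_pair(y, y_hat)
  if (length(p$y) < 4L) stop("need at least 4 observations", call. = FALSE)
  qs <- stats::quantile(p$y, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- qs[2L] - qs[1L]
  if (iqr == 0) stop("interquartile range of y is zero; RPIQ undefined",
                     call. = FALSE)
  e <- rmse(p$y, p$y_hat)
  if (e == 0) {
    warning("zero RMSE; RPIQ reported as Inf", call. = FALSE)
    return(Inf)
  }
  iqr / e
}

#' Evaluate a prediction set into a named metric vector
#'
#' @inheritParams metrics
#' @return named numeric vector `R2`, `RMSE`, `RPD`, `RPIQ`.
#' @export
evaluate_predictions <- function(y, y_hat) {
  c(R2 = r_squared(y, y_hat), RMSE = rmse(y, y_hat),
    RPD = rpd(y, y_hat), RPIQ = rpiq(y, y_hat))
}
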
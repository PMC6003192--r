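#' Linear calibration model
#'
#' A slope/intercept pair mapping an image-derived quantity onto a
#' ground-truth trait, together with the Pearson correlation and sample size
#' of the fit that produced it.
#'
#' @param slope,intercept Model coefficients.
#' @param r Pearson correlation of the fit (`NA` if unknown).
#' @param n Number of samples used (`NA` if unknown).
#' @param x_name,y_name Names of the predictor and response traits.
#' @return A list of class `linear_calibration`.
#' @export
linear_calibration <- function(slope, intercept, r = NA_real_, n = NA_integer_,
                               x_name = "x", y_name = "y") {
  stopifnot(is.numeric(slope), is.numeric(intercept))
  if (!is.na(r) && abs(r) > 1) stop("r must lie in [-1, 1]")
  structure(list(slope = slope, intercept = intercept, r = r,
                 n = if (is.na(n)) NA_integer_ else as.integer(n),
                 x_name = x_name, y_name = y_name),
            class = "linear_calibration")
}

#' @export
print.linear_calibration <- function(x, ...) {
  cat(sprintf("Linear calibration: %s = %.4f * %s %+.4f", x$y_name, x$slope,
              x$x_name, x$intercept))
  if (!is.na(x$r)) cat(sprintf("  (r = %.3f, n = %d)", x$r, x$n))
  cat("\n")
  invisible(x)
}

#' Default visible-to-total kernel count calibration
#'
#' The calibration shipped with the package maps the number of kernels
#' visible on a nadir photo of an intact ear (`kn`) onto the ear's total
#' kernel number: `total = 2.4051 * kn - 6.7334`. It was derived from 340
#' sub-tropical maize ears photographed individually and then threshed and
#' counted (r = 0.98). A visible face covers a bit less than half of the
#' ear, hence the slope above 2.
#'
#' @return A [linear_calibration()].
#' @export
kernel_count_model <- function() {
  linear_calibration(2.4051, -6.7334, r = 0.98, n = 340,
                     x_name = "visible_kernel_number",
                     y_name = "total_kernel_number")
}

#' Default kernel length-to-weight calibration
#'
#' Maps the mean visible kernel length (cm) onto the mean single-kernel
#' weight (g): `weight = 0.7435 * kl - 0.155`, derived from 200 ears of
#' contrasting kernel size weighed at 11--13% kernel moisture. Outside that
#' moisture range the prediction drifts with water content.
#'
#' @return A [linear_calibration()].
#' @export
kernel_weight_model <- function() {
  linear_calibration(0.7435, -0.155, n = 200,
                     x_name = "mean_kernel_length_cm",
                     y_name = "average_kernel_weight_g")
}

predict_calibration <- function(cal, x) {
  pmax(cal$slope * x + cal$intercept, 0)
}

#' Estimate total kernel number from the visible count
#'
#' Applies a linear calibration to the visible kernel count and floors the
#' result at zero (an estimate, reported as-is without rounding).
#'
#' @param kn Visible kernel count(s), >= 0.
#' @param cal A [linear_calibration()]; defaults to [kernel_count_model()].
#' @return Estimated total kernel number(s).
#' @export
total_kernel_number <- function(kn, cal = kernel_count_model()) {
  if (any(!is.finite(kn)) || any(kn < 0)) stop("kn must be >= 0")
  predict_calibration(cal, kn)
}

#' Estimate average kernel weight from mean kernel length
#'
#' @param kl_mean Mean kernel length(s) in cm, > 0.
#' @param cal A [linear_calibration()]; defaults to [kernel_weight_model()].
#' @return Estimated average kernel weight(s) in grams, floored at zero.
#' @export
average_kernel_weight <- function(kl_mean, cal = kernel_weight_model()) {
  if (any(!is.finite(kl_mean)) || any(kl_mean <= 0))
    stop("kl_mean must be > 0")
  predict_calibration(cal, kl_mean)
}

#' Estimate total kernel weight
#'
#' Product of the estimated total kernel number and the estimated average
#' kernel weight; monotone non-decreasing in both inputs for positive
#' slopes.
#'
#' @param kn Visible kernel count(s), >= 0.
#' @param kl_mean Mean kernel length(s) in cm, > 0.
#' @param count_cal,weight_cal The two component calibrations.
#' @return Estimated total kernel weight(s) in grams.
#' @export
total_kernel_weight <- function(kn, kl_mean,
                                count_cal = kernel_count_model(),
                                weight_cal = kernel_weight_model()) {
  total_kernel_number(kn, count_cal) * average_kernel_weight(kl_mean, weight_cal)
}

#' Fit a linear calibration by ordinary least squares
#'
#' @param x,y Equal-length numeric vectors (length >= 2); `x` must not be
#'   constant.
#' @param x_name,y_name Trait names stored in the result.
#' @return A [linear_calibration()] with OLS slope/intercept, Pearson `r`
#'   and `n`.
#' @export
fit_linear_calibration <- function(x, y, x_name = deparse(substitute(x)),
                                   y_name = deparse(substitute(y))) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("at least 2 points are required")
  if (stats::sd(x) == 0) stop("x is constant; the fit is degenerate")
  fit <- lm(y ~ x)
  r <- if (stats::sd(y) == 0) NA_real_ else cor(x, y)
  linear_calibration(unname(coef(fit)[2]), unname(coef(fit)[1]), r = r,
                     n = length(x), x_name = x_name, y_name = y_name)
}

#' Serialize a calibration to JSON
#'
#' @param cal A [linear_calibration()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(cal, path) {
  jsonlite::write_json(unclass(cal), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a calibration from JSON
#'
#' @param path JSON path written by [write_calibration()].
#' @return A [linear_calibration()].
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  linear_calibration(x$slope, x$intercept,
                     r = if (is.null(x$r)) NA_real_ else x$r,
                     n = if (is.null(x$n)) NA_integer_ else x$n,
                     x_name = x$x_name %||% "x", y_name = x$y_name %||% "y")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
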
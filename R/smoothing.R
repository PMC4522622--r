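#' Configuration for curve smoothing
#'
#' @param span Fraction of grid points in each local window (default 0.5,
#'   a conservative degree of smoothing that keeps the variability of
#'   sparse curves visible).
#' @param min_points Minimum number of grid points required to smooth
#'   (default 5); shorter curves are returned unchanged, flagged as not
#'   smoothed.
#' @param degree Local polynomial degree (1 = local linear, the default).
#' @return An object of class `smoothing_config`.
#' @export
smoothing_config <- function(span = 0.5, min_points = 5, degree = 1) {
  if (!(span > 0 && span <= 1)) stop("span must be in (0, 1]")
  if (min_points < 3) stop("min_points must be at least 3")
  if (!degree %in% c(1, 2)) stop("degree must be 1 or 2")
  structure(list(span = span, min_points = as.integer(min_points),
                 degree = degree),
            class = "smoothing_config")
}

#' Locally weighted smoothing of a net-survival curve
#'
#' Smooths the net-survival estimates with a tricube-weighted local
#' linear fit at each grid point over the span-defined neighbourhood
#' (classic LOWESS without robustness iterations; delegated to
#' [stats::lowess()] for `degree = 1`). The time grid is never altered.
#' Curves with fewer than `min_points` points are returned bit-identical
#' with attribute `smoothed = FALSE` — with very sparse data there is no
#' pattern left to show after smoothing.
#'
#' @param curve A `net_survival` curve.
#' @param config A [smoothing_config()].
#' @return The curve with `ns` replaced by its smoothed values, a raw
#'   copy in `ns_raw`, a `smoothed` 0/1 column and attribute `smoothed`.
#' @export
smooth_curve <- function(curve, config = smoothing_config()) {
  stopifnot(inherits(curve, "net_survival"), nrow(curve) >= 1L)
  if (nrow(curve) < config$min_points) {
    attr(curve, "smoothed") <- FALSE
    return(curve)
  }
  if (config$degree == 1) {
    fit <- stats::lowess(curve$time, curve$ns, f = config$span, iter = 0,
                         delta = 0)
    yhat <- fit$y[match(curve$time, fit$x)]
  } else {
    fit <- stats::loess(ns ~ time, data = curve, span = config$span,
                        degree = config$degree,
                        control = stats::loess.control(surface = "direct"))
    yhat <- stats::predict(fit, newdata = curve)
  }
  curve$ns_raw <- curve$ns
  curve$ns <- yhat
  curve$smoothed <- 1
  attr(curve, "smoothed") <- TRUE
  curve
}
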
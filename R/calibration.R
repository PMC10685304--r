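# Film calibration: monotone rational dose-response curve with a daily
# multiplicative dose-scale correction.
#
# The fitted form is dose(x) = (a + b*x) / (1 + c*x) for net response x, a
# standard saturating parametrization for radiochromic film. The fit is a
# linear least-squares problem after clearing the denominator:
#   dose = a + b*x - c*(x*dose).

#' Calibration curve object
#'
#' @param points data frame with columns `dose_gy` and `response`.
#' @param params named numeric `c(a, b, c)` of the rational form.
#' @param daily_scale multiplicative dose-scale factor applied on top of
#'   the batch curve (default 1; updated by [rescale_daily()]).
#' @param residuals fit residuals in Gy (diagnostics).
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(points, params, daily_scale = 1,
                              residuals = NULL) {
  stopifnot(is.data.frame(points),
            all(c("dose_gy", "response") %in% names(points)),
            length(params) == 3L)
  if (!is.finite(daily_scale) || daily_scale <= 0) {
    stop("daily_scale must be > 0")
  }
  structure(
    list(points = points, params = setNames(as.numeric(params),
                                            c("a", "b", "c")),
         daily_scale = daily_scale,
         response_range = range(points$response),
         dose_range = range(points$dose_gy),
         residuals = residuals),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  p <- x$params
  cat("<calibration_curve> dose(x) = (a + b x)/(1 + c x)\n")
  cat(sprintf("  a = %.6g, b = %.6g, c = %.6g, daily scale = %.6g\n",
              p["a"], p["b"], p["c"], x$daily_scale))
  cat(sprintf("  %d points, dose range [%.3g, %.3g] Gy, fit RMS %.3g Gy\n",
              nrow(x$points), x$dose_range[1], x$dose_range[2],
              if (is.null(x$residuals)) NA_real_
              else sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Evaluate a calibration curve: response to dose
#'
#' Applies the fitted rational form and the daily scale factor:
#' `dose = daily_scale * (a + b x) / (1 + c x)`.
#'
#' @param curve a [calibration_curve()].
#' @param response numeric vector/matrix of net response.
#' @return Dose in Gy, same shape as `response`.
#' @export
curve_dose <- function(curve, response) {
  p <- curve$params
  curve$daily_scale * (p["a"] + p["b"] * response) /
    (1 + p["c"] * response)
}

#' Invert a calibration curve: dose to response
#'
#' @param curve a [calibration_curve()].
#' @param dose numeric vector/matrix of dose in Gy.
#' @return Net response, same shape as `dose`.
#' @export
curve_response <- function(curve, dose) {
  p <- curve$params
  d <- dose / curve$daily_scale
  denom <- p["c"] * d - p["b"]
  if (any(abs(denom) < 1e-12, na.rm = TRUE)) {
    stop("dose outside the invertible range of the curve")
  }
  (p["a"] - d) / denom
}

#' Fit the batch calibration curve
#'
#' Fits the monotone rational form `dose(x) = (a + b x)/(1 + c x)` to paired
#' (dose, response) calibration points by least squares. The input points
#' must be strictly monotone (response strictly ordered with dose) and the
#' fitted mapping is verified to be strictly monotone and pole-free over the
#' calibrated response range.
#'
#' @param points data frame (or matrix) with columns `dose_gy`, `response`;
#'   at least 4 points with distinct doses.
#' @return A [calibration_curve()] with `daily_scale = 1` and residual
#'   diagnostics.
#' @export
fit_calibration_curve <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("dose_gy", "response") %in% names(points))) {
    stop("points must have columns dose_gy and response")
  }
  d <- as.numeric(points$dose_gy)
  x <- as.numeric(points$response)
  if (length(d) < 4L) stop("need at least 4 calibration points")
  if (anyDuplicated(d)) stop("calibration error: duplicate doses")
  ord <- order(d)
  dx <- diff(x[ord])
  if (any(dx == 0) || !(all(dx > 0) || all(dx < 0))) {
    stop("calibration error: response is not strictly monotone with dose")
  }
  # linear LS after clearing the denominator: d = a + b x - c (x d)
  X <- cbind(1, x, -x * d)
  qrX <- qr(X)
  if (qrX$rank < 3L) stop("fit error: rank-deficient calibration design")
  beta <- qr.coef(qrX, d)
  cur <- calibration_curve(data.frame(dose_gy = d, response = x), beta)
  cur$residuals <- d - curve_dose(cur, x)
  # monotonicity / pole check by dense sampling over the response range
  xs <- seq(min(x), max(x), length.out = 512L)
  if (any(1 + beta[3] * xs <= 0)) {
    stop("fit error: fitted curve has a pole inside the response range")
  }
  fs <- curve_dose(cur, xs)
  df <- diff(fs)
  if (any(df == 0) || !(all(df > 0) || all(df < 0))) {
    stop("fit error: fitted curve is not strictly monotone")
  }
  cur
}

#' Rescale a calibration curve from daily correction films
#'
#' Daily correction films with known doses are scanned together with the
#' treatment film; the single multiplicative dose-scale factor minimizing
#' the squared error between the known doses and `scale x` the batch-curve
#' inferred doses is stored as `daily_scale`.
#'
#' @param curve a [calibration_curve()].
#' @param daily_points data frame with columns `dose_gy`, `response`; 3 to
#'   5 films with doses inside the batch calibration range.
#' @return The curve with `daily_scale` updated.
#' @export
rescale_daily <- function(curve, daily_points) {
  stopifnot(inherits(curve, "calibration_curve"))
  daily_points <- as.data.frame(daily_points)
  n <- nrow(daily_points)
  if (n < 3L || n > 5L) {
    stop("design error: need 3 to 5 daily correction films, got ", n)
  }
  d <- as.numeric(daily_points$dose_gy)
  x <- as.numeric(daily_points$response)
  rng <- curve$dose_range
  if (any(d < rng[1] - 1e-9 | d > rng[2] + 1e-9)) {
    stop("design error: daily doses outside the batch calibration range")
  }
  base <- curve
  base$daily_scale <- 1
  inferred <- as.numeric(curve_dose(base, x))
  ss <- sum(inferred^2)
  if (ss <= 0) stop("design error: daily films carry no dose signal")
  curve$daily_scale <- sum(d * inferred) / ss
  if (curve$daily_scale <= 0) stop("design error: non-positive daily scale")
  curve
}

#' Convert a registered film scan to absolute dose
#'
#' Applies the (daily-rescaled) calibration curve pixel-wise. Pixels whose
#' response falls outside the calibrated response range, beyond a
#' configurable tolerance band, are flagged invalid (NA); if more than 5%
#' of pixels are out of range the conversion aborts.
#'
#' @param scan a [film_scan()] (typically after [apply_transform()]).
#' @param curve a [calibration_curve()].
#' @param range_tol tolerance band as a fraction of the calibrated response
#'   span allowed beyond each end (default 0.02).
#' @param max_out_frac maximum tolerated fraction of out-of-range pixels
#'   (default 0.05).
#' @return A [dose_plane2d()] in absolute Gy on the scan's grid.
#' @export
convert_response_to_dose <- function(scan, curve, range_tol = 0.02,
                                     max_out_frac = 0.05) {
  stopifnot(inherits(scan, "film_scan"),
            inherits(curve, "calibration_curve"))
  x <- scan$response
  rng <- curve$response_range
  band <- range_tol * diff(rng)
  out <- !is.na(x) & (x < rng[1] - band | x > rng[2] + band)
  n_in <- sum(!is.na(x))
  if (n_in == 0L) stop("conversion error: no valid pixels")
  frac_out <- sum(out) / n_in
  if (frac_out > max_out_frac) {
    stop(sprintf(paste0("conversion error: %.1f%% of pixels outside the ",
                        "calibrated response range (max %.1f%%)"),
                 100 * frac_out, 100 * max_out_frac))
  }
  dose <- curve_dose(curve, x)
  dose[out] <- NA_real_
  dose_plane2d(matrix(dose, nrow(x), ncol(x)), scan$spacing, scan$origin)
}
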
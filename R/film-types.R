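#' Scanned film response image
#'
#' A 2D array of net scanner response (arbitrary units, already netted
#' against the unexposed-film base value; response decreases monotonically
#' with dose for radiochromic film) together with the scan pixel pitch and
#' the three detected cassette-pin landmark positions in the scanner frame.
#'
#' @param response numeric matrix of net response, `>= 0` or NA.
#' @param spacing pixel pitch (mm), scalar or length 2.
#' @param landmarks 3 x 2 matrix of detected landmark positions (mm,
#'   scanner frame); must be non-collinear.
#' @param origin position (mm) of pixel `[1, 1]` in the scanner frame.
#' @return An object of class `film_scan`.
#' @export
film_scan <- function(response, spacing, landmarks, origin = c(0, 0)) {
  if (!is.matrix(response)) stop("response must be a matrix")
  if (any(is.infinite(response)) || any(response < 0, na.rm = TRUE)) {
    stop("response must be finite and >= 0")
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (any(spacing <= 0)) stop("spacing must be > 0")
  landmarks <- as.matrix(landmarks)
  if (!all(dim(landmarks) == c(3L, 2L))) {
    stop("landmarks must be a 3 x 2 matrix")
  }
  .check_noncollinear(landmarks, "detected landmarks")
  structure(
    list(response = response, spacing = as.numeric(spacing),
         landmarks = landmarks, origin = as.numeric(origin)),
    class = "film_scan"
  )
}

#' @export
print.film_scan <- function(x, ...) {
  cat("<film_scan> ", nrow(x$response), " x ", ncol(x$response),
      " px at ", paste(format(x$spacing), collapse = " x "), " mm\n",
      sep = "")
  invisible(x)
}

#' Film calibration design
#'
#' Describes the calibration protocol: the number of batch calibration
#' points and the daily-correction film scheme (3 to 5 films spanning the
#' day's working dose range, scanned together with the treatment film).
#'
#' @param n_points number of batch calibration points (default 20).
#' @param daily_range dose range (Gy) covered by the daily films.
#' @param n_daily number of daily correction films, between 3 and 5.
#' @return An object of class `calibration_design`.
#' @export
calibration_design <- function(n_points = 20L, daily_range = c(0, 10),
                               n_daily = 5L) {
  n_daily <- as.integer(n_daily)
  if (n_daily < 3L || n_daily > 5L) stop("n_daily must be in [3, 5]")
  if (length(daily_range) != 2L || diff(daily_range) <= 0) {
    stop("daily_range must be an increasing dose interval")
  }
  structure(
    list(n_points = as.integer(n_points), daily_range = daily_range,
         n_daily = n_daily),
    class = "calibration_design"
  )
}

#' 2D rigid transform (rotation + translation)
#'
#' Pure rotation and translation, no scaling or shear; used for scanner
#' rotation/translation corrections derived from the cassette-pin
#' landmarks. Applied as `p' = R(rotation) %*% p + translation`.
#'
#' @param rotation rotation angle in degrees (counter-clockwise).
#' @param translation numeric length 2 (mm).
#' @return An object of class `rigid_transform2d`.
#' @export
rigid_transform2d <- function(rotation = 0, translation = c(0, 0)) {
  stopifnot(is.numeric(rotation), length(rotation) == 1L,
            length(translation) == 2L)
  structure(
    list(rotation = as.numeric(rotation),
         translation = as.numeric(translation)),
    class = "rigid_transform2d"
  )
}

#' @noRd
.rotmat <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Apply a rigid transform to 2D points
#'
#' @param t a [rigid_transform2d()].
#' @param pts n x 2 matrix of points (mm).
#' @return The transformed n x 2 matrix.
#' @export
transform_points <- function(t, pts) {
  stopifnot(inherits(t, "rigid_transform2d"))
  pts <- rbind(pts)
  sweep(pts %*% t(.rotmat(t$rotation)), 2, t$translation, "+")
}

#' Invert a rigid transform
#'
#' @param t a [rigid_transform2d()].
#' @return The inverse [rigid_transform2d()].
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform2d"))
  R_inv <- .rotmat(-t$rotation)
  rigid_transform2d(-t$rotation, as.numeric(-R_inv %*% t$translation))
}
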
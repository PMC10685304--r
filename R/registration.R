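# Rigid landmark registration of film scans. The three cassette pins leave
# landmarks on every film; the least-squares rigid transform (Procrustes
# without scaling, solved by SVD) maps the detected scanner-frame positions
# onto the nominal film-frame pin layout and is then used to resample the
# scan onto the film-frame post-processing grid.

#' Solve the rigid transform between detected and nominal landmarks
#'
#' Least-squares rigid (rotation + translation, no scaling) transform
#' mapping the detected landmark positions onto the nominal pin layout,
#' solved in closed form via the SVD of the cross-covariance (Kabsch /
#' orthogonal Procrustes). The solution is exactly invariant to relabeling
#' of the point pairs.
#'
#' @param detected 3 x 2 matrix of detected landmark positions (mm,
#'   scanner frame).
#' @param nominal 3 x 2 matrix of nominal pin positions (mm, film frame).
#' @return A [rigid_transform2d()] with attribute `rms_residual` (mm).
#' @export
solve_landmark_transform <- function(detected, nominal) {
  detected <- as.matrix(detected)
  nominal <- as.matrix(nominal)
  if (!all(dim(detected) == dim(nominal)) || ncol(detected) != 2L ||
      nrow(detected) < 3L) {
    stop("geometry error: need matching n x 2 point sets, n >= 3")
  }
  .check_noncollinear(detected[1:3, ], "detected landmarks")
  .check_noncollinear(nominal[1:3, ], "nominal landmarks")
  cd <- colMeans(detected)
  cn <- colMeans(nominal)
  Xd <- sweep(detected, 2, cd)
  Xn <- sweep(nominal, 2, cn)
  H <- t(Xd) %*% Xn
  sv <- svd(H)
  D <- diag(c(1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% D %*% t(sv$u)
  tr <- cn - as.numeric(R %*% cd)
  ang <- atan2(R[2, 1], R[1, 1]) * 180 / pi
  out <- rigid_transform2d(ang, tr)
  fit <- transform_points(out, detected)
  attr(out, "rms_residual") <- sqrt(mean(rowSums((fit - nominal)^2)))
  out
}

#' Resample a film scan under a rigid transform
#'
#' Applies the solved scanner correction: the output is the response image
#' on the film-frame post-processing grid, each target pixel sampled
#' bilinearly from the scan at the inverse-transformed position. Pixels
#' falling outside the scan support are invalid (NA). The scan landmarks
#' are carried through the transform.
#'
#' @param scan a [film_scan()].
#' @param t a [rigid_transform2d()] mapping scanner frame to film frame
#'   (as returned by [solve_landmark_transform()]).
#' @param spec a [common_grid_spec()]; the output grid is `post_size`
#'   pixels at `spacing`, with origin (0, 0) in the film frame.
#' @return A [film_scan()] on the film-frame grid.
#' @export
apply_transform <- function(scan, t, spec = common_grid_spec()) {
  stopifnot(inherits(scan, "film_scan"),
            inherits(t, "rigid_transform2d"),
            inherits(spec, "common_grid_spec"))
  n1 <- spec$post_size[1]
  n2 <- spec$post_size[2]
  xs <- (seq_len(n1) - 1) * spec$spacing[1]
  ys <- (seq_len(n2) - 1) * spec$spacing[2]
  q <- cbind(rep(xs, times = n2), rep(ys, each = n1))
  p <- transform_points(invert_transform(t), q)
  vals <- .bilinear(scan$response, scan$origin, scan$spacing,
                    p[, 1], p[, 2])
  film_scan(matrix(vals, n1, n2), spec$spacing,
            transform_points(t, scan$landmarks), c(0, 0))
}
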
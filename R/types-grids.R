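#' 3D calculated dose grid
#'
#' Container for an absorbed-dose distribution on a regular 3D lattice with
#' a physical origin and voxel pitch, in the phantom coordinate frame. Axes
#' are labelled `crossline` (lateral, the film's short axis), `inline`
#' (longitudinal, along the bore, the film's long axis) and `depth`
#' (anterior-posterior, perpendicular to the coronal film plane).
#'
#' @param values 3D numeric array of dose in Gy, all values `>= 0` (NA marks
#'   invalid voxels).
#' @param origin numeric length 3; physical position (mm) of the centre of
#'   voxel `[1, 1, 1]`.
#' @param spacing numeric length 3; voxel pitch per axis in mm, all `> 0`.
#' @param axes character length 3; axis labels, a permutation of
#'   `c("crossline", "inline", "depth")`, giving the meaning of the array
#'   dimensions in order.
#' @return An object of class `dose_grid3d`.
#' @export
dose_grid3d <- function(values, origin, spacing,
                        axes = c("crossline", "inline", "depth")) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("values must be a 3D array")
  }
  if (length(origin) != 3L || length(spacing) != 3L) {
    stop("origin and spacing must have length 3")
  }
  if (any(spacing <= 0)) stop("spacing must be > 0 per axis")
  if (!setequal(axes, c("crossline", "inline", "depth")) ||
      length(axes) != 3L) {
    stop("axes must be a permutation of crossline, inline, depth")
  }
  if (any(values < 0, na.rm = TRUE)) stop("doses must be >= 0")
  structure(
    list(values = values, origin = as.numeric(origin),
         spacing = as.numeric(spacing), axes = axes),
    class = "dose_grid3d"
  )
}

#' @export
print.dose_grid3d <- function(x, ...) {
  cat("<dose_grid3d> ", paste(dim(x$values), collapse = " x "),
      " voxels (", paste(x$axes, collapse = ", "), ")\n", sep = "")
  cat("  spacing:", paste(format(x$spacing), collapse = " x "), "mm\n")
  cat("  origin :", paste(format(x$origin), collapse = ", "), "mm\n")
  cat("  dose   : [", format(min(x$values, na.rm = TRUE)), ",",
      format(max(x$values, na.rm = TRUE)), "] Gy\n")
  invisible(x)
}

# Reorder a grid to canonical (crossline, inline, depth) axis order.
#' @noRd
.canonical_grid <- function(grid) {
  canon <- c("crossline", "inline", "depth")
  perm <- match(canon, grid$axes)
  if (identical(perm, 1:3)) return(grid)
  dose_grid3d(aperm(grid$values, perm), grid$origin[perm],
              grid$spacing[perm], canon)
}

#' 2D dose image on the film plane
#'
#' A crossline x inline dose image with grid metadata. Rows index the
#' crossline (short, 60 mm) film axis and columns the inline (long, 165 mm)
#' axis. Values are absolute Gy, or dimensionless relative dose after
#' [normalize_relative()], in which case `norm_dose` records the Gy value the
#' plane was divided by.
#'
#' @param values numeric matrix of dose; NA marks invalid pixels.
#' @param spacing numeric length 2, pixel pitch (mm) for (crossline, inline).
#' @param origin numeric length 2, position (mm) of pixel `[1, 1]` in the
#'   film frame.
#' @param is_relative logical; whether values are relative to `norm_dose`.
#' @param norm_dose normalization dose in the plane's previous units; must be
#'   `> 0` when `is_relative`.
#' @return An object of class `dose_plane2d`.
#' @export
dose_plane2d <- function(values, spacing, origin = c(0, 0),
                         is_relative = FALSE, norm_dose = NA_real_) {
  if (!is.matrix(values)) stop("values must be a matrix")
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (any(spacing <= 0)) stop("spacing must be > 0")
  if (any(is.infinite(values))) stop("values must be finite or NA")
  if (isTRUE(is_relative) && (!is.finite(norm_dose) || norm_dose <= 0)) {
    stop("norm_dose must be > 0 for a relative plane")
  }
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin), is_relative = isTRUE(is_relative),
         norm_dose = norm_dose),
    class = "dose_plane2d"
  )
}

#' @export
print.dose_plane2d <- function(x, ...) {
  cat("<dose_plane2d> ", nrow(x$values), " x ", ncol(x$values),
      " (crossline x inline), ", paste(format(x$spacing), collapse = " x "),
      " mm\n", sep = "")
  cat("  units:", if (x$is_relative)
    paste0("relative (norm ", format(x$norm_dose), ")") else "Gy", "\n")
  n_na <- sum(is.na(x$values))
  if (n_na > 0) cat("  invalid pixels:", n_na, "\n")
  invisible(x)
}

#' Film cassette pose
#'
#' Geometry of the film cassette inside the phantom: the signed offset of
#' the coronal film plane from the phantom mid-coronal plane, the in-plane
#' origin of the film frame, and the nominal positions of the three cassette
#' pins that appear as landmarks on every scanned film.
#'
#' @param plane_offset signed distance (mm) of the film plane from the
#'   phantom mid-coronal plane (depth = 0).
#' @param in_plane_origin numeric length 2 (mm), film-frame position of the
#'   first post-processing voxel centre.
#' @param nominal_landmarks 3 x 2 numeric matrix of pin positions (mm) in
#'   the film frame; must be non-collinear.
#' @return An object of class `cassette_pose`.
#' @export
cassette_pose <- function(plane_offset = 0, in_plane_origin = c(0, 0),
                          nominal_landmarks = matrix(
                            c(5, 5, 55, 5, 30, 160), 3, 2, byrow = TRUE)) {
  nominal_landmarks <- as.matrix(nominal_landmarks)
  if (!all(dim(nominal_landmarks) == c(3L, 2L))) {
    stop("nominal_landmarks must be a 3 x 2 matrix")
  }
  .check_noncollinear(nominal_landmarks, "nominal landmarks")
  structure(
    list(plane_offset = plane_offset,
         in_plane_origin = as.numeric(in_plane_origin),
         nominal_landmarks = nominal_landmarks),
    class = "cassette_pose"
  )
}

#' @noRd
.check_noncollinear <- function(p, what = "landmarks") {
  d12 <- p[2, ] - p[1, ]
  d13 <- p[3, ] - p[1, ]
  scale <- max(sqrt(sum(d12^2)), sqrt(sum(d13^2)),
               sqrt(sum((p[3, ] - p[2, ])^2)))
  if (scale <= 0) stop(what, " are coincident")
  area2 <- abs(d12[1] * d13[2] - d12[2] * d13[1])
  if (area2 < 1e-8 * scale^2) stop(what, " are collinear or coincident")
  invisible(TRUE)
}

#' Common post-processing grid specification
#'
#' The shared 2D grid all film and calculated planes are brought onto before
#' comparison: 1x1 mm pitch over a 61 x 166 voxel extent covering the
#' 60 x 165 mm film, with one voxel trimmed from every border afterwards to
#' remove edge effects (final 59 x 164).
#'
#' @param spacing target pitch (mm), length 2 (crossline, inline).
#' @param post_size post-processing extent in voxels at `spacing`, length 2.
#' @param edge_trim voxels removed per border by [crop_edge_voxels()].
#' @return An object of class `common_grid_spec`.
#' @export
common_grid_spec <- function(spacing = c(1, 1), post_size = c(61, 166),
                             edge_trim = 1L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (any(spacing <= 0)) stop("spacing must be > 0")
  post_size <- as.integer(post_size)
  if (any(post_size < 1L)) stop("post_size must be >= 1 voxel per axis")
  edge_trim <- as.integer(edge_trim)
  if (edge_trim < 0L) stop("edge_trim must be >= 0")
  structure(
    list(spacing = as.numeric(spacing), post_size = post_size,
         edge_trim = edge_trim),
    class = "common_grid_spec"
  )
}
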
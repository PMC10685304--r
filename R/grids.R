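#' Extract the film-plane dose from a 3D dose grid
#'
#' Interpolates the calculated 3D dose trilinearly at the coronal film plane
#' defined by the cassette pose, sampled on the post-processing grid (61 x
#' 166 voxels at 1 mm by default). In-plane sample points outside the 3D
#' grid extent are marked invalid (NA) rather than extrapolated.
#'
#' @param grid a [dose_grid3d()].
#' @param pose a [cassette_pose()]; `plane_offset` selects the depth of the
#'   film plane, `in_plane_origin` anchors the 2D grid.
#' @param spec a [common_grid_spec()].
#' @return A [dose_plane2d()] in absolute Gy.
#' @export
extract_film_plane <- function(grid, pose = cassette_pose(),
                               spec = common_grid_spec()) {
  stopifnot(inherits(grid, "dose_grid3d"), inherits(pose, "cassette_pose"),
            inherits(spec, "common_grid_spec"))
  g <- .canonical_grid(grid)
  dm <- dim(g$values)
  z <- pose$plane_offset
  z_lo <- g$origin[3]
  z_hi <- g$origin[3] + (dm[3] - 1) * g$spacing[3]
  if (z < z_lo - 1e-9 || z > z_hi + 1e-9) {
    stop("film plane (depth ", format(z), " mm) lies outside the grid ",
         "extent [", format(z_lo), ", ", format(z_hi), "] mm")
  }
  # interpolate along depth first, then bilinearly in-plane: this is exact
  # trilinear interpolation and reuses the 2D sampler
  gk <- (z - g$origin[3]) / g$spacing[3] + 1
  gk <- min(max(gk, 1), dm[3])
  fk <- min(floor(gk), max(dm[3] - 1L, 1L))
  wk <- gk - fk
  slab <- (1 - wk) * g$values[, , fk] +
    wk * g$values[, , min(fk + 1L, dm[3])]
  n1 <- spec$post_size[1]
  n2 <- spec$post_size[2]
  xs <- pose$in_plane_origin[1] + (seq_len(n1) - 1) * spec$spacing[1]
  ys <- pose$in_plane_origin[2] + (seq_len(n2) - 1) * spec$spacing[2]
  vals <- .bilinear(slab, g$origin[1:2], g$spacing[1:2],
                    rep(xs, times = n2), rep(ys, each = n1))
  dose_plane2d(matrix(vals, n1, n2), spec$spacing, pose$in_plane_origin)
}

#' Resample a dose plane onto the common grid
#'
#' Bilinear resampling onto the target pitch, anchored at the plane's own
#' origin. No extrapolation: the target grid is restricted to the source
#' voxel-centre extent.
#'
#' @param plane a [dose_plane2d()].
#' @param spec a [common_grid_spec()] giving the target `spacing`.
#' @return A [dose_plane2d()] at the common pitch.
#' @export
resample_plane <- function(plane, spec = common_grid_spec()) {
  stopifnot(inherits(plane, "dose_plane2d"))
  if (length(plane$values) == 0L) stop("empty plane")
  nr <- nrow(plane$values)
  nc <- ncol(plane$values)
  ext <- (c(nr, nc) - 1) * plane$spacing
  n_new <- pmax(floor(ext / spec$spacing + 1e-9), 0) + 1
  xs <- plane$origin[1] + (seq_len(n_new[1]) - 1) * spec$spacing[1]
  ys <- plane$origin[2] + (seq_len(n_new[2]) - 1) * spec$spacing[2]
  vals <- .bilinear(plane$values, plane$origin, plane$spacing,
                    rep(xs, times = n_new[2]), rep(ys, each = n_new[1]))
  dose_plane2d(matrix(vals, n_new[1], n_new[2]), spec$spacing, plane$origin,
               plane$is_relative, plane$norm_dose)
}

#' Trim edge voxels from a dose plane
#'
#' Deletes `edge_trim` rows and columns from every border to remove edge
#' effects (film cutting, interpolation roll-off), advancing the origin
#' accordingly. With the default spec this takes the 61 x 166 mm
#' post-processing grid to the final 59 x 164 mm analysis grid.
#'
#' @inheritParams resample_plane
#' @return The trimmed [dose_plane2d()].
#' @export
crop_edge_voxels <- function(plane, spec = common_grid_spec()) {
  stopifnot(inherits(plane, "dose_plane2d"))
  t <- spec$edge_trim
  if (t == 0L) return(plane)
  nr <- nrow(plane$values)
  nc <- ncol(plane$values)
  if (nr - 2L * t < 1L || nc - 2L * t < 1L) {
    stop("plane extent (", nr, " x ", nc, ") too small to trim ", t,
         " voxel(s) per border")
  }
  dose_plane2d(plane$values[(1L + t):(nr - t), (1L + t):(nc - t),
                            drop = FALSE],
               plane$spacing, plane$origin + t * plane$spacing,
               plane$is_relative, plane$norm_dose)
}

#' Sum per-fraction dose planes
#'
#' Voxel-wise sum of absolute dose planes on identical grid geometry; used
#' to accumulate the five per-fraction calculated planes into the total
#' treatment dose. Invalid (NA) voxels in any fraction stay invalid in the
#' sum.
#'
#' @param planes list of absolute [dose_plane2d()] objects with identical
#'   geometry.
#' @return A [dose_plane2d()] holding the total dose.
#' @export
sum_planes <- function(planes) {
  if (!is.list(planes) || length(planes) == 0L) {
    stop("planes must be a non-empty list")
  }
  if (length(planes) == 1L) {
    stopifnot(inherits(planes[[1L]], "dose_plane2d"))
    if (planes[[1L]]$is_relative) stop("planes must be absolute dose")
    return(planes[[1L]])
  }
  ref <- planes[[1L]]
  for (p in planes) {
    stopifnot(inherits(p, "dose_plane2d"))
    if (p$is_relative) stop("planes must be absolute dose, not relative")
    if (!.same_geometry(ref, p)) {
      stop("planes do not share grid geometry (dim/spacing/origin)")
    }
  }
  total <- Reduce(`+`, lapply(planes, `[[`, "values"))
  dose_plane2d(total, ref$spacing, ref$origin)
}
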
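# Comparison statistics between the measured film plane (reference) and
# the calculated plane (evaluated distribution): relative normalization,
# bounded shift correction, global gamma, dose deviation, DTA, center
# profiles and chamber point comparison. All statistics exclude invalid
# (NA) voxels and report how many were excluded.

#' @noRd
.fine_lattice <- function(plane, h) {
  if (abs(plane$spacing[1] - plane$spacing[2]) > 1e-9) {
    stop("spec error: fine lattice requires isotropic plane spacing")
  }
  k <- plane$spacing[1] / h
  kr <- as.integer(round(k))
  if (kr < 1L || abs(k - kr) > 1e-6) {
    stop("spec error: eval_subsample must divide the grid pitch")
  }
  nr <- nrow(plane$values)
  nc <- ncol(plane$values)
  n1 <- (nr - 1L) * kr + 1L
  n2 <- (nc - 1L) * kr + 1L
  xs <- plane$origin[1] + (seq_len(n1) - 1) * h
  ys <- plane$origin[2] + (seq_len(n2) - 1) * h
  vals <- .bilinear(plane$values, plane$origin, plane$spacing,
                    rep(xs, times = n2), rep(ys, each = n1))
  list(values = matrix(vals, n1, n2), k = kr)
}

#' @noRd
.largest_component <- function(mask) {
  # 8-connectivity flood fill; returns linear indices of the largest
  # connected TRUE component
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  best <- integer(0)
  nb_i <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
  nb_j <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    lab[s] <- cur
    comp <- s
    while (length(stack) > 0L) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- ((p - 1L) %% nr) + 1L
      j <- ((p - 1L) %/% nr) + 1L
      for (d in 1:8) {
        ii <- i + nb_i[d]
        jj <- j + nb_j[d]
        if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc) {
          q <- (jj - 1L) * nr + ii
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- cur
            stack <- c(stack, q)
            comp <- c(comp, q)
          }
        }
      }
    }
    if (length(comp) > length(best)) best <- comp
  }
  best
}

#' Locate the center of the high dose region
#'
#' Returns the centroid of the largest connected component of voxels at or
#' above 90% of the plane maximum.
#'
#' @param plane a [dose_plane2d()].
#' @return Numeric length 2: (crossline, inline) position in mm.
#' @export
locate_high_dose_center <- function(plane) {
  stopifnot(inherits(plane, "dose_plane2d"))
  m <- suppressWarnings(max(plane$values, na.rm = TRUE))
  if (!is.finite(m) || m <= 0) {
    stop("degenerate plane: no positive dose region")
  }
  mask <- !is.na(plane$values) & plane$values >= 0.9 * m
  comp <- .largest_component(mask)
  nr <- nrow(plane$values)
  i <- ((comp - 1L) %% nr) + 1L
  j <- ((comp - 1L) %/% nr) + 1L
  c(plane$origin[1] + (mean(i) - 1) * plane$spacing[1],
    plane$origin[2] + (mean(j) - 1) * plane$spacing[2])
}

#' Normalize a dose plane to the high-dose-center median
#'
#' Divides the plane by the median dose within a disk of given radius
#' around the high-dose center, turning it into a relative distribution.
#' The disk must lie inside the plane extent.
#'
#' @param plane a [dose_plane2d()].
#' @param center numeric length 2 (mm); typically from
#'   [locate_high_dose_center()] on the calculated plane.
#' @param radius_mm disk radius (default 10 mm).
#' @return The relative [dose_plane2d()] with `norm_dose` set to the
#'   median that was divided out.
#' @export
normalize_relative <- function(plane, center, radius_mm = 10) {
  stopifnot(inherits(plane, "dose_plane2d"), length(center) == 2L)
  nr <- nrow(plane$values)
  nc <- ncol(plane$values)
  lo <- plane$origin
  hi <- plane$origin + (c(nr, nc) - 1) * plane$spacing
  if (any(center - radius_mm < lo - 1e-9) ||
      any(center + radius_mm > hi + 1e-9)) {
    stop("normalization error: ", radius_mm,
         " mm disk around the center extends outside the plane")
  }
  xs <- lo[1] + (seq_len(nr) - 1) * plane$spacing[1]
  ys <- lo[2] + (seq_len(nc) - 1) * plane$spacing[2]
  d2 <- outer((xs - center[1])^2, (ys - center[2])^2, "+")
  sel <- d2 <= radius_mm^2 & !is.na(plane$values)
  if (!any(sel)) stop("normalization error: empty disk")
  nd <- median(plane$values[sel])
  if (!is.finite(nd) || nd <= 0) {
    stop("normalization error: non-positive normalization dose")
  }
  dose_plane2d(plane$values / nd, plane$spacing, plane$origin,
               is_relative = TRUE, norm_dose = nd)
}

#' @noRd
.plane_dmax <- function(measured, calculated, thr) {
  src <- if (thr$dmax_source == "calculated") calculated else measured
  m <- suppressWarnings(max(src$values, na.rm = TRUE))
  if (!is.finite(m) || m <= 0) stop("degenerate plane: D_max <= 0")
  m
}

#' Bounded shift correction between measured and calculated planes
#'
#' Grid search over in-plane displacements up to `max_shift` per axis at
#' pitch `step`, minimizing the mean squared relative dose difference over
#' voxels at or above the low threshold of the calculated plane. Among
#' equal objectives the smallest displacement wins. The returned shift `s`
#' is the translation applied to the measured image, i.e. the corrected
#' plane is `measured(r - s)`.
#'
#' @param measured,calculated relative [dose_plane2d()] objects on the
#'   common grid (measured is the distribution being moved).
#' @param spec a [shift_search_spec()].
#' @param thr an [analysis_thresholds()]; the low threshold defines the
#'   objective mask.
#' @return List with `shift` (mm, crossline/inline), `plane` (the shifted
#'   measured plane), `objective` and `n_voxels`.
#' @export
optimize_shift <- function(measured, calculated,
                           spec = shift_search_spec(),
                           thr = analysis_thresholds()) {
  stopifnot(inherits(measured, "dose_plane2d"),
            inherits(calculated, "dose_plane2d"),
            inherits(spec, "shift_search_spec"))
  if (!measured$is_relative || !calculated$is_relative) {
    stop("optimize_shift expects relative planes")
  }
  if (!.same_geometry(measured, calculated)) {
    stop("planes do not share grid geometry")
  }
  dmax <- .plane_dmax(measured, calculated, thr)
  mask <- !is.na(calculated$values) & calculated$values >= thr$low * dmax
  res <- cpp_shift_search(measured$values, calculated$values, mask,
                          measured$spacing[1], measured$spacing[2],
                          spec$step, spec$max_shift)
  s <- res$shift
  nr <- nrow(measured$values)
  nc <- ncol(measured$values)
  xs <- measured$origin[1] + (seq_len(nr) - 1) * measured$spacing[1]
  ys <- measured$origin[2] + (seq_len(nc) - 1) * measured$spacing[2]
  shifted <- .bilinear(measured$values, measured$origin, measured$spacing,
                       rep(xs - s[1], times = nc),
                       rep(ys - s[2], each = nr))
  plane <- dose_plane2d(matrix(shifted, nr, nc), measured$spacing,
                        measured$origin, TRUE, measured$norm_dose)
  list(shift = s, plane = plane, objective = res$objective,
       n_voxels = res$n_voxels)
}

#' Global gamma analysis
#'
#' Computes the gamma index at every reference (measured) voxel:
#' \deqn{\gamma(r) = \min_{|s| \le R} \sqrt{ |s|^2/\delta^2 +
#'   (D_m(r) - D_c(r+s))^2 / (\Delta \cdot D_{norm})^2 }}
#' with distance tolerance \eqn{\delta}, global dose tolerance
#' \eqn{\Delta \cdot D_{norm}}, and the evaluated (calculated) distribution
#' interpolated bilinearly on a lattice of pitch `eval_subsample`. Pass
#' rates are the percentage of voxels with \eqn{\gamma \le 1} among those
#' at or above each dose threshold.
#'
#' @param measured reference relative [dose_plane2d()].
#' @param calculated evaluated relative [dose_plane2d()], same grid.
#' @param crit a [gamma_criteria()].
#' @param thr an [analysis_thresholds()].
#' @return List with `gamma` (map), `pass_rates` (%, named by threshold),
#'   `dmax`, `n_excluded`, and the voxel masks used per threshold.
#' @export
compute_gamma <- function(measured, calculated, crit = gamma_criteria(),
                          thr = analysis_thresholds()) {
  stopifnot(inherits(measured, "dose_plane2d"),
            inherits(calculated, "dose_plane2d"),
            inherits(crit, "gamma_criteria"))
  if (!measured$is_relative || !calculated$is_relative) {
    stop("compute_gamma expects relative planes")
  }
  if (!.same_geometry(measured, calculated)) {
    stop("planes do not share grid geometry")
  }
  fine <- .fine_lattice(calculated, crit$eval_subsample)
  # global criterion: tolerance is dose_tol x the normalization dose, which
  # is 1 in relative units
  g <- cpp_gamma_map(measured$values, fine$values, fine$k,
                     crit$eval_subsample, crit$dist_tol, crit$dose_tol,
                     crit$search_radius)
  dmax <- .plane_dmax(measured, calculated, thr)
  thr_src <- if (thr$dmax_source == "calculated") calculated else measured
  masks <- list(
    low = !is.na(thr_src$values) & thr_src$values >= thr$low * dmax,
    high = !is.na(thr_src$values) & thr_src$values >= thr$high * dmax
  )
  pass <- vapply(masks, function(m) {
    gv <- g[m]
    gv <- gv[!is.na(gv)]
    if (length(gv) == 0L) return(NA_real_)
    100 * mean(gv <= 1 + 1e-9)
  }, numeric(1))
  names(pass) <- c(sprintf("%d%%", round(100 * thr$low)),
                   sprintf("%d%%", round(100 * thr$high)))
  list(gamma = g, pass_rates = pass, dmax = dmax, masks = masks,
       n_excluded = sum(is.na(g) & !is.na(measured$values)) +
         sum(is.na(measured$values)))
}

#' Voxel-wise dose deviation
#'
#' The dose deviation is the voxel-wise difference between measurements
#' and calculations without any distance-to-agreement credit, expressed in
#' percent of the normalization dose. Mean and SD are reported over the
#' voxels at or above each dose threshold.
#'
#' @inheritParams compute_gamma
#' @return List with `deviation` (map, %), and a `stats` data frame
#'   (threshold, mean, sd, n).
#' @export
compute_dose_deviation <- function(measured, calculated,
                                   thr = analysis_thresholds()) {
  stopifnot(inherits(measured, "dose_plane2d"),
            inherits(calculated, "dose_plane2d"))
  if (!measured$is_relative || !calculated$is_relative) {
    stop("compute_dose_deviation expects relative planes")
  }
  if (!.same_geometry(measured, calculated)) {
    stop("planes do not share grid geometry")
  }
  dev <- 100 * (measured$values - calculated$values)
  dmax <- .plane_dmax(measured, calculated, thr)
  thr_src <- if (thr$dmax_source == "calculated") calculated else measured
  stats <- do.call(rbind, lapply(c(thr$low, thr$high), function(f) {
    m <- !is.na(thr_src$values) & thr_src$values >= f * dmax
    v <- dev[m]
    v <- v[!is.na(v)]
    data.frame(threshold = f, mean = mean(v),
               sd = if (length(v) > 1L) sd(v) else 0, n = length(v))
  }))
  list(deviation = dev, stats = stats, dmax = dmax)
}

#' Distance-to-agreement map
#'
#' For each reference voxel, the smallest displacement at which the
#' evaluated distribution matches the reference dose within the local
#' tolerance (0.5% of the voxel's own dose by default), searched on the
#' fine interpolation lattice. Summary statistics are computed over the
#' voxels whose threshold dose lies inside the band (10%-90% of D_max).
#'
#' @inheritParams compute_gamma
#' @param spec a [dta_spec()].
#' @param thr an [analysis_thresholds()] (provides the D_max source).
#' @return List with `dta` (map, mm), `saturated` (flag map), `mean`,
#'   `sd`, `n_band`, `n_saturated`.
#' @export
compute_dta <- function(measured, calculated, spec = dta_spec(),
                        thr = analysis_thresholds()) {
  stopifnot(inherits(measured, "dose_plane2d"),
            inherits(calculated, "dose_plane2d"),
            inherits(spec, "dta_spec"))
  if (!measured$is_relative || !calculated$is_relative) {
    stop("compute_dta expects relative planes")
  }
  if (!.same_geometry(measured, calculated)) {
    stop("planes do not share grid geometry")
  }
  fine <- .fine_lattice(calculated, spec$eval_subsample)
  res <- cpp_dta_map(measured$values, fine$values, fine$k,
                     spec$eval_subsample, spec$local_tol,
                     spec$search_radius)
  dmax <- .plane_dmax(measured, calculated, thr)
  thr_src <- if (thr$dmax_source == "calculated") calculated else measured
  band <- !is.na(thr_src$values) &
    thr_src$values >= spec$band[1] * dmax &
    thr_src$values <= spec$band[2] * dmax
  v <- res$dta[band]
  v <- v[!is.na(v)]
  list(dta = res$dta, saturated = res$saturated,
       mean = if (length(v)) mean(v) else NA_real_,
       sd = if (length(v) > 1L) sd(v) else 0,
       n_band = length(v),
       n_saturated = sum(res$saturated[band], na.rm = TRUE))
}

#' Center dose profiles and percentage-point differences
#'
#' Extracts the inline and crossline 1D profiles through the high-dose
#' center from both planes and reports their differences in percentage
#' points: `100 * (measured - calculated)` in relative units, so a 0.012
#' relative offset reads as 1.2 pp.
#'
#' @inheritParams compute_gamma
#' @param center numeric length 2 (mm), typically from
#'   [locate_high_dose_center()].
#' @return List with `inline` and `crossline` data frames (position,
#'   measured, calculated, diff_pp) and `mean_pp` / `max_abs_pp` per
#'   direction.
#' @export
extract_center_profiles <- function(measured, calculated, center) {
  stopifnot(inherits(measured, "dose_plane2d"),
            inherits(calculated, "dose_plane2d"), length(center) == 2L)
  if (!.same_geometry(measured, calculated)) {
    stop("planes do not share grid geometry")
  }
  nr <- nrow(measured$values)
  nc <- ncol(measured$values)
  i0 <- round((center[1] - measured$origin[1]) / measured$spacing[1]) + 1
  j0 <- round((center[2] - measured$origin[2]) / measured$spacing[2]) + 1
  if (i0 < 1 || i0 > nr || j0 < 1 || j0 > nc) {
    stop("center lies outside the plane")
  }
  inline <- data.frame(
    position = measured$origin[2] + (seq_len(nc) - 1) * measured$spacing[2],
    measured = measured$values[i0, ],
    calculated = calculated$values[i0, ])
  inline$diff_pp <- 100 * (inline$measured - inline$calculated)
  crossline <- data.frame(
    position = measured$origin[1] + (seq_len(nr) - 1) * measured$spacing[1],
    measured = measured$values[, j0],
    calculated = calculated$values[, j0])
  crossline$diff_pp <- 100 * (crossline$measured - crossline$calculated)
  list(inline = inline, crossline = crossline,
       mean_pp = c(inline = mean(inline$diff_pp, na.rm = TRUE),
                   crossline = mean(crossline$diff_pp, na.rm = TRUE)),
       max_abs_pp = c(inline = max(abs(inline$diff_pp), na.rm = TRUE),
                      crossline = max(abs(crossline$diff_pp), na.rm = TRUE)))
}

#' Compare a chamber reading against the calculated dose
#'
#' The calculated value is the mean dose over a sphere matching the
#' chamber's active volume, evaluated by trilinear interpolation on a
#' 0.5 mm sub-lattice of points inside the sphere. The result is the
#' measured-minus-calculated difference as a percentage of the calculated
#' dose.
#'
#' @param measured_gy scalar chamber reading in Gy.
#' @param grid a [dose_grid3d()].
#' @param spec a [chamber_spec()].
#' @param sub_step sub-lattice pitch in mm (default 0.5).
#' @return Scalar percent difference, with attributes `calculated_gy` and
#'   `n_points`.
#' @export
compare_chamber <- function(measured_gy, grid, spec = chamber_spec(),
                            sub_step = 0.5) {
  stopifnot(is.numeric(measured_gy), length(measured_gy) == 1L,
            inherits(grid, "dose_grid3d"), inherits(spec, "chamber_spec"))
  g <- .canonical_grid(grid)
  dm <- dim(g$values)
  lo <- g$origin
  hi <- g$origin + (dm - 1) * g$spacing
  if (any(spec$position - spec$radius < lo - 1e-9) ||
      any(spec$position + spec$radius > hi + 1e-9)) {
    stop("extent error: averaging sphere extends outside the dose grid")
  }
  off <- seq(-spec$radius, spec$radius, by = sub_step)
  pts <- as.matrix(expand.grid(off, off, off))
  pts <- pts[rowSums(pts^2) <= spec$radius^2 + 1e-12, , drop = FALSE]
  pts <- sweep(pts, 2, spec$position, "+")
  vals <- .trilinear(g$values, g$origin, g$spacing, pts)
  calc <- mean(vals, na.rm = TRUE)
  if (!is.finite(calc) || calc <= 0) {
    stop("extent error: no valid calculated dose inside the sphere")
  }
  structure(100 * (measured_gy - calc) / calc,
            calculated_gy = calc, n_points = nrow(pts))
}

#' Assemble a per-dataset comparison summary
#'
#' Collects the component maps and statistics into one `comparison_result`
#' carrying the Table-style summary row: gamma pass rates at the low/high
#' thresholds, dose-deviation mean+-SD at both thresholds, DTA mean+-SD in
#' the threshold band, and the applied shift.
#'
#' @param dataset_id identifier string.
#' @param mode `"single_fraction"` or `"total_dose"`.
#' @param gamma_res result of [compute_gamma()].
#' @param dev_res result of [compute_dose_deviation()].
#' @param dta_res result of [compute_dta()].
#' @param shift applied shift (mm, crossline/inline).
#' @param norm_dose_measured,norm_dose_calculated normalization doses (Gy).
#' @param profiles optional result of [extract_center_profiles()].
#' @return An object of class `comparison_result`; `as.data.frame()` gives
#'   the summary row.
#' @export
summarize_comparison <- function(dataset_id, mode, gamma_res, dev_res,
                                 dta_res, shift,
                                 norm_dose_measured = NA_real_,
                                 norm_dose_calculated = NA_real_,
                                 profiles = NULL) {
  dims <- list(dim(gamma_res$gamma), dim(dev_res$deviation),
               dim(dta_res$dta))
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("consistency error: component maps differ in geometry")
  }
  row <- data.frame(
    dataset = dataset_id, mode = mode,
    pass_low = unname(gamma_res$pass_rates[1]),
    pass_high = unname(gamma_res$pass_rates[2]),
    dev_mean_low = dev_res$stats$mean[1],
    dev_sd_low = dev_res$stats$sd[1],
    dev_mean_high = dev_res$stats$mean[2],
    dev_sd_high = dev_res$stats$sd[2],
    dta_mean = dta_res$mean, dta_sd = dta_res$sd,
    shift_crossline = shift[1], shift_inline = shift[2],
    norm_dose_measured = norm_dose_measured,
    norm_dose_calculated = norm_dose_calculated,
    n_saturated = dta_res$n_saturated,
    n_excluded = gamma_res$n_excluded,
    stringsAsFactors = FALSE)
  structure(
    list(row = row, gamma = gamma_res, deviation = dev_res, dta = dta_res,
         profiles = profiles, shift = shift),
    class = "comparison_result"
  )
}

#' @export
as.data.frame.comparison_result <- function(x, ...) x$row

#' @export
print.comparison_result <- function(x, ...) {
  r <- x$row
  cat(sprintf("<comparison_result> %s (%s)\n", r$dataset, r$mode))
  cat(sprintf("  gamma pass: %.1f%% / %.1f%% (low/high threshold)\n",
              r$pass_low, r$pass_high))
  cat(sprintf("  dose dev  : %.2f +- %.2f %% / %.2f +- %.2f %%\n",
              r$dev_mean_low, r$dev_sd_low, r$dev_mean_high,
              r$dev_sd_high))
  cat(sprintf("  DTA       : %.2f +- %.2f mm\n", r$dta_mean, r$dta_sd))
  cat(sprintf("  shift     : (%.2f, %.2f) mm\n", r$shift_crossline,
              r$shift_inline))
  invisible(x)
}
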
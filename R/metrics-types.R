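# Parameter objects for the comparison statistics.

#' Gamma analysis criteria
#'
#' Global gamma criteria: the dose tolerance is a fraction of the single
#' normalization dose (not of each local dose), the distance tolerance is
#' in mm. The evaluated distribution is interpolated on a fine lattice of
#' pitch `eval_subsample` and searched within `search_radius`.
#'
#' @param dose_tol fractional dose-difference tolerance (default 0.02).
#' @param dist_tol distance-to-agreement tolerance in mm (default 2).
#' @param search_radius search cap in mm (default `3 * dist_tol`); gamma
#'   values are exact up to `search_radius / dist_tol`.
#' @param eval_subsample interpolation pitch (mm) of the evaluated
#'   distribution (default 0.2); must divide the grid pitch.
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_tol = 0.02, dist_tol = 2,
                           search_radius = 3 * dist_tol,
                           eval_subsample = 0.2) {
  if (any(c(dose_tol, dist_tol, search_radius, eval_subsample) <= 0)) {
    stop("spec error: gamma criteria must be strictly positive")
  }
  if (search_radius < dist_tol) {
    stop("spec error: search_radius must be >= dist_tol")
  }
  structure(
    list(dose_tol = dose_tol, dist_tol = dist_tol,
         search_radius = search_radius, eval_subsample = eval_subsample),
    class = "gamma_criteria"
  )
}

#' Dose threshold specification
#'
#' Low and high analysis thresholds as fractions of D_max. D_max is taken
#' from the calculated relative plane by default (configurable).
#'
#' @param low low threshold fraction (default 0.10).
#' @param high high threshold fraction (default 0.90).
#' @param dmax_source which plane defines D_max: "calculated" or
#'   "measured".
#' @return An object of class `analysis_thresholds`.
#' @export
analysis_thresholds <- function(low = 0.10, high = 0.90,
                                dmax_source = c("calculated", "measured")) {
  if (!(low > 0 && low < high && high <= 1)) {
    stop("need 0 < low < high <= 1")
  }
  structure(
    list(low = low, high = high, dmax_source = match.arg(dmax_source)),
    class = "analysis_thresholds"
  )
}

#' Distance-to-agreement specification
#'
#' DTA is the smallest distance from a reference voxel to a point of the
#' evaluated distribution whose dose matches within a local tolerance
#' (default 0.5% of the reference voxel's own dose). Voxels with no match
#' within `search_radius` carry the cap value and a saturation flag.
#'
#' @param local_tol fractional local dose tolerance (default 0.005).
#' @param band threshold band (fractions of D_max) over which summary
#'   statistics are computed (default `c(0.10, 0.90)`).
#' @param search_radius search cap in mm (default 10).
#' @param eval_subsample interpolation pitch (mm, default 0.2).
#' @return An object of class `dta_spec`.
#' @export
dta_spec <- function(local_tol = 0.005, band = c(0.10, 0.90),
                     search_radius = 10, eval_subsample = 0.2) {
  if (local_tol <= 0) stop("local_tol must be > 0")
  if (search_radius <= 0 || eval_subsample <= 0) {
    stop("search_radius and eval_subsample must be > 0")
  }
  structure(
    list(local_tol = local_tol, band = band,
         search_radius = search_radius, eval_subsample = eval_subsample),
    class = "dta_spec"
  )
}

#' Shift-correction search specification
#'
#' Small residual displacements between measured and calculated planes
#' (setup and post-processing errors) are removed by a bounded grid search.
#'
#' @param max_shift bound per axis in mm (default 1.5).
#' @param step search pitch in mm (default 0.1).
#' @return An object of class `shift_search_spec`.
#' @export
shift_search_spec <- function(max_shift = 1.5, step = 0.1) {
  if (!(step > 0 && step <= max_shift)) {
    stop("need 0 < step <= max_shift")
  }
  structure(list(max_shift = max_shift, step = step),
            class = "shift_search_spec")
}

#' Ionization chamber specification
#'
#' Point-dose comparisons average the calculated dose over a sphere
#' matching the chamber's active volume (radius 0.3 cm by default).
#'
#' @param position chamber position, length 3 (mm, phantom frame, canonical
#'   crossline/inline/depth order).
#' @param radius averaging-sphere radius in mm (default 3).
#' @return An object of class `chamber_spec`.
#' @export
chamber_spec <- function(position = c(30, 82.5, 0), radius = 3) {
  if (radius <= 0) stop("radius must be > 0")
  stopifnot(length(position) == 3L)
  structure(list(position = as.numeric(position), radius = radius),
            class = "chamber_spec")
}
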
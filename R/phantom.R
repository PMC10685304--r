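# Synthetic phantom and parametric beam model. The phantom emulates a
# QA motion phantom: an elliptical-cylinder body (water), an empty cylinder
# representing the lung, a coronal film cassette with three pin landmarks,
# an ionization-chamber position and a ball bearing defining the target
# reference point. The dose engine is a deliberately simple parametric
# model: each beam contributes a flat-top field with error-function
# penumbra in both lateral directions and exponential attenuation along its
# axis through the body (lung traversal attenuates at a reduced rate);
# contributions are summed and scaled so the prescription point receives
# the fraction dose exactly.

#' Phantom model
#'
#' Geometry of the synthetic QA phantom in the canonical frame: crossline
#' (x), inline (y, along the bore), depth (z, anterior-posterior). The body
#' is an elliptical cylinder extended along inline; the film plane is
#' coronal (constant depth).
#'
#' @param body_semi_axes semi-axes (mm) of the body ellipse in (crossline,
#'   depth).
#' @param body_center body ellipse center (mm) in (crossline, depth).
#' @param body_length body extent along inline (mm); informational.
#' @param film_cassette a [cassette_pose()].
#' @param lung list with `center` (crossline, depth), `radius` (mm) and
#'   `mu_fraction` (attenuation of lung relative to body, 0-1).
#' @param chamber a [chamber_spec()].
#' @param ball_bearing reference point, length 3 (mm).
#' @return An object of class `phantom_model`.
#' @export
phantom_model <- function(body_semi_axes = c(100, 75),
                          body_center = c(30, 0),
                          body_length = 250,
                          film_cassette = cassette_pose(),
                          lung = list(center = c(-30, 0), radius = 22,
                                      mu_fraction = 0.25),
                          chamber = chamber_spec(),
                          ball_bearing = c(30, 82.5, 0)) {
  stopifnot(length(body_semi_axes) == 2L, all(body_semi_axes > 0),
            inherits(film_cassette, "cassette_pose"),
            inherits(chamber, "chamber_spec"),
            length(ball_bearing) == 3L)
  inside <- function(x, z, scale = 1) {
    ((x - body_center[1]) / (scale * body_semi_axes[1]))^2 +
      ((z - body_center[2]) / (scale * body_semi_axes[2]))^2 <= 1
  }
  if (!inside(chamber$position[1], chamber$position[3])) {
    stop("chamber position lies outside the body")
  }
  if (!inside(0, film_cassette$plane_offset) ||
      !inside(60, film_cassette$plane_offset)) {
    stop("film cassette lies outside the body")
  }
  structure(
    list(body_semi_axes = as.numeric(body_semi_axes),
         body_center = as.numeric(body_center),
         body_length = body_length, film_cassette = film_cassette,
         lung = lung, chamber = chamber,
         ball_bearing = as.numeric(ball_bearing)),
    class = "phantom_model"
  )
}

#' Treatment plan model
#'
#' A thirteen-beam arrangement delivering 1.2 Gy per fraction over five
#' fractions (6.0 Gy total) to the prescription point. The prescription
#' point sits on the inline field edge where the dose falls to
#' `prescription_isodose` of the target-center dose, mirroring stereotactic
#' prescriptions to a covering isodose line; with the default 0.70 the
#' maximum dose is 1.2 / 0.7 = 1.71 Gy per fraction (8.6 Gy over five).
#'
#' @param beams data frame with columns `angle` (gantry angle, degrees,
#'   rotation about the inline axis; 0 = anterior), `weight` (>= 0),
#'   `field_cross` / `field_inline` (full field widths, mm), `sigma`
#'   (penumbra sigma, mm) and `mu` (linear attenuation, per mm).
#' @param n_fractions number of fractions (default 5).
#' @param fraction_dose prescription dose per fraction (Gy, default 1.2).
#' @param prescription_isodose fraction of the target-center dose at the
#'   prescription point (default 0.70).
#' @param isocenter target center (length 3, mm); `NULL` means the
#'   phantom's ball bearing.
#' @return An object of class `plan_model`.
#' @export
plan_model <- function(beams = NULL, n_fractions = 5L, fraction_dose = 1.2,
                       prescription_isodose = 0.70, isocenter = NULL) {
  if (is.null(beams)) {
    beams <- data.frame(angle = seq(-144, 144, by = 24), weight = 1,
                        field_cross = 30, field_inline = 40, sigma = 3,
                        mu = 0.005)
  }
  stopifnot(is.data.frame(beams),
            all(c("angle", "weight", "field_cross", "field_inline",
                  "sigma", "mu") %in% names(beams)))
  if (any(beams$weight < 0)) stop("beam weights must be >= 0")
  if (fraction_dose <= 0) stop("fraction_dose must be > 0")
  if (!(prescription_isodose > 0 && prescription_isodose <= 1)) {
    stop("prescription_isodose must be in (0, 1]")
  }
  structure(
    list(beams = beams, n_fractions = as.integer(n_fractions),
         fraction_dose = fraction_dose,
         prescription_isodose = prescription_isodose,
         isocenter = isocenter),
    class = "plan_model"
  )
}

#' Inter-fractional variation
#'
#' One variation per fraction, from the three experimental families:
#' rigid translations, rigid rotations about the ball bearing, and body
#' modifications (contour rescaling). Online re-planning is emulated by
#' letting the dose distribution follow the varied target rigidly; body
#' modifications change the attenuation paths instead.
#'
#' @param kind one of `"none"`, `"translation"`, `"rotation"`,
#'   `"body_modification"`.
#' @param shift translation vector (crossline, inline, depth) in mm.
#' @param angle rotation angle in degrees.
#' @param axis rotation axis: `"depth"` (in-plane rotation, visible on the
#'   film) or `"inline"`.
#' @param body_scale body contour scale factor (body modifications).
#' @param mu_delta additive change to the body attenuation (per mm).
#' @return An object of class `interfraction_variation`.
#' @export
interfraction_variation <- function(kind = c("none", "translation",
                                             "rotation",
                                             "body_modification"),
                                    shift = c(0, 0, 0), angle = 0,
                                    axis = c("depth", "inline"),
                                    body_scale = 1, mu_delta = 0) {
  kind <- match.arg(kind)
  axis <- match.arg(axis)
  if (length(shift) == 2L) shift <- c(shift, 0)
  stopifnot(length(shift) == 3L, body_scale > 0)
  structure(
    list(kind = kind, shift = as.numeric(shift), angle = angle,
         axis = axis, body_scale = body_scale, mu_delta = mu_delta),
    class = "interfraction_variation"
  )
}

# Map evaluation points back to the nominal frame (dose follows the
# target: evaluating the nominal field at the inverse-varied point makes
# the whole distribution, body included, move rigidly with the phantom).
#' @noRd
.inverse_vary_points <- function(pts, variation, bb) {
  switch(variation$kind,
    none = ,
    body_modification = pts,
    translation = sweep(pts, 2, variation$shift, "-"),
    rotation = {
      th <- -variation$angle * pi / 180
      p <- sweep(pts, 2, bb, "-")
      out <- p
      if (variation$axis == "depth") {
        out[, 1] <- cos(th) * p[, 1] - sin(th) * p[, 2]
        out[, 2] <- sin(th) * p[, 1] + cos(th) * p[, 2]
      } else {
        out[, 1] <- cos(th) * p[, 1] - sin(th) * p[, 3]
        out[, 3] <- sin(th) * p[, 1] + cos(th) * p[, 3]
      }
      sweep(out, 2, bb, "+")
    })
}

#' @noRd
.vary_point <- function(p, variation, bb) {
  switch(variation$kind,
    none = ,
    body_modification = p,
    translation = p + variation$shift,
    rotation = {
      th <- variation$angle * pi / 180
      q <- p - bb
      out <- q
      if (variation$axis == "depth") {
        out[1] <- cos(th) * q[1] - sin(th) * q[2]
        out[2] <- sin(th) * q[1] + cos(th) * q[2]
      } else {
        out[1] <- cos(th) * q[1] - sin(th) * q[3]
        out[3] <- sin(th) * q[1] + cos(th) * q[3]
      }
      bb + out
    })
}

# flat-top profile with error-function penumbra; half width h, sigma s
#' @noRd
.erf_edge <- function(l, h, s) {
  pnorm((h - l) / s) + pnorm((h + l) / s) - 1
}

# upstream chord length through an ellipse (semi-axes A, B, center C) for
# rays arriving at pts along direction u (2D, crossline/depth plane)
#' @noRd
.upstream_chord <- function(x, z, ux, uz, Cx, Cz, A, B) {
  dx <- x - Cx
  dz <- z - Cz
  a <- (ux / A)^2 + (uz / B)^2
  b <- -2 * (dx * ux / A^2 + dz * uz / B^2)
  cc <- (dx / A)^2 + (dz / B)^2 - 1
  disc <- b^2 - 4 * a * cc
  out <- numeric(length(x))
  hit <- disc > 0
  if (any(hit)) {
    sq <- sqrt(disc[hit])
    r1 <- (-b[hit] - sq) / (2 * a)
    r2 <- (-b[hit] + sq) / (2 * a)
    out[hit] <- pmax(0, r2 - pmax(r1, 0))
  }
  out
}

# raw (unscaled) plan dose at arbitrary canonical-frame points, nominal
# phantom pose; body_scale / mu_delta implement body modifications
#' @noRd
.plan_dose_points <- function(pts, plan, phantom, body_scale = 1,
                              mu_delta = 0) {
  c0 <- if (is.null(plan$isocenter)) phantom$ball_bearing else plan$isocenter
  A <- phantom$body_semi_axes[1] * body_scale
  B <- phantom$body_semi_axes[2] * body_scale
  Cx <- phantom$body_center[1]
  Cz <- phantom$body_center[2]
  lung <- phantom$lung
  x <- pts[, 1]
  y <- pts[, 2]
  z <- pts[, 3]
  dose <- numeric(nrow(pts))
  for (b in seq_len(nrow(plan$beams))) {
    bm <- plan$beams[b, ]
    if (bm$weight == 0) next
    th <- bm$angle * pi / 180
    ux <- sin(th)
    uz <- -cos(th)
    # central axis must cross the body
    ax_chord <- .upstream_chord(c0[1], c0[3], ux, uz, Cx, Cz, A, B)
    if (ax_chord <= 0) {
      stop("geometry error: beam at gantry ", bm$angle,
           " deg misses the body")
    }
    l <- (x - c0[1]) * cos(th) + (z - c0[3]) * sin(th)
    v <- y - c0[2]
    fl <- .erf_edge(l, bm$field_cross / 2, bm$sigma) *
      .erf_edge(v, bm$field_inline / 2, bm$sigma)
    path <- .upstream_chord(x, z, ux, uz, Cx, Cz, A, B)
    lpath <- .upstream_chord(x, z, ux, uz, lung$center[1], lung$center[2],
                             lung$radius, lung$radius)
    eff <- pmax(0, path - (1 - lung$mu_fraction) * pmin(lpath, path))
    mu <- bm$mu + mu_delta
    dose <- dose + bm$weight * fl * exp(-mu * eff)
  }
  dose
}

#' Calculate the per-fraction 3D dose grid
#'
#' Evaluates the parametric beam model on a regular 3D grid in the phantom
#' frame, after applying the inter-fractional variation. Online adaptation
#' is emulated by the dose distribution rigidly following the varied
#' target (translations, rotations) and by recomputed attenuation paths
#' for body modifications; the grid is then scaled so the prescription
#' point receives exactly `fraction_dose`.
#'
#' @param plan a [plan_model()].
#' @param phantom a [phantom_model()].
#' @param variation an [interfraction_variation()].
#' @param grid_spec list with `origin`, `spacing`, `dim` (canonical axis
#'   order); `NULL` uses [plan_grid_spec()].
#' @return A [dose_grid3d()] with attributes `prescription_point` (mm) and
#'   `scale`.
#' @export
compute_plan_dose <- function(plan, phantom,
                              variation = interfraction_variation("none"),
                              grid_spec = NULL) {
  stopifnot(inherits(plan, "plan_model"), inherits(phantom, "phantom_model"),
            inherits(variation, "interfraction_variation"))
  if (is.null(grid_spec)) grid_spec <- plan_grid_spec()
  dm <- grid_spec$dim
  xs <- grid_spec$origin[1] + (seq_len(dm[1]) - 1) * grid_spec$spacing[1]
  ys <- grid_spec$origin[2] + (seq_len(dm[2]) - 1) * grid_spec$spacing[2]
  zs <- grid_spec$origin[3] + (seq_len(dm[3]) - 1) * grid_spec$spacing[3]
  pts <- cbind(rep(xs, times = dm[2] * dm[3]),
               rep(rep(ys, each = dm[1]), times = dm[3]),
               rep(zs, each = dm[1] * dm[2]))
  bscale <- if (variation$kind == "body_modification")
    variation$body_scale else 1
  mudelta <- if (variation$kind == "body_modification")
    variation$mu_delta else 0
  p_nom <- .inverse_vary_points(pts, variation, phantom$ball_bearing)
  raw <- .plan_dose_points(p_nom, plan, phantom, bscale, mudelta)
  vals <- array(raw, dim = dm)
  if (max(raw) <= 0) {
    grid <- dose_grid3d(vals, grid_spec$origin, grid_spec$spacing)
    attr(grid, "prescription_point") <- NULL
    attr(grid, "scale") <- 0
    return(grid)
  }
  # prescription point: along +inline from the target center, where the
  # analytic dose falls to prescription_isodose of the center value
  c0 <- if (is.null(plan$isocenter)) phantom$ball_bearing else plan$isocenter
  f_at <- function(v) {
    .plan_dose_points(rbind(c0 + c(0, v, 0)), plan, phantom, bscale, mudelta)
  }
  d0 <- f_at(0)
  vmax <- max(plan$beams$field_inline) / 2 + 8 * max(plan$beams$sigma)
  v_star <- uniroot(function(v) f_at(v) / d0 - plan$prescription_isodose,
                    c(0, vmax), tol = 1e-10)$root
  p_presc <- .vary_point(c0 + c(0, v_star, 0), variation,
                         phantom$ball_bearing)
  grid_val <- .trilinear(vals, grid_spec$origin, grid_spec$spacing,
                         rbind(p_presc))
  if (!is.finite(grid_val) || grid_val <= 0) {
    stop("geometry error: prescription point outside the dose grid")
  }
  scale <- plan$fraction_dose / grid_val
  grid <- dose_grid3d(vals * scale, grid_spec$origin, grid_spec$spacing)
  attr(grid, "prescription_point") <- p_presc
  attr(grid, "scale") <- scale
  grid
}

#' Default calculation grid for the plan dose
#'
#' 2 mm pitch covering the film plane with margin on every axis.
#'
#' @param spacing voxel pitch (mm), scalar or length 3.
#' @return List with `origin`, `spacing`, `dim`.
#' @export
plan_grid_spec <- function(spacing = 2) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  origin <- c(-10, -12, -30)
  extent <- c(80, 188, 60)
  list(origin = origin, spacing = as.numeric(spacing),
       dim = as.integer(floor(extent / spacing) + 1L))
}
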
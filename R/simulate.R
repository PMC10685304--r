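# Treatment simulation: delivered film-plane doses, film scans through the
# physical calibration curve with day-to-day drift and noise, daily
# correction films, chamber readings, and the fourteen-dataset experimental
# layout (three total doses + eleven single fractions). Every injected
# perturbation is recorded in a ground-truth ledger.

#' Measurement noise model
#'
#' All stochastic ingredients of the simulated measurement chain. The
#' defaults emulate a well-controlled film workflow: 0.3% multiplicative
#' response noise per pixel, 0.3 mm landmark selection jitter, a few
#' percent day-to-day response drift, small scanner rotations and
#' translations, and no delivery error.
#'
#' @param film_response_noise fractional SD of the per-pixel response
#'   noise (default 0.003).
#' @param landmark_jitter_sd SD (mm) of the manual landmark selection
#'   jitter (default 0.3).
#' @param daily_drift_range range of the day's dose-scale factor the daily
#'   correction recovers (default `c(0.96, 1.04)`).
#' @param scanner_rotation_range scanner rotation range, degrees.
#' @param scanner_translation_range scanner translation range, mm.
#' @param delivery_dose_scale_sd SD of the per-fraction delivered/planned
#'   dose-scale error (default 0).
#' @param delivery_shift_sd SD (mm) of the per-fraction residual in-plane
#'   shift of the delivered dose (default 0).
#' @param chamber_noise_sd fractional SD of the chamber reading (default
#'   0.002).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(film_response_noise = 0.003,
                        landmark_jitter_sd = 0.3,
                        daily_drift_range = c(0.96, 1.04),
                        scanner_rotation_range = c(-3, 3),
                        scanner_translation_range = c(-2, 2),
                        delivery_dose_scale_sd = 0,
                        delivery_shift_sd = 0,
                        chamber_noise_sd = 0.002) {
  vals <- c(film_response_noise, landmark_jitter_sd,
            delivery_dose_scale_sd, delivery_shift_sd, chamber_noise_sd)
  if (any(vals < 0)) stop("noise SDs must be >= 0")
  structure(
    list(film_response_noise = film_response_noise,
         landmark_jitter_sd = landmark_jitter_sd,
         daily_drift_range = daily_drift_range,
         scanner_rotation_range = scanner_rotation_range,
         scanner_translation_range = scanner_translation_range,
         delivery_dose_scale_sd = delivery_dose_scale_sd,
         delivery_shift_sd = delivery_shift_sd,
         chamber_noise_sd = chamber_noise_sd),
    class = "noise_model"
  )
}

#' Noise-free noise model
#'
#' Convenience for null experiments: every noise source zero, drift 1,
#' identity scanner transform.
#' @return A [noise_model()].
#' @export
null_noise_model <- function() {
  noise_model(film_response_noise = 0, landmark_jitter_sd = 0,
              daily_drift_range = c(1, 1),
              scanner_rotation_range = c(0, 0),
              scanner_translation_range = c(0, 0),
              chamber_noise_sd = 0)
}

#' Default inter-fractional variation schedule
#'
#' Five variations per family: in-plane translations (<= 6 mm), rotations
#' about the anterior-posterior axis (<= 4 degrees) and body contour
#' rescalings (+-5%).
#'
#' @return Named list of lists of [interfraction_variation()] objects.
#' @export
default_variations <- function() {
  list(
    translation = lapply(
      list(c(3, 0), c(0, 5), c(-4, 3), c(2, -6), c(-2, -3)),
      function(s) interfraction_variation("translation", shift = s)),
    rotation = lapply(
      c(2, -3, 4, -2, 3),
      function(a) interfraction_variation("rotation", angle = a,
                                          axis = "depth")),
    body_modification = lapply(
      c(1.05, 0.97, 1.03, 0.95, 1.02),
      function(s) interfraction_variation("body_modification",
                                          body_scale = s))
  )
}

#' Simulation configuration
#'
#' Bundles everything the simulator needs: phantom, plan, grids, noise,
#' the film batch's true physical calibration parameters, the calibration
#' and daily-film dose schedules, and the dataset layout.
#'
#' @param phantom a [phantom_model()].
#' @param plan a [plan_model()].
#' @param grid_spec 3D calculation grid (see [plan_grid_spec()]).
#' @param gspec a [common_grid_spec()].
#' @param noise a [noise_model()].
#' @param variations as [default_variations()].
#' @param curve_params true physical film curve `c(a, b, c)` of
#'   `dose(x) = (a + b x)/(1 + c x)`.
#' @param batch_doses doses (Gy) of the 20 batch calibration points.
#' @param daily_doses_total daily-film doses for total-dose datasets.
#' @param daily_max_single rotation of maximum daily doses for
#'   single-fraction datasets (three films at 0, max/2, max).
#' @param scan_pitch film scanner pixel pitch (mm).
#' @param layout `"paper14"` (3 totals + 11 singles) or `"null"` (the
#'   unvaried original plan only).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(phantom = phantom_model(),
                              plan = plan_model(),
                              grid_spec = plan_grid_spec(),
                              gspec = common_grid_spec(),
                              noise = noise_model(),
                              variations = default_variations(),
                              curve_params = c(a = 10, b = -0.25,
                                               c = 0.25),
                              batch_doses = c(0, 0.25, 0.5, 0.75, 1, 1.25,
                                              1.5, 2, 2.5, 3, 3.5, 4, 5, 6,
                                              7, 8, 8.5, 9, 9.5, 10),
                              daily_doses_total = c(0, 2.5, 5, 7.5, 10),
                              daily_max_single = c(2, 2.2, 2.5),
                              scan_pitch = 0.25,
                              layout = c("paper14", "null")) {
  layout <- match.arg(layout)
  structure(
    list(phantom = phantom, plan = plan, grid_spec = grid_spec,
         gspec = gspec, noise = noise, variations = variations,
         curve_params = curve_params, batch_doses = batch_doses,
         daily_doses_total = daily_doses_total,
         daily_max_single = daily_max_single, scan_pitch = scan_pitch,
         layout = layout),
    class = "simulation_config"
  )
}

#' Null simulation configuration
#'
#' One unvaried dataset, zero noise: every downstream comparison is the
#' identity case.
#' @return A [simulation_config()].
#' @export
null_simulation_config <- function() {
  simulation_config(noise = null_noise_model(), layout = "null")
}

# true physical calibration curve of the simulated film batch
#' @noRd
.true_curve <- function(config) {
  p <- config$curve_params
  d <- config$batch_doses
  x <- (p[1] - d) / (p[3] * d - p[2])
  calibration_curve(data.frame(dose_gy = d, response = as.numeric(x)),
                    p)
}

#' Simulate the delivered film-plane dose of one fraction
#'
#' The delivered plane is the calculated plane extracted at the film
#' position, optionally perturbed by a per-fraction dose-scale error and a
#' residual in-plane shift (pattern moved by `residual_shift`).
#'
#' @param calculated a [dose_grid3d()].
#' @param pose a [cassette_pose()].
#' @param gspec a [common_grid_spec()].
#' @param dose_scale delivered/planned dose ratio (default 1).
#' @param residual_shift in-plane shift (mm) of the delivered pattern.
#' @return A [dose_plane2d()] in absolute Gy.
#' @export
simulate_fraction_delivery <- function(calculated, pose = cassette_pose(),
                                       gspec = common_grid_spec(),
                                       dose_scale = 1,
                                       residual_shift = c(0, 0)) {
  plane <- extract_film_plane(calculated, pose, gspec)
  vals <- plane$values * dose_scale
  if (any(residual_shift != 0)) {
    nr <- nrow(vals)
    nc <- ncol(vals)
    xs <- plane$origin[1] + (seq_len(nr) - 1) * plane$spacing[1]
    ys <- plane$origin[2] + (seq_len(nc) - 1) * plane$spacing[2]
    vals <- matrix(
      .bilinear(vals, plane$origin, plane$spacing,
                rep(xs - residual_shift[1], times = nc),
                rep(ys - residual_shift[2], each = nr)),
      nr, nc)
  }
  dose_plane2d(vals, plane$spacing, plane$origin)
}

#' Simulate a scanned film
#'
#' Turns an accumulated absolute dose plane into a scanner-frame response
#' image: the film is placed in the scanner under a rigid transform, the
#' dose is mapped to response through the inverse of the true calibration
#' curve (with the day's dose drift), multiplicative per-pixel noise is
#' applied, and the pin landmarks are written with selection jitter. Doses
#' beyond the calibration range abort (film saturation).
#'
#' @param dose_plane absolute [dose_plane2d()] (the accumulated film
#'   dose).
#' @param curve the true physical [calibration_curve()] of the batch.
#' @param pose a [cassette_pose()] (nominal landmarks).
#' @param drift the day's dose-scale factor: the analysis should recover
#'   `daily_scale = drift`.
#' @param scanner_t [rigid_transform2d()] placing the film in the scanner
#'   frame.
#' @param noise a [noise_model()].
#' @param scan_pitch scanner pixel pitch (mm).
#' @return A [film_scan()]; attribute `daily_response` is a function
#'   generating daily-film responses for given doses on the same day.
#' @export
simulate_film_scan <- function(dose_plane, curve, pose = cassette_pose(),
                               drift = 1,
                               scanner_t = rigid_transform2d(),
                               noise = noise_model(), scan_pitch = 0.25) {
  stopifnot(inherits(dose_plane, "dose_plane2d"), !dose_plane$is_relative,
            inherits(curve, "calibration_curve"))
  dmax <- suppressWarnings(max(dose_plane$values, na.rm = TRUE))
  if (dmax / drift > curve$dose_range[2] + 1e-9) {
    stop("simulation error: dose ", format(dmax), " Gy exceeds the ",
         "calibration range (film saturation)")
  }
  nr <- nrow(dose_plane$values)
  nc <- ncol(dose_plane$values)
  corners <- rbind(
    dose_plane$origin,
    dose_plane$origin + c((nr - 1) * dose_plane$spacing[1], 0),
    dose_plane$origin + c(0, (nc - 1) * dose_plane$spacing[2]),
    dose_plane$origin + (c(nr, nc) - 1) * dose_plane$spacing)
  sc <- transform_points(scanner_t, corners)
  margin <- 2
  org <- apply(sc, 2, min) - margin
  ext <- apply(sc, 2, max) + margin - org
  n <- as.integer(floor(ext / scan_pitch)) + 1L
  xs <- org[1] + (seq_len(n[1]) - 1) * scan_pitch
  ys <- org[2] + (seq_len(n[2]) - 1) * scan_pitch
  p_scan <- cbind(rep(xs, times = n[2]), rep(ys, each = n[1]))
  p_film <- transform_points(invert_transform(scanner_t), p_scan)
  dose <- .bilinear(dose_plane$values, dose_plane$origin,
                    dose_plane$spacing, p_film[, 1], p_film[, 2])
  dose[is.na(dose)] <- 0  # off-film background reads as unexposed
  resp <- curve_response(curve, dose / drift)
  if (noise$film_response_noise > 0) {
    resp <- resp * (1 + rnorm(length(resp),
                              sd = noise$film_response_noise))
  }
  resp[resp < 0] <- 0
  lm <- transform_points(scanner_t, pose$nominal_landmarks)
  if (noise$landmark_jitter_sd > 0) {
    lm <- lm + matrix(rnorm(6, sd = noise$landmark_jitter_sd), 3, 2)
  }
  film_scan(matrix(resp, n[1], n[2]), scan_pitch, lm, org)
}

#' @noRd
.paper14_layout <- function() {
  out <- list(list(id = "original_single", series = "original",
                   mode = "single_fraction", fractions = 0L))
  for (f in 1:5) {
    out[[length(out) + 1L]] <- list(id = paste0("translation_f", f),
                                    series = "translation",
                                    mode = "single_fraction",
                                    fractions = f)
  }
  out[[length(out) + 1L]] <- list(id = "translation_total",
                                  series = "translation",
                                  mode = "total_dose", fractions = 1:5)
  for (f in c(1L, 3L, 5L)) {
    out[[length(out) + 1L]] <- list(id = paste0("rotation_f", f),
                                    series = "rotation",
                                    mode = "single_fraction",
                                    fractions = f)
  }
  out[[length(out) + 1L]] <- list(id = "rotation_total",
                                  series = "rotation",
                                  mode = "total_dose", fractions = 1:5)
  for (f in c(1L, 5L)) {
    out[[length(out) + 1L]] <- list(id = paste0("body_modification_f", f),
                                    series = "body_modification",
                                    mode = "single_fraction",
                                    fractions = f)
  }
  out[[length(out) + 1L]] <- list(id = "body_modification_total",
                                  series = "body_modification",
                                  mode = "total_dose", fractions = 1:5)
  out
}

#' Generate a complete simulated treatment dataset collection
#'
#' Runs the full experiment: per-fraction calculated 3D dose grids for
#' every variation family, accumulated delivered film-plane doses, film
#' scans through the physical calibration curve, daily correction films,
#' batch calibration table, chamber readings for the original plan and the
#' translation singles, and a ground-truth ledger recording every injected
#' perturbation. With `layout = "paper14"` this yields fourteen analysis
#' datasets: three total doses and eleven single fractions.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; the run is fully reproducible from it.
#' @param path optional directory; when given, the dataset tree is written
#'   to disk (see [write_treatment_dataset()]).
#' @return An object of class `treatment_collection`: `datasets` (list of
#'   `qa_dataset` objects), `calibration` (batch table), `phantom`,
#'   `plan`, `gspec`, `ledger`.
#' @export
generate_treatment_dataset <- function(config = simulation_config(),
                                       seed = 1L, path = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(as.integer(seed))
  phantom <- config$phantom
  pose <- phantom$film_cassette
  noise <- config$noise
  curve_true <- .true_curve(config)
  resp_noise <- function(x) {
    if (noise$film_response_noise > 0) {
      x * (1 + rnorm(length(x), sd = noise$film_response_noise))
    } else x
  }
  calibration <- data.frame(
    dose_gy = config$batch_doses,
    response = resp_noise(curve_response(curve_true, config$batch_doses)))

  series_vars <- c(list(original = list(interfraction_variation("none"))),
                   config$variations)
  layout <- if (config$layout == "paper14") .paper14_layout() else {
    list(list(id = "original_single", series = "original",
              mode = "single_fraction", fractions = 0L))
  }
  # per-fraction calculated grids, computed once per (series, fraction)
  # actually used by the layout
  needed <- list()
  for (entry in layout) {
    fr <- if (identical(entry$fractions, 0L)) 1L else entry$fractions
    sr <- if (identical(entry$fractions, 0L)) "original" else entry$series
    needed[[sr]] <- sort(unique(c(needed[[sr]], fr)))
  }
  grids <- lapply(names(series_vars), function(sr) {
    out <- vector("list", length(series_vars[[sr]]))
    for (f in needed[[sr]]) {
      out[[f]] <- compute_plan_dose(config$plan, phantom,
                                    series_vars[[sr]][[f]],
                                    config$grid_spec)
    }
    out
  })
  names(grids) <- names(series_vars)

  ledger <- list(seed = as.integer(seed),
                 curve_params = as.list(config$curve_params),
                 variations = lapply(series_vars, function(vs) {
                   lapply(vs, unclass)
                 }),
                 datasets = list())
  datasets <- list()
  chamber_series <- c("original_single", paste0("translation_f", 1:5))
  for (entry in layout) {
    fr <- entry$fractions
    g_list <- if (identical(fr, 0L)) list(grids$original[[1L]]) else
      grids[[entry$series]][fr]
    dscale <- if (noise$delivery_dose_scale_sd > 0)
      1 + rnorm(length(g_list), sd = noise$delivery_dose_scale_sd) else
      rep(1, length(g_list))
    dshift <- if (noise$delivery_shift_sd > 0)
      matrix(rnorm(2L * length(g_list), sd = noise$delivery_shift_sd),
             ncol = 2L) else matrix(0, length(g_list), 2L)
    delivered <- lapply(seq_along(g_list), function(k) {
      simulate_fraction_delivery(g_list[[k]], pose, config$gspec,
                                 dscale[k], dshift[k, ])
    })
    accumulated <- sum_planes(delivered)
    drift <- runif(1, noise$daily_drift_range[1],
                   noise$daily_drift_range[2])
    st <- rigid_transform2d(
      runif(1, noise$scanner_rotation_range[1],
            noise$scanner_rotation_range[2]),
      runif(2, noise$scanner_translation_range[1],
            noise$scanner_translation_range[2]))
    scan <- simulate_film_scan(accumulated, curve_true, pose, drift, st,
                               noise, config$scan_pitch)
    if (entry$mode == "total_dose") {
      daily_doses <- config$daily_doses_total
    } else {
      dmx <- config$daily_max_single[
        (length(datasets) %% length(config$daily_max_single)) + 1L]
      daily_doses <- c(0, dmx / 2, dmx)
    }
    daily <- data.frame(
      dose_gy = daily_doses,
      response = resp_noise(curve_response(curve_true,
                                           daily_doses / drift)))
    chamber <- NULL
    if (entry$id %in% chamber_series) {
      cs <- phantom$chamber
      v_used <- if (identical(fr, 0L))
        series_vars$original[[1L]] else series_vars[[entry$series]][[fr]]
      cpos <- .vary_point(cs$position, v_used, phantom$ball_bearing)
      cspec <- chamber_spec(cpos, cs$radius)
      g <- .canonical_grid(g_list[[1L]])
      off <- seq(-cs$radius, cs$radius, by = 0.5)
      sp <- as.matrix(expand.grid(off, off, off))
      sp <- sp[rowSums(sp^2) <= cs$radius^2 + 1e-12, , drop = FALSE]
      calc <- mean(.trilinear(g$values, g$origin, g$spacing,
                              sweep(sp, 2, cpos, "+")), na.rm = TRUE)
      meas <- calc * dscale[1L] *
        (1 + if (noise$chamber_noise_sd > 0)
          rnorm(1, sd = noise$chamber_noise_sd) else 0)
      chamber <- list(measured_gy = meas, spec = cspec)
    }
    ds <- structure(
      list(id = entry$id, series = entry$series, mode = entry$mode,
           fractions = fr, grids = g_list, scan = scan, daily = daily,
           chamber = chamber, ground_truth = accumulated),
      class = "qa_dataset")
    datasets[[entry$id]] <- ds
    ledger$datasets[[entry$id]] <- list(
      fractions = fr, drift = drift,
      scanner_rotation = st$rotation,
      scanner_translation = st$translation,
      delivery_dose_scale = dscale, delivery_shift = dshift)
  }
  collection <- structure(
    list(datasets = datasets, calibration = calibration,
         phantom = phantom, plan = config$plan, gspec = config$gspec,
         config = config, ledger = ledger),
    class = "treatment_collection")
  if (!is.null(path)) write_treatment_dataset(collection, path)
  collection
}

#' @export
print.treatment_collection <- function(x, ...) {
  n_tot <- sum(vapply(x$datasets, function(d) d$mode == "total_dose",
                      logical(1)))
  cat("<treatment_collection> ", length(x$datasets), " datasets (",
      n_tot, " totals, ", length(x$datasets) - n_tot, " singles), seed ",
      x$ledger$seed, "\n", sep = "")
  invisible(x)
}

#' Write / read a simulated dataset tree
#'
#' Writes the collection as a directory tree: the batch calibration as
#' CSV, each dataset with its calculated grids and ground-truth plane in
#' the portable container, the film scan as 16-bit TIFF + sidecar, daily
#' films as CSV, chamber readings and the ground-truth ledger as JSON.
#'
#' @param collection a `treatment_collection`.
#' @param path target directory (created if needed).
#' @return `write_treatment_dataset` returns `path` invisibly;
#'   `read_treatment_dataset` returns the `treatment_collection` (film
#'   scans carry 16-bit quantization).
#' @export
write_treatment_dataset <- function(collection, path) {
  stopifnot(inherits(collection, "treatment_collection"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write.csv(collection$calibration, file.path(path, "calibration.csv"),
            row.names = FALSE)
  ph <- collection$phantom
  jsonlite::write_json(
    list(body_semi_axes = ph$body_semi_axes,
         body_center = ph$body_center, body_length = ph$body_length,
         cassette = list(plane_offset = ph$film_cassette$plane_offset,
                         in_plane_origin = ph$film_cassette$in_plane_origin,
                         nominal_landmarks = ph$film_cassette$nominal_landmarks),
         lung = ph$lung,
         chamber = list(position = ph$chamber$position,
                        radius = ph$chamber$radius),
         ball_bearing = ph$ball_bearing,
         gspec = unclass(collection$gspec)),
    file.path(path, "phantom.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(collection$ledger, file.path(path, "ledger.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (ds in collection$datasets) {
    dd <- file.path(path, "datasets", ds$id)
    dir.create(dd, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(id = ds$id, series = ds$series, mode = ds$mode,
           fractions = ds$fractions, n_grids = length(ds$grids),
           has_chamber = !is.null(ds$chamber)),
      file.path(dd, "meta.json"), auto_unbox = FALSE, digits = NA)
    for (k in seq_along(ds$grids)) {
      write_dose_grid(ds$grids[[k]], file.path(dd, sprintf("calc_f%02d", k)))
    }
    write_dose_plane(ds$ground_truth, file.path(dd, "ground_truth"))
    write_film_scan(ds$scan, file.path(dd, "scan"))
    write.csv(ds$daily, file.path(dd, "daily.csv"), row.names = FALSE)
    if (!is.null(ds$chamber)) {
      jsonlite::write_json(
        list(measured_gy = ds$chamber$measured_gy,
             position = ds$chamber$spec$position,
             radius = ds$chamber$spec$radius),
        file.path(dd, "chamber.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(path)
}

#' @rdname write_treatment_dataset
#' @export
read_treatment_dataset <- function(path) {
  if (!file.exists(file.path(path, "phantom.json"))) {
    stop("not a dataset tree: missing ", file.path(path, "phantom.json"))
  }
  pj <- jsonlite::read_json(file.path(path, "phantom.json"),
                            simplifyVector = TRUE)
  pose <- cassette_pose(pj$cassette$plane_offset,
                        pj$cassette$in_plane_origin,
                        matrix(as.numeric(as.matrix(
                          pj$cassette$nominal_landmarks)), 3L, 2L))
  phantom <- phantom_model(pj$body_semi_axes, pj$body_center,
                           pj$body_length, pose,
                           as.list(pj$lung),
                           chamber_spec(pj$chamber$position,
                                        pj$chamber$radius),
                           pj$ball_bearing)
  gspec <- common_grid_spec(pj$gspec$spacing, pj$gspec$post_size,
                            pj$gspec$edge_trim)
  calibration <- read.csv(file.path(path, "calibration.csv"))
  ledger <- jsonlite::read_json(file.path(path, "ledger.json"),
                                simplifyVector = TRUE)
  ds_dirs <- list.dirs(file.path(path, "datasets"), recursive = FALSE)
  datasets <- list()
  for (dd in ds_dirs) {
    m <- jsonlite::read_json(file.path(dd, "meta.json"),
                             simplifyVector = TRUE)
    grids <- lapply(seq_len(m$n_grids), function(k) {
      read_dose_grid(file.path(dd, sprintf("calc_f%02d", k)))
    })
    chamber <- NULL
    if (isTRUE(m$has_chamber)) {
      cj <- jsonlite::read_json(file.path(dd, "chamber.json"),
                                simplifyVector = TRUE)
      chamber <- list(measured_gy = cj$measured_gy,
                      spec = chamber_spec(cj$position, cj$radius))
    }
    datasets[[m$id]] <- structure(
      list(id = m$id, series = m$series, mode = m$mode,
           fractions = m$fractions, grids = grids,
           scan = read_film_scan(file.path(dd, "scan")),
           daily = read.csv(file.path(dd, "daily.csv")),
           chamber = chamber,
           ground_truth = read_dose_plane(file.path(dd, "ground_truth"))),
      class = "qa_dataset")
  }
  structure(
    list(datasets = datasets, calibration = calibration,
         phantom = phantom, plan = NULL, gspec = gspec, config = NULL,
         ledger = ledger),
    class = "treatment_collection")
}
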
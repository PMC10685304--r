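# Orchestration: calibrate -> register -> convert -> extract -> sum ->
# normalize -> shift-correct -> compare, for single-fraction and
# total-dose QA, producing per-dataset summary rows mirroring the usual
# film-QA reporting table (gamma pass at the low/high thresholds,
# dose-deviation mean+-SD at both, DTA mean+-SD in the band, applied
# shift).

#' QA analysis configuration
#'
#' Validates and bundles the inputs of one analysis run. `dataset` and
#' `calibration` may be in-memory objects or file paths; referenced files
#' must exist at construction time.
#'
#' @param dataset a `qa_dataset` (from [generate_treatment_dataset()] /
#'   [read_treatment_dataset()]) or the path of a dataset directory.
#' @param calibration batch calibration data frame (`dose_gy`,
#'   `response`) or a CSV path.
#' @param pose a [cassette_pose()].
#' @param gspec a [common_grid_spec()].
#' @param gamma a [gamma_criteria()].
#' @param thresholds an [analysis_thresholds()].
#' @param dta a [dta_spec()].
#' @param shift a [shift_search_spec()].
#' @param chamber a [chamber_spec()] (used when the dataset carries a
#'   chamber reading).
#' @param mode `"single_fraction"` or `"total_dose"`.
#' @param norm_radius normalization disk radius (mm, default 10).
#' @param expected_fractions fraction count required in total mode
#'   (default 5); set `allow_any_fractions = TRUE` to override.
#' @param allow_any_fractions disable the fraction-count check.
#' @return An object of class `qa_config`.
#' @export
qa_config <- function(dataset, calibration, pose = cassette_pose(),
                      gspec = common_grid_spec(),
                      gamma = gamma_criteria(),
                      thresholds = analysis_thresholds(),
                      dta = dta_spec(), shift = shift_search_spec(),
                      chamber = chamber_spec(),
                      mode = c("single_fraction", "total_dose"),
                      norm_radius = 10, expected_fractions = 5L,
                      allow_any_fractions = FALSE) {
  mode <- match.arg(mode)
  if (is.character(calibration)) {
    if (!file.exists(calibration)) {
      stop("config error: calibration file not found: ", calibration)
    }
    calibration <- read.csv(calibration)
  }
  if (!all(c("dose_gy", "response") %in% names(calibration))) {
    stop("config error: calibration must have columns dose_gy, response")
  }
  if (is.character(dataset)) {
    if (!dir.exists(dataset)) {
      stop("config error: dataset directory not found: ", dataset)
    }
    dataset <- .read_qa_dataset_dir(dataset)
  }
  if (!inherits(dataset, "qa_dataset")) {
    stop("config error: dataset must be a qa_dataset or a directory path")
  }
  structure(
    list(dataset = dataset, calibration = calibration, pose = pose,
         gspec = gspec, gamma = gamma, thresholds = thresholds,
         dta = dta, shift = shift, chamber = chamber, mode = mode,
         norm_radius = norm_radius,
         expected_fractions = as.integer(expected_fractions),
         allow_any_fractions = isTRUE(allow_any_fractions)),
    class = "qa_config"
  )
}

#' @noRd
.read_qa_dataset_dir <- function(dd) {
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
  gt <- if (file.exists(file.path(dd, "ground_truth.json")))
    read_dose_plane(file.path(dd, "ground_truth")) else NULL
  structure(
    list(id = m$id, series = m$series, mode = m$mode,
         fractions = m$fractions, grids = grids,
         scan = read_film_scan(file.path(dd, "scan")),
         daily = read.csv(file.path(dd, "daily.csv")),
         chamber = chamber, ground_truth = gt),
    class = "qa_dataset")
}

#' @noRd
.with_stage <- function(stage, id, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s: %s", stage, id, conditionMessage(e)),
         call. = FALSE)
  })
}

# Full per-dataset analysis chain; shared verbatim by the single-fraction
# and total-dose paths (the only difference is how many calculated planes
# are summed).
#' @noRd
.analyze_dataset <- function(config) {
  ds <- config$dataset
  id <- ds$id
  curve <- .with_stage("calibrate", id,
                       fit_calibration_curve(config$calibration))
  curve <- .with_stage("daily_rescale", id, rescale_daily(curve, ds$daily))
  tform <- .with_stage("register", id,
                       solve_landmark_transform(ds$scan$landmarks,
                                                config$pose$nominal_landmarks))
  reg <- .with_stage("register", id,
                     apply_transform(ds$scan, tform, config$gspec))
  meas_abs <- .with_stage("convert", id,
                          convert_response_to_dose(reg, curve))
  calc_abs <- .with_stage("extract", id, {
    planes <- lapply(ds$grids, extract_film_plane, pose = config$pose,
                     spec = config$gspec)
    sum_planes(planes)
  })
  meas_abs <- crop_edge_voxels(meas_abs, config$gspec)
  calc_abs <- crop_edge_voxels(calc_abs, config$gspec)
  center <- .with_stage("normalize", id, locate_high_dose_center(calc_abs))
  calc_rel <- .with_stage("normalize", id,
                          normalize_relative(calc_abs, center,
                                             config$norm_radius))
  meas_rel <- .with_stage("normalize", id,
                          normalize_relative(meas_abs, center,
                                             config$norm_radius))
  sh <- .with_stage("shift_correct", id,
                    optimize_shift(meas_rel, calc_rel, config$shift,
                                   config$thresholds))
  meas_c <- sh$plane
  gamma_res <- .with_stage("gamma", id,
                           compute_gamma(meas_c, calc_rel, config$gamma,
                                         config$thresholds))
  dev_res <- .with_stage("dose_deviation", id,
                         compute_dose_deviation(meas_c, calc_rel,
                                                config$thresholds))
  dta_res <- .with_stage("dta", id,
                         compute_dta(meas_c, calc_rel, config$dta,
                                     config$thresholds))
  profiles <- .with_stage("profiles", id,
                          extract_center_profiles(meas_c, calc_rel,
                                                  center))
  res <- summarize_comparison(id, config$mode, gamma_res, dev_res,
                              dta_res, sh$shift,
                              norm_dose_measured = meas_rel$norm_dose,
                              norm_dose_calculated = calc_rel$norm_dose,
                              profiles = profiles)
  if (!is.null(ds$chamber)) {
    res$chamber_diff_pct <- .with_stage(
      "chamber", id,
      as.numeric(compare_chamber(ds$chamber$measured_gy, ds$grids[[1L]],
                                 ds$chamber$spec)))
    res$row$chamber_diff_pct <- res$chamber_diff_pct
  } else {
    res$row$chamber_diff_pct <- NA_real_
  }
  res$registration <- tform
  res
}

#' Run single-fraction QA
#'
#' Executes the full chain for one fraction: calibration with daily
#' rescaling, landmark registration, response-to-dose conversion,
#' film-plane extraction of the calculated dose, edge trimming, relative
#' normalization, bounded shift correction, and the gamma / dose-deviation
#' / DTA / profile comparison.
#'
#' @param config a [qa_config()] with `mode = "single_fraction"`.
#' @return A [qa_report()] with one row.
#' @export
run_fraction_qa <- function(config) {
  stopifnot(inherits(config, "qa_config"))
  if (config$mode != "single_fraction") {
    stop("config error: run_fraction_qa needs mode = 'single_fraction'")
  }
  if (length(config$dataset$grids) != 1L) {
    stop("config error: single-fraction QA expects exactly 1 calculated ",
         "grid, got ", length(config$dataset$grids))
  }
  qa_report(list(.analyze_dataset(config)))
}

#' Run total-dose QA
#'
#' Sums the per-fraction calculated planes and compares the accumulated
#' film measurement against the total, with the identical metric chain as
#' [run_fraction_qa()].
#'
#' @param config a [qa_config()] with `mode = "total_dose"`; the dataset
#'   must carry `expected_fractions` (default 5) calculated grids unless
#'   `allow_any_fractions` is set.
#' @return A [qa_report()] with one row.
#' @export
run_total_qa <- function(config) {
  stopifnot(inherits(config, "qa_config"))
  if (config$mode != "total_dose") {
    stop("config error: run_total_qa needs mode = 'total_dose'")
  }
  n <- length(config$dataset$grids)
  if (!config$allow_any_fractions && n != config$expected_fractions) {
    stop("config error: total-dose QA expects ", config$expected_fractions,
         " fractions, got ", n,
         " (set allow_any_fractions = TRUE to override)")
  }
  qa_report(list(.analyze_dataset(config)))
}

#' Run the QA suite over a simulated collection
#'
#' Analyzes every dataset of a [generate_treatment_dataset()] collection
#' with its own mode, using one shared set of criteria.
#'
#' @param collection a `treatment_collection`.
#' @param gamma,thresholds,dta,shift,norm_radius as in [qa_config()].
#' @return A [qa_report()] with one row per dataset.
#' @export
run_qa_suite <- function(collection, gamma = gamma_criteria(),
                         thresholds = analysis_thresholds(),
                         dta = dta_spec(), shift = shift_search_spec(),
                         norm_radius = 10) {
  stopifnot(inherits(collection, "treatment_collection"))
  results <- lapply(collection$datasets, function(ds) {
    cfg <- qa_config(ds, collection$calibration,
                     pose = collection$phantom$film_cassette,
                     gspec = collection$gspec, gamma = gamma,
                     thresholds = thresholds, dta = dta, shift = shift,
                     mode = ds$mode, norm_radius = norm_radius,
                     allow_any_fractions = TRUE)
    .analyze_dataset(cfg)
  })
  qa_report(results, provenance = list(seed = collection$ledger$seed))
}

#' Assemble a QA report
#'
#' Binds per-dataset comparison results into the report object: the
#' summary table, the applied shifts with their mean +- SD across
#' datasets, and provenance (package version, criteria hash, seed).
#'
#' @param results list of `comparison_result` objects.
#' @param provenance optional named list merged into the provenance block.
#' @return An object of class `qa_report` with elements `rows`,
#'   `results`, `shift_summary`, `provenance`.
#' @export
qa_report <- function(results, provenance = list()) {
  rows <- do.call(rbind, lapply(results, as.data.frame))
  rownames(rows) <- NULL
  shift_summary <- data.frame(
    direction = c("crossline", "inline"),
    mean = c(mean(rows$shift_crossline), mean(rows$shift_inline)),
    sd = c(if (nrow(rows) > 1L) sd(rows$shift_crossline) else 0,
           if (nrow(rows) > 1L) sd(rows$shift_inline) else 0))
  tf <- tempfile(fileext = ".json")
  jsonlite::write_json(rows, tf, digits = 10)
  prov <- c(list(package_version = as.character(
    utils::packageVersion("filmqa")),
    report_hash = unname(tools::md5sum(tf))), provenance)
  unlink(tf)
  structure(
    list(rows = rows, results = results, shift_summary = shift_summary,
         provenance = prov),
    class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  cat("<qa_report> ", nrow(x$rows), " dataset(s)\n", sep = "")
  df <- x$rows
  cat(sprintf("  %-26s %5s %6s %6s  %14s  %12s\n", "dataset", "mode",
              "pass10", "pass90", "dev10 (mean+-sd)", "DTA (mm)"))
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-26s %5s %6.1f %6.1f  %6.2f +- %5.2f  %4.2f +- %4.2f\n",
                df$dataset[i], substr(df$mode[i], 1, 5), df$pass_low[i],
                df$pass_high[i], df$dev_mean_low[i], df$dev_sd_low[i],
                df$dta_mean[i], df$dta_sd[i]))
  }
  ss <- x$shift_summary
  cat(sprintf("  applied shifts: crossline %.2f +- %.2f mm, inline %.2f +- %.2f mm\n",
              ss$mean[1], ss$sd[1], ss$mean[2], ss$sd[2]))
  invisible(x)
}

#' Write a QA report to disk
#'
#' Writes the summary table as CSV (one row per dataset, mirroring the
#' standard film-QA table columns) and optionally the gamma /
#' dose-deviation / DTA maps in the portable container.
#'
#' @param report a [qa_report()].
#' @param path output directory.
#' @param maps also write the per-dataset metric maps.
#' @return `path`, invisibly.
#' @export
write_qa_report <- function(report, path, maps = FALSE) {
  stopifnot(inherits(report, "qa_report"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$rows, file.path(path, "report.csv"), row.names = FALSE)
  write.csv(report$shift_summary, file.path(path, "shifts.csv"),
            row.names = FALSE)
  jsonlite::write_json(report$provenance,
                       file.path(path, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  if (maps) {
    for (res in report$results) {
      id <- res$row$dataset
      md <- file.path(path, "maps", id)
      dir.create(md, recursive = TRUE, showWarnings = FALSE)
      sp <- c(1, 1)
      write_dose_plane(dose_plane2d(res$gamma$gamma, sp),
                       file.path(md, "gamma"))
      write_dose_plane(dose_plane2d(res$deviation$deviation, sp),
                       file.path(md, "deviation"))
      write_dose_plane(dose_plane2d(res$dta$dta, sp), file.path(md, "dta"))
    }
  }
  invisible(path)
}
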
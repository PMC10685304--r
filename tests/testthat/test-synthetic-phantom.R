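# Parametric beam model, delivery simulation, film-scan synthesis and
# dataset generation.

test_that("a single unattenuated beam shows the closed-form erf penumbra width", {
  plan <- plan_model(beams = data.frame(angle = 0, weight = 1,
                                        field_cross = 40,
                                        field_inline = 60, sigma = 3,
                                        mu = 0))
  g <- compute_plan_dose(plan, phantom_model(),
                         grid_spec = list(origin = c(-10, -12, -30),
                                          spacing = c(0.5, 2, 2),
                                          dim = c(161L, 95L, 31L)))
  p <- extract_film_plane(g, cassette_pose(),
                          common_grid_spec(spacing = c(0.5, 1),
                                           post_size = c(121, 166)))
  prof <- p$values[, 83] / max(p$values[, 83])
  xs <- (seq_along(prof) - 1) * 0.5
  # falling edge beyond the flat top (beam centered at crossline 30)
  edge_idx <- xs >= 30
  x20 <- stats::approx(prof[edge_idx], xs[edge_idx], xout = 0.2)$y
  x80 <- stats::approx(prof[edge_idx], xs[edge_idx], xout = 0.8)$y
  width <- x20 - x80
  expected <- (qnorm(0.8) - qnorm(0.2)) * 3
  expect_lt(abs(width - expected) / expected, 0.05)
})

test_that("a zero-weight plan yields zero dose", {
  plan <- plan_model(beams = data.frame(angle = c(0, 90), weight = 0,
                                        field_cross = 30,
                                        field_inline = 40, sigma = 3,
                                        mu = 0.005))
  g <- compute_plan_dose(plan, phantom_model())
  expect_true(all(g$values == 0))
})

test_that("the prescription point receives the fraction dose exactly and doses stay non-negative", {
  g <- compute_plan_dose(plan_model(), phantom_model())
  pp <- attr(g, "prescription_point")
  expect_equal(
    filmqa:::.trilinear(g$values, g$origin, g$spacing, rbind(pp)),
    1.2, tolerance = 1e-12)
  expect_true(all(g$values >= 0))
  # prescribing to the 70% isodose puts the maximum near 1.2 / 0.7 Gy
  expect_lt(abs(max(g$values) - 1.2 / 0.7) / (1.2 / 0.7), 0.05)
})

test_that("a beam arrangement missing the body raises a geometry error", {
  plan <- plan_model(isocenter = c(400, 82.5, 0))
  expect_error(compute_plan_dose(plan, phantom_model()),
               "geometry error")
})

test_that("delivery perturbations behave as dose scale and recoverable residual shift", {
  g <- compute_plan_dose(plan_model(), phantom_model())
  pose <- cassette_pose()
  gspec <- common_grid_spec()
  base <- simulate_fraction_delivery(g, pose, gspec)
  expect_equal(base$values, extract_film_plane(g, pose, gspec)$values)

  scaled <- simulate_fraction_delivery(g, pose, gspec, dose_scale = 1.02)
  expect_equal(scaled$values, 1.02 * base$values, tolerance = 1e-12)

  shifted <- simulate_fraction_delivery(g, pose, gspec,
                                        residual_shift = c(0.8, 0))
  ctr <- locate_high_dose_center(crop_edge_voxels(base))
  calc_rel <- normalize_relative(crop_edge_voxels(base), ctr)
  meas_rel <- normalize_relative(crop_edge_voxels(shifted), ctr)
  sh <- optimize_shift(meas_rel, calc_rel)
  expect_lt(abs(abs(sh$shift[1]) - 0.8), 0.1 + 1e-9)
  expect_lt(abs(sh$shift[2]), 0.1 + 1e-9)
})

test_that("a noise-free film scan round-trips the dose plane through the full film chain", {
  g <- compute_plan_dose(plan_model(), phantom_model())
  pose <- cassette_pose()
  gspec <- common_grid_spec()
  plane <- simulate_fraction_delivery(g, pose, gspec)
  cfg <- null_simulation_config()
  curve_true <- filmqa:::.true_curve(cfg)
  scan <- simulate_film_scan(plane, curve_true, pose, drift = 1,
                             scanner_t = rigid_transform2d(),
                             noise = null_noise_model())
  tform <- solve_landmark_transform(scan$landmarks,
                                    pose$nominal_landmarks)
  reg <- apply_transform(scan, tform, gspec)
  curve_fit <- fit_calibration_curve(batch_calibration_table())
  recovered <- convert_response_to_dose(reg, curve_fit)
  expect_lt(max(abs(recovered$values - plane$values)), 1e-6)
})

test_that("five accumulated 1.2 Gy fractions encode 6.0 Gy on the film", {
  uni <- dose_plane2d(matrix(1.2, 61, 166), c(1, 1))
  total <- sum_planes(replicate(5, uni, simplify = FALSE))
  cfg <- null_simulation_config()
  curve_true <- filmqa:::.true_curve(cfg)
  scan <- simulate_film_scan(total, curve_true, cassette_pose(),
                             noise = null_noise_model())
  curve_fit <- fit_calibration_curve(batch_calibration_table())
  tform <- solve_landmark_transform(scan$landmarks,
                                    cassette_pose()$nominal_landmarks)
  reg <- apply_transform(scan, tform, common_grid_spec())
  dose <- convert_response_to_dose(reg, curve_fit)
  expect_equal(max(abs(dose$values - 6.0)), 0, tolerance = 1e-6)
})

test_that("doses beyond the calibration range abort as film saturation", {
  cfg <- null_simulation_config()
  curve_true <- filmqa:::.true_curve(cfg)
  hot <- dose_plane2d(matrix(11, 61, 166), c(1, 1))
  expect_error(simulate_film_scan(hot, curve_true, cassette_pose(),
                                  noise = null_noise_model()),
               "saturation")
})

test_that("an injected scanner rotation is recovered exactly without jitter", {
  plane <- dose_plane2d(matrix(seq(0, 5, length.out = 61 * 166), 61, 166),
                        c(1, 1))
  cfg <- null_simulation_config()
  curve_true <- filmqa:::.true_curve(cfg)
  st <- rigid_transform2d(2.0, c(1.5, -0.8))
  scan <- simulate_film_scan(plane, curve_true, cassette_pose(),
                             scanner_t = st, noise = null_noise_model())
  sol <- solve_landmark_transform(scan$landmarks,
                                  cassette_pose()$nominal_landmarks)
  expect_equal(sol$rotation, -2.0, tolerance = 1e-9)
})

test_that("dataset generation is deterministic under a fixed seed, on disk byte for byte", {
  cfg <- simulation_config(layout = "null")
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  c1 <- generate_treatment_dataset(cfg, seed = 11, path = d1)
  c2 <- generate_treatment_dataset(cfg, seed = 11, path = d2)
  expect_equal(c1$datasets$original_single$scan$response,
               c2$datasets$original_single$scan$response)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f2)))
  expect_identical(h1, h2)
  # and a different seed changes the stochastic content
  c3 <- generate_treatment_dataset(cfg, seed = 12)
  expect_false(identical(c1$datasets$original_single$scan$response,
                         c3$datasets$original_single$scan$response))
})

test_that("the experimental layout lists fourteen datasets: three totals and eleven singles", {
  lay <- filmqa:::.paper14_layout()
  expect_length(lay, 14L)
  modes <- vapply(lay, `[[`, character(1), "mode")
  expect_equal(sum(modes == "total_dose"), 3L)
  expect_equal(sum(modes == "single_fraction"), 11L)
  ids <- vapply(lay, `[[`, character(1), "id")
  expect_false(anyDuplicated(ids) > 0)
  singles <- vapply(lay[modes == "single_fraction"], `[[`, character(1),
                    "series")
  expect_equal(as.integer(table(singles)[c("original", "translation",
                                           "rotation",
                                           "body_modification")]),
               c(1L, 5L, 3L, 2L))
})

test_that("the ground-truth ledger records every injected perturbation", {
  cfg <- simulation_config(layout = "null")
  col <- generate_treatment_dataset(cfg, seed = 21)
  led <- col$ledger$datasets$original_single
  expect_true(all(c("drift", "scanner_rotation", "scanner_translation",
                    "delivery_dose_scale") %in% names(led)))
  expect_gte(led$drift, cfg$noise$daily_drift_range[1])
  expect_lte(led$drift, cfg$noise$daily_drift_range[2])
  # the recorded drift is recoverable from the daily films
  curve <- fit_calibration_curve(col$calibration)
  curve <- rescale_daily(curve, col$datasets$original_single$daily)
  expect_lt(abs(curve$daily_scale - led$drift) / led$drift, 0.01)
  # the recorded scanner rotation is recoverable from the landmarks
  sol <- solve_landmark_transform(
    col$datasets$original_single$scan$landmarks,
    col$phantom$film_cassette$nominal_landmarks)
  expect_lt(abs(sol$rotation + led$scanner_rotation), 0.5)
})

test_that("the accumulated ground truth equals the sum of delivered fraction planes", {
  cfg <- null_simulation_config()
  col <- generate_treatment_dataset(cfg, seed = 2)
  ds <- col$datasets$original_single
  manual <- sum_planes(lapply(ds$grids, simulate_fraction_delivery,
                              pose = col$phantom$film_cassette,
                              gspec = col$gspec))
  expect_equal(max(abs(ds$ground_truth$values - manual$values)), 0,
               tolerance = 1e-12)
})
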
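# Calibration fitting, daily rescaling, response-to-dose conversion and
# landmark registration.

test_that("noiseless calibration points recover the generating parameters", {
  tbl <- batch_calibration_table()
  cur <- fit_calibration_curve(tbl)
  expect_equal(unname(cur$params), unname(true_film_params),
               tolerance = 1e-8)
  expect_lt(max(abs(cur$residuals)), 1e-9)
})

test_that("the fitted mapping is strictly monotone over its domain", {
  for (s in 1:20) {
    set.seed(s)
    tbl <- batch_calibration_table(noise_sd = 0.003, seed = s)
    cur <- fit_calibration_curve(tbl)
    xs <- seq(cur$response_range[1], cur$response_range[2],
              length.out = 1000)
    expect_true(all(diff(curve_dose(cur, xs)) < 0))
  }
})

test_that("degenerate calibration inputs are rejected", {
  expect_error(fit_calibration_curve(
    data.frame(dose_gy = c(0, 1, 2), response = c(40, 30, 20))),
    "at least 4")
  # two points with equal response, different dose
  expect_error(fit_calibration_curve(
    data.frame(dose_gy = c(0, 1, 2, 3), response = c(40, 30, 30, 10))),
    "monotone")
  expect_error(fit_calibration_curve(
    data.frame(dose_gy = c(0, 1, 1, 3), response = c(40, 30, 25, 10))),
    "duplicate")
})

test_that("an identity day yields daily_scale 1 and a noiseless drift is recovered exactly", {
  cur <- fit_calibration_curve(batch_calibration_table())
  daily0 <- data.frame(dose_gy = c(0, 5, 10),
                       response = film_response_for(c(0, 5, 10)))
  expect_equal(rescale_daily(cur, daily0)$daily_scale, 1,
               tolerance = 1e-10)
  # day with true dose scale 1.05: responses as if doses were d / 1.05
  d <- c(0, 2.5, 5, 7.5, 10)
  daily <- data.frame(dose_gy = d, response = film_response_for(d / 1.05))
  expect_equal(rescale_daily(cur, daily)$daily_scale, 1.05,
               tolerance = 1e-8)
  expect_error(rescale_daily(cur, daily[1:2, ]), "design error")
  expect_error(rescale_daily(
    cur, data.frame(dose_gy = c(0, 6, 12),
                    response = film_response_for(c(0, 6, 9.9)))),
    "design error")
})

test_that("daily scale recovery is unbiased and its spread matches the delta-method oracle", {
  cur <- fit_calibration_curve(batch_calibration_table())
  d <- c(0, 2.5, 5, 7.5, 10)
  x0 <- film_response_for(d / 1.05)
  scales <- vapply(1:200, function(s) {
    set.seed(s)
    daily <- data.frame(dose_gy = d,
                        response = x0 * (1 + rnorm(5, sd = 0.003)))
    rescale_daily(cur, daily)$daily_scale
  }, numeric(1))
  expect_lt(abs(mean(scales) - 1.05) / 1.05, 0.002)
  sd_pred <- oracle_daily_scale_sd(d / 1.05, true_film_params, 0.003) *
    1.05
  ratio <- sd(scales) / sd_pred
  expect_gt(ratio, 1 / 1.5)
  expect_lt(ratio, 1.5)
})

test_that("response converts to dose consistently with the curve", {
  cur <- fit_calibration_curve(batch_calibration_table())
  lm <- matrix(c(1, 1, 9, 1, 5, 9), 3, 2, byrow = TRUE)
  r12 <- film_response_for(1.2)
  sc <- film_scan(matrix(r12, 12, 10), 1, lm)
  p <- convert_response_to_dose(sc, cur)
  expect_equal(max(abs(p$values - 1.2)), 0, tolerance = 1e-8)

  # noiseless simulator round trip
  set.seed(77)
  dose <- matrix(runif(120, 0.3, 8.6), 12, 10)
  sc2 <- film_scan(film_response_for(dose), 1, lm)
  p2 <- convert_response_to_dose(sc2, cur)
  expect_lt(max(abs(p2$values - dose)), 1e-6)
})

test_that("out-of-range responses are flagged and bounded", {
  cur <- fit_calibration_curve(batch_calibration_table())
  resp <- matrix(film_response_for(5), 10, 10)
  resp[1, 1:2] <- film_response_for(0) * 1.2  # far beyond zero-dose response
  lm <- matrix(c(1, 1, 9, 1, 5, 9), 3, 2, byrow = TRUE)
  p <- convert_response_to_dose(film_scan(resp, 1, lm), cur)
  expect_true(all(is.na(p$values[1, 1:2])))
  expect_equal(sum(is.na(p$values)), 2L)
  resp_bad <- resp
  resp_bad[1:3, ] <- film_response_for(0) * 1.2  # 30% out of range
  expect_error(convert_response_to_dose(film_scan(resp_bad, 1, lm), cur),
               "conversion error")
})

test_that("per-pixel dose noise matches slope propagation through the curve", {
  cur <- fit_calibration_curve(batch_calibration_table())
  lm <- matrix(c(1, 1, 9, 1, 5, 9), 3, 2, byrow = TRUE)
  d0 <- 4
  x0 <- film_response_for(d0)
  slope <- (true_film_params[["b"]] -
              true_film_params[["a"]] * true_film_params[["c"]]) /
    (1 + true_film_params[["c"]] * x0)^2
  pred_sd <- abs(slope) * x0 * 0.003
  sds <- vapply(1:20, function(s) {
    set.seed(s)
    resp <- matrix(x0 * (1 + rnorm(2500, sd = 0.003)), 50, 50)
    p <- convert_response_to_dose(film_scan(resp, 1, lm), cur)
    sd(p$values)
  }, numeric(1))
  expect_lt(abs(mean(sds) - pred_sd) / pred_sd, 0.2)
})

test_that("landmark registration solves identity and known transforms and is label-invariant", {
  nom <- matrix(c(5, 5, 55, 5, 30, 160), 3, 2, byrow = TRUE)
  t0 <- solve_landmark_transform(nom, nom)
  expect_equal(t0$rotation, 0, tolerance = 1e-12)
  expect_equal(t0$translation, c(0, 0), tolerance = 1e-12)
  expect_lt(attr(t0, "rms_residual"), 1e-12)

  fwd <- rigid_transform2d(2.0, c(1.0, -0.5))
  det <- transform_points(fwd, nom)
  sol <- solve_landmark_transform(det, nom)
  inv <- invert_transform(fwd)
  expect_equal(sol$rotation, inv$rotation, tolerance = 1e-9)
  expect_equal(sol$translation, inv$translation, tolerance = 1e-9)
  expect_equal(transform_points(sol, det), nom, tolerance = 1e-9)

  perm <- c(3, 1, 2)
  sol_p <- solve_landmark_transform(det[perm, ], nom[perm, ])
  expect_equal(sol_p$rotation, sol$rotation, tolerance = 1e-12)
  expect_equal(sol_p$translation, sol$translation, tolerance = 1e-12)
})

test_that("degenerate landmark sets raise geometry errors", {
  nom <- matrix(c(5, 5, 55, 5, 30, 160), 3, 2, byrow = TRUE)
  coincident <- matrix(c(5, 5, 5, 5, 30, 160), 3, 2, byrow = TRUE)
  expect_error(solve_landmark_transform(coincident, nom), "collinear")
  collinear <- matrix(c(0, 0, 10, 10, 20, 20), 3, 2, byrow = TRUE)
  expect_error(solve_landmark_transform(collinear, nom), "collinear")
})

test_that("transform application preserves constants and inverts within interpolation tolerance", {
  spec <- common_grid_spec(post_size = c(40, 50))
  lm <- matrix(c(5, 5, 35, 5, 20, 45), 3, 2, byrow = TRUE)
  const <- film_scan(matrix(4, 60, 70), 1, lm, c(-10, -10))
  out <- apply_transform(const, rigid_transform2d(2.5, c(1, -1)), spec)
  expect_true(all(abs(out$response - 4) < 1e-12, na.rm = TRUE))

  # identity transform on a scan aligned with the post grid
  set.seed(6)
  v <- matrix(runif(40 * 50), 40, 50)
  sc <- film_scan(v, 1, lm, c(0, 0))
  idt <- apply_transform(sc, rigid_transform2d(), spec)
  expect_equal(idt$response, v)

  # smooth field: rotate theta then -theta recovers within 1% of range
  xs <- 0:59
  ys <- 0:69
  smooth <- outer(xs, ys, function(x, y) {
    1 + sin(x / 12) * cos(y / 15)
  })
  sc2 <- film_scan(smooth, 1, lm, c(-10, -10))
  th <- 3
  rng <- diff(range(smooth))
  # round trip: forward by t then backward by its inverse
  t1 <- rigid_transform2d(th, c(0.4, -0.3))
  fwd2 <- apply_transform(sc2, t1, common_grid_spec(post_size = c(60, 70)))
  fwd2_sc <- film_scan(fwd2$response, 1, fwd2$landmarks, c(0, 0))
  back2 <- apply_transform(fwd2_sc, invert_transform(t1),
                           common_grid_spec(post_size = c(60, 70)))
  ok <- !is.na(back2$response)
  # back2 lives on the original film frame shifted by origin (-10,-10)
  orig_on_grid <- filmqa:::.bilinear(smooth, c(-10, -10), c(1, 1),
                                     rep(0:59, times = 70),
                                     rep(0:69, each = 60))
  diff_map <- abs(back2$response - matrix(orig_on_grid, 60, 70))
  expect_lt(max(diff_map[ok & !is.na(orig_on_grid)]), 0.01 * rng)
})
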
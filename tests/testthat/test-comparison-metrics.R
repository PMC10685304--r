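# Comparison statistics: high-dose center, normalization, shift search,
# gamma, dose deviation, DTA, profiles, chamber comparison, summary rows.

shift_pattern <- function(plane, u) {
  # move the dose pattern by u (mm): out(r) = plane(r - u)
  nr <- nrow(plane$values)
  nc <- ncol(plane$values)
  xs <- plane$origin[1] + (seq_len(nr) - 1) * plane$spacing[1]
  ys <- plane$origin[2] + (seq_len(nc) - 1) * plane$spacing[2]
  v <- filmqa:::.bilinear(plane$values, plane$origin, plane$spacing,
                          rep(xs - u[1], times = nc),
                          rep(ys - u[2], each = nr))
  dose_plane2d(matrix(v, nr, nc), plane$spacing, plane$origin,
               plane$is_relative, plane$norm_dose)
}

crop_n <- function(plane, n) {
  crop_edge_voxels(plane, common_grid_spec(edge_trim = n))
}

test_that("the high-dose center finds a Gaussian peak and the middle of a flat top", {
  xs <- 0:30
  ys <- 0:34
  peak <- c(14.3, 16.7)
  v <- outer(xs, ys, function(x, y) {
    exp(-((x - peak[1])^2 + (y - peak[2])^2) / (2 * 6^2))
  })
  ctr <- locate_high_dose_center(dose_plane2d(v, c(1, 1)))
  expect_lt(max(abs(ctr - peak)), 0.5)

  flat <- matrix(0, 21, 21)
  flat[6:16, 4:18] <- 1
  ctr2 <- locate_high_dose_center(dose_plane2d(flat, c(1, 1)))
  expect_equal(ctr2, c(10, 10))

  expect_error(locate_high_dose_center(dose_plane2d(matrix(0, 5, 5),
                                                    c(1, 1))),
               "degenerate")
})

test_that("normalization divides by the in-disk median and is idempotent", {
  u <- dose_plane2d(matrix(5, 30, 30), c(1, 1))
  un <- normalize_relative(u, c(14, 14))
  expect_equal(un$norm_dose, 5)
  expect_true(all(un$values == 1))
  expect_true(un$is_relative)

  p <- smooth_rel_plane(42, 35, 35)
  p_abs <- dose_plane2d(p$values * 4, c(1, 1))
  ctr <- locate_high_dose_center(p_abs)
  pn <- normalize_relative(p_abs, ctr)
  # independent sort-and-pick median over the disk mask
  xs <- 0:34
  d2 <- outer((xs - ctr[1])^2, (xs - ctr[2])^2, "+")
  vals <- sort(p_abs$values[d2 <= 100])
  n <- length(vals)
  med <- if (n %% 2 == 1) vals[(n + 1) / 2] else
    (vals[n / 2] + vals[n / 2 + 1]) / 2
  expect_equal(pn$norm_dose, med)
  expect_equal(pn$values, p_abs$values / med)

  pn2 <- normalize_relative(pn, ctr)
  expect_equal(pn2$norm_dose, 1.0)
  expect_equal(pn2$values, pn$values)

  expect_error(normalize_relative(p_abs, c(3, 3)), "disk")
})

test_that("shift correction recovers injected displacements and clamps at the bound", {
  base <- smooth_rel_plane(7, 40, 40)
  idres <- optimize_shift(base, base)
  expect_equal(idres$shift, c(0, 0))

  u <- c(1.0, -0.5)
  meas <- crop_n(shift_pattern(base, u), 3)
  calc <- crop_n(base, 3)
  res <- optimize_shift(meas, calc)
  expect_lt(max(abs(res$shift - (-u))), 0.1 + 1e-9)

  big <- c(2.5, 0)
  meas2 <- crop_n(shift_pattern(base, big), 4)
  calc2 <- crop_n(base, 4)
  res2 <- optimize_shift(meas2, calc2)
  expect_equal(abs(res2$shift[1]), 1.5)
})

test_that("gamma is zero for identical planes and 1.5 for a uniform 3% offset", {
  p <- smooth_rel_plane(3)
  g <- compute_gamma(p, p)
  expect_true(all(g$gamma == 0))
  expect_equal(unname(g$pass_rates), c(100, 100))

  ref <- uniform_rel_plane(1.0)
  ev <- uniform_rel_plane(1.03)
  g2 <- compute_gamma(ref, ev)
  expect_equal(max(abs(g2$gamma - 1.5)), 0, tolerance = 1e-12)
  expect_equal(unname(g2$pass_rates), c(0, 0))
})

test_that("gamma never exceeds its no-search value and never grows with the search radius", {
  calc <- smooth_rel_plane(12)
  meas <- perturbed_partner(calc, 12)
  g_small <- compute_gamma(meas, calc,
                           gamma_criteria(search_radius = 2))$gamma
  g_big <- compute_gamma(meas, calc,
                         gamma_criteria(search_radius = 6))$gamma
  expect_true(all(g_big <= g_small + 1e-12))
  no_search <- abs(meas$values - calc$values) / 0.02
  expect_true(all(g_big <= no_search + 1e-12))
})

test_that("gamma is invariant under an identical rigid shift of both planes", {
  calc <- smooth_rel_plane(15)
  meas <- perturbed_partner(calc, 15)
  g1 <- compute_gamma(meas, calc)$gamma
  shift_origin <- function(p) {
    dose_plane2d(p$values, p$spacing, p$origin + c(3.2, -1.7),
                 p$is_relative, p$norm_dose)
  }
  g2 <- compute_gamma(shift_origin(meas), shift_origin(calc))$gamma
  expect_equal(g1, g2, tolerance = 1e-12)
})

test_that("DTA is zero for identical planes and matches the linear-ramp closed form", {
  p <- smooth_rel_plane(9)
  d <- compute_dta(p, p)
  expect_true(all(d$dta == 0))
  expect_equal(d$mean, 0)

  # ramp with dose 1.0 and gradient g = 0.04 / mm at the center row;
  # evaluated pattern shifted by s = 2.0 mm:
  # DTA = s - local_tol * d / g = 2.0 - 0.005 * 1.0 / 0.04 = 1.875 mm
  gslope <- 0.04
  v <- matrix(rep(1 + gslope * ((1:41) - 21), 11), 41, 11)
  ref <- dose_plane2d(v, c(1, 1), is_relative = TRUE, norm_dose = 1)
  ev <- dose_plane2d(matrix(rep(1 + gslope * ((1:41) - 23), 11), 41, 11),
                     c(1, 1), is_relative = TRUE, norm_dose = 1)
  spec <- dta_spec(search_radius = 5, eval_subsample = 0.05)
  res <- compute_dta(ref, ev, spec)
  expect_equal(res$dta[21, 6], 2.0 - 0.005 / 0.04, tolerance = 0.051)
})

test_that("enlarging the DTA dose tolerance never increases any DTA value", {
  calc <- smooth_rel_plane(18)
  meas <- perturbed_partner(calc, 18)
  d1 <- compute_dta(meas, calc, dta_spec(local_tol = 0.005,
                                         search_radius = 5))$dta
  d2 <- compute_dta(meas, calc, dta_spec(local_tol = 0.02,
                                         search_radius = 5))$dta
  expect_true(all(d2 <= d1 + 1e-12))
})

test_that("dose deviation reports constant offsets exactly and matches direct statistics", {
  p <- smooth_rel_plane(25, 25, 25)
  d0 <- compute_dose_deviation(p, p)
  expect_true(all(d0$deviation == 0))
  expect_equal(d0$stats$mean, c(0, 0))
  expect_equal(d0$stats$sd, c(0, 0))

  off <- dose_plane2d(p$values + 0.017, p$spacing, p$origin, TRUE, 1)
  d1 <- compute_dose_deviation(off, p)
  expect_equal(max(abs(d1$deviation - 1.7)), 0, tolerance = 1e-9)

  meas <- perturbed_partner(p, 25)
  d2 <- compute_dose_deviation(meas, p)
  dmax <- max(p$values)
  for (k in 1:2) {
    f <- c(0.1, 0.9)[k]
    sel <- p$values >= f * dmax
    dev <- 100 * (meas$values[sel] - p$values[sel])
    expect_equal(d2$stats$mean[k], mean(dev))
    expect_equal(d2$stats$sd[k], sd(dev))
  }
})

test_that("center profiles report percentage-point differences and localize penumbra errors", {
  p <- smooth_rel_plane(31, 21, 21)
  pr <- extract_center_profiles(p, p, c(10, 10))
  expect_true(all(pr$inline$diff_pp == 0))
  expect_true(all(pr$crossline$diff_pp == 0))

  off <- dose_plane2d(p$values + 0.012, p$spacing, p$origin, TRUE, 1)
  pr2 <- extract_center_profiles(off, p, c(10, 10))
  expect_equal(max(abs(pr2$inline$diff_pp - 1.2)), 0, tolerance = 1e-9)

  # erf penumbra along inline, shifted by 1 mm in the measurement: the
  # largest pp difference must sit inside the 20-80% penumbra band
  ys <- 0:60
  edge <- function(y) pnorm((30 - y) / 3)
  calc <- dose_plane2d(matrix(rep(edge(ys), each = 21), 21, 61), c(1, 1),
                       is_relative = TRUE, norm_dose = 1)
  meas <- dose_plane2d(matrix(rep(edge(ys - 1), each = 21), 21, 61),
                       c(1, 1), is_relative = TRUE, norm_dose = 1)
  pr3 <- extract_center_profiles(meas, calc, c(10, 30))
  j_max <- which.max(abs(pr3$inline$diff_pp))
  calc_at_max <- pr3$inline$calculated[j_max]
  dmax <- max(calc$values)
  expect_gt(calc_at_max, 0.2 * dmax)
  expect_lt(calc_at_max, 0.8 * dmax)

  expect_error(extract_center_profiles(p, p, c(100, 100)), "outside")
})

test_that("chamber comparison matches symmetry and the quadratic-field closed form", {
  mk_grid <- function(f, n = 17, sp = 0.5) {
    xs <- (seq_len(n) - 1) * sp
    vals <- array(0, c(n, n, n))
    for (k in seq_len(n)) {
      vals[, , k] <- outer(xs, xs, function(x, y) f(x, y, xs[k]))
    }
    dose_grid3d(vals, c(0, 0, 0), rep(sp, 3))
  }
  ctr <- c(4, 4, 4)
  spec <- chamber_spec(ctr, radius = 3)

  gu <- mk_grid(function(x, y, z) 2 + 0 * x)
  r0 <- compare_chamber(2, gu, spec)
  expect_equal(as.numeric(r0), 0)
  expect_equal(attr(r0, "calculated_gy"), 2)

  glin <- mk_grid(function(x, y, z) 1 + 0.05 * x + 0.02 * y - 0.03 * z)
  center_val <- 1 + 0.05 * 4 + 0.02 * 4 - 0.03 * 4
  rl <- compare_chamber(center_val, glin, spec)
  expect_equal(as.numeric(rl), 0, tolerance = 1e-10)

  a <- 0.01
  gq <- mk_grid(function(x, y, z) {
    2 + a * ((x - 4)^2 + (y - 4)^2 + (z - 4)^2)
  })
  expected <- 2 + 3 / 5 * a * 9
  rq <- compare_chamber(expected, gq, spec)
  expect_equal(attr(rq, "calculated_gy"), expected, tolerance = 0.01)

  expect_error(compare_chamber(2, gu, chamber_spec(c(1, 1, 1), 3)),
               "extent")
})

test_that("summary rows pass through identity and offset cases and match recomputation", {
  calc <- smooth_rel_plane(55, 25, 25)
  g <- compute_gamma(calc, calc)
  dv <- compute_dose_deviation(calc, calc)
  dt <- compute_dta(calc, calc, dta_spec(search_radius = 5))
  row <- as.data.frame(summarize_comparison("id_case", "single_fraction",
                                            g, dv, dt, c(0, 0)))
  expect_equal(row$pass_low, 100)
  expect_equal(row$pass_high, 100)
  expect_equal(row$dev_mean_low, 0)
  expect_equal(row$dev_sd_high, 0)
  expect_equal(row$dta_mean, 0)

  # the 90%-threshold voxels are a subset of the 10%-threshold voxels
  expect_true(all(g$masks$low[g$masks$high]))

  meas <- perturbed_partner(calc, 55)
  g2 <- compute_gamma(meas, calc)
  dv2 <- compute_dose_deviation(meas, calc)
  dt2 <- compute_dta(meas, calc, dta_spec(search_radius = 5))
  row2 <- as.data.frame(summarize_comparison("rand", "single_fraction",
                                             g2, dv2, dt2, c(0.2, -0.1)))
  dmax <- max(calc$values)
  sel <- calc$values >= 0.1 * dmax
  expect_equal(row2$pass_low,
               100 * mean(g2$gamma[sel] <= 1 + 1e-9))
  expect_equal(row2$dev_mean_low, mean(100 * (meas$values - calc$values)[sel]))
  band <- calc$values >= 0.1 * dmax & calc$values <= 0.9 * dmax
  expect_equal(row2$dta_mean, mean(dt2$dta[band]))
})
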
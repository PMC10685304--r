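# Programmatic fixtures: smooth random relative dose planes and simple
# analytic fields used across the tests.

# smooth positive field normalized to max 1 on an n1 x n2 grid at `spacing`
smooth_rel_plane <- function(seed, n1 = 15, n2 = 15, spacing = 1) {
  set.seed(seed)
  xs <- (seq_len(n1) - 1) * spacing
  ys <- (seq_len(n2) - 1) * spacing
  cx <- runif(1, 0.3, 0.7) * max(xs)
  cy <- runif(1, 0.3, 0.7) * max(ys)
  w <- runif(1, 0.25, 0.45) * max(xs)
  f <- outer(xs, ys, function(x, y) {
    exp(-((x - cx)^2 + (y - cy)^2) / (2 * w^2))
  })
  ph <- runif(4, 0, 2 * pi)
  f <- f + 0.08 * outer(xs, ys, function(x, y) {
    sin(2 * pi * x / max(xs) + ph[1]) * cos(2 * pi * y / max(ys) + ph[2])
  }) + 0.05 * outer(xs, ys, function(x, y) {
    cos(pi * x / max(xs) + ph[3]) * sin(pi * y / max(ys) + ph[4])
  }) + 0.3
  f <- f / max(f)
  dose_plane2d(f, c(spacing, spacing), c(0, 0), is_relative = TRUE,
               norm_dose = 1)
}

# a perturbed partner: small smooth multiplicative error plus a sub-mm
# rigid shift of the pattern
perturbed_partner <- function(plane, seed, shift_mm = NULL,
                              amp = 0.015) {
  set.seed(seed + 7919L)
  nr <- nrow(plane$values)
  nc <- ncol(plane$values)
  if (is.null(shift_mm)) shift_mm <- runif(2, -0.8, 0.8)
  xs <- plane$origin[1] + (seq_len(nr) - 1) * plane$spacing[1]
  ys <- plane$origin[2] + (seq_len(nc) - 1) * plane$spacing[2]
  shifted <- filmqa:::.bilinear(plane$values, plane$origin, plane$spacing,
                                rep(xs - shift_mm[1], times = nc),
                                rep(ys - shift_mm[2], each = nr))
  shifted <- matrix(shifted, nr, nc)
  # fill border NAs with the nearest valid value so fixtures stay complete
  shifted[is.na(shifted)] <- plane$values[is.na(shifted)]
  ph <- runif(2, 0, 2 * pi)
  mod <- 1 + amp * outer(xs, ys, function(x, y) {
    sin(2 * pi * x / max(xs) + ph[1]) * sin(2 * pi * y / max(ys) + ph[2])
  })
  dose_plane2d(shifted * mod, plane$spacing, plane$origin,
               is_relative = TRUE, norm_dose = 1)
}

# uniform relative plane
uniform_rel_plane <- function(value, n1 = 15, n2 = 15, spacing = 1) {
  dose_plane2d(matrix(value, n1, n2), c(spacing, spacing), c(0, 0),
               is_relative = TRUE, norm_dose = 1)
}

# the true physical film curve used by the simulator defaults
true_film_params <- c(a = 10, b = -0.25, c = 0.25)

film_response_for <- function(dose, p = true_film_params) {
  (p[["a"]] - dose) / (p[["c"]] * dose - p[["b"]])
}

film_dose_for <- function(resp, p = true_film_params) {
  (p[["a"]] + p[["b"]] * resp) / (1 + p[["c"]] * resp)
}

# 20-point batch calibration table, optionally with multiplicative
# response noise
batch_calibration_table <- function(noise_sd = 0, seed = NULL,
                                    doses = c(0, 0.25, 0.5, 0.75, 1, 1.25,
                                              1.5, 2, 2.5, 3, 3.5, 4, 5, 6,
                                              7, 8, 8.5, 9, 9.5, 10)) {
  if (!is.null(seed)) set.seed(seed)
  resp <- film_response_for(doses)
  if (noise_sd > 0) resp <- resp * (1 + rnorm(length(resp), sd = noise_sd))
  data.frame(dose_gy = doses, response = as.numeric(resp))
}
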
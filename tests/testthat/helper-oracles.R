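# Independent brute-force oracles. These deliberately avoid the package's
# internal samplers and search kernels: trilinear interpolation is written
# out corner by corner, the fine lattice is built by separable 1D linear
# interpolation with stats::approx, and the gamma/DTA searches scan the
# full displacement set with no ordering or early exit.

# direct 8-corner trilinear formula at a single point
oracle_trilinear <- function(values, origin, spacing, pt) {
  g <- (pt - origin) / spacing + 1
  dm <- dim(values)
  f <- pmin(pmax(floor(g), 1), pmax(dm - 1, 1))
  w <- g - f
  acc <- 0
  for (di in 0:1) {
    for (dj in 0:1) {
      for (dk in 0:1) {
        ii <- min(f[1] + di, dm[1])
        jj <- min(f[2] + dj, dm[2])
        kk <- min(f[3] + dk, dm[3])
        wt <- (if (di) w[1] else 1 - w[1]) *
          (if (dj) w[2] else 1 - w[2]) *
          (if (dk) w[3] else 1 - w[3])
        acc <- acc + wt * values[ii, jj, kk]
      }
    }
  }
  acc
}

# fine bilinear lattice by separable 1D interpolation (exact for bilinear)
oracle_fine_lattice <- function(plane, h) {
  nr <- nrow(plane$values)
  nc <- ncol(plane$values)
  k <- as.integer(round(plane$spacing[1] / h))
  xs <- plane$origin[1] + (seq_len(nr) - 1) * plane$spacing[1]
  ys <- plane$origin[2] + (seq_len(nc) - 1) * plane$spacing[2]
  fx <- plane$origin[1] + (seq_len((nr - 1) * k + 1) - 1) * h
  fy <- plane$origin[2] + (seq_len((nc - 1) * k + 1) - 1) * h
  tmp <- matrix(NA_real_, nr, length(fy))
  for (i in seq_len(nr)) {
    tmp[i, ] <- stats::approx(ys, plane$values[i, ], xout = fy)$y
  }
  fine <- matrix(NA_real_, length(fx), length(fy))
  for (j in seq_along(fy)) {
    fine[, j] <- stats::approx(xs, tmp[, j], xout = fx)$y
  }
  list(values = fine, k = k)
}

# displacement set within `radius` on the h-lattice (unordered)
oracle_offsets <- function(h, radius) {
  n <- floor(radius / h + 1e-9)
  g <- expand.grid(di = -n:n, dj = -n:n)
  r2 <- (g$di^2 + g$dj^2) * h * h
  keep <- r2 <= radius^2 + 1e-12
  list(di = g$di[keep], dj = g$dj[keep], r2 = r2[keep])
}

# exhaustive-search global gamma: full scan over the displacement set
oracle_gamma <- function(measured, calculated, dose_tol, dist_tol,
                         radius, h) {
  fine <- oracle_fine_lattice(calculated, h)
  off <- oracle_offsets(h, radius)
  fr <- nrow(fine$values)
  fc <- ncol(fine$values)
  nr <- nrow(measured$values)
  nc <- ncol(measured$values)
  out <- matrix(NA_real_, nr, nc)
  for (j in seq_len(nc)) {
    J0 <- (j - 1L) * fine$k + 1L
    for (i in seq_len(nr)) {
      I0 <- (i - 1L) * fine$k + 1L
      rv <- measured$values[i, j]
      I <- I0 + off$di
      J <- J0 + off$dj
      ok <- I >= 1L & I <= fr & J >= 1L & J <= fc
      ev <- fine$values[(J[ok] - 1L) * fr + I[ok]]
      g2 <- off$r2[ok] / dist_tol^2 + (ev - rv)^2 / dose_tol^2
      out[i, j] <- sqrt(min(g2))
    }
  }
  out
}

# exhaustive radial DTA: full scan, minimum distance among dose matches
oracle_dta <- function(measured, calculated, local_tol, cap, h) {
  fine <- oracle_fine_lattice(calculated, h)
  off <- oracle_offsets(h, cap)
  fr <- nrow(fine$values)
  fc <- ncol(fine$values)
  nr <- nrow(measured$values)
  nc <- ncol(measured$values)
  out <- matrix(NA_real_, nr, nc)
  for (j in seq_len(nc)) {
    J0 <- (j - 1L) * fine$k + 1L
    for (i in seq_len(nr)) {
      I0 <- (i - 1L) * fine$k + 1L
      rv <- measured$values[i, j]
      I <- I0 + off$di
      J <- J0 + off$dj
      ok <- I >= 1L & I <= fr & J >= 1L & J <= fc
      ev <- fine$values[(J[ok] - 1L) * fr + I[ok]]
      hit <- abs(ev - rv) <= local_tol * abs(rv)
      out[i, j] <- if (any(hit)) sqrt(min(off$r2[ok][hit])) else cap
    }
  }
  out
}

# delta-method SD of the daily scale factor s = sum(d f) / sum(f^2) under
# multiplicative response noise of fractional SD `sigma`
oracle_daily_scale_sd <- function(doses, params, sigma) {
  a <- params[["a"]]
  b <- params[["b"]]
  cc <- params[["c"]]
  x <- (a - doses) / (cc * doses - b)
  f <- (a + b * x) / (1 + cc * x)
  fp <- (b - a * cc) / (1 + cc * x)^2  # df/dx
  S2 <- sum(f^2)
  Sdf <- sum(doses * f)
  dsdf <- (doses * S2 - 2 * f * Sdf) / S2^2
  sqrt(sum((dsdf * fp * x * sigma)^2))
}
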
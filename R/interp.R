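# Internal interpolation utilities shared across modules.
# Everything is voxel-centre based: matrix index i maps to physical
# coordinate origin + (i - 1) * spacing. NA values propagate; points
# outside the voxel-centre extent return NA (no extrapolation).

#' @noRd
.bilinear <- function(values, origin, spacing, x, y) {
  nr <- nrow(values)
  nc <- ncol(values)
  gi <- (x - origin[1]) / spacing[1] + 1
  gj <- (y - origin[2]) / spacing[2] + 1
  eps <- 1e-7
  inside <- gi >= 1 - eps & gi <= nr + eps & gj >= 1 - eps & gj <= nc + eps
  inside[is.na(inside)] <- FALSE
  gi <- pmin(pmax(gi, 1), nr)
  gj <- pmin(pmax(gj, 1), nc)
  fi <- pmin(floor(gi), max(nr - 1L, 1L))
  fj <- pmin(floor(gj), max(nc - 1L, 1L))
  wi <- gi - fi
  wj <- gj - fj
  i2 <- pmin(fi + 1, nr)
  j2 <- pmin(fj + 1, nc)
  v11 <- values[cbind(fi, fj)]
  v21 <- values[cbind(i2, fj)]
  v12 <- values[cbind(fi, j2)]
  v22 <- values[cbind(i2, j2)]
  out <- (1 - wi) * (1 - wj) * v11 + wi * (1 - wj) * v21 +
    (1 - wi) * wj * v12 + wi * wj * v22
  out[!inside] <- NA_real_
  out
}

#' @noRd
.trilinear <- function(values, origin, spacing, pts) {
  # pts: n x 3 matrix of physical coordinates (same axis order as values)
  dm <- dim(values)
  g <- sweep(sweep(pts, 2, origin, "-"), 2, spacing, "/") + 1
  eps <- 1e-7
  inside <- g[, 1] >= 1 - eps & g[, 1] <= dm[1] + eps &
    g[, 2] >= 1 - eps & g[, 2] <= dm[2] + eps &
    g[, 3] >= 1 - eps & g[, 3] <= dm[3] + eps
  inside[is.na(inside)] <- FALSE
  g <- pmin(pmax(g, 1), matrix(dm, nrow(g), 3, byrow = TRUE))
  f <- pmin(floor(g), matrix(pmax(dm - 1L, 1L), nrow(g), 3, byrow = TRUE))
  w <- g - f
  out <- numeric(nrow(pts))
  for (di in 0:1) {
    for (dj in 0:1) {
      for (dk in 0:1) {
        ii <- pmin(f[, 1] + di, dm[1])
        jj <- pmin(f[, 2] + dj, dm[2])
        kk <- pmin(f[, 3] + dk, dm[3])
        idx <- ii + (jj - 1) * dm[1] + (kk - 1) * dm[1] * dm[2]
        wt <- (if (di) w[, 1] else 1 - w[, 1]) *
          (if (dj) w[, 2] else 1 - w[, 2]) *
          (if (dk) w[, 3] else 1 - w[, 3])
        out <- out + wt * values[idx]
      }
    }
  }
  out[!inside] <- NA_real_
  unname(out)
}

#' @noRd
.same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}
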
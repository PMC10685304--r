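# File I/O: a portable array container (raw little-endian float64 values in
# <path>.bin plus a <path>.json metadata sidecar, lossless for doubles), and
# 16-bit TIFF + JSON sidecar for film scans. All readers validate the
# sidecar and fail with the offending field named; no partial objects are
# returned.

#' @noRd
.write_portable <- function(values, meta, path) {
  meta$n_values <- length(values)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  v <- as.numeric(values)
  v[is.na(v)] <- NaN
  writeBin(v, con, size = 8, endian = "little")
  invisible(path)
}

#' @noRd
.read_portable <- function(path) {
  jpath <- paste0(path, ".json")
  bpath <- paste0(path, ".bin")
  if (!file.exists(jpath)) stop("missing sidecar: ", jpath)
  if (!file.exists(bpath)) stop("missing values file: ", bpath)
  meta <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  if (is.null(meta$n_values)) stop("parse error in ", jpath,
                                   ": missing field 'n_values'")
  n <- as.integer(meta$n_values)
  sz <- file.size(bpath)
  if (sz != 8 * n) {
    stop("parse error in ", bpath, ": field 'values' expected ", n,
         " float64 (", 8 * n, " bytes), file has ", sz, " bytes")
  }
  con <- file(bpath, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  v[is.nan(v)] <- NA_real_
  list(meta = meta, values = v)
}

#' Write / read a 3D dose grid (portable container)
#'
#' Stores the dose array as raw float64 (`<path>.bin`) with a JSON metadata
#' sidecar (`<path>.json`); the round trip is bit-exact.
#'
#' @param grid a [dose_grid3d()].
#' @param path file path without extension.
#' @return `write_dose_grid` returns `path` invisibly; `read_dose_grid`
#'   returns the [dose_grid3d()].
#' @export
write_dose_grid <- function(grid, path) {
  stopifnot(inherits(grid, "dose_grid3d"))
  .write_portable(grid$values,
                  list(type = "dose_grid3d", dim = dim(grid$values),
                       origin = grid$origin, spacing = grid$spacing,
                       axes = grid$axes),
                  path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path) {
  p <- .read_portable(path)
  m <- p$meta
  for (f in c("type", "dim", "origin", "spacing", "axes")) {
    if (is.null(m[[f]])) stop("parse error: missing field '", f, "'")
  }
  if (!identical(m$type, "dose_grid3d")) {
    stop("parse error: field 'type' is '", m$type, "', not 'dose_grid3d'")
  }
  if (prod(m$dim) != length(p$values)) {
    stop("parse error: field 'dim' inconsistent with stored values")
  }
  dose_grid3d(array(p$values, dim = m$dim), m$origin, m$spacing, m$axes)
}

#' Write / read a 2D dose plane (portable container)
#'
#' @param plane a [dose_plane2d()].
#' @param path file path without extension.
#' @return `write_dose_plane` returns `path` invisibly; `read_dose_plane`
#'   returns the [dose_plane2d()].
#' @export
write_dose_plane <- function(plane, path) {
  stopifnot(inherits(plane, "dose_plane2d"))
  .write_portable(plane$values,
                  list(type = "dose_plane2d", dim = dim(plane$values),
                       origin = plane$origin, spacing = plane$spacing,
                       is_relative = plane$is_relative,
                       norm_dose = plane$norm_dose),
                  path)
}

#' @rdname write_dose_plane
#' @export
read_dose_plane <- function(path) {
  p <- .read_portable(path)
  m <- p$meta
  for (f in c("type", "dim", "origin", "spacing")) {
    if (is.null(m[[f]])) stop("parse error: missing field '", f, "'")
  }
  if (!identical(m$type, "dose_plane2d")) {
    stop("parse error: field 'type' is '", m$type, "', not 'dose_plane2d'")
  }
  if (prod(m$dim) != length(p$values)) {
    stop("parse error: field 'dim' inconsistent with stored values")
  }
  nd <- if (is.null(m$norm_dose)) NA_real_ else as.numeric(m$norm_dose)
  dose_plane2d(matrix(p$values, m$dim[1], m$dim[2]), m$spacing, m$origin,
               isTRUE(m$is_relative), nd)
}

#' Write / read a film scan (16-bit TIFF + JSON sidecar)
#'
#' The response image is stored as a 16-bit grayscale TIFF scaled by
#' `response_scale` (recorded in the sidecar together with pixel spacing,
#' origin and the three landmark positions). Quantization of the 16-bit
#' encoding limits the round trip to about `response_scale / 2^16`.
#'
#' @param scan a [film_scan()].
#' @param path file path without extension (`.tif` and `.json` are added).
#' @return `write_film_scan` returns `path` invisibly; `read_film_scan`
#'   returns the [film_scan()].
#' @export
write_film_scan <- function(scan, path) {
  stopifnot(inherits(scan, "film_scan"))
  v <- scan$response
  scale <- max(v, na.rm = TRUE)
  if (!is.finite(scale) || scale <= 0) scale <- 1
  img <- v / scale
  img[is.na(img)] <- 0
  tiff::writeTIFF(img, paste0(path, ".tif"), bits.per.sample = 16L)
  jsonlite::write_json(
    list(type = "film_scan", dim = dim(v), response_scale = scale,
         spacing = scan$spacing, origin = scan$origin,
         landmarks = scan$landmarks),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_film_scan
#' @export
read_film_scan <- function(path) {
  jpath <- paste0(path, ".json")
  tpath <- paste0(path, ".tif")
  if (!file.exists(jpath)) stop("missing sidecar: ", jpath)
  if (!file.exists(tpath)) stop("missing image: ", tpath)
  m <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  for (f in c("type", "dim", "response_scale", "spacing", "landmarks")) {
    if (is.null(m[[f]])) stop("parse error in ", jpath,
                              ": missing field '", f, "'")
  }
  if (!identical(m$type, "film_scan")) {
    stop("parse error: field 'type' is '", m$type, "', not 'film_scan'")
  }
  img <- tiff::readTIFF(tpath)
  if (!all(dim(img)[1:2] == m$dim)) {
    stop("parse error: field 'dim' inconsistent with TIFF image")
  }
  org <- if (is.null(m$origin)) c(0, 0) else as.numeric(m$origin)
  film_scan(img * m$response_scale, m$spacing,
            matrix(as.numeric(as.matrix(m$landmarks)), 3L, 2L), org)
}
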
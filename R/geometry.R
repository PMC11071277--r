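#' Tilt geometry for single-axis tomography
#'
#' Describes the acquisition geometry of a single-axis tilt series. The tilt
#' axis is fixed to the y-axis (second volume dimension) and the electron beam
#' travels along the z-axis (third dimension) at zero tilt. Positive tilt
#' rotates the beam from +z towards +x.
#'
#' @param angles Numeric vector of tilt angles in degrees, strictly
#'   increasing, each within \[-90, 90\].
#' @return An object of class `tilt_geometry`: a list with elements `angles`
#'   (degrees) and `n_tilts`.
#' @seealso [angles_from_params()] to build the geometry from a step and
#'   range, [read_angles()] / [write_angles()] for `.tlt` files.
#' @export
tilt_geometry <- function(angles) {
  angles <- as.numeric(angles)
  if (length(angles) < 1L || anyNA(angles) || any(!is.finite(angles))) {
    stop("tilt angles must be a non-empty finite numeric vector")
  }
  if (any(abs(angles) > 90)) {
    stop("tilt angles must lie within [-90, 90] degrees")
  }
  if (length(angles) > 1L && any(diff(angles) <= 0)) {
    stop("tilt angles must be strictly increasing")
  }
  structure(list(angles = angles, n_tilts = length(angles)),
            class = "tilt_geometry")
}

#' Build a symmetric tilt geometry from an angular step and range
#'
#' Generates the angle list \{-beta, -beta + alpha, ..., +beta\}, always
#' including 0 degrees, i.e. `2 * beta / alpha + 1` tilts. The step must
#' divide the range: no silent truncation is performed.
#'
#' @param alpha Angular step between tilts, degrees (> 0).
#' @param beta Half-range, degrees; angles span \[-beta, +beta\], 0 < beta <= 90.
#' @param tol Relative tolerance for the divisibility check.
#' @return A [tilt_geometry()].
#' @examples
#' g <- angles_from_params(2, 60)  # the standard +/-60 degree, 2 degree series
#' g$n_tilts                       # 61
#' @export
angles_from_params <- function(alpha, beta, tol = 1e-6) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.numeric(beta),
            length(beta) == 1L)
  if (alpha <= 0) stop("alpha must be positive")
  if (beta <= 0 || beta > 90) stop("beta must lie in (0, 90]")
  n_half <- beta / alpha
  if (abs(n_half - round(n_half)) > tol * max(1, n_half)) {
    stop(sprintf("angular step alpha = %g does not divide the range 2*beta = %g",
                 alpha, 2 * beta))
  }
  n_half <- round(n_half)
  tilt_geometry(alpha * seq(-n_half, n_half))
}

#' @export
print.tilt_geometry <- function(x, ...) {
  cat(sprintf("tilt_geometry: %d tilts, %g to %g degrees (y tilt axis)\n",
              x$n_tilts, min(x$angles), max(x$angles)))
  invisible(x)
}

#' A tilt series: projection image stack plus its geometry
#'
#' @param images 3D numeric array of dimension `c(x, y, l)`: `l` projection
#'   frames, each `x` by `y` (y is the tilt axis).
#' @param geometry A [tilt_geometry()] with `l` angles.
#' @return An object of class `tilt_series` with elements `images` and
#'   `geometry`.
#' @export
tilt_series <- function(images, geometry) {
  if (!is.array(images) || length(dim(images)) != 3L) {
    stop("images must be a 3D array of dimension c(x, y, l)")
  }
  if (!inherits(geometry, "tilt_geometry")) geometry <- tilt_geometry(geometry)
  if (dim(images)[3] != geometry$n_tilts) {
    stop(sprintf("frame count (%d) does not match angle count (%d)",
                 dim(images)[3], geometry$n_tilts))
  }
  if (any(!is.finite(images))) stop("tilt series contains non-finite values")
  structure(list(images = images, geometry = geometry), class = "tilt_series")
}

#' @export
print.tilt_series <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("tilt_series: %d frames of %d x %d, %g to %g degrees\n",
              d[3], d[1], d[2], min(x$geometry$angles), max(x$geometry$angles)))
  invisible(x)
}

#' Read or write tilt angles in plain-text `.tlt` format
#'
#' One ASCII decimal per line, degrees, in acquisition order (no reordering).
#'
#' @param path File path.
#' @return `read_angles()` returns a [tilt_geometry()].
#' @export
read_angles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty angle file: ", path)
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) {
    stop(sprintf("non-numeric line in angle file %s: '%s'",
                 path, lines[which(is.na(vals))[1]]))
  }
  tilt_geometry(vals)
}

#' @rdname read_angles
#' @param geometry A [tilt_geometry()] (or numeric angle vector).
#' @export
write_angles <- function(geometry, path) {
  if (!inherits(geometry, "tilt_geometry")) geometry <- tilt_geometry(geometry)
  writeLines(formatC(geometry$angles, format = "g", digits = 12), path)
  invisible(path)
}
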
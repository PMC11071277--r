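#' Sparse parallel-beam projection operator
#'
#' Builds the linear operator that maps one x-z slice of a volume to the
#' corresponding detector rows at every tilt angle. Because the tilt axis is
#' the y-axis, projection is separable in y: the same operator applies
#' independently to every y-slice, so the full projector never has to be
#' materialized. The operator is voxel-driven: each voxel's density is
#' splatted onto the detector coordinate `u = dx cos(t) - dz sin(t)` (its
#' position along the detector axis after rotating the beam about y) and
#' shared linearly between the two nearest detector pixels. This conserves
#' mass exactly for voxels whose footprint stays on the detector, and at 0
#' degrees every voxel lands on its own detector column, so the frame is the
#' exact sum over z. Rays falling off the detector are lost (vacuum framing,
#' no wrap-around). Positive tilt rotates the beam from +z towards +x.
#'
#' @param nx,nz Volume extent along x (detector width) and z (thickness).
#' @param angles Tilt angles in degrees (or a [tilt_geometry()]).
#' @return A `dgCMatrix` of dimension `(l * nx) x (nx * nz)`; row
#'   `(t - 1) * nx + d` is detector pixel `d` of tilt `t`, column
#'   `x + nx * (z - 1)` is voxel `(x, z)` (1-based).
#' @export
build_projector <- function(nx, nz, angles) {
  if (inherits(angles, "tilt_geometry")) angles <- angles$angles
  l <- length(angles)
  cx <- (nx - 1) / 2
  cz <- (nz - 1) / 2
  dx <- rep(seq(0, nx - 1) - cx, times = nz)   # voxel offsets, x fastest
  dz <- rep(seq(0, nz - 1) - cz, each = nx)
  col <- seq_len(nx * nz)
  trip_i <- vector("list", l)
  trip_j <- vector("list", l)
  trip_x <- vector("list", l)
  for (t in seq_len(l)) {
    th <- angles[t] * pi / 180
    u <- cx + dx * cos(th) - dz * sin(th)      # detector coordinate, 0-based
    d0 <- floor(u)
    fu <- u - d0
    dets <- c(d0, d0 + 1)
    ws <- c(1 - fu, fu)
    cols <- rep(col, 2L)
    keep <- dets >= 0 & dets <= nx - 1 & ws > 0
    trip_i[[t]] <- (t - 1L) * nx + dets[keep] + 1L
    trip_j[[t]] <- cols[keep]
    trip_x[[t]] <- ws[keep]
  }
  Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                       x = unlist(trip_x),
                       dims = c(l * nx, nx * nz))
}

# volume (nx, ny, nz) -> matrix (nx*nz, ny) matching the projector columns
vol_to_slices <- function(vol) {
  d <- dim(vol)
  matrix(aperm(vol, c(1, 3, 2)), d[1] * d[3], d[2])
}

slices_to_vol <- function(m, nx, ny, nz) {
  aperm(array(m, c(nx, nz, ny)), c(1, 3, 2))
}

# frames (l*nx, ny) matrix -> array (nx, ny, l)
rows_to_frames <- function(m, nx, ny, l) {
  aperm(array(as.matrix(m), c(nx, l, ny)), c(1, 3, 2))
}

frames_to_rows <- function(images) {
  d <- dim(images)  # (nx, ny, l)
  matrix(aperm(images, c(1, 3, 2)), d[1] * d[3], d[2])
}

#' Project a volume into a tilt series
#'
#' Applies the parallel-beam projection operator: each frame is the line
#' integral of the volume along the beam direction (the z-axis rotated about
#' the y tilt axis), sampled on the x-y detector grid. The operation is
#' linear in the voxel values, which is what makes the reconstruction
#' objective differentiable.
#'
#' @param vol 3D numeric array `(x, y, z)`.
#' @param geometry A [tilt_geometry()] (or numeric angles, degrees).
#' @param projector Optional precomputed [build_projector()] matrix for this
#'   `(nx, nz, angles)` combination; built on the fly if `NULL`.
#' @return A [tilt_series()].
#' @export
project <- function(vol, geometry, projector = NULL) {
  if (!inherits(geometry, "tilt_geometry")) geometry <- tilt_geometry(geometry)
  if (any(!is.finite(vol))) stop("volume contains non-finite values")
  d <- dim(vol)
  stopifnot(length(d) == 3L)
  A <- projector %||% build_projector(d[1], d[3], geometry)
  frames <- A %*% vol_to_slices(vol)
  tilt_series(rows_to_frames(frames, d[1], d[2], geometry$n_tilts), geometry)
}

#' @rdname project
#' @details `reproject()` is the identical operator under a different name:
#'   it is applied to reconstruction estimates so that logs and code
#'   distinguish data projections from model reprojections.
#' @export
reproject <- project

#' Adjoint of the projection operator (back projection)
#'
#' Smears every detector row back along its beam direction and accumulates.
#' This is the exact transpose of [build_projector()], used for weighted
#' back projection and for the gradient of the reconstruction objective.
#'
#' @param p A [tilt_series()].
#' @param nz Thickness (z extent) of the output volume.
#' @param projector Optional precomputed projector matrix.
#' @return 3D numeric array `(x, y, nz)`.
#' @export
backproject <- function(p, nz, projector = NULL) {
  stopifnot(inherits(p, "tilt_series"))
  d <- dim(p$images)
  A <- projector %||% build_projector(d[1], nz, p$geometry)
  m <- Matrix::crossprod(A, frames_to_rows(p$images))
  slices_to_vol(as.matrix(m), d[1], d[2], nz)
}
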
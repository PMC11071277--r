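#' Phantom recipe
#'
#' Parameter bundle describing an in-silico test volume: a slab-shaped grid
#' populated with binarized hollow spheres (`kind = "spheres"`) or a mixture of
#' eight geometric shape families (`kind = "shapes"`). The slab geometry (z
#' extent smaller than x and y) mimics a specimen suspended in a thin layer of
#' vitreous ice. The seed fully determines the generated volume.
#'
#' @param kind `"spheres"` or `"shapes"`.
#' @param dims Integer vector `c(x, y, z)` of the voxel grid.
#' @param n_objects Number of objects to place.
#' @param diameter_range Overall object extent, voxels: `c(min, max)`.
#' @param hollow For spheres: generate hollow shells (default `TRUE`).
#' @param shell_thickness Shell thickness of hollow spheres, voxels.
#' @param density Voxel value assigned to object interiors before any
#'   filtering (volumes are binarized: exactly \{0, density\}).
#' @param lowpass_cutoff Low-pass cutoff (fraction of Nyquist) applied by
#'   [simulate_phantom()]; `NULL` skips filtering.
#' @param families For `kind = "shapes"`: subset of
#'   `c("sphere", "ellipsoid", "pyramid", "cube", "prism", "disc", "cross4",
#'   "cross6")` to sample from.
#' @param allow_overlap Permit overlapping objects (default `FALSE`:
#'   rejection sampling with `max_attempts` tries per object).
#' @param max_attempts Placement attempts per object before failing.
#' @param seed Integer RNG seed; identical recipe + seed give bit-identical
#'   volumes.
#' @return A list of class `phantom_recipe`.
#' @export
phantom_recipe <- function(kind = c("spheres", "shapes"),
                           dims = c(1024L, 1024L, 256L),
                           n_objects = 60L,
                           diameter_range = c(16, 64),
                           hollow = TRUE,
                           shell_thickness = 2,
                           density = 1,
                           lowpass_cutoff = 0.25,
                           families = shape_families(),
                           allow_overlap = FALSE,
                           max_attempts = 1000L,
                           seed = 1L) {
  kind <- match.arg(kind)
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) stop("dims must be 3 positive integers")
  if (length(diameter_range) == 1L) diameter_range <- rep(diameter_range, 2L)
  if (diameter_range[1] < 1 || diameter_range[2] > min(dims)) {
    stop("diameter_range must lie within [1, min(dims)]")
  }
  if (n_objects < 0L) stop("n_objects must be non-negative")
  families <- match.arg(families, shape_families(), several.ok = TRUE)
  structure(list(kind = kind, dims = dims, n_objects = as.integer(n_objects),
                 diameter_range = as.numeric(diameter_range), hollow = hollow,
                 shell_thickness = shell_thickness, density = density,
                 lowpass_cutoff = lowpass_cutoff, families = families,
                 allow_overlap = allow_overlap,
                 max_attempts = as.integer(max_attempts),
                 seed = as.integer(seed)),
            class = "phantom_recipe")
}

#' Shape families available to the mixed-shapes phantom
#' @return Character vector of the eight family names.
#' @export
shape_families <- function() {
  c("sphere", "ellipsoid", "pyramid", "cube", "prism", "disc",
    "cross4", "cross6")
}

# Voxel coordinate convention used throughout: voxel centers sit at 0-based
# integer positions (0 .. n-1 along each axis, x fastest); an R array index
# (i, j, k) corresponds to position (i-1, j-1, k-1).

#' Voxels covered by an axis-aligned geometric shape
#'
#' Brute-force membership over the shape's bounding box, used both by the
#' phantom generator and as a test oracle. Box-like families (cube, prism,
#' the cross arms, disc thickness) use half-open intervals
#' `-s/2 <= x - c < s/2` per axis so an integer side `s` covers exactly `s`
#' voxel planes regardless of the (possibly fractional) center.
#'
#' @param family One of [shape_families()].
#' @param center Numeric length-3 center, 0-based voxel coordinates.
#' @param size Family-specific size, voxels: sphere = diameter; ellipsoid =
#'   three semi-axes; cube = side; prism = three sides; pyramid = c(base,
#'   height); disc = c(diameter, thickness); cross4/cross6 = c(arm length,
#'   arm width).
#' @param dims Grid dimensions `c(x, y, z)`; voxels outside are dropped.
#' @return Integer matrix (n x 3) of 1-based array indices of member voxels.
#' @export
shape_voxels <- function(family, center, size, dims) {
  family <- match.arg(family, shape_families())
  stopifnot(length(center) == 3L, length(dims) == 3L)
  half <- shape_halfwidths(family, size)
  lo <- pmax(floor(center - half), 0)
  hi <- pmin(ceiling(center + half), dims - 1)
  if (any(hi < lo)) return(matrix(integer(0), 0, 3))
  gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
  g <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  dx <- g[, 1] - center[1]; dy <- g[, 2] - center[2]; dz <- g[, 3] - center[3]
  inside <- shape_membership(family, size, dx, dy, dz)
  m <- g[inside, , drop = FALSE] + 1L
  storage.mode(m) <- "integer"
  m
}

# conservative per-axis half-extents for the bounding box
shape_halfwidths <- function(family, size) {
  switch(family,
    sphere    = rep(size[1] / 2, 3),
    ellipsoid = size[1:3],
    cube      = rep(size[1] / 2, 3),
    prism     = size[1:3] / 2,
    pyramid   = c(size[1] / 2, size[1] / 2, size[2] / 2),
    disc      = c(size[1] / 2, size[1] / 2, size[2] / 2),
    cross4    = c(size[1] / 2, size[1] / 2, size[2] / 2),
    cross6    = rep(size[1] / 2, 3)
  )
}

in_box <- function(dx, dy, dz, hx, hy, hz) {
  (dx >= -hx & dx < hx) & (dy >= -hy & dy < hy) & (dz >= -hz & dz < hz)
}

shape_membership <- function(family, size, dx, dy, dz) {
  switch(family,
    sphere = sqrt(dx^2 + dy^2 + dz^2) <= size[1] / 2,
    ellipsoid = (dx / size[1])^2 + (dy / size[2])^2 + (dz / size[3])^2 <= 1,
    cube = in_box(dx, dy, dz, size[1] / 2, size[1] / 2, size[1] / 2),
    prism = in_box(dx, dy, dz, size[1] / 2, size[2] / 2, size[3] / 2),
    pyramid = {
      # square base at the bottom, apex on top, height along z
      u <- (dz + size[2] / 2) / size[2]        # 0 at base, 1 at apex
      hw <- (size[1] / 2) * (1 - u)
      u >= 0 & u <= 1 & abs(dx) <= hw & abs(dy) <= hw
    },
    disc = sqrt(dx^2 + dy^2) <= size[1] / 2 &
      dz >= -size[2] / 2 & dz < size[2] / 2,
    cross4 = {
      w <- size[2]
      in_box(dx, dy, dz, size[1] / 2, w / 2, w / 2) |
        in_box(dx, dy, dz, w / 2, size[1] / 2, w / 2)
    },
    cross6 = {
      w <- size[2]
      in_box(dx, dy, dz, size[1] / 2, w / 2, w / 2) |
        in_box(dx, dy, dz, w / 2, size[1] / 2, w / 2) |
        in_box(dx, dy, dz, w / 2, w / 2, size[1] / 2)
    }
  )
}

#' Generate a hollow-spheres phantom
#'
#' Places `n_objects` binarized hollow spherical shells of constant density
#' with diameters drawn uniformly from `diameter_range`, centers uniform
#' within the slab such that every sphere lies fully inside the grid. A voxel
#' at position x belongs to a shell with inner/outer radii `r_in`, `r_out`
#' iff `r_in <= |x - c| < r_out`. Overlaps (center distance below the sum of
#' outer radii plus one voxel) are rejected unless `allow_overlap`.
#'
#' @param recipe A [phantom_recipe()] with `kind = "spheres"`.
#' @return 3D numeric array of dimension `recipe$dims`; background exactly 0;
#'   attribute `"objects"` holds a data frame of placed centers and radii.
#' @export
make_spheres_phantom <- function(recipe) {
  stopifnot(inherits(recipe, "phantom_recipe"))
  if (recipe$kind != "spheres") stop("recipe kind must be 'spheres'")
  dims <- recipe$dims
  vol <- array(0, dims)
  if (recipe$n_objects == 0L) {
    attr(vol, "objects") <- data.frame()
    return(vol)
  }
  dmin <- recipe$diameter_range[1]
  if (any(dims - 1 < dmin)) {
    stop("grid too small to place a sphere of the minimum diameter")
  }
  objs <- with_seed(recipe$seed, {
    placed <- vector("list", recipe$n_objects)
    for (i in seq_len(recipe$n_objects)) {
      ok <- FALSE
      for (att in seq_len(recipe$max_attempts)) {
        d <- stats::runif(1, recipe$diameter_range[1], recipe$diameter_range[2])
        r_out <- d / 2
        if (any(dims - 1 - r_out < r_out)) next
        ctr <- vapply(1:3, function(a) stats::runif(1, r_out, dims[a] - 1 - r_out),
                      numeric(1))
        if (!recipe$allow_overlap && i > 1L) {
          clash <- any(vapply(placed[seq_len(i - 1L)], function(o) {
            sqrt(sum((o$center - ctr)^2)) < o$r_out + r_out + 1
          }, logical(1)))
          if (clash) next
        }
        r_in <- if (isTRUE(recipe$hollow)) max(0, r_out - recipe$shell_thickness) else 0
        placed[[i]] <- list(center = ctr, r_in = r_in, r_out = r_out)
        ok <- TRUE
        break
      }
      if (!ok) stop(sprintf("failed to place sphere %d after %d attempts",
                            i, recipe$max_attempts))
    }
    placed
  })
  for (o in objs) {
    lo <- pmax(floor(o$center - o$r_out), 0)
    hi <- pmin(ceiling(o$center + o$r_out), dims - 1)
    gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
    g <- as.matrix(expand.grid(gx, gy, gz))
    r <- sqrt((g[, 1] - o$center[1])^2 + (g[, 2] - o$center[2])^2 +
                (g[, 3] - o$center[3])^2)
    sel <- r >= o$r_in & r < o$r_out
    vol[g[sel, , drop = FALSE] + 1L] <- recipe$density
  }
  attr(vol, "objects") <- do.call(rbind, lapply(objs, function(o) {
    data.frame(cx = o$center[1], cy = o$center[2], cz = o$center[3],
               r_in = o$r_in, r_out = o$r_out)
  }))
  vol
}

#' Generate a mixed geometric-shapes phantom
#'
#' Places a seeded mixture of the eight shape families (full spheres,
#' ellipsoids, pyramids, cubes, rectangular prisms, circular discs, and 4-
#' and 6-pointed 3D crosses, all axis-aligned), binarized to constant
#' density, non-overlapping by rejection sampling: a candidate is rejected if
#' any already-occupied voxel lies inside its 1-voxel-padded bounding box,
#' which also forbids touching shapes.
#'
#' @inheritParams make_spheres_phantom
#' @return 3D numeric array; attribute `"objects"` lists family, center and
#'   size of each placed shape.
#' @export
make_shapes_phantom <- function(recipe) {
  stopifnot(inherits(recipe, "phantom_recipe"))
  if (recipe$kind != "shapes") stop("recipe kind must be 'shapes'")
  dims <- recipe$dims
  vol <- array(0, dims)
  objs <- list()
  if (recipe$n_objects == 0L) {
    attr(vol, "objects") <- list()
    return(vol)
  }
  with_seed(recipe$seed, {
    for (i in seq_len(recipe$n_objects)) {
      ok <- FALSE
      for (att in seq_len(recipe$max_attempts)) {
        family <- sample(recipe$families, 1L)
        ext <- stats::runif(1, recipe$diameter_range[1], recipe$diameter_range[2])
        size <- sample_shape_size(family, ext)
        half <- shape_halfwidths(family, size)
        if (any(dims - 1 - half < half)) next
        ctr <- vapply(1:3, function(a) stats::runif(1, half[a], dims[a] - 1 - half[a]),
                      numeric(1))
        # occupancy check over the padded bounding box
        lo <- pmax(floor(ctr - half) - 1, 0) + 1L
        hi <- pmin(ceiling(ctr + half) + 1, dims - 1) + 1L
        if (!recipe$allow_overlap &&
            any(vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] != 0)) next
        idx <- shape_voxels(family, ctr, size, dims)
        if (nrow(idx) == 0L) next
        vol[idx] <- recipe$density
        objs[[i]] <- list(family = family, center = ctr, size = size)
        ok <- TRUE
        break
      }
      if (!ok) stop(sprintf("failed to place shape %d after %d attempts",
                            i, recipe$max_attempts))
    }
  })
  attr(vol, "objects") <- objs
  vol
}

sample_shape_size <- function(family, ext) {
  switch(family,
    sphere    = ext,
    ellipsoid = (ext / 2) * stats::runif(3, 0.5, 1),
    cube      = ext,
    prism     = ext * stats::runif(3, 0.4, 1),
    pyramid   = c(ext, ext),
    disc      = c(ext, max(2, ext / 6)),
    cross4    = c(ext, max(2, ext / 4)),
    cross6    = c(ext, max(2, ext / 4))
  )
}

#' Low-pass filter a volume in Fourier space
#'
#' Attenuates Fourier amplitudes beyond `cutoff` (a fraction of the Nyquist
#' frequency, 0.5 cycles/voxel, using the Euclidean frequency radius with
#' per-axis normalization). `rolloff = "gaussian"` applies
#' `H(f) = exp(-f^2 / (2 fc^2))` (amplitude falls to ~0.607 at the cutoff);
#' `rolloff = "hard"` zeroes everything beyond the cutoff and is idempotent.
#' As a special case, a hard cutoff of 1 passes the whole grid, including
#' corner frequencies above the axial Nyquist, and is an exact no-op. The
#' mean (DC term) is always preserved.
#'
#' @param vol 3D numeric array.
#' @param cutoff Fraction of Nyquist in (0, 1].
#' @param rolloff `"gaussian"` (default) or `"hard"`.
#' @return Filtered real volume of the same dimensions.
#' @export
lowpass_filter <- function(vol, cutoff, rolloff = c("gaussian", "hard")) {
  rolloff <- match.arg(rolloff)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop("cutoff must be a positive scalar (fraction of Nyquist)")
  }
  if (cutoff > 1) stop("cutoff must be <= 1")
  d <- dim(vol)
  stopifnot(length(d) == 3L)
  f <- frequency_radius(d)           # cycles/voxel, per-axis normalized
  fc <- cutoff * 0.5
  H <- if (rolloff == "gaussian") {
    exp(-0.5 * (f / fc)^2)
  } else if (cutoff >= 1) {
    array(1, d)
  } else {
    (f <= fc + 1e-12) * 1
  }
  out <- Re(stats::fft(stats::fft(vol) * H, inverse = TRUE)) / prod(d)
  array(out, d)
}

# Euclidean frequency radius in cycles/voxel for each Fourier-grid voxel.
frequency_radius <- function(d) {
  fx <- fft_freq_index(d[1]) / d[1]
  fy <- fft_freq_index(d[2]) / d[2]
  fz <- fft_freq_index(d[3]) / d[3]
  sqrt(outer(outer(fx^2, fy^2, "+"), fz^2, "+"))
}

#' Min-max normalize a tilt series to \[0, 1\]
#'
#' A single affine rescale applied jointly across all frames of the stack
#' (not per frame), standardizing the values presented to the network.
#'
#' @param p A [tilt_series()] or 3D array.
#' @return Same type as the input, with `min = 0` and `max = 1`.
#' @export
normalize_series <- function(p) {
  img <- if (inherits(p, "tilt_series")) p$images else p
  if (any(!is.finite(img))) stop("tilt series contains non-finite values")
  rng <- range(img)
  if (diff(rng) == 0) stop("degenerate (constant) tilt series cannot be normalized")
  out <- (img - rng[1]) / diff(rng)
  if (inherits(p, "tilt_series")) {
    p$images <- out
    p
  } else {
    out
  }
}

#' Generate, filter and describe a phantom in one call
#'
#' Runs the recipe's generator and applies its low-pass smoothing step, the
#' final processing applied to the binarized volumes.
#'
#' @param recipe A [phantom_recipe()].
#' @param rolloff Passed to [lowpass_filter()].
#' @return The processed volume (objects attribute preserved).
#' @export
simulate_phantom <- function(recipe, rolloff = "gaussian") {
  vol <- switch(recipe$kind,
                spheres = make_spheres_phantom(recipe),
                shapes = make_shapes_phantom(recipe))
  if (!is.null(recipe$lowpass_cutoff)) {
    objs <- attr(vol, "objects")
    vol <- lowpass_filter(vol, recipe$lowpass_cutoff, rolloff = rolloff)
    attr(vol, "objects") <- objs
  }
  vol
}
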
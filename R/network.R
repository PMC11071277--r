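#' Coordinate-network architecture specification
#'
#' The reconstruction represents a (sub)volume as a continuous function
#' G_theta: R^3 -> R realized by a fully-connected network with sinusoidal
#' activations and a positional encoding of the input coordinate. The
#' network's nominal capacity is accounted as `hidden_layers * width^2`
#' (hidden-to-hidden weights only); the true trainable parameter count,
#' including the input/output layers and biases, is reported separately by
#' [count_parameters()].
#'
#' @param hidden_layers Number of hidden layers (default 4).
#' @param width Features per hidden layer (default 256).
#' @param pe_frequencies Number K of positional-encoding frequency bands
#'   (default 6); the encoded input has length `3 + 6 K`.
#' @param omega0 Frequency multiplier of the sinusoidal activations
#'   (default 30).
#' @return A list of class `network_spec`.
#' @export
network_spec <- function(hidden_layers = 4L, width = 256L,
                         pe_frequencies = 6L, omega0 = 30) {
  stopifnot(hidden_layers >= 1L, width >= 1L, pe_frequencies >= 0L, omega0 > 0)
  structure(list(hidden_layers = as.integer(hidden_layers),
                 width = as.integer(width),
                 pe_frequencies = as.integer(pe_frequencies),
                 omega0 = omega0),
            class = "network_spec")
}

#' Nominal parameter count of a network specification
#'
#' The accounting convention used for the parameter-to-measurement ratio:
#' `hidden_layers * width^2`, independent of the encoding width. The default
#' network (4 x 256) counts 262,144 parameters.
#'
#' @param spec A [network_spec()].
#' @return Integer count.
#' @export
nominal_param_count <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  spec$hidden_layers * spec$width^2
}

#' Exact trainable parameter count (weights + biases of all layers)
#' @param theta A parameter set from [init_network()].
#' @return Integer count.
#' @export
count_parameters <- function(theta) {
  sum(vapply(theta$layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

#' Sinusoidal positional encoding of 3D coordinates
#'
#' Lifts each coordinate `c` in \[-1, 1\]^3 to the feature vector
#' `(c, sin(2^0 pi c), cos(2^0 pi c), ..., sin(2^(K-1) pi c),
#' cos(2^(K-1) pi c))` of length `3 + 6 K`; the raw coordinates are kept
#' alongside the encoding. `K = 0` returns the identity features.
#'
#' @param coords Numeric matrix (n x 3) of coordinates in \[-1, 1\].
#' @param K Number of frequency bands (>= 0).
#' @return Numeric matrix (n x (3 + 6 K)).
#' @export
positional_encoding <- function(coords, K) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  stopifnot(ncol(coords) == 3L)
  if (K < 0) stop("K must be non-negative")
  if (K == 0L) return(coords)
  out <- matrix(0, nrow(coords), 3 + 6 * K)
  out[, 1:3] <- coords
  for (k in 0:(K - 1L)) {
    a <- 2^k * pi * coords
    out[, 3 + 6 * k + 1:3] <- sin(a)
    out[, 3 + 6 * k + 4:6] <- cos(a)
  }
  out
}

#' Normalized coordinate grid of a voxel volume
#'
#' Maps every voxel of an `(x, y, z)` grid to a coordinate in \[-1, 1\]^3,
#' with voxel index i (1-based) along an axis of n voxels mapped to
#' `2 (i - 1) / (n - 1) - 1` (a single-voxel axis maps to 0). The index <->
#' coordinate mapping is bijective.
#'
#' @param dims Integer vector `c(x, y, z)`.
#' @param order Voxel enumeration order: `"xyz"` (x fastest, matching R's
#'   array linearization) or `"xzy"` (used internally by the subvolume
#'   fitter, whose measurement matrices are laid out as x-z slices per y).
#' @return Numeric matrix `(prod(dims) x 3)`; columns are the x, y, z
#'   coordinates regardless of enumeration order.
#' @export
coordinate_grid <- function(dims, order = c("xyz", "xzy")) {
  order <- match.arg(order)
  stopifnot(length(dims) == 3L, all(dims >= 1L))
  ax <- lapply(dims, function(n) {
    if (n == 1L) 0 else 2 * (seq_len(n) - 1) / (n - 1) - 1
  })
  g <- if (order == "xyz") {
    expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  } else {
    e <- expand.grid(x = ax[[1]], z = ax[[3]], y = ax[[2]])
    e[, c("x", "y", "z")]
  }
  unname(as.matrix(g))
}

#' Initialize coordinate-network parameters
#'
#' Draws weights with the standard sinusoidal-network scheme: first-layer
#' weights uniform in `[-1/fan_in, 1/fan_in]`; deeper sine layers uniform in
#' `[-sqrt(6/fan_in)/omega0, sqrt(6/fan_in)/omega0]` (compensating the
#' `omega0` activation gain). Biases start at zero. The linear output layer
#' starts at zero by default (`out_init = "zero"`), so the untrained network
#' is exactly the zero volume: Fourier components the tilt series never
#' measures (the missing wedge) then start from zero, like WBP's, instead of
#' from initialization noise that the data can never correct.
#' `out_init = "siren"` draws the output layer with the deep-layer bound
#' instead. The draw is fully determined by `seed`.
#'
#' @param spec A [network_spec()].
#' @param seed Integer RNG seed.
#' @param out_init `"zero"` (default) or `"siren"` output-layer
#'   initialization.
#' @return A list of class `cn_theta` with elements `layers` (each a list
#'   `W`, `b`), `spec`, `in_features`, and `seed`.
#' @export
init_network <- function(spec, seed = 1L, out_init = c("zero", "siren")) {
  out_init <- match.arg(out_init)
  stopifnot(inherits(spec, "network_spec"))
  in_features <- if (spec$pe_frequencies == 0L) 3L else 3L + 6L * spec$pe_frequencies
  sizes <- c(in_features, rep(spec$width, spec$hidden_layers), 1L)
  layers <- with_seed(seed, {
    lapply(seq_len(length(sizes) - 1L), function(i) {
      fan_in <- sizes[i]
      bound <- if (i == 1L) 1 / fan_in else sqrt(6 / fan_in) / spec$omega0
      W <- matrix(stats::runif(fan_in * sizes[i + 1L], -bound, bound),
                  fan_in, sizes[i + 1L])
      if (i == length(sizes) - 1L && out_init == "zero") W <- W * 0
      list(W = W, b = numeric(sizes[i + 1L]))
    })
  })
  structure(list(layers = layers, spec = spec, in_features = in_features,
                 seed = as.integer(seed)),
            class = "cn_theta")
}

# Forward pass on encoded features X (n x in_features).
# Returns list(out, cache) when keep_cache, else the n-vector of outputs.
# Hidden layers: a = sin(omega0 * (a W + b)); output layer linear.
cn_forward <- function(theta, X, keep_cache = FALSE) {
  w0 <- theta$spec$omega0
  nl <- length(theta$layers)
  a <- X
  cache <- if (keep_cache) vector("list", nl) else NULL
  for (i in seq_len(nl - 1L)) {
    z <- sweep_add(a %*% theta$layers[[i]]$W, theta$layers[[i]]$b)
    if (keep_cache) cache[[i]] <- list(a_in = a, z = z)
    a <- sin(w0 * z)
  }
  out <- sweep_add(a %*% theta$layers[[nl]]$W, theta$layers[[nl]]$b)
  if (keep_cache) {
    cache[[nl]] <- list(a_in = a)
    list(out = as.numeric(out), cache = cache)
  } else {
    as.numeric(out)
  }
}

sweep_add <- function(m, b) {
  if (all(b == 0)) m else m + rep(b, each = nrow(m))
}

# Backward pass: gradient of sum(dout * out) w.r.t. all weights and biases.
# dout is an n-vector. Returns a list of layer gradients (gW, gb).
cn_backward <- function(theta, cache, dout) {
  w0 <- theta$spec$omega0
  nl <- length(theta$layers)
  grads <- vector("list", nl)
  d <- matrix(dout, ncol = 1)
  grads[[nl]] <- list(gW = crossprod(cache[[nl]]$a_in, d),
                      gb = colSums(d))
  da <- d %*% t(theta$layers[[nl]]$W)
  for (i in seq(nl - 1L, 1L)) {
    dz <- da * (w0 * cos(w0 * cache[[i]]$z))
    grads[[i]] <- list(gW = crossprod(cache[[i]]$a_in, dz),
                       gb = colSums(dz))
    if (i > 1L) da <- dz %*% t(theta$layers[[i]]$W)
  }
  grads
}

#' Evaluate a coordinate network over a voxel grid
#'
#' Pure function: applies the network to every coordinate of the grid and
#' reshapes the result to `dims`. Evaluation is chunked internally so the
#' peak working set stays bounded regardless of grid size.
#'
#' @param theta Parameters from [init_network()] or a fit.
#' @param grid Coordinate matrix (n x 3), e.g. from [coordinate_grid()]
#'   (`"xyz"` order if `dims` is given).
#' @param dims Optional `(x, y, z)` to reshape the output into a volume; if
#'   `NULL` the raw vector (in grid order) is returned.
#' @param chunk_size Coordinates per evaluation chunk.
#' @return Numeric vector of length n, or a `dims` array.
#' @export
evaluate_network <- function(theta, grid, dims = NULL, chunk_size = 65536L) {
  stopifnot(inherits(theta, "cn_theta"))
  if (is.null(dim(grid))) grid <- matrix(grid, ncol = 3)
  n <- nrow(grid)
  if (!is.null(dims) && prod(dims) != n) {
    stop("grid size does not match target dims")
  }
  K <- theta$spec$pe_frequencies
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk_size)) {
    idx <- start:min(n, start + chunk_size - 1L)
    out[idx] <- cn_forward(theta, positional_encoding(grid[idx, , drop = FALSE], K))
  }
  if (is.null(dims)) out else array(out, dims)
}

#' Slab partition plan for subvolume fitting
#'
#' Divides the volume into y-axis slabs so that the ratio of nominal network
#' parameters to measurements per subvolume stays fixed: the slab width j
#' solves `nominal_params / (x * j * z) = ratio`, rounded and clamped to
#' `[1, y]`. With the default network and ratio 1/8, a 1024 x 1024 x 256
#' tomogram partitions into 128 slabs of width 8.
#'
#' @param dims Volume dimensions `c(x, y, z)`.
#' @param spec A [network_spec()].
#' @param ratio Target parameters-per-measurement ratio (default 1/8).
#' @return A list of class `partition_plan`: `slab_width` (j), `n_networks`,
#'   `ratio`, and `slabs`, a data frame of 1-based y index ranges (the last
#'   slab may be narrower).
#' @export
partition_plan <- function(dims, spec, ratio = 1 / 8) {
  stopifnot(length(dims) == 3L)
  if (any(dims <= 0)) stop("dims must be positive")
  if (ratio <= 0) stop("ratio must be positive")
  x <- dims[1]; y <- dims[2]; z <- dims[3]
  j_real <- nominal_param_count(spec) / (ratio * x * z)
  j <- max(1L, min(as.integer(y), as.integer(round(j_real))))
  starts <- as.integer(seq.int(1L, as.integer(y), by = j))
  ends <- pmin(starts + j - 1L, as.integer(y))
  structure(list(slab_width = j,
                 n_networks = length(starts),
                 ratio = ratio,
                 slabs = data.frame(start = starts, end = ends,
                                    width = ends - starts + 1L)),
            class = "partition_plan")
}

#' @export
print.partition_plan <- function(x, ...) {
  cat(sprintf("partition_plan: %d networks, slab width %d (ratio %.4g)\n",
              x$n_networks, x$slab_width, x$ratio))
  invisible(x)
}
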
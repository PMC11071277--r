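#' Training plan for subvolume fitting
#'
#' Iteration counts and learning-rate schedules for the reprojection-matching
#' optimization. The first slab is fitted from random initialization; every
#' subsequent slab is warm-started from the previous slab's fitted parameters
#' (learned initialization), which needs far fewer iterations. Learning rates
#' decay logarithmically (geometric interpolation) from the initial to the
#' final value across the iterations of a slab.
#'
#' @param iters_first Iterations for the first slab (default 2000).
#' @param iters_rest Iterations for each warm-started slab (default 400).
#' @param lr_first `c(initial, final)` learning rate for the first slab
#'   (default `c(1e-3, 1e-4)`).
#' @param lr_rest `c(initial, final)` for warm-started slabs
#'   (default `c(1e-4, 1e-5)`).
#' @param lambda Regularization strength (default 0: no regularizer).
#' @param regularizer `"none"` or `"tv"` (total variation of the estimate).
#' @param seed Integer seed for the random initialization of the first slab.
#' @return A list of class `train_plan`.
#' @export
train_plan <- function(iters_first = 2000L, iters_rest = 400L,
                       lr_first = c(1e-3, 1e-4), lr_rest = c(1e-4, 1e-5),
                       lambda = 0, regularizer = c("none", "tv"),
                       seed = 1L) {
  regularizer <- match.arg(regularizer)
  stopifnot(iters_first >= 1L, iters_rest >= 1L,
            length(lr_first) == 2L, length(lr_rest) == 2L,
            all(lr_first > 0), all(lr_rest > 0),
            lr_first[2] <= lr_first[1], lr_rest[2] <= lr_rest[1],
            lambda >= 0)
  structure(list(iters_first = as.integer(iters_first),
                 iters_rest = as.integer(iters_rest),
                 lr_first = lr_first, lr_rest = lr_rest,
                 lambda = lambda, regularizer = regularizer,
                 seed = as.integer(seed)),
            class = "train_plan")
}

# geometric (log-linear) interpolation from lr[1] to lr[2] over n iterations
lr_schedule <- function(lr, n) {
  if (n == 1L) return(lr[1])
  lr[1] * (lr[2] / lr[1])^((seq_len(n) - 1) / (n - 1))
}

# coordinate grid of one y-slab in the projector's x-z slice layout
# (x fastest, then z, then y), with explicit normalized y coordinates
slab_grid <- function(nx, nz, y_coords) {
  ax <- function(n) if (n == 1L) 0 else 2 * (seq_len(n) - 1) / (n - 1) - 1
  e <- expand.grid(x = ax(nx), z = ax(nz), y = y_coords)
  unname(as.matrix(e[, c("x", "y", "z")]))
}

default_y_coords <- function(j) {
  if (j == 1L) 0 else 2 * (seq_len(j) - 1) / (j - 1) - 1
}

# total variation (mean absolute forward difference over the three axes)
# and its subgradient with respect to the volume
tv_value_grad <- function(v) {
  d <- dim(v)
  n <- prod(d)
  val <- 0
  g <- array(0, d)
  for (ax in 1:3) {
    idx_hi <- slice_index(d, ax, 2:d[ax])
    idx_lo <- slice_index(d, ax, 1:(d[ax] - 1L))
    diffs <- v[idx_hi] - v[idx_lo]
    val <- val + sum(abs(diffs))
    s <- sign(diffs)
    g[idx_hi] <- g[idx_hi] + s
    g[idx_lo] <- g[idx_lo] - s
  }
  list(value = val / n, grad = g / n)
}

slice_index <- function(d, ax, take) {
  args <- list(1:d[1], 1:d[2], 1:d[3])
  args[[ax]] <- take
  as.matrix(do.call(expand.grid, args))
}

#' Reconstruction objective for one subvolume
#'
#' The reprojection-matching loss: the mean squared error between the
#' measured projections of the subvolume and the projections of the network
#' output, plus an optional regularizer on the estimate,
#' `MSE(p_sub, P G_theta(C)) + lambda * R(G_theta(C))`. With `lambda = 0`
#' the second term is dropped exactly.
#'
#' @param theta Network parameters ([init_network()]).
#' @param p_sub A [tilt_series()] whose frames are `nx` by `j` (a y-slab of
#'   the full series).
#' @param nz Thickness of the subvolume being estimated.
#' @param lambda Regularization strength.
#' @param regularizer `"none"` or `"tv"`.
#' @param projector Optional precomputed [build_projector()] matrix.
#' @return Scalar loss.
#' @export
objective <- function(theta, p_sub, nz, lambda = 0,
                      regularizer = c("none", "tv"), projector = NULL,
                      y_coords = NULL) {
  regularizer <- match.arg(regularizer)
  stopifnot(inherits(p_sub, "tilt_series"))
  d <- dim(p_sub$images)
  A <- projector %||% build_projector(d[1], nz, p_sub$geometry)
  grid <- slab_grid(d[1], nz, y_coords %||% default_y_coords(d[2]))
  v <- evaluate_network(theta, grid)           # xzy order = projector layout
  vmat <- matrix(v, d[1] * nz, d[2])
  resid <- as.matrix(A %*% vmat) - frames_to_rows(p_sub$images)
  loss <- mean(resid^2)
  if (lambda > 0 && regularizer == "tv") {
    varr <- aperm(array(v, c(d[1], nz, d[2])), c(1, 3, 2))
    loss <- loss + lambda * tv_value_grad(varr)$value
  }
  loss
}

#' Fit a coordinate network to one subvolume's projections
#'
#' Gradient-based minimization of [objective()] with Adam and the plan's
#' logarithmically decayed learning rate. Every iteration evaluates the
#' network on the full subvolume coordinate grid, reprojects through the
#' sparse projector, and backpropagates the reprojection residual. The
#' best-loss iterate (not the last) is returned. With identical inputs and
#' seed the loss trace is identical run to run.
#'
#' @param p_sub A [tilt_series()] slab (frames `nx` by `j`).
#' @param nz Subvolume thickness.
#' @param spec A [network_spec()].
#' @param plan A [train_plan()].
#' @param theta_init `NULL` for random initialization (first slab; uses
#'   `plan$iters_first` / `plan$lr_first`), or the previous slab's fitted
#'   parameters (uses `plan$iters_rest` / `plan$lr_rest`).
#' @param projector Optional precomputed projector matrix.
#' @param verbose Print the loss every 100 iterations.
#' @param engine `"auto"` (default), `"cpp"` or `"r"`. The compiled engine
#'   runs the unregularized objective; the R engine is the reference
#'   implementation and handles `lambda > 0`. `"auto"` picks the compiled
#'   path whenever `plan$lambda == 0`.
#' @param y_coords Normalized y coordinates of the slab's voxel planes
#'   (length `j`). [cn_reconstruct()] passes each slab's window of the
#'   whole-volume \[-1, 1\] axis so that a warm-started network continues
#'   the previous slab's function across the boundary; standalone fits
#'   default to a \[-1, 1\] span of the slab itself.
#' @return A list of class `fit_result`: `theta` (best iterate),
#'   `loss_trace`, `final_loss` (best loss), `volume` (the best-iterate
#'   subvolume estimate, `nx` x `j` x `nz`), and `warm_start`.
#' @export
fit_subvolume <- function(p_sub, nz, spec, plan, theta_init = NULL,
                          projector = NULL, verbose = FALSE,
                          engine = c("auto", "cpp", "r"), y_coords = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(p_sub, "tilt_series"), inherits(spec, "network_spec"),
            inherits(plan, "train_plan"))
  if (engine == "auto") engine <- if (plan$lambda == 0) "cpp" else "r"
  if (engine == "cpp" && plan$lambda > 0) {
    stop("the compiled engine only implements the unregularized objective")
  }
  d <- dim(p_sub$images)
  nx <- d[1]; j <- d[2]
  A <- projector %||% build_projector(nx, nz, p_sub$geometry)
  warm <- !is.null(theta_init)
  iters <- if (warm) plan$iters_rest else plan$iters_first
  lrs <- lr_schedule(if (warm) plan$lr_rest else plan$lr_first, iters)
  theta <- if (warm) theta_init else init_network(spec, seed = plan$seed)
  if (is.null(y_coords)) y_coords <- default_y_coords(j)
  stopifnot(length(y_coords) == j)
  grid <- slab_grid(nx, nz, y_coords)
  X <- positional_encoding(grid, spec$pe_frequencies)
  pmat <- frames_to_rows(p_sub$images)
  n_meas <- length(pmat)
  n_vox <- nrow(X)

  if (engine == "cpp") {
    res <- cn_train_cpp(theta$layers, spec$omega0, X,
                        methods::as(A, "CsparseMatrix"), pmat, lrs,
                        0.9, 0.999, 1e-8)
    if (!is.null(res$diverged_at)) {
      stop(sprintf("divergence at iteration %d (loss not finite); trace: %s",
                   res$diverged_at,
                   paste(utils::tail(signif(res$loss_trace, 4), 5),
                         collapse = " ")))
    }
    theta$layers <- lapply(res$layers, function(l) {
      list(W = l$W, b = as.numeric(l$b))
    })
    vol_best <- evaluate_network(theta, grid)
    return(structure(list(theta = theta,
                          loss_trace = as.numeric(res$loss_trace),
                          final_loss = res$best_loss,
                          volume = aperm(array(vol_best, c(nx, nz, j)),
                                         c(1, 3, 2)),
                          warm_start = warm,
                          n_voxels = n_vox),
                     class = "fit_result"))
  }

  opt <- adam_state(theta)
  best_loss <- Inf
  best_theta <- theta
  loss_trace <- numeric(iters)
  for (it in seq_len(iters)) {
    fwd <- cn_forward(theta, X, keep_cache = TRUE)
    vmat <- matrix(fwd$out, nx * nz, j)
    resid <- as.matrix(A %*% vmat) - pmat
    loss <- sum(resid^2) / n_meas
    dv <- as.matrix(Matrix::crossprod(A, resid)) * (2 / n_meas)
    if (plan$lambda > 0 && plan$regularizer == "tv") {
      varr <- aperm(array(fwd$out, c(nx, nz, j)), c(1, 3, 2))
      tv <- tv_value_grad(varr)
      loss <- loss + plan$lambda * tv$value
      dv <- dv + plan$lambda * matrix(aperm(tv$grad, c(1, 3, 2)), nx * nz, j)
    }
    if (!is.finite(loss)) {
      stop(sprintf("divergence at iteration %d (loss not finite); trace: %s",
                   it, paste(utils::tail(signif(loss_trace[seq_len(it - 1)], 4), 5),
                             collapse = " ")))
    }
    loss_trace[it] <- loss
    if (loss < best_loss) {
      best_loss <- loss
      best_theta <- theta
    }
    grads <- cn_backward(theta, fwd$cache, as.numeric(dv))
    upd <- adam_step(opt, theta, grads, lrs[it])
    theta <- upd$theta
    opt <- upd$state
    if (verbose && (it %% 100L == 0L || it == 1L)) {
      message(sprintf("  iter %4d/%d  loss %.6g  lr %.3g", it, iters, loss, lrs[it]))
    }
  }
  vol_best <- evaluate_network(best_theta, grid)
  structure(list(theta = best_theta,
                 loss_trace = loss_trace,
                 final_loss = best_loss,
                 volume = aperm(array(vol_best, c(nx, nz, j)), c(1, 3, 2)),
                 warm_start = warm,
                 n_voxels = n_vox),
            class = "fit_result")
}

# Adam with standard moments (beta1 = .9, beta2 = .999, eps = 1e-8)
adam_state <- function(theta) {
  zeros <- lapply(theta$layers, function(l) {
    list(mW = array(0, dim(l$W)), vW = array(0, dim(l$W)),
         mb = numeric(length(l$b)), vb = numeric(length(l$b)))
  })
  list(t = 0L, m = zeros)
}

adam_step <- function(state, theta, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(theta$layers)) {
    s <- state$m[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * grads[[i]]$gW
    s$vW <- beta2 * s$vW + (1 - beta2) * grads[[i]]$gW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * grads[[i]]$gb
    s$vb <- beta2 * s$vb + (1 - beta2) * grads[[i]]$gb^2
    theta$layers[[i]]$W <- theta$layers[[i]]$W -
      lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    theta$layers[[i]]$b <- theta$layers[[i]]$b -
      lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state$m[[i]] <- s
  }
  list(theta = theta, state = state)
}

#' Reconstruct a tomogram by chained subvolume fitting
#'
#' Splits the tilt series into y-axis slabs per the partition plan, fits a
#' coordinate network to the first slab from random initialization, then
#' warm-starts each subsequent slab from the previous slab's fitted
#' parameters (learned initialization), and concatenates the slab estimates
#' along y with no blending.
#'
#' @param p A [tilt_series()] (typically [normalize_series()]d).
#' @param nz Thickness of the reconstructed volume.
#' @param spec A [network_spec()].
#' @param plan A [train_plan()].
#' @param ratio Parameters-per-measurement ratio for [partition_plan()].
#' @param slab_width Override the plan's slab width (voxels along y).
#' @param single_network If `TRUE`, fit the whole volume with one network
#'   (no slab partition).
#' @param verbose Log per-slab progress to stderr.
#' @return The reconstructed volume `(x, y, nz)` with attribute
#'   `"fit_summary"`: a data frame of per-slab width, iterations and final
#'   loss, plus attribute `"loss_traces"` (list of per-slab traces).
#' @export
cn_reconstruct <- function(p, nz, spec = network_spec(), plan = train_plan(),
                           ratio = 1 / 8, slab_width = NULL,
                           single_network = FALSE, verbose = TRUE) {
  stopifnot(inherits(p, "tilt_series"))
  d <- dim(p$images)
  nx <- d[1]; ny <- d[2]
  dims <- c(nx, ny, nz)
  part <- if (single_network) {
    list(slab_width = ny, n_networks = 1L,
         slabs = data.frame(start = 1L, end = ny, width = ny))
  } else if (!is.null(slab_width)) {
    starts <- seq(1L, ny, by = slab_width)
    ends <- pmin(starts + slab_width - 1L, ny)
    list(slab_width = as.integer(slab_width), n_networks = length(starts),
         slabs = data.frame(start = starts, end = ends,
                            width = ends - starts + 1L))
  } else {
    partition_plan(dims, spec, ratio)
  }
  A <- build_projector(nx, nz, p$geometry)
  out <- array(0, dims)
  theta_prev <- NULL
  summaries <- vector("list", part$n_networks)
  traces <- vector("list", part$n_networks)
  y_axis <- default_y_coords(ny)
  for (s in seq_len(part$n_networks)) {
    sl <- part$slabs[s, ]
    p_sub <- tilt_series(p$images[, sl$start:sl$end, , drop = FALSE],
                         p$geometry)
    fit <- tryCatch(
      fit_subvolume(p_sub, nz, spec, plan, theta_init = theta_prev,
                    projector = A, verbose = FALSE,
                    y_coords = y_axis[sl$start:sl$end]),
      error = function(e) stop(sprintf("slab %d (y %d-%d): %s",
                                       s, sl$start, sl$end, conditionMessage(e)))
    )
    out[, sl$start:sl$end, ] <- fit$volume
    theta_prev <- fit$theta
    summaries[[s]] <- data.frame(slab = s, start = sl$start, end = sl$end,
                                 width = sl$width,
                                 iters = length(fit$loss_trace),
                                 final_loss = fit$final_loss,
                                 warm_start = fit$warm_start)
    traces[[s]] <- fit$loss_trace
    if (verbose) {
      message(sprintf("slab %d/%d (y %d-%d): %d iters, final loss %.6g%s",
                      s, part$n_networks, sl$start, sl$end,
                      length(fit$loss_trace), fit$final_loss,
                      if (fit$warm_start) " (warm start)" else ""))
    }
  }
  attr(out, "fit_summary") <- do.call(rbind, summaries)
  attr(out, "loss_traces") <- traces
  out
}

#' Weighted back-projection (WBP) reconstruction
#'
#' The classical baseline: each frame is optionally ramp-filtered along the
#' x (detector) axis in Fourier space, then smeared back along its beam
#' direction and accumulated via the exact adjoint of the projector, scaled
#' by the angular spacing in radians. Linear in the input series. No
#' attempt is made to replicate any particular software package's filter
#' apodization.
#'
#' @param p A [tilt_series()].
#' @param nz Output volume thickness.
#' @param filter `"ramp"` (Ram-Lak, default) or `"none"`.
#' @param projector Optional precomputed projector matrix.
#' @return 3D numeric array `(x, y, nz)`.
#' @export
wbp_reconstruct <- function(p, nz, filter = c("ramp", "none"),
                            projector = NULL) {
  filter <- match.arg(filter)
  stopifnot(inherits(p, "tilt_series"))
  d <- dim(p$images)
  imgs <- p$images
  if (filter == "ramp") {
    ramp <- abs(fft_freq_index(d[1])) / d[1]  # |f| in cycles/pixel
    for (t in seq_len(d[3])) {
      fr <- imgs[, , t]
      imgs[, , t] <- Re(stats::mvfft(stats::mvfft(fr) * ramp,
                                     inverse = TRUE)) / d[1]
    }
  }
  ang <- p$geometry$angles * pi / 180
  dtheta <- if (length(ang) > 1L) mean(diff(ang)) else pi
  ps <- tilt_series(imgs, p$geometry)
  backproject(ps, nz, projector = projector) * dtheta
}
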
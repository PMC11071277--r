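make_zero_theta <- function(spec) {
  th <- init_network(spec, seed = 1)
  th$layers <- lapply(th$layers, function(l) {
    list(W = l$W * 0, b = l$b * 0)
  })
  th
}

test_that("the objective is zero for an exact fit and drops the null regularizer", {
  spec <- network_spec(hidden_layers = 2, width = 8, pe_frequencies = 1)
  theta0 <- make_zero_theta(spec)
  g <- tilt_geometry(c(-30, 0, 30))
  p0 <- tilt_series(array(0, c(8, 4, 3)), g)
  expect_identical(objective(theta0, p0, nz = 8), 0)
  # a constant (here zero) estimate has zero total variation
  expect_identical(objective(theta0, p0, nz = 8, lambda = 0.5,
                             regularizer = "tv"),
                   objective(theta0, p0, nz = 8))
})

test_that("the objective equals an independently composed project-evaluate residual", {
  spec <- network_spec(hidden_layers = 2, width = 8, pe_frequencies = 1)
  theta <- init_network(spec, seed = 17)
  g <- tilt_geometry(c(-25, 0, 40))
  set.seed(18)
  p_sub <- tilt_series(array(rnorm(8 * 8 * 3), c(8, 8, 3)), g)
  # hand-composed: evaluate the network as a volume, push it through the
  # projector, take the mean squared residual
  vol <- evaluate_network(theta, coordinate_grid(c(8, 8, 8)), dims = c(8, 8, 8))
  p_hat <- project(vol, g)
  expected <- mean((p_sub$images - p_hat$images)^2)
  expect_equal(objective(theta, p_sub, nz = 8), expected, tolerance = 1e-10)
})

test_that("backpropagated gradients match finite differences", {
  spec <- network_spec(hidden_layers = 2, width = 6, pe_frequencies = 1)
  theta <- init_network(spec, seed = 4)
  g <- tilt_geometry(c(-20, 20))
  set.seed(5)
  p_sub <- tilt_series(array(rnorm(6 * 2 * 2), c(6, 2, 2)), g)
  nz <- 6
  A <- build_projector(6, nz, g)
  grid <- coordinate_grid(c(6, 2, nz), order = "xzy")
  X <- positional_encoding(grid, spec$pe_frequencies)
  pmat <- cntomo:::frames_to_rows(p_sub$images)
  fwd <- cntomo:::cn_forward(theta, X, keep_cache = TRUE)
  resid <- as.matrix(A %*% matrix(fwd$out, 6 * nz, 2)) - pmat
  dv <- as.numeric(Matrix::crossprod(A, resid)) * (2 / length(pmat))
  grads <- cntomo:::cn_backward(theta, fwd$cache, dv)
  eps <- 1e-6
  for (li in seq_along(theta$layers)) {
    for (k in c(1L, length(theta$layers[[li]]$W))) {
      th_p <- theta; th_p$layers[[li]]$W[k] <- th_p$layers[[li]]$W[k] + eps
      th_m <- theta; th_m$layers[[li]]$W[k] <- th_m$layers[[li]]$W[k] - eps
      num <- (objective(th_p, p_sub, nz, projector = A) -
                objective(th_m, p_sub, nz, projector = A)) / (2 * eps)
      expect_equal(grads[[li]]$gW[k], num, tolerance = 1e-4)
    }
  }
})

test_that("compiled and reference training engines agree", {
  spec <- network_spec(hidden_layers = 2, width = 8, pe_frequencies = 2)
  plan <- train_plan(iters_first = 6, iters_rest = 3, seed = 2)
  g <- tilt_geometry(c(-30, 0, 30))
  vol <- smooth_sphere_volume(16)[, 1:4, ]
  p_sub <- project(vol, g)
  f_r <- fit_subvolume(p_sub, 16, spec, plan, engine = "r")
  f_c <- fit_subvolume(p_sub, 16, spec, plan, engine = "cpp")
  expect_equal(f_r$loss_trace, f_c$loss_trace, tolerance = 1e-12)
  expect_equal(f_r$final_loss, f_c$final_loss, tolerance = 1e-12)
})

test_that("fitting is deterministic and improves monotonically in best loss", {
  spec <- network_spec(hidden_layers = 2, width = 12, pe_frequencies = 3)
  plan <- train_plan(iters_first = 40, iters_rest = 10, seed = 3)
  g <- angles_from_params(20, 60)
  vol <- smooth_sphere_volume(16)[, 1:4, ]
  p_sub <- normalize_series(project(vol, g))
  f1 <- fit_subvolume(p_sub, 16, spec, plan)
  f2 <- fit_subvolume(p_sub, 16, spec, plan)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(length(f1$loss_trace), 40L)
  # best-so-far loss never increases, and the returned loss is the minimum
  expect_true(all(diff(cummin(f1$loss_trace)) <= 0))
  expect_equal(f1$final_loss, min(f1$loss_trace))
  expect_lt(f1$final_loss, f1$loss_trace[1])
})

test_that("a warm start dominates a random start on the same data", {
  spec <- network_spec(hidden_layers = 2, width = 12, pe_frequencies = 3)
  g <- angles_from_params(20, 60)
  vol <- smooth_sphere_volume(16)[, 1:4, ]
  p_sub <- normalize_series(project(vol, g))
  fitted <- fit_subvolume(p_sub, 16, spec,
                          train_plan(iters_first = 60, iters_rest = 10, seed = 3))
  one <- train_plan(iters_first = 1, iters_rest = 1, seed = 3)
  warm <- fit_subvolume(p_sub, 16, spec, one, theta_init = fitted$theta)
  cold <- fit_subvolume(p_sub, 16, spec, one)
  expect_lte(warm$loss_trace[1], cold$loss_trace[1])
})

test_that("subvolume fitting reaches a small reprojection residual", {
  spec <- network_spec(hidden_layers = 3, width = 16, pe_frequencies = 4)
  plan <- train_plan(iters_first = 300, iters_rest = 50, seed = 6)
  g <- angles_from_params(15, 60)
  vol <- array(0.5, c(16, 4, 16))  # constant-density slab
  p_sub <- project(vol, g)
  fit <- fit_subvolume(p_sub, 16, spec, plan)
  p_hat <- reproject(fit$volume, g)
  rel <- sum((p_sub$images - p_hat$images)^2) / sum(p_sub$images^2)
  expect_lt(rel, 0.05)
})

test_that("single-slab reconstruction reduces to one subvolume fit", {
  spec <- network_spec(hidden_layers = 2, width = 8, pe_frequencies = 2)
  plan <- train_plan(iters_first = 20, iters_rest = 5, seed = 9)
  g <- angles_from_params(30, 60)
  vol <- smooth_sphere_volume(16)
  p <- normalize_series(project(vol, g))
  v_rec <- cn_reconstruct(p, 16, spec, plan, single_network = TRUE,
                          verbose = FALSE)
  fit <- fit_subvolume(p, 16, spec, plan)
  expect_equal(unclass(v_rec)[, , ], fit$volume, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(attr(v_rec, "fit_summary")$slab, 1L)
})

test_that("slab errors are reported with their slab index", {
  spec <- network_spec(hidden_layers = 2, width = 8, pe_frequencies = 2)
  plan <- train_plan(iters_first = 2, iters_rest = 2, lr_first = c(1e300, 1e300),
                     seed = 1)
  g <- angles_from_params(30, 60)
  p <- normalize_series(project(smooth_sphere_volume(16), g))
  expect_error(cn_reconstruct(p, 16, spec, plan, slab_width = 8,
                              verbose = FALSE),
               "slab 1")
})

test_that("WBP back-projects a single untilted frame as a constant z-smear", {
  expect_true(all(wbp_reconstruct(
    tilt_series(array(0, c(8, 6, 3)), tilt_geometry(c(-30, 0, 30))), 8) == 0))
  set.seed(20)
  frame <- matrix(runif(8 * 6), 8, 6)
  p <- tilt_series(array(frame, c(8, 6, 1)), tilt_geometry(0))
  v <- wbp_reconstruct(p, nz = 5, filter = "none")
  for (z in 1:5) {
    expect_equal(v[, , z], frame * pi, tolerance = 1e-12)
  }
})

test_that("restricting the angular range degrades WBP fidelity", {
  vol <- smooth_sphere_volume(32)
  full <- normalize_series(project(vol, angles_from_params(5, 90)))
  limited <- normalize_series(project(vol, angles_from_params(5, 60)))
  w_full <- affine_match(wbp_reconstruct(full, 32), vol)
  w_lim <- affine_match(wbp_reconstruct(limited, 32), vol)
  expect_gt(psnr(w_full, vol), psnr(w_lim, vol))
})
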
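test_that("PSNR matches its closed form and sentinels", {
  v_star <- array(c(0, 1), c(2, 1, 1))
  v_hat <- array(c(0, 0.5), c(2, 1, 1))
  expect_equal(psnr(v_hat, v_star, Im = 1), 10 * log10(8), tolerance = 1e-12)
  expect_identical(psnr(v_star, v_star), Inf)
  expect_error(psnr(array(0, c(2, 2, 2)), array(0, c(2, 2, 3))), "dimensions")
  expect_error(psnr(v_hat, v_star, Im = 0), "positive")
})

test_that("affine registration recovers scale and offset", {
  set.seed(30)
  ref <- array(rnorm(6^3), c(6, 6, 6))
  v <- 0.25 * ref + 3
  m <- affine_match(v, ref)
  expect_equal(attr(m, "a"), 4, tolerance = 1e-10)
  expect_equal(attr(m, "b"), -12, tolerance = 1e-10)
  expect_equal(as.numeric(m), as.numeric(ref), tolerance = 1e-8)
})

test_that("SSIM matches a literal sliding-window implementation", {
  set.seed(31)
  n <- 8
  v1 <- array(runif(n^3), c(n, n, n))
  v2 <- v1 + 0.1 * array(rnorm(n^3), c(n, n, n))
  w <- 7L; h <- 3L; sigma <- 1.5; L <- 1
  k1 <- gaussian_oracle_kernel(w, sigma)
  ker <- outer(outer(k1, k1), k1)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  vals <- c()
  for (i in (h + 1):(n - h)) for (j in (h + 1):(n - h)) for (l in (h + 1):(n - h)) {
    w1 <- v1[(i - h):(i + h), (j - h):(j + h), (l - h):(l + h)]
    w2 <- v2[(i - h):(i + h), (j - h):(j + h), (l - h):(l + h)]
    mu1 <- sum(ker * w1); mu2 <- sum(ker * w2)
    s11 <- sum(ker * w1^2) - mu1^2
    s22 <- sum(ker * w2^2) - mu2^2
    s12 <- sum(ker * w1 * w2) - mu1 * mu2
    vals <- c(vals, ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
                ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)))
  }
  expect_equal(ssim_volume(v1, v2, Im = 1, window = 7), mean(vals),
               tolerance = 1e-10)
})

test_that("SSIM is 1 for identical volumes and negative for anti-correlation", {
  v <- smooth_sphere_volume(16)
  expect_equal(ssim_volume(v, v), 1, tolerance = 1e-12)
  # anti-correlation flips the sign for volumes with (locally) zero mean:
  # the luminance term stays positive while the structure term goes to -1
  set.seed(77)
  z <- array(rnorm(16^3, 0, 0.05), c(16, 16, 16))
  expect_lt(ssim_volume(-z, z), 0)
  # window clips to fit small volumes
  small <- v[1:4, 1:4, 1:4]
  expect_equal(ssim_volume(small, small), 1, tolerance = 1e-12)
  expect_error(ssim_volume(array(0, c(4, 4, 4)), array(0, c(4, 4, 3))),
               "dimensions")
})

test_that("VIF is 1 at identity, below 1 under blur, above 1 under contrast gain", {
  v <- smooth_sphere_volume(32)
  expect_equal(vif_volume(v, v), 1, tolerance = 1e-6)
  blurred <- lowpass_filter(v, 0.1)
  expect_lt(vif_volume(blurred, v), 1)
  expect_gt(vif_volume(blurred, v), 0)
  expect_gte(vif_volume(1.5 * v, v), 1)
  expect_error(vif_volume(v, array(2, dim(v))), "degenerate")
})

test_that("FSC matches a brute-force per-voxel shell loop", {
  set.seed(32)
  v1 <- array(rnorm(16^3), c(16, 16, 16))
  v2 <- array(rnorm(16^3), c(16, 16, 16))
  ref <- brute_force_fsc(v1, v2)
  out <- fsc(v1, v2)
  expect_identical(out$radius, as.integer(ref$radius))
  expect_identical(out$n_voxels, as.integer(ref$n_voxels))
  expect_lt(max(abs(out$correlation - ref$correlation)), 1e-10)
})

test_that("FSC is symmetric, scale-invariant and signed", {
  v <- smooth_sphere_volume(16)
  set.seed(33)
  u <- v + 0.2 * array(rnorm(16^3), c(16, 16, 16))
  expect_equal(fsc(v, u)$correlation, fsc(u, v)$correlation, tolerance = 1e-12)
  expect_equal(fsc(2.5 * v, 0.3 * u)$correlation, fsc(v, u)$correlation,
               tolerance = 1e-10)
  expect_true(all(abs(fsc(v, v)$correlation - 1) < 1e-12))
  expect_true(all(abs(fsc(v, -v)$correlation + 1) < 1e-12))
  expect_true(all(fsc(v, u)$correlation >= -1 & fsc(v, u)$correlation <= 1))
})

test_that("directional masks partition Fourier space around the wedge", {
  dims <- c(64, 64, 64)
  m60 <- directional_masks(angles_from_params(2, 60), dims)
  # every non-DC voxel is labeled exactly once
  expect_identical(sum(is.na(m60$labels)), 1L)
  expect_true(all(m60$labels[-1] %in% c(1L, 2L)))
  # wedge fraction at high-radius shells ~ (90 - beta) / 90
  si <- cntomo:::shell_index(dims)
  high <- si$shell >= 24 & si$shell <= si$nyquist
  frac <- mean(m60$labels[high] == 2L, na.rm = TRUE)
  expect_lt(abs(frac - (90 - 60) / 90), 0.03)
  # full angular coverage leaves (almost) nothing missing
  m90 <- directional_masks(angles_from_params(1, 90), dims)
  expect_lt(mean(m90$labels == 2L, na.rm = TRUE), 0.02)
})

test_that("widening the angular range never shrinks the present region", {
  dims <- c(32, 32, 32)
  m40 <- directional_masks(angles_from_params(10, 40), dims)
  m60 <- directional_masks(angles_from_params(10, 60), dims)
  p40 <- which(m40$labels == 1L)
  p60 <- which(m60$labels == 1L)
  expect_true(all(p40 %in% p60))
  expect_gt(length(p60), length(p40))
})

test_that("present and missing FSC recombine to the full-volume curve", {
  set.seed(34)
  v1 <- array(rnorm(16^3), c(16, 16, 16))
  v2 <- array(rnorm(16^3), c(16, 16, 16))
  mask <- directional_masks(angles_from_params(10, 60), dim(v1))
  full <- fsc(v1, v2)
  pre <- masked_fsc(v1, v2, mask, "present", min_voxels = 0)
  mis <- masked_fsc(v1, v2, mask, "missing", min_voxels = 0)
  for (r in full$radius) {
    gp <- function(curve, col) {
      i <- match(r, curve$radius)
      if (is.na(i)) 0 else curve[[col]][i]
    }
    recomb <- (gp(pre, "num") + gp(mis, "num")) /
      sqrt((gp(pre, "den1") + gp(mis, "den1")) *
             (gp(pre, "den2") + gp(mis, "den2")))
    expect_lt(abs(recomb - full$correlation[match(r, full$radius)]), 1e-10)
  }
  # self-correlation is 1 on every retained shell of the missing region
  self <- masked_fsc(v1, v1, mask, "missing")
  expect_true(all(abs(self$correlation - 1) < 1e-12))
  expect_true(all(self$n_voxels >= 10))
})

test_that("WBP leaves the missing wedge uninformative at higher frequencies", {
  vol <- smooth_sphere_volume(32)
  g <- angles_from_params(3, 60)
  v_wbp <- wbp_reconstruct(normalize_series(project(vol, g)), 32)
  mask <- directional_masks(g, dim(vol))
  mis <- masked_fsc(v_wbp, vol, mask, "missing")
  upper <- mis$correlation[mis$radius > max(mis$radius) / 2]
  expect_lt(mean(abs(upper)), 0.3)
})

test_that("metrics reports bundle consistent curves and print", {
  vol <- smooth_sphere_volume(16)
  set.seed(35)
  noisy <- vol + 0.05 * array(rnorm(16^3), dim(vol))
  g <- angles_from_params(20, 60)
  rep <- metrics_report(noisy, vol, geometry = g)
  expect_s3_class(rep, "metrics_report")
  expect_true(is.finite(rep$psnr) && rep$ssim <= 1 && rep$vif >= 0)
  expect_output(print(rep), "PSNR")
  tf <- tempfile(fileext = ".tsv")
  write_fsc_table(rep, tf)
  tab <- read.delim(tf)
  expect_identical(names(tab), c("radius", "full", "present", "missing"))
  expect_identical(tab$radius, rep$fsc_full$radius)
})
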
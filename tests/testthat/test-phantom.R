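test_that("sphere phantoms are seed-deterministic and binarized", {
  rec <- phantom_recipe("spheres", dims = c(48, 48, 24), n_objects = 3,
                        diameter_range = c(6, 12), seed = 9)
  v1 <- make_spheres_phantom(rec)
  v2 <- make_spheres_phantom(rec)
  expect_identical(v1, v2)
  expect_setequal(unique(as.numeric(v1)), c(0, 1))
  # density propagates to the binarized value
  rec$density <- 2.5
  expect_setequal(unique(as.numeric(make_spheres_phantom(rec))), c(0, 2.5))
})

test_that("an empty recipe yields an all-zero volume", {
  rec <- phantom_recipe("spheres", dims = c(64, 64, 16), n_objects = 0,
                        diameter_range = c(4, 8))
  expect_true(all(make_spheres_phantom(rec) == 0))
})

test_that("hollow shell voxel count matches a brute-force distance test", {
  rec <- phantom_recipe("spheres", dims = c(32, 32, 32), n_objects = 1,
                        diameter_range = c(10, 10), shell_thickness = 2,
                        seed = 7)
  v <- make_spheres_phantom(rec)
  o <- attr(v, "objects")
  # independent per-voxel classification over the whole grid
  g <- as.matrix(expand.grid(x = 0:31, y = 0:31, z = 0:31))
  r <- sqrt((g[, 1] - o$cx)^2 + (g[, 2] - o$cy)^2 + (g[, 3] - o$cz)^2)
  expect_identical(sum(v != 0), sum(r >= o$r_in & r < o$r_out))
  # and the same voxels, not just the same count
  expect_identical(which(v != 0), which(array(r >= o$r_in & r < o$r_out, dim(v))))
})

test_that("impossible placements raise an error", {
  expect_error(
    make_spheres_phantom(phantom_recipe("spheres", dims = c(8, 8, 8),
                                        n_objects = 1,
                                        diameter_range = c(8, 8))),
    "place")
})

test_that("box-like shapes cover exactly their integer volume", {
  dims <- c(32, 32, 32)
  expect_identical(nrow(shape_voxels("cube", c(12.3, 10.7, 9.2), 8, dims)),
                   512L)
  expect_identical(nrow(shape_voxels("prism", c(15.5, 16.2, 14.9),
                                     c(4, 6, 8), dims)),
                   as.integer(4 * 6 * 8))
})

test_that("mixed-shapes phantoms place non-overlapping shapes", {
  rec <- phantom_recipe("shapes", dims = c(96, 96, 48), n_objects = 20,
                        diameter_range = c(6, 14), seed = 3)
  v <- make_shapes_phantom(rec)
  expect_identical(v, make_shapes_phantom(rec))  # determinism
  objs <- attr(v, "objects")
  expect_length(objs, 20L)
  # per-voxel membership oracle: every nonzero voxel belongs to exactly one
  # placed shape, so the per-shape voxel sets sum to the nonzero count and
  # their union covers it
  per_shape <- lapply(objs, function(o) {
    shape_voxels(o$family, o$center, o$size, rec$dims)
  })
  counts <- vapply(per_shape, nrow, integer(1))
  lin <- unlist(lapply(per_shape, function(m) {
    (m[, 3] - 1) * 96 * 96 + (m[, 2] - 1) * 96 + m[, 1]
  }))
  expect_identical(sum(counts), sum(v != 0))
  expect_identical(anyDuplicated(lin), 0L)
  expect_setequal(lin, which(v != 0))
})

test_that("slab recipes keep objects inside the grid", {
  rec <- phantom_recipe("spheres", dims = c(64, 64, 20), n_objects = 4,
                        diameter_range = c(6, 12), seed = 5)
  v <- make_spheres_phantom(rec)
  # boundary faces stay empty because spheres must fit fully inside
  expect_true(all(v[1, , ] == 0) && all(v[64, , ] == 0))
  expect_true(all(v[, , 1] == 0) && all(v[, , 20] == 0))
})

test_that("low-pass filtering preserves the mean and the DC-only limit", {
  set.seed(2)
  v <- array(runif(16^3), c(16, 16, 16))
  for (roll in c("gaussian", "hard")) {
    out <- lowpass_filter(v, 0.3, rolloff = roll)
    expect_lt(abs(mean(out) - mean(v)) / abs(mean(v)), 1e-6)
  }
  const <- array(3.7, c(8, 8, 8))
  expect_equal(lowpass_filter(const, 0.4), const, tolerance = 1e-12)
})

test_that("a hard passband at cutoff 1 is an exact no-op", {
  set.seed(3)
  v <- array(rnorm(12^3), c(12, 12, 12))
  expect_equal(lowpass_filter(v, 1, rolloff = "hard"), v, tolerance = 1e-12)
})

test_that("hard low-pass removes out-of-band power and is idempotent", {
  set.seed(4)
  n <- 32
  v <- array(rnorm(n^3), c(n, n, n))
  out <- lowpass_filter(v, 0.25, rolloff = "hard")
  # direct FFT shell sums
  Fo <- fft(out)
  k <- 0:(n - 1); k[k > n / 2] <- k[k > n / 2] - n
  f <- sqrt(outer(outer(k^2, k^2, "+"), k^2, "+")) / n
  p_beyond <- sum(Mod(Fo[f > 0.25 * 0.5])^2)
  p_pass <- sum(Mod(Fo[f <= 0.25 * 0.5])^2)
  expect_lt(p_beyond, 0.01 * p_pass)
  twice <- lowpass_filter(out, 0.25, rolloff = "hard")
  expect_lt(max(abs(twice - out)), 1e-6 * max(abs(out)))
})

test_that("parameter errors are rejected", {
  v <- array(1, c(4, 4, 4))
  expect_error(lowpass_filter(v, 0), "cutoff")
  expect_error(lowpass_filter(v, -0.2), "cutoff")
})

test_that("tilt-series normalization is a joint affine min-max map", {
  s <- array(c(-2, 0, 2, 1, -1, 0), c(3, 1, 2))
  out <- normalize_series(s)
  expect_equal(range(out), c(0, 1))
  expect_equal(out[, 1, 1], c(0, 0.5, 1))
  # already-normalized stacks pass through unchanged
  expect_equal(normalize_series(out), out)
  # invertibility
  set.seed(5)
  s2 <- array(rnorm(60), c(5, 4, 3))
  n2 <- normalize_series(s2)
  back <- n2 * diff(range(s2)) + min(s2)
  expect_lt(max(abs(back - s2)), 1e-6)
  expect_error(normalize_series(array(1, c(2, 2, 2))), "degenerate")
})
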
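# shared fixtures and oracles built in code

# small smooth test volume: one full sphere, low-passed
smooth_sphere_volume <- function(n = 32, seed = 42) {
  vol <- array(0, c(n, n, n))
  idx <- shape_voxels("sphere", center = rep((n - 1) / 2, 3), size = n / 2,
                      dims = c(n, n, n))
  vol[idx] <- 1
  lowpass_filter(vol, 0.25)
}

# brute-force FSC: per-voxel shell loop, no vectorized shell machinery
brute_force_fsc <- function(v1, v2) {
  stopifnot(identical(dim(v1), dim(v2)))
  n <- dim(v1)[1]
  F1 <- fft(v1); F2 <- fft(v2)
  k <- 0:(n - 1); k[k > n / 2] <- k[k > n / 2] - n
  out <- data.frame()
  for (r in 1:floor(n / 2)) {
    num <- 0; d1 <- 0; d2 <- 0; cnt <- 0
    for (i in 1:n) for (j in 1:n) for (l in 1:n) {
      rad <- sqrt(k[i]^2 + k[j]^2 + k[l]^2)
      if (round(rad) == r) {
        num <- num + Re(F1[i, j, l] * Conj(F2[i, j, l]))
        d1 <- d1 + Mod(F1[i, j, l])^2
        d2 <- d2 + Mod(F2[i, j, l])^2
        cnt <- cnt + 1
      }
    }
    out <- rbind(out, data.frame(radius = r, correlation = num / sqrt(d1 * d2),
                                 n_voxels = cnt))
  }
  out
}

# normalized Gaussian window written out independently of the package
gaussian_oracle_kernel <- function(size, sigma) {
  x <- seq(-(size - 1) / 2, (size - 1) / 2)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# the heavy desk-scale head-to-head run, computed once per test session
.desk_cache <- new.env(parent = emptyenv())
desk_run <- function() {
  if (is.null(.desk_cache$run)) {
    .desk_cache$run <- spheres_benchmark(seed = 1L)
  }
  .desk_cache$run
}
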
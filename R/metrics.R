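#' Peak signal-to-noise ratio between two volumes
#'
#' `10 log10(Im^2 / MSE)` in decibels, where `Im` is the maximum possible
#' voxel value (1 for \[0, 1\]-normalized volumes) and MSE the mean squared
#' error. Identical volumes return `Inf`.
#'
#' @param v_hat,v_star Volumes of equal dimension (estimate, reference).
#' @param Im Maximum possible voxel value (> 0).
#' @return PSNR in dB.
#' @export
psnr <- function(v_hat, v_star, Im = 1) {
  stop_dims(v_hat, v_star)
  if (Im <= 0) stop("Im must be positive")
  mse <- mean((v_hat - v_star)^2)
  if (mse == 0) return(Inf)
  10 * log10(Im^2 / mse)
}

#' Least-squares affine intensity registration
#'
#' Returns `a * v + b` with `a`, `b` chosen to minimize the squared error to
#' the reference. Used to put reconstructions with arbitrary intensity scale
#' (WBP filter normalization, network output units) on the reference scale
#' before voxel-based metrics; FSC is scale-invariant and does not need it.
#'
#' @param v Volume to rescale.
#' @param ref Reference volume of equal dimension.
#' @return Rescaled volume with attributes `"a"` and `"b"`.
#' @export
affine_match <- function(v, ref) {
  stop_dims(v, ref)
  vv <- as.numeric(v); rr <- as.numeric(ref)
  sv <- stats::var(vv)
  a <- if (sv == 0) 0 else stats::cov(vv, rr) / sv
  b <- mean(rr) - a * mean(vv)
  out <- a * v + b
  attr(out, "a") <- a
  attr(out, "b") <- b
  out
}

# separable convolution helpers ------------------------------------------

gaussian_kernel <- function(size, sigma) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# band matrix realizing 'same'-size 1D convolution with zero padding
conv_band <- function(n, kern) {
  h <- (length(kern) - 1L) / 2L
  B <- matrix(0, n, n)
  for (o in -h:h) {
    idx <- seq_len(n)
    j <- idx + o
    ok <- j >= 1L & j <= n
    B[cbind(idx[ok], j[ok])] <- kern[o + h + 1L]
  }
  B
}

# separable 3D convolution ('same' size, zero padded)
conv3_sep <- function(v, kern) {
  d <- dim(v)
  for (ax in 1:3) {
    B <- conv_band(d[ax], kern)
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(v, perm), d[ax])
    v <- aperm(array(B %*% m, d[perm]), order(perm))
  }
  v
}

# crop the margins where the zero padding contaminates windowed sums
valid_crop <- function(v, h) {
  d <- dim(v)
  if (any(d < 2 * h + 1)) stop("window larger than volume")
  v[(h + 1):(d[1] - h), (h + 1):(d[2] - h), (h + 1):(d[3] - h), drop = FALSE]
}

#' Structural similarity index between two volumes
#'
#' Mean local SSIM with a 3D Gaussian window (default size 11, sigma 1.5,
#' clipped to the largest odd size fitting the volume), standard stabilizers
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` with dynamic range `L = Im`. Local
#' statistics are averaged over the interior region where the full window
#' fits. The result lies in \[-1, 1\]; identical volumes give 1.
#'
#' @inheritParams psnr
#' @param window Window size (odd).
#' @param sigma Gaussian window standard deviation.
#' @return Scalar SSIM.
#' @export
ssim_volume <- function(v_hat, v_star, Im = 1, window = 11L, sigma = 1.5) {
  stop_dims(v_hat, v_star)
  d <- dim(v_hat)
  w <- min(window, min(d))
  if (w %% 2L == 0L) w <- w - 1L
  if (w < 1L) stop("window larger than volume")
  h <- (w - 1L) / 2L
  k <- gaussian_kernel(w, sigma)
  mu1 <- conv3_sep(v_hat, k); mu2 <- conv3_sep(v_star, k)
  s11 <- conv3_sep(v_hat^2, k) - mu1^2
  s22 <- conv3_sep(v_star^2, k) - mu2^2
  s12 <- conv3_sep(v_hat * v_star, k) - mu1 * mu2
  C1 <- (0.01 * Im)^2
  C2 <- (0.03 * Im)^2
  map <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  mean(valid_crop(map, h))
}

# 2D 'valid' Gaussian filtering for VIF
gf2_valid <- function(m, kern) {
  h <- (length(kern) - 1L) / 2L
  d <- dim(m)
  if (any(d < length(kern))) return(NULL)
  B1 <- conv_band(d[1], kern)
  B2 <- conv_band(d[2], kern)
  out <- B1 %*% m %*% t(B2)
  out[(h + 1):(d[1] - h), (h + 1):(d[2] - h), drop = FALSE]
}

vif_slice <- function(ref, dist, sigma_nsq = 2) {
  num <- 0; den <- 0
  for (scale in 1:4) {
    N <- 2^(4 - scale + 1) + 1
    # clip the window for small slices (standard sizes need >= 17 px)
    fit <- min(dim(ref))
    if (fit < 5) break
    if (N > fit) N <- fit - (1 - fit %% 2)
    k <- gaussian_kernel(N, N / 5)
    if (scale > 1) {
      ref <- gf2_valid(ref, k)
      dist <- gf2_valid(dist, k)
      if (is.null(ref) || is.null(dist)) break
      ref <- ref[seq(1, nrow(ref), by = 2), seq(1, ncol(ref), by = 2), drop = FALSE]
      dist <- dist[seq(1, nrow(dist), by = 2), seq(1, ncol(dist), by = 2), drop = FALSE]
    }
    mu1 <- gf2_valid(ref, k); mu2 <- gf2_valid(dist, k)
    if (is.null(mu1) || is.null(mu2)) break
    s1 <- pmax(gf2_valid(ref^2, k) - mu1^2, 0)
    s2 <- pmax(gf2_valid(dist^2, k) - mu2^2, 0)
    s12 <- gf2_valid(ref * dist, k) - mu1 * mu2
    g <- s12 / (s1 + 1e-10)
    sv <- s2 - g * s12
    g[s1 < 1e-10] <- 0
    sv[s1 < 1e-10] <- s2[s1 < 1e-10]
    sv[g < 0] <- s2[g < 0]
    g[g < 0] <- 0
    sv[sv < 1e-10] <- 1e-10
    num <- num + sum(log10(1 + g^2 * s1 / (sv + sigma_nsq)))
    den <- den + sum(log10(1 + s1 / sigma_nsq))
  }
  c(num = num, den = den)
}

#' Visual information fidelity of a reconstruction
#'
#' Pixel-domain multi-scale VIF under the Gaussian-scale-mixture model of
#' natural images: the ratio of the information the distorted channel
#' retains about the reference to the information in the reference channel
#' itself. Computed on the central half of the z slices (2D, averaged by
#' pooling the information sums across slices and scales) after jointly
#' rescaling both volumes to the 0-255 range of the reference. Identical
#' volumes give 1; blur gives values in (0, 1); noiseless contrast
#' enhancement gives values above 1.
#'
#' @inheritParams psnr
#' @param sigma_nsq Variance of the HVS internal noise (default 2, on the
#'   0-255 scale).
#' @return Scalar VIF (>= 0).
#' @export
vif_volume <- function(v_hat, v_star, sigma_nsq = 2) {
  stop_dims(v_hat, v_star)
  rng <- range(v_star)
  if (diff(rng) == 0) stop("degenerate (constant) reference volume")
  sc <- function(v) (v - rng[1]) / diff(rng) * 255
  d <- dim(v_star)
  q <- floor(d[3] / 4)
  zsel <- max(1, q + 1):min(d[3], d[3] - q)
  num <- 0; den <- 0
  for (z in zsel) {
    s <- vif_slice(sc(v_star[, , z]), sc(v_hat[, , z]), sigma_nsq)
    num <- num + s["num"]; den <- den + s["den"]
  }
  if (den == 0) stop("reference volume carries no local variance on the evaluated slices")
  unname(num / den)
}

# Fourier shell machinery -------------------------------------------------

# per-voxel shell index (integer frequency radius) and scaled axis indices;
# anisotropic grids are put on a common frequency unit (cycles per largest
# box edge) so a shell is geometrically spherical
shell_index <- function(d) {
  nmax <- max(d)
  kx <- fft_freq_index(d[1]) * (nmax / d[1])
  ky <- fft_freq_index(d[2]) * (nmax / d[2])
  kz <- fft_freq_index(d[3]) * (nmax / d[3])
  r <- sqrt(outer(outer(kx^2, ky^2, "+"), kz^2, "+"))
  list(shell = as.integer(round(r)), nyquist = floor(nmax / 2), nmax = nmax)
}

fsc_tabulate <- function(F1, F2, shell, nyquist, sel = NULL) {
  num <- Re(F1 * Conj(F2))
  d1 <- Mod(F1)^2
  d2 <- Mod(F2)^2
  sh <- as.integer(shell)
  if (!is.null(sel)) {
    num <- num[sel]; d1 <- d1[sel]; d2 <- d2[sel]; sh <- sh[sel]
  }
  keep <- sh >= 1L & sh <= nyquist
  sh <- sh[keep]
  agg <- rowsum(cbind(num[keep], d1[keep], d2[keep], 1), group = sh)
  radius <- as.integer(rownames(agg))
  den <- sqrt(agg[, 2] * agg[, 3])
  corr <- ifelse(den > 0, agg[, 1] / den, NA_real_)
  data.frame(radius = radius,
             correlation = as.numeric(corr),
             n_voxels = as.integer(agg[, 4]),
             num = as.numeric(agg[, 1]),
             den1 = as.numeric(agg[, 2]),
             den2 = as.numeric(agg[, 3]))
}

#' Fourier shell correlation between two volumes
#'
#' For each integer Fourier radius r from 1 up to Nyquist, correlates the
#' Fourier coefficients of the two volumes over the voxels within a half
#' unit of the shell of radius r: `Re(sum(F1 conj(F2))) /
#' sqrt(sum(|F1|^2) sum(|F2|^2))` — a normalized Pearson correlation
#' computed without subtracting the mean. The DC term is excluded. Empty
#' shells are dropped with a warning. On anisotropic grids the frequency
#' unit is cycles per largest box edge.
#'
#' @param v1,v2 Volumes of equal dimension.
#' @return Data frame with columns `radius` (frequency units),
#'   `correlation`, `n_voxels`, and the per-shell sums `num`, `den1`, `den2`
#'   from which the correlation is formed.
#' @export
fsc <- function(v1, v2) {
  stop_dims(v1, v2)
  si <- shell_index(dim(v1))
  out <- fsc_tabulate(stats::fft(v1), stats::fft(v2), si$shell, si$nyquist)
  if (nrow(out) < si$nyquist) {
    warning("some Fourier shells contain no voxels and were dropped")
  }
  out
}

#' Present/missing partition of Fourier space for a tilt geometry
#'
#' Labels every Fourier voxel as "present" if it lies within a half frequency
#' unit of the central-section plane of at least one acquired tilt (the
#' plane through the origin perpendicular to that tilt's beam direction),
#' else "missing" — the missing wedge. The DC voxel is excluded from both
#' regions.
#'
#' @param geometry A [tilt_geometry()].
#' @param dims Volume dimensions `c(x, y, z)`.
#' @param half_width Slab half-width in frequency units (default 0.5).
#' @return An object of class `directional_mask`: list with `labels` (array
#'   of 1 = present, 2 = missing, NA at DC), `angles`, `dims`, `half_width`.
#' @export
directional_masks <- function(geometry, dims, half_width = 0.5) {
  if (!inherits(geometry, "tilt_geometry")) geometry <- tilt_geometry(geometry)
  stopifnot(length(dims) == 3L)
  nmax <- max(dims)
  kx <- fft_freq_index(dims[1]) * (nmax / dims[1])
  kz <- fft_freq_index(dims[3]) * (nmax / dims[3])
  th <- geometry$angles * pi / 180
  dmin <- NULL
  for (t in th) {
    dist <- abs(outer(kx * sin(t), kz * cos(t), "+"))
    dmin <- if (is.null(dmin)) dist else pmin(dmin, dist)
  }
  present2d <- dmin <= half_width
  lab2d <- ifelse(present2d, 1L, 2L)
  labels <- aperm(array(rep(lab2d, dims[2]), c(dims[1], dims[3], dims[2])),
                  c(1, 3, 2))
  labels[1, 1, 1] <- NA_integer_
  structure(list(labels = labels, angles = geometry$angles, dims = dims,
                 half_width = half_width),
            class = "directional_mask")
}

#' @export
print.directional_mask <- function(x, ...) {
  fr <- mean(x$labels == 2L, na.rm = TRUE)
  cat(sprintf("directional_mask: %d x %d x %d, %d tilts, %.1f%% missing\n",
              x$dims[1], x$dims[2], x$dims[3], length(x$angles), 100 * fr))
  invisible(x)
}

#' Directional FSC restricted to the present or missing Fourier region
#'
#' Shell correlation as in [fsc()], but using only the Fourier voxels that
#' carry the requested label, quantifying how much genuine information a
#' reconstruction supplies inside (or outside) the missing wedge. Shells
#' retaining fewer than `min_voxels` labeled voxels are dropped.
#'
#' @param v1,v2 Volumes of equal dimension.
#' @param mask A [directional_masks()] object with matching dims.
#' @param region `"present"` or `"missing"`.
#' @param min_voxels Minimum labeled voxels for a shell to be reported.
#' @return Data frame in the format of [fsc()].
#' @export
masked_fsc <- function(v1, v2, mask, region = c("present", "missing"),
                       min_voxels = 10L) {
  region <- match.arg(region)
  stop_dims(v1, v2)
  stopifnot(inherits(mask, "directional_mask"))
  if (!identical(as.integer(dim(v1)), as.integer(mask$dims))) {
    stop("mask dims do not match volumes")
  }
  code <- if (region == "present") 1L else 2L
  sel <- which(mask$labels == code)
  if (length(sel) == 0L) stop("no Fourier voxels carry the requested label")
  si <- shell_index(dim(v1))
  out <- fsc_tabulate(stats::fft(v1), stats::fft(v2), si$shell, si$nyquist,
                      sel = sel)
  out[out$n_voxels >= min_voxels, , drop = FALSE]
}

#' Full reference-based evaluation of a reconstruction
#'
#' Bundles PSNR, SSIM, VIF, the global FSC and (when a geometry is given)
#' the directional present/missing FSC curves into one report.
#'
#' @param v_hat Reconstruction.
#' @param v_star Ground-truth reference of equal dimension.
#' @param geometry Optional [tilt_geometry()] for the directional FSC.
#' @param Im Maximum possible voxel value for PSNR/SSIM.
#' @param register If `TRUE`, [affine_match()] `v_hat` to `v_star` before
#'   the voxel-based metrics (FSC is computed on the unregistered volumes;
#'   it is scale-invariant).
#' @return A list of class `metrics_report`.
#' @export
metrics_report <- function(v_hat, v_star, geometry = NULL, Im = 1,
                           register = FALSE) {
  stop_dims(v_hat, v_star)
  v_m <- if (register) affine_match(v_hat, v_star) else v_hat
  rep <- list(psnr = psnr(v_m, v_star, Im = Im),
              ssim = ssim_volume(v_m, v_star, Im = Im),
              vif = vif_volume(v_m, v_star),
              Im = Im,
              registered = register,
              fsc_full = fsc(v_hat, v_star))
  if (!is.null(geometry)) {
    mask <- directional_masks(geometry, dim(v_hat))
    rep$fsc_present <- masked_fsc(v_hat, v_star, mask, "present")
    rep$fsc_missing <- masked_fsc(v_hat, v_star, mask, "missing")
  }
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report: PSNR %.3f dB, SSIM %.4f, VIF %.4f\n",
              x$psnr, x$ssim, x$vif))
  cat(sprintf("  global FSC: %d shells, mean %.4f\n",
              nrow(x$fsc_full), mean(x$fsc_full$correlation, na.rm = TRUE)))
  if (!is.null(x$fsc_missing)) {
    cat(sprintf("  missing-region FSC: %d shells, mean %.4f\n",
                nrow(x$fsc_missing), mean(x$fsc_missing$correlation, na.rm = TRUE)))
  }
  invisible(x)
}

#' Write the per-shell FSC tables of a report as TSV
#'
#' Columns: radius, full, present, missing (absent curves as NA).
#'
#' @param report A [metrics_report()].
#' @param path Output file.
#' @export
write_fsc_table <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  full <- report$fsc_full
  tab <- data.frame(radius = full$radius, full = full$correlation)
  for (nm in c("present", "missing")) {
    curve <- report[[paste0("fsc_", nm)]]
    tab[[nm]] <- if (is.null(curve)) NA_real_ else {
      curve$correlation[match(tab$radius, curve$radius)]
    }
  }
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
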
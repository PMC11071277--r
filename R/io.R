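#' Read an MRC2014 volume
#'
#' Supports modes 0 (int8), 1 (int16) and 2 (float32), little- or big-endian
#' (detected from the machine-stamp / header plausibility). The file stores
#' x fastest, then y, then z sections, which maps directly onto the in-memory
#' convention: `vol[i, j, k]` is column i, row j, section k.
#'
#' @param path MRC file path.
#' @return 3D numeric array with attribute `voxel_size` (Angstrom/voxel,
#'   from the cell dimensions) when present in the header.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024L)
  if (length(hdr_raw) < 1024L) stop("malformed MRC header (file too short): ", path)
  parse_hdr <- function(endian) {
    list(nx = readBin(hdr_raw[1:4], "integer", size = 4, endian = endian),
         ny = readBin(hdr_raw[5:8], "integer", size = 4, endian = endian),
         nz = readBin(hdr_raw[9:12], "integer", size = 4, endian = endian),
         mode = readBin(hdr_raw[13:16], "integer", size = 4, endian = endian),
         cella = readBin(hdr_raw[41:52], "numeric", n = 3, size = 4, endian = endian),
         mx = readBin(hdr_raw[29:32], "integer", size = 4, endian = endian))
  }
  endian <- "little"
  h <- parse_hdr(endian)
  plausible <- function(h) {
    all(c(h$nx, h$ny, h$nz) > 0) && all(c(h$nx, h$ny, h$nz) < 1e6) &&
      h$mode %in% c(0L, 1L, 2L)
  }
  if (!plausible(h)) {
    endian <- "big"
    h <- parse_hdr(endian)
    if (!plausible(h)) stop("malformed or unsupported MRC header: ", path)
  }
  n <- h$nx * h$ny * h$nz
  nsymbt <- readBin(hdr_raw[93:96], "integer", size = 4, endian = endian)
  if (nsymbt > 0) readBin(con, "raw", n = nsymbt)
  data <- switch(as.character(h$mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE,
                             endian = endian)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = TRUE,
                             endian = endian)),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = endian),
    stop("unsupported MRC mode: ", h$mode))
  if (length(data) < n) stop("truncated MRC data block: ", path)
  vol <- array(data, c(h$nx, h$ny, h$nz))
  if (h$mx > 0 && h$cella[1] > 0) {
    attr(vol, "voxel_size") <- h$cella[1] / h$mx
  }
  vol
}

#' Write a volume as MRC2014 (mode 2, float32, little-endian)
#'
#' @param vol 3D numeric array.
#' @param path Output path.
#' @param voxel_size Physical sampling in Angstrom/voxel (header metadata).
#' @export
write_mrc <- function(vol, path, voxel_size = 1) {
  stopifnot(is.array(vol), length(dim(vol)) == 3L)
  d <- dim(vol)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                       # nx ny nz
  wi(2L)                      # mode 2 = float32
  wi(c(0L, 0L, 0L))           # nxstart nystart nzstart
  wi(d)                       # mx my mz
  wf(d * voxel_size)          # cella
  wf(c(90, 90, 90))           # cellb
  wi(c(1L, 2L, 3L))           # mapc mapr maps
  v <- as.numeric(vol)
  wf(c(min(v), max(v), mean(v)))  # dmin dmax dmean
  wi(c(1L, 0L))               # ispg, nsymbt
  wi(integer(25L))            # extra
  wf(c(0, 0, 0))              # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst: little-endian
  wf(stats::sd(v))            # rms
  wi(1L)                      # nlabl
  lab <- charToRaw(formatC("cntomo volume", width = -80))
  writeBin(lab, con)
  writeBin(raw(800L - length(lab)), con)
  writeBin(v, con, size = 4, endian = "little")
  invisible(path)
}

#' Read/write a volume by file extension
#'
#' `.mrc` / `.rec` / `.map` use MRC2014; `.tif` / `.tiff` use (multi-page)
#' 32-bit float TIFF, one x-y section per page.
#'
#' @param path File path.
#' @return `read_volume()`: a 3D numeric array.
#' @export
read_volume <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mrc", "rec", "map", "st", "ali")) {
    read_mrc(path)
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1]])
    vol <- array(0, c(d[2], d[1], length(pages)))  # page rows are y
    for (k in seq_along(pages)) vol[, , k] <- t(pages[[k]])
    vol
  } else {
    stop("unsupported volume format: .", ext)
  }
}

#' @rdname read_volume
#' @param vol 3D numeric array.
#' @param voxel_size Angstrom/voxel (MRC only).
#' @export
write_volume <- function(vol, path, voxel_size = 1) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mrc", "rec", "map")) {
    write_mrc(vol, path, voxel_size = voxel_size)
  } else if (ext %in% c("tif", "tiff")) {
    pages <- lapply(seq_len(dim(vol)[3]), function(k) t(vol[, , k]))
    tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  } else {
    stop("unsupported volume format: .", ext)
  }
  invisible(path)
}

#' Read a tilt series: projection stack plus angle file
#'
#' The stack (MRC or multipage TIFF) holds one frame per section; the `.tlt`
#' file holds one angle per line. Frames pair with angles by index; a count
#' mismatch is an error.
#'
#' @param stack_path Projection stack file.
#' @param angles_path Plain-text angle file (degrees, one per line).
#' @return A [tilt_series()].
#' @export
read_tilt_series <- function(stack_path, angles_path) {
  imgs <- read_volume(stack_path)
  geom <- read_angles(angles_path)
  if (dim(imgs)[3] != geom$n_tilts) {
    stop(sprintf("stack has %d frames but angle file lists %d angles",
                 dim(imgs)[3], geom$n_tilts))
  }
  tilt_series(imgs, geom)
}

#' @rdname read_tilt_series
#' @param p A [tilt_series()].
#' @export
write_tilt_series <- function(p, stack_path, angles_path) {
  stopifnot(inherits(p, "tilt_series"))
  write_volume(p$images, stack_path)
  write_angles(p$geometry, angles_path)
  invisible(stack_path)
}
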
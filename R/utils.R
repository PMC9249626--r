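## Shared low-level helpers: lattice-disk kernels, image coercion, raster IO.
## All images are plain R matrices/arrays indexed [row, col(, channel)] with
## intensities on [0, 1]; coordinates are 0-based half-open at the API
## boundary (SpotBox), 1-based internally as usual in R.

`%||%` <- function(a, b) if (is.null(a)) b else a

.mat <- function(x) {
  if (inherits(x, "Image")) EBImage::imageData(x) else unclass(x)
}

#' Discrete disk kernel
#'
#' Binary (2r+1) x (2r+1) matrix marking the lattice points with
#' x^2 + y^2 <= r^2. This is the structuring element used for every
#' morphological disk operation in the package (dilation, closing,
#' low-pass disk means), so kernel footprints match lattice-point counts
#' exactly (e.g. radius 2 -> 13 pixels, radius 10 -> 317 pixels).
#'
#' @param r integer radius in pixels (>= 0)
#' @return 0/1 matrix of odd dimension
#' @export
disk_kernel <- function(r) {
  r <- as.integer(round(r))
  if (r < 0) stop("disk radius must be >= 0")
  d <- 2L * r + 1L
  x <- matrix(rep(-r:r, d), d, d)
  k <- (x^2 + t(x)^2) <= r^2
  storage.mode(k) <- "double"
  k
}

dilate_mask <- function(mask, r) {
  if (r <= 0 || !any(mask)) return(mask)
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  .mat(EBImage::dilate(m, disk_kernel(r))) > 0.5
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Read a spot image
#'
#' Reads an 8/16-bit PNG or TIFF raster into a numeric array on [0, 1],
#' indexed [row, col, channel].
#'
#' @param path file path (.png, .tif, .tiff)
#' @return numeric array (grayscale images are returned as matrices)
#' @export
read_spot_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]
  img
}

#' Write a spot image
#'
#' Writes an array on [0, 1] as 8-bit PNG or 32-bit float TIFF,
#' depending on the file extension. PNG quantises to 8 bits; TIFF
#' preserves float channels (used for demultiplexed channels).
#'
#' @param img numeric matrix or array on [0, 1]
#' @param path output path
#' @export
write_spot_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(clamp01(img), path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 32L,
                    compression = "none", reduce = FALSE)
  } else {
    stop("unsupported image format: ", ext)
  }
  invisible(path)
}

## 8-bit round trip without touching disk; used to emulate scanner output.
quantize8 <- function(img) round(clamp01(img) * 255) / 255

## Deterministic 32-bit sub-seed for stream `i` of master seed `seed`.
## Plain integer arithmetic kept below 2^53 so the modulus is exact.
mix_seed <- function(seed, i) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  as.integer((s * 48271 + as.numeric(i) * 16807 + 11) %% 2147483647)
}

luminance <- function(img) {
  if (length(dim(img)) == 3L) (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  else img
}
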
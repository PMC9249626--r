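## Nucleus segmentation: robust intensity rescaling, adaptive Otsu
## thresholding, shape-based declumping of touching nuclei, size filtering.

#' Robust linear intensity stretch
#'
#' Maps the 1st percentile to 0 and the 99th to 1, clipping to [0, 1].
#' Affine transformations of the input (positive scale) give identical
#' output. A constant channel returns all zeros with a warning and the
#' attribute `constant = TRUE`.
#'
#' @param channel numeric image matrix with finite values
#' @param probs lower/upper stretch percentiles
#' @return rescaled matrix on [0, 1]
#' @export
rescale_channel <- function(channel, probs = c(0.01, 0.99)) {
  if (!all(is.finite(channel))) stop("channel has non-finite values")
  q <- quantile(channel, probs, names = FALSE)
  if (q[2] <= q[1]) {
    warning("constant channel; returning zeros")
    out <- channel * 0
    attr(out, "constant") <- TRUE
    return(out)
  }
  clamp01((channel - q[1]) / (q[2] - q[1]))
}

## Bilinear interpolation of per-tile values to a full-size surface.
.interp_surface <- function(vals, centers_r, centers_c, nr, nc) {
  if (length(centers_r) == 1L && length(centers_c) == 1L)
    return(matrix(vals[1, 1], nr, nc))
  rows <- if (length(centers_r) == 1L) {
    matrix(vals[1, ], 1L, ncol(vals))
  } else {
    apply(vals, 2, function(col)
      approx(centers_r, col, xout = seq_len(nr), rule = 2)$y)
  }
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = nr)
  if (length(centers_c) == 1L) {
    matrix(rows[, 1], nr, nc)
  } else {
    t(apply(rows, 1, function(r)
      approx(centers_c, r, xout = seq_len(nc), rule = 2)$y))
  }
}

#' Adaptive Otsu foreground mask
#'
#' The channel is pre-blurred with a Gaussian whose FWHM equals the
#' threshold smoothing scale (sigma = scale/2.35, the convention of the
#' originating segmentation tool; 0 disables the blur). Otsu thresholds
#' are computed on a grid of `tile_size` tiles, each over its own observed
#' value range (which makes the mask covariant under constant offsets),
#' bilinearly interpolated to a per-pixel threshold surface, and the mask
#' is `blurred >= surface`. A tile grid that does not fit the image falls
#' back to a single global Otsu threshold with a warning; a constant image
#' yields an empty mask.
#'
#' @param channel image matrix on [0, 1]
#' @param tile_size adaptive window in pixels
#' @param smoothing_scale threshold smoothing scale (FWHM in pixels)
#' @return logical mask
#' @export
adaptive_otsu_mask <- function(channel, tile_size = 128,
                               smoothing_scale = 1.3488) {
  nr <- nrow(channel); nc <- ncol(channel)
  x <- channel
  if (smoothing_scale > 0)
    x <- .mat(EBImage::gblur(channel, sigma = smoothing_scale / 2.35))
  rng <- range(x)
  if (diff(rng) <= 0) return(matrix(FALSE, nr, nc))
  if (tile_size > nr || tile_size > nc) {
    warning("tile size exceeds image; falling back to global Otsu")
    return(x >= otsu_threshold(x))
  }
  ntr <- max(1L, floor(nr / tile_size))
  ntc <- max(1L, floor(nc / tile_size))
  br <- floor(seq(0L, nr, length.out = ntr + 1L))
  bc <- floor(seq(0L, nc, length.out = ntc + 1L))
  vals <- matrix(NA_real_, ntr, ntc)
  for (i in seq_len(ntr)) {
    for (j in seq_len(ntc)) {
      tile <- x[(br[i] + 1L):br[i + 1L], (bc[j] + 1L):bc[j + 1L]]
      vals[i, j] <- tryCatch(otsu_threshold(tile), error = function(e) NA_real_)
    }
  }
  # degenerate tiles (constant) inherit the global threshold
  if (anyNA(vals)) vals[is.na(vals)] <- otsu_threshold(x)
  centers_r <- (br[-length(br)] + br[-1] + 1) / 2
  centers_c <- (bc[-length(bc)] + bc[-1] + 1) / 2
  surface <- .interp_surface(vals, centers_r, centers_c, nr, nc)
  x >= surface
}

## Greedy minimum-separation peak selection within one connected component.
.select_peaks <- function(peaks_rc, values, min_sep) {
  o <- order(-values, peaks_rc[, 1], peaks_rc[, 2])
  acc <- matrix(numeric(0), 0, 2)
  for (k in o) {
    p <- peaks_rc[k, ]
    if (nrow(acc) == 0 ||
        min((acc[, 1] - p[1])^2 + (acc[, 2] - p[2])^2) >= min_sep^2) {
      acc <- rbind(acc, p)
    }
  }
  acc
}

#' Declump touching nuclei by shape
#'
#' Uses object shape rather than intensity: the Euclidean distance
#' transform of the mask is Gaussian-smoothed (sigma = 2 px), local maxima
#' at least `min_diameter / 2` apart seed each connected component, and
#' mask pixels are assigned to the nearest seed (exact Euclidean,
#' equivalent to a watershed of the smoothed distance map for the convex
#' nuclei this targets). Each output region is connected and lies within
#' one connected component of the input mask; the union of labels equals
#' the mask.
#'
#' @param mask logical foreground mask
#' @param min_diameter minimum object diameter (seeds closer than half of
#'   it are merged)
#' @param sigma distance-map smoothing in pixels
#' @return integer label matrix (4-connected regions, labels 1..N)
#' @export
declump_by_shape <- function(mask, min_diameter = 25, sigma = 2) {
  mask <- mask & TRUE
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  if (!any(mask)) return(labels)
  comp <- .mat(EBImage::bwlabel(matrix(as.numeric(mask), nr, nc)))
  dist <- .mat(EBImage::distmap(matrix(as.numeric(mask), nr, nc)))
  sm <- .mat(EBImage::gblur(dist, sigma = sigma))
  min_sep <- max(1, min_diameter / 2)
  # local maxima of the smoothed distance map (within-mask plateau maxima)
  mx <- .mat(EBImage::dilate(sm, disk_kernel(ceiling(min_sep))))
  is_peak <- mask & (sm >= mx - 1e-12)

  next_label <- 0L
  for (ci in seq_len(max(comp))) {
    sel <- comp == ci
    pk <- which(is_peak & sel, arr.ind = TRUE)
    if (nrow(pk) == 0L) {
      # blur can displace the maximum across components; fall back to the
      # component's own distance maximum
      inside <- which(sel, arr.ind = TRUE)
      pk <- inside[which.max(dist[sel]), , drop = FALSE]
    }
    seeds <- .select_peaks(pk, sm[pk], min_sep)
    k <- nrow(seeds)
    if (k == 1L) {
      next_label <- next_label + 1L
      labels[sel] <- next_label
      next
    }
    # nearest-seed assignment restricted to this component
    rr <- range(which(sel, arr.ind = TRUE)[, 1])
    cr <- range(which(sel, arr.ind = TRUE)[, 2])
    sub <- sel[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
    seed_img <- matrix(0L, nrow(sub), ncol(sub))
    seed_img[cbind(seeds[, 1] - rr[1] + 1L, seeds[, 2] - cr[1] + 1L)] <-
      seq_len(k)
    diag_len <- sqrt(nrow(sub)^2 + ncol(sub)^2) + 1
    claimed <- assign_nearest_label_cpp(seed_img, sub, rep(diag_len, k))
    claimed[seed_img > 0L] <- seed_img[seed_img > 0L]
    patch <- labels[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
    patch[sub] <- claimed[sub] + next_label
    labels[rr[1]:rr[2], cr[1]:cr[2]] <- patch
    next_label <- next_label + k
  }
  labels
}

#' Filter labelled regions by equivalent circular diameter
#'
#' Keeps regions whose equivalent diameter 2*sqrt(area/pi) lies in
#' `[min_diameter, max_diameter]` (inclusive) and renumbers the survivors
#' contiguously preserving raster order (order of first pixel in
#' column-major scan). Idempotent.
#'
#' @param labels integer label matrix
#' @param min_diameter,max_diameter diameter bounds in pixels
#' @return filtered, renumbered label matrix
#' @export
filter_by_size <- function(labels, min_diameter = 25, max_diameter = 170) {
  n <- max(labels)
  if (n == 0L) return(labels)
  area <- tabulate(labels[labels > 0L], nbins = n)
  ed <- 2 * sqrt(area / pi)
  keep <- which(area > 0L & ed >= min_diameter & ed <= max_diameter)
  out <- matrix(0L, nrow(labels), ncol(labels))
  if (!length(keep)) return(out)
  first_px <- vapply(keep, function(l) which(labels == l)[1], numeric(1))
  keep <- keep[order(first_px)]
  map <- integer(n)
  map[keep] <- seq_along(keep)
  sel <- labels > 0L
  out[sel] <- map[labels[sel]]
  out
}

#' Segment nuclei from a (restored) counterstain channel
#'
#' Composition of [rescale_channel()], [adaptive_otsu_mask()],
#' [declump_by_shape()] and [filter_by_size()]. The shipped defaults
#' (diameter 25-170 px, smoothing scale 1.3488) target 40x TMA scans;
#' adjust the diameters to the pixel scale of the material.
#'
#' @param channel nuclear channel matrix
#' @param min_diameter,max_diameter object diameter limits in pixels
#' @param tile_size adaptive threshold window
#' @param smoothing_scale threshold smoothing scale (FWHM px)
#' @return integer label matrix
#' @export
segment_nuclei <- function(channel, min_diameter = 25, max_diameter = 170,
                           tile_size = 128, smoothing_scale = 1.3488) {
  x <- rescale_channel(channel)
  if (isTRUE(attr(x, "constant"))) return(matrix(0L, nrow(x), ncol(x)))
  mask <- adaptive_otsu_mask(x, tile_size, smoothing_scale)
  labels <- declump_by_shape(mask, min_diameter)
  filter_by_size(labels, min_diameter, max_diameter)
}
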
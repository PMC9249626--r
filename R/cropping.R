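## TMA spot detection and cropping from a stitched slide raster.
## Coordinates are 0-based, half-open throughout ([row_min, row_max) x
## [col_min, col_max)).

#' Detect TMA spots on a stitched slide
#'
#' Foreground (tissue darker than the light background) by global Otsu on
#' the luminance, morphological closing with a disk of radius
#' `min_spot_diameter / 10`, 4-connected labelling, and one box per
#' region with equivalent diameter at least `min_spot_diameter`. Boxes
#' are padded and clipped to the slide, ordered row-major by centroid and
#' given ids `r{i}c{j}`. Touching or merged spots are not split
#' (no grid-model dearraying).
#'
#' @param slide RGB array on [0, 1]
#' @param min_spot_diameter minimum spot equivalent diameter (px)
#' @param padding padding added around each box (px)
#' @return data.frame of boxes: `spot_id`, `row_min`, `row_max`,
#'   `col_min`, `col_max` (0-based, half-open); empty for an
#'   all-background slide
#' @export
detect_spots <- function(slide, min_spot_diameter = 800, padding = 50) {
  if (length(dim(slide)) != 3L || dim(slide)[3] != 3L)
    stop("expected an RGB slide array")
  lum <- luminance(slide)
  nr <- nrow(lum); nc <- ncol(lum)
  empty <- data.frame(spot_id = character(0), row_min = integer(0),
                      row_max = integer(0), col_min = integer(0),
                      col_max = integer(0))
  thr <- tryCatch(otsu_threshold(lum), error = function(e) NULL)
  if (is.null(thr)) return(empty)
  fg <- lum < thr
  if (!any(fg)) return(empty)
  r <- max(1L, round(min_spot_diameter / 10))
  fg <- .mat(EBImage::closing(matrix(as.numeric(fg), nr, nc),
                              disk_kernel(r))) > 0.5
  lab <- .mat(EBImage::bwlabel(matrix(as.numeric(fg), nr, nc)))
  n <- max(lab)
  if (n == 0L) return(empty)
  area <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(2 * sqrt(area / pi) >= min_spot_diameter)
  if (!length(keep)) return(empty)
  boxes <- do.call(rbind, lapply(keep, function(l) {
    px <- which(lab == l, arr.ind = TRUE)
    data.frame(row_min = max(0L, min(px[, 1]) - 1L - padding),
               row_max = min(nr, max(px[, 1]) + padding),
               col_min = max(0L, min(px[, 2]) - 1L - padding),
               col_max = min(nc, max(px[, 2]) + padding),
               cen_r = mean(px[, 1]), cen_c = mean(px[, 2]))
  }))
  # row-major ids: group centroids into rows, order left-to-right
  tol <- min_spot_diameter / 2
  o <- order(boxes$cen_r)
  row_id <- integer(nrow(boxes))
  cur <- 0L; last_r <- -Inf
  for (i in o) {
    if (boxes$cen_r[i] - last_r > tol) cur <- cur + 1L
    row_id[i] <- cur
    last_r <- boxes$cen_r[i]
  }
  ord <- order(row_id, boxes$cen_c)
  boxes <- boxes[ord, , drop = FALSE]
  row_id <- row_id[ord]
  col_id <- ave(seq_along(row_id), row_id, FUN = seq_along)
  out <- data.frame(spot_id = sprintf("r%dc%d", row_id, col_id),
                    boxes[, c("row_min", "row_max", "col_min", "col_max")])
  rownames(out) <- NULL
  out
}

#' Crop detected spots out of a slide
#'
#' Pixel-exact sub-rasters; each crop carries its box as the attribute
#' `box`.
#'
#' @param slide RGB array
#' @param boxes data.frame from [detect_spots()]
#' @return named list of crops (by `spot_id`)
#' @export
crop_spots <- function(slide, boxes) {
  if (!nrow(boxes)) return(list())
  stopifnot(all(boxes$row_min < boxes$row_max),
            all(boxes$col_min < boxes$col_max))
  out <- lapply(seq_len(nrow(boxes)), function(i) {
    b <- boxes[i, ]
    cr <- slide[(b$row_min + 1L):b$row_max,
                (b$col_min + 1L):b$col_max, , drop = FALSE]
    attr(cr, "box") <- b
    cr
  })
  names(out) <- boxes$spot_id
  out
}
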
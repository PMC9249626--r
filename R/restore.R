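## Restoration of the nuclear counterstain channel where strong chromogenic
## signal destroyed the underlying absorbance information. Voids are derived
## from the marker mask and filled by discrete harmonic interpolation.

#' Build the void mask from the marker mask
#'
#' Dilates the suprathreshold marker mask by a lattice disk so the fringe
#' of each signal dot (where unmixing is least reliable) is included.
#'
#' @param marker_mask logical image of suprathreshold marker pixels
#' @param dilation_radius disk radius in pixels
#' @return logical mask with attributes `dilation_radius` and
#'   `flagged` (TRUE when the void fraction is >= 0.9)
#' @export
build_void_mask <- function(marker_mask, dilation_radius = 2) {
  stopifnot(is.logical(marker_mask) || all(marker_mask %in% c(0, 1)))
  m <- dilate_mask(marker_mask, dilation_radius)
  attr(m, "dilation_radius") <- dilation_radius
  frac <- mean(m)
  attr(m, "flagged") <- frac >= 0.9
  if (frac >= 0.9)
    warning(sprintf("void mask covers %.0f%% of the image", 100 * frac))
  m
}

#' Fill voids by harmonic interpolation
#'
#' Pixels outside the voids are returned bit-exact. Inside each void the
#' discrete Laplace equation is solved with Dirichlet data taken from the
#' non-void 4-neighbours (sparse Cholesky via the Matrix package), so the
#' fill is the unique discrete harmonic extension of the boundary: it
#' reproduces constants and linear ramps exactly and obeys the maximum
#' principle (filled values stay within the boundary extrema of their
#' connected void). Segmentation needs this smooth continuity rather than
#' texture fidelity.
#'
#' A void component with no known neighbour (only possible when it spans
#' the whole image edge-to-edge) is filled with the median of the known
#' pixels; a void covering the entire image is an error.
#'
#' @param channel numeric image matrix
#' @param voids logical mask (e.g. from [build_void_mask()])
#' @return restored channel matrix
#' @export
inpaint_harmonic <- function(channel, voids) {
  stopifnot(all(dim(channel) == dim(voids)))
  voids <- voids & TRUE
  if (!any(voids)) return(channel)
  if (all(voids)) stop("void mask covers the entire image")
  nr <- nrow(channel); nc <- ncol(channel)
  idx <- which(voids)
  n <- length(idx)
  pos <- integer(nr * nc)
  pos[idx] <- seq_len(n)
  r0 <- (idx - 1L) %% nr + 1L
  c0 <- (idx - 1L) %/% nr + 1L

  triplets_i <- vector("list", 5L)
  triplets_j <- vector("list", 5L)
  triplets_x <- vector("list", 5L)
  b <- numeric(n)
  deg <- numeric(n)
  nk <- integer(n) # known (non-void, in-image) neighbour count

  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  k <- 1L
  for (o in offs) {
    rn <- r0 + o[1]; cn <- c0 + o[2]
    inside <- rn >= 1L & rn <= nr & cn >= 1L & cn <= nc
    lin <- (pmin(pmax(cn, 1L), nc) - 1L) * nr + pmin(pmax(rn, 1L), nr)
    nb_void <- inside & voids[lin]
    deg <- deg + as.numeric(inside)
    # known neighbours feed the right-hand side
    known <- inside & !nb_void
    if (any(known)) {
      b[known] <- b[known] + channel[lin[known]]
      nk[known] <- nk[known] + 1L
    }
    if (any(nb_void)) {
      triplets_i[[k]] <- which(nb_void)
      triplets_j[[k]] <- pos[lin[nb_void]]
      triplets_x[[k]] <- rep(-1, sum(nb_void))
      k <- k + 1L
    }
  }
  ii <- c(seq_len(n), unlist(triplets_i))
  jj <- c(seq_len(n), unlist(triplets_j))
  xx <- c(deg, unlist(triplets_x))
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))

  # components without any Dirichlet data are singular: fill from median
  lab <- .mat(EBImage::bwlabel(matrix(as.numeric(voids), nr, nc)))
  has_known <- tapply(nk > 0L, lab[idx], any)
  orphan <- as.integer(names(has_known))[!has_known]
  out <- channel
  if (length(orphan)) {
    med <- median(channel[!voids])
    sel <- lab[idx] %in% orphan
    out[idx[sel]] <- med
    keep <- !sel
    if (any(keep)) {
      A2 <- A[keep, keep, drop = FALSE]
      out[idx[keep]] <- as.numeric(Matrix::solve(A2, b[keep]))
    }
    warning(length(orphan), " void component(s) had no boundary data; ",
            "filled with the median of known pixels")
  } else {
    out[idx] <- as.numeric(Matrix::solve(A, b))
  }
  out
}

#' Restore the nuclear channel under strong marker signal
#'
#' @param nucleus hematoxylin concentration image
#' @param marker_mask logical suprathreshold marker mask
#' @param dilation_radius void dilation radius in pixels
#' @return restored nucleus channel
#' @export
restore_nucleus <- function(nucleus, marker_mask, dilation_radius = 2) {
  voids <- build_void_mask(marker_mask, dilation_radius)
  inpaint_harmonic(nucleus, voids)
}
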
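## Per-cell marker quantification: masking of nonspecific staining,
## signal integration over expanded segments, positive-control spot QC.

#' Mask nonspecific (saturated) marker regions
#'
#' Nonspecific staining manifests as regions driven to (near) chromogen
#' saturation. Seeds are pixels within the 5 darkest of 256 display bins
#' of saturation, i.e. signal intensity >= 1 - 5/256 (the marker channel
#' displays dark = strong stain; this package stores it as signal
#' intensity where 1 = saturated). Seeds are expanded by a 10 px lattice
#' disk. The output is monotone in the seed threshold.
#'
#' @param marker signal-intensity image on [0, 1]
#' @param bins number of display bins treated as saturated (of 256)
#' @param radius expansion disk radius (px)
#' @return logical exclusion mask
#' @export
mask_nonspecific <- function(marker, bins = 5, radius = 10) {
  seed <- marker >= 1 - bins / 256
  dilate_mask(seed, radius)
}

#' Integrate marker signal per cell
#'
#' Per cell i: `Intensity_i` = sum of marker signal over its expanded
#' segment excluding masked pixels, `Area_i` = count of those pixels.
#' Masked pixels reduce both, keeping the per-cell mean unbiased.
#' Cells left with no usable area are dropped; the count of dropped
#' cells is returned as attribute `n_dropped`.
#'
#' @param expanded expanded label matrix (quantification support)
#' @param marker background-suppressed signal-intensity image
#' @param exclusion logical mask from [mask_nonspecific()] (or NULL)
#' @param cell_table optional data.frame with per-label metadata
#'   (must contain `label`); joined onto the output
#' @return data.frame with `label`, `area`, `intensity` (+ metadata)
#' @export
integrate_cell_signal <- function(expanded, marker, exclusion = NULL,
                                  cell_table = NULL) {
  stopifnot(all(dim(expanded) == dim(marker)))
  n <- max(expanded)
  use <- expanded > 0L
  if (!is.null(exclusion)) use <- use & !exclusion
  idx <- which(use)
  if (n == 0L || !length(idx)) {
    out <- data.frame(label = integer(0), area = numeric(0),
                      intensity = numeric(0))
    attr(out, "n_dropped") <- if (n > 0L) n else 0L
    return(out)
  }
  l <- expanded[idx]
  area <- tabulate(l, nbins = n)
  inten <- numeric(n)
  s <- rowsum(marker[idx], l)
  inten[as.integer(rownames(s))] <- s[, 1]
  present <- sort(unique(expanded[expanded > 0L]))
  kept <- present[area[present] > 0]
  out <- data.frame(label = kept, area = as.numeric(area[kept]),
                    intensity = inten[kept])
  if (!is.null(cell_table))
    out <- merge(cell_table, out, by = "label", sort = TRUE)
  attr(out, "n_dropped") <- length(present) - length(kept)
  out
}

#' Positive-control spot quality filter
#'
#' RNA quality is checked through a housekeeping control (e.g. PPIB): a
#' spot whose control expression is below an Otsu split of the cohort's
#' spot-level weighted means is considered unreliable. With all values
#' identical no split exists and every spot passes (with a warning).
#'
#' @param spot_means named numeric vector (or data.frame with `spot_id`
#'   and `ppib_mean`) of spot-level control weighted means
#' @param threshold optional fixed threshold overriding the Otsu split
#' @return data.frame with `spot_id`, `ppib_mean`, `pass`, `threshold`
#' @export
spot_qc_ppib <- function(spot_means, threshold = NULL) {
  if (is.data.frame(spot_means)) {
    ids <- as.character(spot_means$spot_id)
    vals <- spot_means$ppib_mean
  } else {
    ids <- names(spot_means) %||% as.character(seq_along(spot_means))
    vals <- as.numeric(spot_means)
  }
  if (length(vals) < 2L && is.null(threshold))
    stop("need at least 2 spots to estimate a QC threshold")
  if (is.null(threshold)) {
    if (diff(range(vals)) <= 0) {
      warning("all control means identical; all spots pass QC")
      return(data.frame(spot_id = ids, ppib_mean = vals, pass = TRUE,
                        threshold = NA_real_))
    }
    threshold <- otsu_threshold(vals, range = range(vals))
  }
  data.frame(spot_id = ids, ppib_mean = vals,
             pass = vals >= threshold, threshold = threshold)
}
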
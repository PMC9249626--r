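## Stain demultiplexing: Beer-Lambert optical-density transform, linear
## unmixing of the hematoxylin / DAB stain pair, and entropy-based
## suppression of marker-channel background.

#' Build a stain matrix for optical-density unmixing
#'
#' Columns are unit optical-density direction vectors for the nuclear
#' counterstain (hematoxylin), the chromogenic marker (DAB), and a residual
#' direction completed by their cross product. Absorbances of stain
#' mixtures are linear in this basis (Beer-Lambert), so per-pixel stain
#' concentrations are recovered by inverting the matrix.
#'
#' @param hematoxylin,dab length-3 optical-density direction vectors
#'   (normalised internally)
#' @param white per-channel white reference in (0, 1]
#' @return object of class `stain_matrix`: list with the 3x3 matrix `M`,
#'   its inverse, and `white`
#' @export
stain_matrix <- function(hematoxylin = c(0.650, 0.704, 0.286),
                         dab = c(0.269, 0.568, 0.778),
                         white = c(1, 1, 1)) {
  h <- hematoxylin / sqrt(sum(hematoxylin^2))
  d <- dab / sqrt(sum(dab^2))
  if (any(white <= 0)) stop("white reference must be positive")
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  nr <- sqrt(sum(r^2))
  if (nr < 1e-6)
    stop("singular stain matrix: hematoxylin and dab vectors are collinear")
  M <- cbind(hematoxylin = h, dab = d, residual = r / nr)
  structure(list(M = M, Minv = solve(M), white = rep(white, length.out = 3)),
            class = "stain_matrix")
}

#' Convert an RGB image to optical density
#'
#' Per channel, OD = -ln(max(I, eps) / white) with eps = 1/512, so fully
#' dark 8-bit pixels map to a finite absorbance ceiling.
#'
#' @param img `[row, col, 3]` array of transmitted intensities on [0, 1]
#' @param white per-channel white reference in (0, 1]
#' @return array of the same shape, OD >= 0 wherever I <= white
#' @export
rgb_to_od <- function(img, white = c(1, 1, 1)) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected an RGB array [row, col, 3]")
  if (any(white <= 0)) stop("white reference must be positive")
  eps <- 1 / 512
  od <- img
  for (c in 1:3) od[, , c] <- -log(pmax(img[, , c], eps) / white[c])
  od
}

#' Unmix optical density into stain concentration channels
#'
#' Solves OD = M c per pixel by the exact matrix inverse (the stain basis
#' is completed to full rank, so the least-squares solution coincides with
#' it). Negative concentrations are clipped to zero. The marker channel is
#' additionally expressed as a "signal intensity" on [0, 1]: DAB
#' concentration divided by the saturation constant (default: OD 2
#' maps to 1) and clipped, so 1 means chromogen-saturated.
#'
#' @param od optical-density array from [rgb_to_od()]
#' @param stains a [stain_matrix()]
#' @param saturation DAB concentration mapped to signal intensity 1
#' @param clip clip negative concentrations (disable to check linearity)
#' @return list with matrices `nucleus` (hematoxylin concentration, >= 0),
#'   `dab` (raw DAB concentration), `residual`, and `marker`
#'   (signal intensity on [0, 1])
#' @export
deconvolve_stains <- function(od, stains = stain_matrix(), saturation = 2,
                              clip = TRUE) {
  stopifnot(inherits(stains, "stain_matrix"))
  d <- dim(od)
  flat <- matrix(od, ncol = 3L)
  conc <- flat %*% t(stains$Minv)
  if (clip) conc[conc < 0] <- 0
  shp <- d[1:2]
  nucleus <- matrix(conc[, 1], shp[1], shp[2])
  dab <- matrix(conc[, 2], shp[1], shp[2])
  res <- matrix(conc[, 3], shp[1], shp[2])
  list(nucleus = nucleus, dab = dab, residual = res,
       marker = clamp01(dab / saturation))
}

.hist256 <- function(x, n_bins = 256L, range = c(0, 1)) {
  lo <- range[1]; hi <- range[2]
  if (hi <= lo) stop("degenerate histogram range")
  b <- pmin(pmax(floor((x - lo) / (hi - lo) * n_bins) + 1L, 1L), n_bins)
  tabulate(b, nbins = n_bins)
}

#' Otsu threshold on a 256-bin histogram
#'
#' Maximises the between-class variance over all bin-edge candidates
#' (equivalently minimises intra-class variance); ties resolve to the
#' lowest threshold. Computed over `range` (default the observed value
#' range), so the threshold is covariant under shifts of the data.
#'
#' @param x numeric values or image matrix
#' @param n_bins histogram resolution
#' @param range histogram support; `NULL` uses the observed range
#' @return threshold value; pixels `>= threshold` are foreground
#' @export
otsu_threshold <- function(x, n_bins = 256L, range = NULL) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite values")
  if (is.null(range)) range <- c(min(x), max(x))
  if (diff(range) <= 0) stop("degenerate histogram")
  cnt <- .hist256(x, n_bins, range)
  p <- cnt / sum(cnt)
  mid <- (seq_len(n_bins) - 0.5) / n_bins
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mid)
  mu_t <- mu0[n_bins]
  t_cand <- seq_len(n_bins - 1L)
  w0c <- w0[t_cand]; m0c <- mu0[t_cand]
  valid <- w0c > 0 & w0c < 1
  sig_b <- rep(-Inf, n_bins - 1L)
  sig_b[valid] <- (mu_t * w0c[valid] - m0c[valid])^2 /
    (w0c[valid] * (1 - w0c[valid]))
  t_star <- which.max(sig_b) # which.max returns the first (lowest) maximiser
  range[1] + t_star / n_bins * diff(range)
}

#' Renyi entropy threshold
#'
#' Splits a 256-bin histogram over [0, 1] at the bin edge maximising the
#' sum of the Renyi entropies of order `alpha` of the background and
#' foreground class histograms (each renormalised to a distribution).
#' `alpha = 1` is the Shannon/Kapur maximum-entropy limit. Ties resolve
#' to the lowest threshold.
#'
#' @param x image matrix or numeric vector with values on [0, 1]
#' @param alpha entropy order (> 0); default 0.5
#' @param n_bins histogram resolution
#' @return threshold on [0, 1]; pixels `>= threshold` are foreground
#' @export
renyi_threshold <- function(x, alpha = 0.5, n_bins = 256L) {
  if (alpha <= 0) stop("alpha must be positive")
  x <- as.numeric(x)
  cnt <- .hist256(x, n_bins, c(0, 1))
  if (sum(cnt > 0) < 2L) stop("degenerate histogram")
  p <- cnt / sum(cnt)
  w0 <- cumsum(p)
  w1 <- 1 - w0
  t_cand <- seq_len(n_bins - 1L)
  if (abs(alpha - 1) < 1e-12) {
    plogp <- ifelse(p > 0, p * log(p), 0)
    a0 <- cumsum(plogp)
    a1 <- a0[n_bins] - a0
    h0 <- log(w0[t_cand]) - a0[t_cand] / w0[t_cand]
    h1 <- log(w1[t_cand]) - a1[t_cand] / w1[t_cand]
  } else {
    pa <- p^alpha
    s0 <- cumsum(pa)
    s1 <- s0[n_bins] - s0
    h0 <- log(s0[t_cand] / w0[t_cand]^alpha) / (1 - alpha)
    h1 <- log(s1[t_cand] / w1[t_cand]^alpha) / (1 - alpha)
  }
  crit <- h0 + h1
  crit[!(w0[t_cand] > 0 & w1[t_cand] > 0)] <- -Inf
  t_star <- which.max(crit)
  t_star / n_bins
}

#' Suppress sub-threshold marker background
#'
#' @param marker signal-intensity image on [0, 1]
#' @param threshold threshold on [0, 1]
#' @return list with `marker` (sub-threshold pixels zeroed) and
#'   `mask` (logical, `marker >= threshold`)
#' @export
suppress_background <- function(marker, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  mask <- marker >= threshold
  cleaned <- marker
  cleaned[!mask] <- 0
  list(marker = cleaned, mask = mask)
}

#' Estimate the white reference from image background
#'
#' Background pixels are those at or above the Otsu threshold of the
#' luminance (tissue is darker than background on a brightfield slide);
#' the white reference is the per-channel 99th percentile over that set.
#' Falls back to 1 when no background can be identified.
#'
#' @param img RGB array on [0, 1]
#' @return length-3 white reference
#' @export
estimate_white <- function(img) {
  lum <- luminance(img)
  thr <- tryCatch(otsu_threshold(lum), error = function(e) NULL)
  if (is.null(thr)) return(c(1, 1, 1))
  bg <- lum >= thr
  if (sum(bg) < 16) return(c(1, 1, 1))
  vapply(1:3, function(c) {
    w <- as.numeric(quantile(img[, , c][bg], 0.99, names = FALSE))
    if (w <= 0) 1 else w
  }, numeric(1))
}

#' Demultiplex a chromogenic spot image
#'
#' Convenience composition: optical-density transform, stain unmixing and
#' Renyi background suppression. A degenerate (constant) marker histogram
#' falls back to an all-false mask with a warning.
#'
#' @param img RGB array on [0, 1]
#' @param stains a [stain_matrix()]; its `white` is used unless
#'   `auto_white` re-estimates it from the image background
#' @param alpha Renyi entropy order
#' @param saturation DAB saturation constant (see [deconvolve_stains()])
#' @param auto_white estimate white reference from the image background
#' @return list with `nucleus`, `marker` (background-suppressed),
#'   `marker_raw`, `mask`, `threshold`, `white`
#' @export
demux_spot <- function(img, stains = stain_matrix(), alpha = 0.5,
                       saturation = 2, auto_white = TRUE) {
  white <- if (auto_white) estimate_white(img) else stains$white
  od <- rgb_to_od(img, white)
  ch <- deconvolve_stains(od, stains, saturation)
  thr <- tryCatch(renyi_threshold(ch$marker, alpha), error = function(e) {
    warning("degenerate marker histogram; using empty marker mask")
    NULL
  })
  if (is.null(thr)) {
    sup <- list(marker = ch$marker * 0, mask = ch$marker > 1)
    thr <- NA_real_
  } else {
    sup <- suppress_background(ch$marker, thr)
  }
  list(nucleus = ch$nucleus, marker = sup$marker, marker_raw = ch$marker,
       mask = sup$mask, threshold = thr, white = white)
}
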
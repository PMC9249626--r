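## Synthetic chromogenic ISH spots with complete ground truth. The forward
## model is Beer-Lambert absorbance mixing of a hematoxylin counterstain
## field (elliptical nuclei of three morphologically distinct classes) and
## a DAB marker field (radially decaying dots per cell, negative-binomial
## counts), so the demultiplexing stage has an exact inverse to recover.

#' Specification of one synthetic spot
#'
#' Defaults encode the morphology conventions of the pipeline: cancer
#' nuclei large and pale (equivalent radius 20-35 px), immune nuclei
#' small, round and dark (8-12 px), stromal nuclei elongated
#' (eccentricity >= 0.9). Dot counts per cell are negative binomial
#' (mean `mu`, dispersion `k`), the super-Poisson mean-linked family the
#' expression-variability statistics presume. The default white level
#' 0.96 exercises background/white estimation.
#'
#' @param image_size (rows, cols) in px
#' @param counts named cell counts per class
#' @param geometry per class: `radius` (equivalent-radius range px),
#'   `ecc` (eccentricity range in [0,1)), `od` (counterstain
#'   optical-density range)
#' @param dots per class: `mu` (mean dots/cell), `k` (NB dispersion),
#'   `radius` (dot radius px), `peak_od` (dot peak DAB optical density)
#' @param marker_background diffuse nonspecific DAB haze added to the
#'   marker concentration: a smoothed random field (`mean_od`, `sd_od`,
#'   correlation `scale` in px) plus unsmoothed per-pixel granularity
#'   (`pixel_sd_od`), clipped at zero. This is the broad low-amplitude
#'   background the entropy-suppression stage removes; set
#'   `mean_od = 0` for an exact dots-only render.
#' @param stains a [stain_matrix()]
#' @param white background white level (scalar or per channel)
#' @param saturation DAB saturation constant used for signal-intensity
#'   ground truth (matches [deconvolve_stains()])
#' @param seed integer; same spec and seed give bit-identical output
#' @return object of class `synth_spot_spec`
#' @export
synth_spot_spec <- function(image_size = c(512, 512),
                            counts = c(cancer = 12, immune = 8, stromal = 8),
                            geometry = list(
                              cancer = list(radius = c(20, 35),
                                            ecc = c(0, 0.4),
                                            od = c(0.35, 0.55)),
                              immune = list(radius = c(8, 12),
                                            ecc = c(0, 0.3),
                                            od = c(0.80, 1.10)),
                              stromal = list(radius = c(9, 13),
                                             ecc = c(0.90, 0.95),
                                             od = c(0.60, 0.90))),
                            dots = list(
                              cancer = list(mu = 6, k = 2, radius = 3,
                                            peak_od = 0.6),
                              immune = list(mu = 2, k = 2, radius = 2,
                                            peak_od = 0.6),
                              stromal = list(mu = 2, k = 2, radius = 2,
                                             peak_od = 0.6)),
                            marker_background = list(mean_od = 0.10,
                                                     sd_od = 0.05,
                                                     scale = 6,
                                                     pixel_sd_od = 0.05),
                            stains = stain_matrix(),
                            white = 0.96,
                            saturation = 2,
                            seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 32))
  if (any(counts < 0)) stop("class counts must be >= 0")
  for (cl in names(geometry)) {
    g <- geometry[[cl]]
    if (any(g$ecc < 0) || any(g$ecc >= 1))
      stop("eccentricity range must lie in [0, 1) for class ", cl)
    if (any(g$radius <= 0) || any(g$od <= 0))
      stop("radius and od ranges must be positive for class ", cl)
  }
  structure(list(image_size = as.integer(image_size), counts = counts,
                 geometry = geometry, dots = dots,
                 marker_background = marker_background, stains = stains,
                 white = rep(white, length.out = 3),
                 saturation = saturation, seed = as.integer(seed)),
            class = "synth_spot_spec")
}

## expansion radii shared with the classification stage so dots fall
## inside the expanded segments by construction
.expansion_radii <- c(cancer = 20, immune = 5, stromal = 5)

## pixels of an ellipse (centre r0/c0, semi-axes a/b, orientation theta)
.ellipse_pixels <- function(r0, c0, a, b, theta, nr, nc, pad = 0) {
  m <- ceiling(max(a, b) + pad)
  rs <- max(1L, floor(r0 - m)):min(nr, ceiling(r0 + m))
  cs <- max(1L, floor(c0 - m)):min(nc, ceiling(c0 + m))
  dr <- rep(rs - r0, times = length(cs))
  dc <- rep(cs - c0, each = length(rs))
  u <- (dr * cos(theta) + dc * sin(theta)) / (a + pad)
  w <- (-dr * sin(theta) + dc * cos(theta)) / (b + pad)
  sel <- u * u + w * w <= 1
  cbind(row = rep(rs, times = length(cs))[sel],
        col = rep(cs, each = length(rs))[sel])
}

#' Render the nuclear counterstain field
#'
#' Places non-overlapping elliptical nuclei by class (rejection sampling,
#' up to 1000 retries per cell, with a deterministic PRNG stream per cell
#' index) and paints each nucleus with its counterstain optical density.
#'
#' @param spec a [synth_spot_spec()]
#' @return list with `labels` (cell-id map, 0 = background), `hema`
#'   (hematoxylin concentration image, zero outside nuclei), and `cells`
#'   (data.frame: cell_id, class, center, semi-axes, orientation, od)
#' @export
render_nucleus_field <- function(spec) {
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  labels <- matrix(0L, nr, nc)
  hema <- matrix(0, nr, nc)
  rows <- list()
  i <- 0L
  for (cl in names(spec$counts)) {
    cnt <- spec$counts[[cl]]
    if (cnt == 0) next
    g <- spec$geometry[[cl]]
    for (j in seq_len(cnt)) {
      i <- i + 1L
      set.seed(mix_seed(spec$seed, i))
      radius <- runif(1, g$radius[1], g$radius[2])
      ecc <- runif(1, g$ecc[1], g$ecc[2])
      theta <- runif(1, 0, pi)
      od <- runif(1, g$od[1], g$od[2])
      q <- (1 - ecc^2)^(1 / 4)
      a <- radius / q
      b <- radius * q
      m <- ceiling(max(a, b)) + 2L
      if (2L * m + 4L >= min(nr, nc))
        stop("image too small to place a '", cl, "' cell")
      placed <- FALSE
      for (try in seq_len(1000L)) {
        r0 <- runif(1, m + 1, nr - m)
        c0 <- runif(1, m + 1, nc - m)
        fp <- .ellipse_pixels(r0, c0, a, b, theta, nr, nc, pad = 2)
        if (all(labels[fp] == 0L)) {
          px <- .ellipse_pixels(r0, c0, a, b, theta, nr, nc)
          labels[px] <- i
          hema[px] <- od
          rows[[i]] <- data.frame(cell_id = i, class = cl,
                                  center_r = r0, center_c = c0,
                                  a = a, b = b, theta = theta,
                                  radius = radius, ecc = ecc, od = od)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("placement failed for class '", cl,
             "' after 1000 retries; reduce counts or enlarge the image")
    }
  }
  cells <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = integer(0), class = character(0),
               center_r = numeric(0), center_c = numeric(0), a = numeric(0),
               b = numeric(0), theta = numeric(0), radius = numeric(0),
               ecc = numeric(0), od = numeric(0))
  list(labels = labels, hema = hema, cells = cells)
}

## one radially decaying dot (quadratic falloff), accumulated in place
.dot_profile <- function(rd) {
  x <- -ceiling(rd):ceiling(rd)
  d2 <- outer(x^2, x^2, "+")
  p <- 1 - d2 / rd^2
  p[p < 0] <- 0
  p
}

#' Render the chromogenic spot image from a nucleus field
#'
#' Draws per-cell dot counts from the class negative binomial, scatters
#' dots uniformly within the cell's cytoplasmic footprint (nucleus
#' ellipse grown by the class expansion radius minus the dot radius, so
#' expanded segments capture the dots by construction), accumulates the
#' radially decaying DAB optical density, and mixes both stains through
#' Beer-Lambert: per channel, I = white * exp(-(C_H h + C_D d)).
#'
#' @param field output of [render_nucleus_field()]
#' @param spec the same [synth_spot_spec()]
#' @return list with `image` (float RGB array), `cd` (DAB concentration
#'   image), `hema`, `labels`, `cells`, and `truth` (per cell:
#'   `cell_id`, `class`, `true_dots`, `true_od_sum`, `true_signal`)
#' @export
render_cish_image <- function(field, spec) {
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  cd <- matrix(0, nr, nc)
  cells <- field$cells
  ndot <- integer(nrow(cells))
  odsum <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    dp <- spec$dots[[cell$class]]
    set.seed(mix_seed(spec$seed, 500000L + cell$cell_id))
    n_dots <- rnbinom(1, size = dp$k, mu = dp$mu)
    ndot[i] <- n_dots
    if (n_dots == 0) next
    grow <- max(0, .expansion_radii[[cell$class]] - dp$radius)
    a2 <- cell$a + grow; b2 <- cell$b + grow
    prof <- dp$peak_od * .dot_profile(dp$radius)
    half <- (nrow(prof) - 1L) / 2L
    for (d in seq_len(n_dots)) {
      repeat {
        dr <- runif(1, -a2, a2); dc <- runif(1, -b2, b2)
        u <- (dr * cos(cell$theta) + dc * sin(cell$theta)) / a2
        w <- (-dr * sin(cell$theta) + dc * cos(cell$theta)) / b2
        if (u * u + w * w <= 1) break
      }
      r0 <- round(cell$center_r + dr); c0 <- round(cell$center_c + dc)
      rs <- (r0 - half):(r0 + half); cs <- (c0 - half):(c0 + half)
      rok <- rs >= 1 & rs <= nr; cok <- cs >= 1 & cs <= nc
      if (!any(rok) || !any(cok)) next
      patch <- prof[rok, cok, drop = FALSE]
      cd[rs[rok], cs[cok]] <- cd[rs[rok], cs[cok]] + patch
      odsum[i] <- odsum[i] + sum(patch)
    }
  }
  # diffuse nonspecific background haze (what suppression removes)
  bg <- matrix(0, nr, nc)
  mb <- spec$marker_background
  if (!is.null(mb) && mb$mean_od > 0) {
    set.seed(mix_seed(spec$seed, 777001L))
    raw <- matrix(rnorm(nr * nc, mb$mean_od, mb$sd_od), nr, nc)
    bg <- .mat(EBImage::gblur(raw, sigma = mb$scale))
    psd <- mb$pixel_sd_od %||% 0
    if (psd > 0) bg <- bg + matrix(rnorm(nr * nc, 0, psd), nr, nc)
    bg[bg < 0] <- 0
  }
  cd_total <- cd + bg
  h <- spec$stains$M[, 1]; dv <- spec$stains$M[, 2]
  img <- array(0, c(nr, nc, 3))
  for (c in 1:3)
    img[, , c] <- spec$white[c] * exp(-(field$hema * h[c] + cd_total * dv[c]))
  truth <- data.frame(cell_id = cells$cell_id, class = cells$class,
                      true_dots = ndot, true_od_sum = odsum,
                      true_signal = odsum / spec$saturation)
  list(image = img, cd = cd_total, cd_dots = cd, cd_background = bg,
       hema = field$hema, labels = field$labels,
       cells = cells, truth = truth)
}

#' Render a complete synthetic spot
#'
#' @param spec a [synth_spot_spec()]
#' @param quantize emulate 8-bit scanner output (round-trip through
#'   256 intensity levels)
#' @return as [render_cish_image()]
#' @export
render_synth_spot <- function(spec, quantize = TRUE) {
  out <- render_cish_image(render_nucleus_field(spec), spec)
  if (quantize) out$image <- quantize8(out$image)
  out
}

#' Generate a synthetic multi-spot cohort with clinical follow-up
#'
#' Emulates a TMA cohort: each patient contributes several spots; the
#' patient's cancer-cell expression level (dot mean, log-normal across
#' patients) and cell-to-cell dispersion (negative-binomial `k`,
#' log-normal across patients) are shared by the patient's spots.
#' Progression and survival times are exponential with hazard
#' `h0 * exp(gamma_mean * z_m + gamma_var * z_v)` where `z_m` and `z_v`
#' are the patient's standardised log expression level and log
#' overdispersion (1/k), censored administratively - so survival can be
#' linked to mean expression, to expression variability, or to neither.
#'
#' @param n_patients number of patients (> 0)
#' @param spots_per_patient spots per patient (> 0)
#' @param spot_spec template [synth_spot_spec()] for every spot (its
#'   cancer dot mean/dispersion are overridden per patient)
#' @param mu0,sigma_m median and log-sd of the patient dot means
#' @param k0,sigma_k median and log-sd of the patient NB dispersions
#' @param h0 baseline hazard (events/month)
#' @param gamma_mean,gamma_var log hazard ratios per SD of mean / of
#'   variability
#' @param censor_months administrative censoring horizon
#' @param out_dir if non-NULL, write images (8-bit PNG), truth and
#'   clinical tables (CSV) and the spec (JSON) under it
#' @param seed master seed; drives all patient, spot and survival draws
#' @return list with `truth` (per-cell table with patient_id/spot_id),
#'   `clinical` (patient_id, pfi_months, pfi_event, os_months, os_event),
#'   `patients` (latent per-patient mu/k/z), and `spots` (list of
#'   rendered spots, named `P<p>_S<s>`) unless `keep_images = FALSE`
#' @param keep_images keep rendered images in the return value
#' @export
generate_cohort <- function(n_patients = 20, spots_per_patient = 2,
                            spot_spec = synth_spot_spec(),
                            mu0 = 6, sigma_m = 0.5, k0 = 2, sigma_k = 0.6,
                            h0 = 0.03, gamma_mean = 0, gamma_var = 0,
                            censor_months = 60,
                            out_dir = NULL, seed = 1L,
                            keep_images = TRUE) {
  if (n_patients <= 0 || spots_per_patient <= 0)
    stop("patient and spot counts must be positive")
  set.seed(mix_seed(seed, 900001L))
  lmu <- rnorm(n_patients, log(mu0), sigma_m)
  set.seed(mix_seed(seed, 900002L))
  lk <- rnorm(n_patients, log(k0), sigma_k)
  z_m <- (lmu - log(mu0)) / sigma_m
  z_v <- -(lk - log(k0)) / sigma_k  # + = more overdispersed
  hz <- h0 * exp(gamma_mean * z_m + gamma_var * z_v)
  set.seed(mix_seed(seed, 900003L))
  t_pfi <- rexp(n_patients, hz)
  set.seed(mix_seed(seed, 900004L))
  t_os <- t_pfi + rexp(n_patients, hz * 1.5) + 6
  clinical <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n_patients)),
    pfi_months = round(pmin(t_pfi, censor_months), 2),
    pfi_event = as.integer(t_pfi <= censor_months),
    os_months = round(pmin(t_os, censor_months * 2), 2),
    os_event = as.integer(t_os <= censor_months * 2))

  truth_rows <- list()
  spots <- list()
  for (p in seq_len(n_patients)) {
    for (s in seq_len(spots_per_patient)) {
      sp <- spot_spec
      sp$dots$cancer$mu <- exp(lmu[p])
      sp$dots$cancer$k <- exp(lk[p])
      sp$seed <- mix_seed(seed, p * 1000L + s)
      spot <- render_synth_spot(sp)
      sid <- sprintf("P%03d_S%d", p, s)
      tr <- spot$truth
      tr$patient_id <- sprintf("P%03d", p)
      tr$spot_id <- sid
      truth_rows[[sid]] <- tr[, c("patient_id", "spot_id", "cell_id",
                                  "class", "true_dots", "true_signal")]
      if (keep_images || !is.null(out_dir)) spots[[sid]] <- spot
      if (!is.null(out_dir)) {
        dir.create(file.path(out_dir, "images"), recursive = TRUE,
                   showWarnings = FALSE)
        write_spot_image(spot$image, file.path(out_dir, "images",
                                               paste0(sid, ".png")))
        if (!keep_images) spots[[sid]] <- NULL
      }
    }
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  patients <- data.frame(patient_id = clinical$patient_id,
                         mu = exp(lmu), k = exp(lk), z_m = z_m, z_v = z_v,
                         hazard = hz)
  if (!is.null(out_dir)) {
    write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    write.csv(clinical, file.path(out_dir, "clinical.csv"),
              row.names = FALSE)
    cfg <- list(n_patients = n_patients,
                spots_per_patient = spots_per_patient,
                mu0 = mu0, sigma_m = sigma_m, k0 = k0, sigma_k = sigma_k,
                h0 = h0, gamma_mean = gamma_mean, gamma_var = gamma_var,
                censor_months = censor_months, seed = seed)
    jsonlite::write_json(cfg, file.path(out_dir, "cohort_spec.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(truth = truth, clinical = clinical, patients = patients,
       spots = if (keep_images) spots else NULL)
}

#' Simulate per-sample (mean, variance) pairs from a power law
#'
#' Direct statistics-level simulator used to validate the
#' variability-factor regression: v = c * m^beta * 10^eps with
#' eps ~ N(0, sigma).
#'
#' @param n number of samples
#' @param beta power-law exponent
#' @param log10_c intercept (log10 of the prefactor)
#' @param sigma residual SD in log10 space
#' @param m_range log10 range of the means
#' @param seed integer seed
#' @return data.frame with `m`, `v`, `eps` (the injected residuals)
#' @export
simulate_power_law <- function(n = 200, beta = 1.6, log10_c = 0.5,
                               sigma = 0.3, m_range = c(-3, -1), seed = 1L) {
  set.seed(mix_seed(seed, 77001L))
  lm_ <- runif(n, m_range[1], m_range[2])
  eps <- rnorm(n, 0, sigma)
  lv <- log10_c + beta * lm_ + eps
  data.frame(m = 10^lm_, v = 10^lv, eps = eps)
}
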
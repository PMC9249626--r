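## Pipeline orchestration: a single configuration drives the stage
## sequence demux -> restore -> segment -> classify -> expand -> mask ->
## integrate per spot, and the cohort-level QC, summaries, variability
## and survival statistics.

#' Pipeline configuration
#'
#' Collects every stage parameter with the shipped defaults. In
#' `mode = "fluorescent"` the demultiplexing and restoration stages are
#' skipped: the marker and nuclear channels arrive separate and the
#' marker is min-max scaled with the configured `fluor_bounds`.
#'
#' @param mode "chromogenic" or "fluorescent"
#' @param stains a [stain_matrix()]
#' @param renyi_alpha Renyi entropy order for background suppression
#' @param saturation DAB saturation constant (signal intensity 1)
#' @param void_radius void-mask dilation radius (px); `restore = FALSE`
#'   disables inpainting
#' @param min_diameter,max_diameter nucleus diameter limits (px)
#' @param tile_size adaptive threshold window (px)
#' @param smoothing_scale threshold smoothing scale (FWHM px)
#' @param qda_model optional fitted [fit_qda()] model; without one every
#'   cell is reported as class "cancer"
#' @param smooth_radius posterior smoothing disk radius (px);
#'   `smooth = FALSE` disables spatial smoothing
#' @param expansion_radii per-class segment expansion radii (px)
#' @param mask_bins,mask_radius nonspecific-mask parameters
#' @param restore,smooth,qc stage switches
#' @param fluor_bounds fixed (lo, hi) marker scaling bounds in
#'   fluorescent mode
#' @param seed integer seed recorded in the run manifest
#' @return a `spot_config` list
#' @export
spot_config <- function(mode = c("chromogenic", "fluorescent"),
                        stains = stain_matrix(),
                        renyi_alpha = 0.5, saturation = 2,
                        void_radius = 2, restore = TRUE,
                        min_diameter = 25, max_diameter = 170,
                        tile_size = 128, smoothing_scale = 1.3488,
                        qda_model = NULL, smooth = TRUE,
                        smooth_radius = 100,
                        expansion_radii = c(cancer = 20, immune = 5,
                                            stromal = 5),
                        mask_bins = 5, mask_radius = 10,
                        qc = TRUE, fluor_bounds = c(0, 1), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(all(expansion_radii > 0), void_radius > 0, mask_radius > 0)
  structure(list(mode = mode, stains = stains, renyi_alpha = renyi_alpha,
                 saturation = saturation, void_radius = void_radius,
                 restore = restore, min_diameter = min_diameter,
                 max_diameter = max_diameter, tile_size = tile_size,
                 smoothing_scale = smoothing_scale, qda_model = qda_model,
                 smooth = smooth, smooth_radius = smooth_radius,
                 expansion_radii = expansion_radii, mask_bins = mask_bins,
                 mask_radius = mask_radius, qc = qc,
                 fluor_bounds = fluor_bounds, seed = as.integer(seed)),
            class = "spot_config")
}

#' Hash of a pipeline configuration
#'
#' MD5 of the canonical JSON serialisation (model reduced to its
#' parameters); changes whenever any stage parameter changes. Used for
#' resumability checks.
#'
#' @param config a [spot_config()]
#' @return hex string
#' @export
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$stains <- list(M = config$stains$M, white = config$stains$white)
  if (!is.null(cfg$qda_model))
    cfg$qda_model <- lapply(cfg$qda_model$pars, function(p)
      list(mu = p$mu, sigma = p$sigma))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, digits = NA, auto_unbox = TRUE,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full stage sequence on one spot image
#'
#' Chromogenic mode: demultiplex, suppress background, restore the
#' nuclear channel under the marker mask, segment, extract features,
#' classify (when a model is configured), smooth posteriors spatially,
#' expand segments by class, mask nonspecific signal, and integrate the
#' marker per cell. An empty segmentation yields an empty table with a
#' warning, not a failure.
#'
#' @param img RGB array (chromogenic) or a list with elements `marker`
#'   and `nucleus` (fluorescent)
#' @param config a [spot_config()]
#' @param spot_id,patient_id identifiers stamped onto the cell table
#' @return list with `cells` (one row per retained cell: identifiers,
#'   class, area, intensity, centroid), `labels`, `expanded`, `channels`
#' @export
run_spot <- function(img, config = spot_config(), spot_id = "spot",
                     patient_id = "patient") {
  if (config$mode == "chromogenic") {
    dm <- demux_spot(img, config$stains, config$renyi_alpha,
                     config$saturation)
    nucleus <- dm$nucleus
    if (config$restore && any(dm$mask))
      nucleus <- restore_nucleus(nucleus, dm$mask, config$void_radius)
    marker <- dm$marker
    mask <- dm$mask
  } else {
    lo <- config$fluor_bounds[1]; hi <- config$fluor_bounds[2]
    marker <- clamp01((img$marker - lo) / (hi - lo))
    nucleus <- img$nucleus
    thr <- tryCatch(renyi_threshold(marker, config$renyi_alpha),
                    error = function(e) NULL)
    if (is.null(thr)) {
      mask <- marker > 1
    } else {
      sup <- suppress_background(marker, thr)
      marker <- sup$marker
      mask <- sup$mask
    }
  }

  labels <- segment_nuclei(nucleus, config$min_diameter,
                           config$max_diameter, config$tile_size,
                           config$smoothing_scale)
  empty_cells <- data.frame(patient_id = character(0), spot_id = character(0),
                            label = integer(0), class = character(0),
                            area = numeric(0), intensity = numeric(0),
                            centroid_r = numeric(0), centroid_c = numeric(0))
  if (max(labels) == 0L) {
    warning("empty segmentation for spot ", spot_id)
    return(list(cells = empty_cells, labels = labels, expanded = labels,
                channels = list(nucleus = nucleus, marker = marker)))
  }
  feats <- extract_features(labels, nucleus)
  if (!is.null(config$qda_model)) {
    post <- qda_posteriors(config$qda_model, feats)
    if (config$smooth) {
      sm <- spatial_smooth(post, feats, labels, config$smooth_radius)
      cls <- sm$class
    } else {
      cls <- colnames(post)[max.col(post, ties.method = "first")]
    }
  } else {
    cls <- rep("cancer", nrow(feats))
  }
  class_by_label <- rep(NA_character_, max(labels))
  class_by_label[feats$label] <- cls
  expanded <- expand_segments(labels, class_by_label, config$expansion_radii)
  excl <- mask_nonspecific(marker, config$mask_bins, config$mask_radius)
  meta <- data.frame(label = feats$label, class = cls,
                     centroid_r = feats$centroid_r,
                     centroid_c = feats$centroid_c)
  cells <- integrate_cell_signal(expanded, marker, excl, meta)
  if (nrow(cells)) {
    cells <- data.frame(patient_id = patient_id, spot_id = spot_id, cells)
  } else {
    cells <- empty_cells
  }
  list(cells = cells, labels = labels, expanded = expanded,
       channels = list(nucleus = nucleus, marker = marker, mask = mask))
}

#' Run a cohort of spot images through the pipeline
#'
#' Iterates `run_spot()` over a directory of images named
#' `<patient>_<spot>.png` (or an in-memory list), applies the
#' positive-control QC when control summaries are supplied, and computes
#' patient summaries, variability factors and (when a clinical table is
#' given) median-split and optimised three-way survival results. A run
#' manifest (JSON) with the config hash supports resumability: rerunning
#' a completed cohort with an unchanged config reloads the outputs
#' instead of recomputing.
#'
#' @param images directory of PNG spot images or a named list of arrays;
#'   names must be `<patient>_<spot>`
#' @param config a [spot_config()]
#' @param clinical optional data.frame (patient_id, pfi_months,
#'   pfi_event, os_months, os_event)
#' @param ppib optional control table for [spot_qc_ppib()]
#' @param out_dir optional output directory for tables and the manifest
#' @param split_on compute survival splits on "factor" (variability
#'   factor), "mean", or both
#' @return list with `cells`, `spots`, `patients` (incl. `varfactor`),
#'   `varfit`, `qc`, `survival`
#' @export
run_cohort <- function(images, config = spot_config(), clinical = NULL,
                       ppib = NULL, out_dir = NULL,
                       split_on = c("factor", "mean")) {
  hash <- config_hash(config)
  if (!is.null(out_dir)) {
    man_path <- file.path(out_dir, "manifest.json")
    cells_path <- file.path(out_dir, "cells.csv")
    if (file.exists(man_path) && file.exists(cells_path)) {
      man <- jsonlite::read_json(man_path)
      if (identical(man$config_hash, hash)) {
        message("unchanged config; reloading completed run")
        cells <- read.csv(cells_path)
        return(.cohort_stats(cells, clinical, ppib, out_dir, split_on,
                             hash))
      }
    }
  }
  if (is.character(images)) {
    files <- list.files(images, pattern = "\\.png$", full.names = TRUE)
    if (!length(files)) stop("no images found in ", images)
    ids <- sub("\\.png$", "", basename(files))
    images <- setNames(lapply(files, read_spot_image), ids)
  }
  if (!length(images)) stop("empty cohort")
  tabs <- vector("list", length(images))
  for (i in seq_along(images)) {
    id <- names(images)[i]
    parts <- strsplit(id, "_", fixed = TRUE)[[1]]
    pid <- parts[1]
    res <- tryCatch(
      run_spot(images[[i]], config, spot_id = id, patient_id = pid),
      error = function(e) {
        warning("spot ", id, " failed: ", conditionMessage(e))
        NULL
      })
    if (!is.null(res)) tabs[[i]] <- res$cells
  }
  cells <- do.call(rbind, tabs[!vapply(tabs, is.null, logical(1))])
  if (is.null(cells) || !nrow(cells)) stop("no cells quantified in cohort")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
  }
  .cohort_stats(cells, clinical, ppib, out_dir, split_on, hash)
}

.cohort_stats <- function(cells, clinical, ppib, out_dir, split_on, hash) {
  qc <- if (!is.null(ppib)) spot_qc_ppib(ppib) else NULL
  sums <- summarize_expression(cells, classes = "cancer", qc = qc)
  pat <- sums$patients
  vf <- tryCatch(fit_variability_factor(pat$m, pat$v), error = function(e) NULL)
  if (!is.null(vf)) pat$varfactor <- vf$factor
  surv <- NULL
  if (!is.null(clinical)) {
    d <- merge(pat, clinical, by = "patient_id")
    surv <- list()
    if ("mean" %in% split_on)
      surv$mean_split <- tryCatch(
        median_split(d$m, d$pfi_months, d$pfi_event), error = function(e) e)
    if ("factor" %in% split_on && !is.null(vf))
      surv$factor_split <- tryCatch(
        median_split(d$varfactor, d$pfi_months, d$pfi_event),
        error = function(e) e)
    surv$three_way <- tryCatch(
      optimize_three_way_split(d$m, d$pfi_months, d$pfi_event),
      error = function(e) e)
  }
  if (!is.null(out_dir)) {
    write.csv(sums$spots, file.path(out_dir, "spot_summaries.csv"),
              row.names = FALSE)
    write.csv(pat, file.path(out_dir, "patient_summaries.csv"),
              row.names = FALSE)
    jsonlite::write_json(list(config_hash = hash,
                              n_spots = nrow(sums$spots),
                              n_patients = nrow(pat)),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(cells = cells, spots = sums$spots, patients = pat, varfit = vf,
       qc = qc, survival = surv)
}

#' Train the cell-type classifier from an annotation table
#'
#' @param features feature table from [extract_features()]
#' @param annotations data.frame with `label` and `class` (as written by
#'   an annotation tool), or a class vector aligned with `features`
#' @return a fitted `qda_model`
#' @export
train_classifier <- function(features, annotations) {
  if (is.data.frame(annotations)) {
    key <- match(features$label, annotations$label)
    cls <- annotations$class[key]
    keep <- !is.na(cls)
    fit_qda(features[keep, , drop = FALSE], cls[keep])
  } else {
    fit_qda(features, annotations)
  }
}
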
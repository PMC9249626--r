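## Shared fixtures, computed lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, make(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# default-condition synthetic spot (the study's standard render)
fix_spot <- function() fixture("spot", function() {
  spec <- synth_spot_spec(seed = 7)
  list(spec = spec, spot = render_synth_spot(spec))
})

# heavily occluded spot: ~30% of nuclear area under saturating dots
# (haze disabled: this study condition isolates saturation corruption)
occluded_spec <- function(seed = 11) synth_spot_spec(
  image_size = c(768, 768),
  counts = c(cancer = 40, immune = 80, stromal = 80),
  dots = list(cancer = list(mu = 50, k = 3, radius = 4, peak_od = 10),
              immune = list(mu = 8, k = 3, radius = 3, peak_od = 10),
              stromal = list(mu = 8, k = 3, radius = 3, peak_od = 10)),
  marker_background = list(mean_od = 0),
  seed = seed)

# pipeline parameters matched to the synthetic geometry (immune nuclei
# of equivalent radius 8-12 px need a lower diameter floor than the 40x
# TMA default; random cell placement voids the co-localisation prior, so
# posterior smoothing is off)
synth_config <- function(model = NULL, ...) {
  spot_config(min_diameter = 12, max_diameter = 120, qda_model = model,
              smooth = FALSE, ...)
}

# QDA model trained on ground-truth label fields of two independent spots
fix_model <- function() fixture("model", function() {
  feats <- list(); cls <- list()
  for (s in 1:2) {
    fld <- render_nucleus_field(synth_spot_spec(seed = 100 + s))
    f <- extract_features(fld$labels, fld$hema)
    feats[[s]] <- f
    cls[[s]] <- fld$cells$class[f$label]
  }
  fit_qda(do.call(rbind, feats), unlist(cls))
})

# draw a digital disk/ellipse into a matrix
draw_ellipse <- function(m, r0, c0, a, b = a, theta = 0, value = 1) {
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    dr <- i - r0; dc <- j - c0
    u <- (dr * cos(theta) + dc * sin(theta)) / a
    w <- (-dr * sin(theta) + dc * cos(theta)) / b
    if (u^2 + w^2 <= 1) m[i, j] <- value
  }
  m
}

# cohort-scale spot geometry: smaller nuclei so several patients' worth of
# multi-spot images stay tractable; class morphology contrasts preserved
cohort_spot_spec <- function() {
  sp <- synth_spot_spec(image_size = c(224, 224),
                        counts = c(cancer = 8, immune = 3, stromal = 3))
  sp$geometry$cancer$radius <- c(12, 18)
  sp$geometry$immune$radius <- c(6, 9)
  sp$geometry$stromal$radius <- c(7, 10)
  sp
}

# classifier trained on ground-truth fields at the cohort geometry
fix_cohort_model <- function() fixture("cohort_model", function() {
  feats <- list(); cls <- list()
  for (s in 1:2) {
    sp <- cohort_spot_spec(); sp$seed <- 7000 + s
    fld <- render_nucleus_field(sp)
    f <- extract_features(fld$labels, fld$hema)
    feats[[s]] <- f
    cls[[s]] <- fld$cells$class[f$label]
  }
  fit_qda(do.call(rbind, feats), unlist(cls))
})

cohort_config <- function(model = fix_cohort_model())
  spot_config(min_diameter = 10, max_diameter = 60, qda_model = model,
              smooth = FALSE)
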
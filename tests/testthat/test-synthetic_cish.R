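test_that("nucleus field honours counts, morphology and determinism", {
  # zero counts: empty identity case
  spec0 <- synth_spot_spec(counts = c(cancer = 0, immune = 0, stromal = 0),
                           image_size = c(64, 64))
  fld0 <- render_nucleus_field(spec0)
  expect_equal(max(fld0$labels), 0)
  expect_equal(sum(fld0$hema), 0)

  # one near-circular cancer cell measures as near-circular
  spec1 <- synth_spot_spec(counts = c(cancer = 1, immune = 0, stromal = 0),
                           image_size = c(128, 128), seed = 3)
  spec1$geometry$cancer$ecc <- c(0, 0.05)
  fld1 <- render_nucleus_field(spec1)
  f <- extract_features(fld1$labels, fld1$hema)
  expect_lt(f$eccentricity, 0.2)

  # same spec, same seed: bit-identical label maps
  spec2 <- synth_spot_spec(seed = 9, image_size = c(256, 256),
                           counts = c(cancer = 4, immune = 4, stromal = 4))
  expect_identical(render_nucleus_field(spec2)$labels,
                   render_nucleus_field(spec2)$labels)

  # stromal nuclei elongated, immune round and dark, cancer large and pale
  fld2 <- render_nucleus_field(spec2)
  f2 <- extract_features(fld2$labels, fld2$hema)
  cls <- fld2$cells$class[f2$label]
  expect_gt(min(f2$eccentricity[cls == "stromal"]), 0.8)
  expect_gt(min(f2$area[cls == "cancer"]), max(f2$area[cls != "cancer"]))
  expect_gt(min(f2$mean_intensity[cls == "immune"]),
            max(f2$mean_intensity[cls == "cancer"]))

  # an image too small for the request fails naming the class
  tiny <- synth_spot_spec(image_size = c(96, 96),
                          counts = c(cancer = 40, immune = 0, stromal = 0))
  expect_error(render_nucleus_field(tiny), "cancer")
})

test_that("the forward model is exact Beer-Lambert mixing", {
  spec <- synth_spot_spec(image_size = c(128, 128),
                          counts = c(cancer = 2, immune = 2, stromal = 2),
                          seed = 5)
  out <- render_synth_spot(spec, quantize = FALSE)
  # zero concentrations render the white background exactly
  spec0 <- synth_spot_spec(image_size = c(64, 64),
                           counts = c(cancer = 0, immune = 0, stromal = 0),
                           marker_background = list(mean_od = 0))
  blank <- render_synth_spot(spec0, quantize = FALSE)
  expect_equal(as.numeric(blank$image), rep(0.96, 64 * 64 * 3))

  # per pixel: -ln(I/white) equals C_H h + C_D d to machine precision
  h <- spec$stains$M[, 1]; d <- spec$stains$M[, 2]
  for (c in 1:3) {
    od_c <- -log(out$image[, , c] / spec$white[c])
    expect_equal(od_c, out$hema * h[c] + out$cd * d[c], tolerance = 1e-12)
  }

  # single-pixel closed form
  cd1 <- matrix(0, 4, 4); cd1[2, 3] <- 1
  img <- sapply(1:3, function(c) 0.96 * exp(-cd1 * d[c]), simplify = "array")
  expect_equal(img[2, 3, ], 0.96 * exp(-d))

  # truth conservation: per-cell sums equal the rendered dot concentration
  # mass (the diffuse haze is carried separately)
  expect_equal(sum(out$truth$true_od_sum), sum(out$cd_dots), tolerance = 1e-9)
  expect_equal(out$cd, out$cd_dots + out$cd_background, tolerance = 1e-12)
})

test_that("dot statistics follow the requested negative binomial family", {
  # near-Poisson limit: variance-to-mean of dot counts ~ 1
  spec <- synth_spot_spec(image_size = c(448, 448),
                          counts = c(cancer = 30, immune = 0, stromal = 0),
                          seed = 21)
  spec$dots$cancer$k <- 1e9
  spec$dots$cancer$mu <- 8
  reps <- lapply(1:4, function(r) {
    s <- spec; s$seed <- 21 + r
    render_cish_image(render_nucleus_field(s), s)$truth$true_dots
  })
  dots <- unlist(reps)
  expect_gt(length(dots), 100)
  vm <- var(dots) / mean(dots)
  expect_gt(vm, 0.7); expect_lt(vm, 1.4)

  # overdispersed: variance-to-mean well above 1
  spec$dots$cancer$k <- 1
  over <- unlist(lapply(1:4, function(r) {
    s <- spec; s$seed <- 121 + r
    render_cish_image(render_nucleus_field(s), s)$truth$true_dots
  }))
  expect_gt(var(over) / mean(over), 1 + mean(over) / 2 * 0.4)
})

test_that("cohort generation is deterministic and carries the injected
           structure", {
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  unlink(c(d1, d2), recursive = TRUE)
  sp <- synth_spot_spec(image_size = c(160, 160),
                        counts = c(cancer = 3, immune = 2, stromal = 2))
  a <- generate_cohort(n_patients = 3, spots_per_patient = 2, spot_spec = sp,
                       out_dir = d1, seed = 17, keep_images = FALSE)
  b <- generate_cohort(n_patients = 3, spots_per_patient = 2, spot_spec = sp,
                       out_dir = d2, seed = 17, keep_images = FALSE)
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_equal(nrow(a$clinical), 3)
  expect_true(all(c("pfi_months", "pfi_event", "os_months", "os_event")
                  %in% names(a$clinical)))
  expect_error(generate_cohort(n_patients = 0), "positive")

  # ground-truth variability factor increases with injected overdispersion
  sp2 <- synth_spot_spec(image_size = c(224, 224),
                         counts = c(cancer = 10, immune = 0, stromal = 0))
  sp2$geometry$cancer$radius <- c(12, 18) # denser core layout
  coh <- generate_cohort(n_patients = 24, spots_per_patient = 1,
                         spot_spec = sp2, sigma_k = 0.8, sigma_m = 0.4,
                         seed = 29, keep_images = FALSE)
  tr <- coh$truth
  per_pat <- split(tr, tr$patient_id)
  mv <- t(vapply(per_pat, function(d)
    c(m = mean(d$true_signal), v = var(d$true_signal)), numeric(2)))
  fit <- fit_variability_factor(mv[, "m"], mv[, "v"])
  z <- coh$patients$z_v[match(names(per_pat), coh$patients$patient_id)]
  expect_gt(cor(fit$factor, z), 0.5)
  expect_gt(fit$beta, 0.8); expect_lt(fit$beta, 2.5)
})
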
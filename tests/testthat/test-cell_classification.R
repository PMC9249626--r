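test_that("morphology features match analytic circle and ellipse values", {
  disk <- draw_ellipse(matrix(0, 60, 60), 30, 30, 20)
  ch <- matrix(0.5, 60, 60)
  f <- extract_features(matrix(as.integer(disk), 60, 60), ch)
  expect_equal(f$area, 400 * pi, tolerance = 0.02)
  expect_lt(f$eccentricity, 0.2)
  expect_equal(f$perim_area, 2 / 20, tolerance = 0.1)
  expect_identical(f$mean_intensity, 0.5)

  ell <- draw_ellipse(matrix(0, 70, 70), 35, 35, 20, 10, theta = pi / 5)
  f2 <- extract_features(matrix(as.integer(ell), 70, 70), matrix(0.5, 70, 70))
  expect_equal(f2$eccentricity, sqrt(1 - 0.25), tolerance = 0.05)
})

test_that("QDA log densities equal the brute-force Gaussian oracle", {
  set.seed(20)
  n <- 40
  x <- rbind(matrix(rnorm(n * 4, 0), n, 4),
             matrix(rnorm(n * 4, 2), n, 4) %*% chol(diag(4) * 1.5))
  cls <- rep(c("a", "b"), each = n)
  model <- fit_qda(x, cls)
  ld <- qda_log_density(model, x)
  for (i in c(1, 17, 55)) for (k in c("a", "b"))
    expect_equal(unname(ld[i, k]),
                 oracle_mvn_logpdf(x[i, ], model$pars[[k]]$mu,
                                   model$pars[[k]]$sigma),
                 tolerance = 1e-9)
  post <- qda_posteriors(model, x)
  expect_equal(rowSums(post), rep(1, 2 * n), tolerance = 1e-9)

  skip_if_not_installed("MASS")
  ref <- MASS::qda(x, grouping = factor(cls))
  agree <- mean(colnames(post)[max.col(post)] ==
                  as.character(predict(ref, x)$class))
  expect_gte(agree, 0.97)
})

test_that("equal covariances reduce the quadratic boundary to a hyperplane", {
  set.seed(21)
  base <- matrix(rnorm(200 * 4), 200, 4)
  x <- rbind(base, sweep(base, 2, c(2, 0, 0, 0), "+"))
  cls <- rep(c("lo", "hi"), each = 200)
  model <- fit_qda(x, cls)
  # force exactly shared covariance to isolate the boundary geometry
  model$pars$hi$sigma <- model$pars$lo$sigma
  model$pars$hi$chol <- model$pars$lo$chol
  model$pars$hi$logdet <- model$pars$lo$logdet
  model$pars$lo$mu <- c(0, 0, 0, 0)
  model$pars$hi$mu <- c(2, 0, 0, 0)
  mid <- matrix(c(1, 0, 0, 0), 1)
  p <- qda_posteriors(model, mid)
  expect_equal(unname(p[1, "lo"]), 0.5, tolerance = 1e-9)
  left <- qda_posteriors(model, matrix(c(0.9, 0, 0, 0), 1))
  expect_gt(left[1, "lo"], 0.5)

  expect_error(fit_qda(matrix(1, 10, 4), rep("a", 10)), "degenerate|singular")
  expect_error(fit_qda(matrix(rnorm(40), 10, 4), rep(c("a", "b"), c(8, 2))),
               "b")
})

test_that("a single-class model yields posterior one and x = mu wins", {
  set.seed(22)
  x <- matrix(rnorm(80), 20, 4)
  m1 <- fit_qda(x, rep("only", 20))
  expect_equal(as.numeric(qda_posteriors(m1, x[1:3, , drop = FALSE])),
               rep(1, 3))

  mus <- list(a = c(0, 0, 0, 0), b = c(3, 1, 0, 0), c = c(-2, 2, 1, 0))
  xs <- do.call(rbind, lapply(mus, function(m)
    sweep(matrix(rnorm(30 * 4), 30, 4), 2, m, "+")))
  model <- fit_qda(xs, rep(names(mus), each = 30))
  shared <- cov(matrix(rnorm(400), 100, 4))
  for (k in names(mus)) {
    model$pars[[k]]$sigma <- shared
    model$pars[[k]]$chol <- chol(shared)
    model$pars[[k]]$logdet <- 2 * sum(log(diag(chol(shared))))
    model$pars[[k]]$mu <- mus[[k]]
  }
  for (k in names(mus)) {
    p <- qda_posteriors(model, matrix(mus[[k]], 1))
    expect_equal(colnames(p)[which.max(p)], k)
  }
})

test_that("posterior smoothing matches the dense disk-mean oracle and flips
           an uncertain cell amid confident neighbours", {
  # 9 cells on a grid: uncertain centre, 8 confident stromal neighbours
  nr <- 260
  labels <- matrix(0L, nr, nr)
  ctr <- as.matrix(expand.grid(r = c(70, 130, 190), c = c(70, 130, 190)))
  for (i in 1:9)
    labels[draw_ellipse(matrix(0, nr, nr), ctr[i, 1], ctr[i, 2], 12) > 0] <- i
  post <- matrix(0.99, 9, 2, dimnames = list(NULL, c("cancer", "stromal")))
  post[, "cancer"] <- 0.01
  post[5, ] <- c(0.55, 0.45) # centre of the grid
  feats <- data.frame(label = 1:9, centroid_r = ctr[, 1], centroid_c = ctr[, 2])
  sm <- spatial_smooth(post, feats, labels, radius = 100)
  expect_equal(sm$class[5], "stromal")
  expect_equal(rowSums(sm$posteriors), rep(1, 9), tolerance = 1e-9)

  # dense spatial oracle at the centroids
  maps <- lapply(1:2, function(k) {
    mp <- matrix(log(1 / 2), nr, nr)
    mp[labels > 0] <- log(pmax(post, 1e-300))[labels[labels > 0], k]
    mp
  })
  osm <- oracle_smooth_at(maps, ctr, 100, log(1 / 2))
  ow <- exp(osm - apply(osm, 1, max))
  ow <- ow / rowSums(ow)
  expect_equal(unname(sm$posteriors), unname(ow), tolerance = 1e-6)
})

test_that("smoothing leaves uniform posterior fields and isolated cells
           unchanged", {
  labels <- matrix(0L, 240, 240)
  labels[draw_ellipse(matrix(0, 240, 240), 120, 120, 10) > 0] <- 1L
  post <- matrix(c(0.7, 0.3), 1, 2, dimnames = list(NULL, c("a", "b")))
  feats <- data.frame(label = 1, centroid_r = 120, centroid_c = 120)
  sm <- spatial_smooth(post, feats, labels, radius = 60)
  expect_equal(sm$class, "a") # isolation: argmax preserved

  # spatially uniform posteriors: classes unchanged everywhere
  labels2 <- matrix(0L, 240, 240)
  ctr <- as.matrix(expand.grid(r = c(60, 120, 180), c = c(60, 120, 180)))
  for (i in 1:9)
    labels2[draw_ellipse(matrix(0, 240, 240), ctr[i, 1], ctr[i, 2], 9) > 0] <- i
  post2 <- matrix(rep(c(0.8, 0.2), each = 9), 9, 2,
                  dimnames = list(NULL, c("a", "b")))
  feats2 <- data.frame(label = 1:9, centroid_r = ctr[, 1],
                       centroid_c = ctr[, 2])
  sm2 <- spatial_smooth(post2, feats2, labels2, radius = 60)
  expect_equal(sm2$class, rep("a", 9))

  expect_warning(sm3 <- spatial_smooth(post2, feats2, labels2, radius = 0),
                 "skipped")
  expect_equal(sm3$class, rep("a", 9))
})

test_that("segment expansion equals the lattice-disk count for an isolated
           nucleus and the nearest-segment oracle under contention", {
  # isolated cancer nucleus: digital disk radius 25 grown by 20
  m <- matrix(0L, 120, 120)
  m[draw_ellipse(matrix(0, 120, 120), 60, 60, 25) > 0] <- 1L
  ex <- expand_segments(m, "cancer")
  seg <- which(m == 1L, arr.ind = TRUE)
  all_px <- as.matrix(expand.grid(r = 1:120, c = 1:120))
  d2seg <- apply(all_px, 1, function(p)
    min((seg[, 1] - p[1])^2 + (seg[, 2] - p[2])^2))
  expect_equal(sum(ex > 0), sum(d2seg <= 400))
  expect_true(all(ex[m == 1L] == 1L))

  # immune 5 px radius
  m5 <- matrix(0L, 40, 40)
  m5[draw_ellipse(matrix(0, 40, 40), 20, 20, 8) > 0] <- 1L
  ex5 <- expand_segments(m5, "immune")
  seg5 <- which(m5 == 1L, arr.ind = TRUE)
  apx <- as.matrix(expand.grid(r = 1:40, c = 1:40))
  d2 <- apply(apx, 1, function(p)
    min((seg5[, 1] - p[1])^2 + (seg5[, 2] - p[2])^2))
  expect_equal(sum(ex5 > 0), sum(d2 <= 25))

  # contested band between an immune and a cancer cell 30 px apart
  mc <- matrix(0L, 80, 110)
  mc[draw_ellipse(matrix(0, 80, 110), 40, 30, 12) > 0] <- 1L
  mc[draw_ellipse(matrix(0, 80, 110), 40, 72, 8) > 0] <- 2L
  exc <- expand_segments(mc, c("cancer", "immune"))
  expect_equal(exc, oracle_expand(mc, setNames(c("cancer", "immune"), 1:2),
                                  c(cancer = 20, immune = 5, stromal = 5)))
})

test_that("expansion is conservative and regions stay disjoint over random
           configurations", {
  set.seed(23)
  radii <- c(cancer = 20, immune = 5, stromal = 5)
  for (rep in 1:60) {
    m <- matrix(0L, 80, 80)
    k <- sample(2:5, 1)
    cls <- sample(names(radii), k, replace = TRUE)
    for (i in seq_len(k)) {
      e <- draw_ellipse(matrix(0, 80, 80), runif(1, 12, 68),
                        runif(1, 12, 68), runif(1, 4, 10))
      m[e > 0 & m == 0L] <- i
    }
    present <- sort(unique(m[m > 0]))
    cls_v <- rep(NA_character_, k)
    cls_v[present] <- cls[present]
    ex <- expand_segments(m, cls_v, radii)
    expect_true(all(ex[m > 0L] == m[m > 0L])) # originals never relabelled
    # every claimed pixel lies within its class radius of its own segment
    for (l in present) {
      seg <- which(m == l, arr.ind = TRUE)
      claimed <- which(ex == l & m == 0L, arr.ind = TRUE)
      if (nrow(claimed)) {
        dmin <- apply(claimed, 1, function(p)
          min((seg[, 1] - p[1])^2 + (seg[, 2] - p[2])^2))
        expect_lte(max(dmin), radii[cls_v[l]]^2)
      }
    }
    # full dense-oracle equality on a subset of repetitions
    if (rep %% 20 == 0)
      expect_equal(ex, oracle_expand(m, setNames(cls_v, seq_len(k)), radii))
  }
})
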
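test_that("optical density transform matches the Beer-Lambert closed form", {
  img <- array(1, c(2, 2, 3))
  expect_equal(rgb_to_od(img, c(1, 1, 1)), array(0, c(2, 2, 3)))

  img[1, 1, 2] <- exp(-1)
  od <- rgb_to_od(img, c(1, 1, 1))
  expect_equal(od[1, 1, 2], 1.0)

  set.seed(1)
  rnd <- array(runif(4 * 5 * 3, 1 / 400, 1), c(4, 5, 3))
  white <- c(0.96, 0.98, 1.0)
  od <- rgb_to_od(rnd, white)
  for (i in 1:4) for (j in 1:5) for (c in 1:3)
    expect_equal(od[i, j, c], -log(max(rnd[i, j, c], 1 / 512) / white[c]))

  expect_error(rgb_to_od(rnd, c(0, 1, 1)), "positive")
})

test_that("unmixing inverts pure and mixed stain absorbances", {
  st <- stain_matrix()
  h <- st$M[, 1]; d <- st$M[, 2]
  od <- array(0, c(1, 2, 3))
  od[1, 1, ] <- 0.7 * h
  od[1, 2, ] <- 0.5 * h + 0.25 * d
  ch <- deconvolve_stains(od, st)
  expect_equal(ch$nucleus[1, 1], 0.7, tolerance = 1e-9)
  expect_equal(ch$dab[1, 1], 0, tolerance = 1e-9)
  expect_equal(ch$nucleus[1, 2], 0.5, tolerance = 1e-9)
  expect_equal(ch$dab[1, 2], 0.25, tolerance = 1e-9)
  expect_equal(ch$residual[1, 2], 0, tolerance = 1e-9)

  expect_error(stain_matrix(c(1, 1, 0), c(2, 2, 0)), "collinear")
})

test_that("unmixing is linear before clipping", {
  st <- stain_matrix()
  set.seed(2)
  od1 <- array(runif(2 * 3 * 3), c(2, 3, 3))
  od2 <- array(runif(2 * 3 * 3), c(2, 3, 3))
  a <- 0.7; b <- 1.3
  lhs <- deconvolve_stains(a * od1 + b * od2, st, clip = FALSE)
  r1 <- deconvolve_stains(od1, st, clip = FALSE)
  r2 <- deconvolve_stains(od2, st, clip = FALSE)
  expect_equal(lhs$dab, a * r1$dab + b * r2$dab, tolerance = 1e-12)
  expect_equal(lhs$nucleus, a * r1$nucleus + b * r2$nucleus,
               tolerance = 1e-12)
})

test_that("round trip recovers rendered DAB concentrations under 1% RMSE", {
  fx <- fix_spot()
  od <- rgb_to_od(fx$spot$image, fx$spec$white)
  ch <- deconvolve_stains(od, fx$spec$stains)
  rmse <- sqrt(mean((ch$dab - fx$spot$cd)^2))
  expect_lt(rmse / max(fx$spot$cd), 0.01)
})

test_that("Renyi threshold equals exhaustive search and is order-free", {
  x <- c(rep(30.5 / 256, 500), rep(220.5 / 256, 500))
  thr <- renyi_threshold(x, alpha = 0.5)
  expect_gt(thr, 30 / 256)
  expect_lt(thr, 221 / 256)
  expect_equal(thr, oracle_renyi(x, 0.5))

  set.seed(3)
  expect_equal(renyi_threshold(sample(x)), renyi_threshold(x))

  for (alpha in c(0.3, 0.5, 2, 4)) {
    for (rep in 1:5) {
      y <- rbeta(400, sample(1:4, 1), sample(1:4, 1))
      expect_equal(renyi_threshold(y, alpha), oracle_renyi(y, alpha),
                   info = sprintf("alpha=%g rep=%d", alpha, rep))
    }
  }
  expect_error(renyi_threshold(rep(0.4, 100)), "degenerate")
})

test_that("the alpha -> 1 limit is the Kapur maximum-entropy threshold", {
  set.seed(4)
  for (rep in 1:10) {
    y <- c(rbeta(300, 1, 6), rbeta(150, 6, 2))
    expect_equal(renyi_threshold(y, alpha = 1), oracle_renyi(y, 1))
    expect_equal(renyi_threshold(y, alpha = 1 - 1e-7),
                 renyi_threshold(y, alpha = 1))
  }
})

test_that("Otsu threshold equals exhaustive search over random histograms", {
  set.seed(5)
  for (rep in 1:40) {
    y <- c(rnorm(200, 0.3, 0.05), rnorm(150, 0.7, 0.08))
    y <- pmin(pmax(y, 0), 1)
    expect_equal(otsu_threshold(y, range = c(0, 1)),
                 oracle_otsu(y, range = c(0, 1)), info = paste("rep", rep))
  }
})

test_that("background suppression zeroes exactly the sub-threshold pixels", {
  set.seed(6)
  m <- matrix(runif(400), 20, 20)
  s <- suppress_background(m, 0)
  expect_equal(s$marker, m)
  expect_true(all(s$mask))

  s <- suppress_background(m, 1)
  expect_equal(sum(s$marker), 0)
  expect_false(any(s$mask))

  thr <- 0.63
  s <- suppress_background(m, thr)
  expect_equal(sum(s$marker > 0), sum(m >= thr & m > 0))
  expect_equal(s$mask, m >= thr)
})
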
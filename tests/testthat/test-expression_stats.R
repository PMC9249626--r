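test_that("weighted mean and variance reproduce the worked examples", {
  expect_equal(weighted_mean_expr(c(100, 300), c(1.0, 0.6)), 0.004)
  m <- weighted_mean_expr(c(100, 100), c(0.2, 0.6))
  expect_equal(m, 0.004)
  expect_equal(weighted_var_expr(c(100, 100), c(0.2, 0.6), m), 4e-6)

  # all cells with identical per-cell mean c -> m = c, v = 0
  a <- c(50, 120, 300)
  expect_equal(weighted_mean_expr(a, a * 0.007), 0.007)
  expect_equal(weighted_var_expr(a, a * 0.007), 0)

  expect_error(weighted_mean_expr(numeric(0), numeric(0)), "no cells")
})

test_that("weighted moments equal brute-force forms and are split-merge
           invariant", {
  set.seed(40)
  for (rep in 1:50) {
    n <- sample(2:30, 1)
    area <- runif(n, 10, 500)
    inten <- runif(n, 0, 3)
    m <- weighted_mean_expr(area, inten)
    w <- area / sum(area)
    expect_equal(m, sum(w * inten / area))
    expect_equal(weighted_var_expr(area, inten),
                 sum(w * (inten / area - m)^2))
    # order invariance
    o <- sample(n)
    expect_equal(weighted_mean_expr(area[o], inten[o]), m)
    # splitting one cell proportionally leaves both moments unchanged
    a2 <- c(area, area[1] * c(0.3, 0.7))[-1]
    i2 <- c(inten, inten[1] * c(0.3, 0.7))[-1]
    expect_equal(weighted_mean_expr(a2, i2), m)
    expect_equal(weighted_var_expr(a2, i2), weighted_var_expr(area, inten))
    # homogeneity: intensity scaling
    cc <- 2.7
    expect_equal(weighted_mean_expr(area, cc * inten), cc * m)
    expect_equal(weighted_var_expr(area, cc * inten),
                 cc^2 * weighted_var_expr(area, inten))
  }
})

test_that("variability factor is the residual of the log-log mean-variance
           fit", {
  # exact power law: residuals vanish, coefficients recovered
  m <- 10^seq(-3, -1, length.out = 12)
  v <- 10^0.4 * m^1.6
  fit <- fit_variability_factor(m, v)
  expect_equal(fit$beta, 1.6, tolerance = 1e-9)
  expect_equal(fit$alpha, 0.4, tolerance = 1e-9)
  expect_equal(fit$factor, rep(0, 12), tolerance = 1e-9)

  # OLS normal equations: residuals sum to 0 and are orthogonal to log m
  set.seed(41)
  m2 <- 10^runif(40, -3, -1)
  v2 <- 10^(0.2 + 1.3 * log10(m2) + rnorm(40, 0, 0.4))
  f2 <- fit_variability_factor(m2, v2)
  expect_lt(abs(sum(f2$factor)), 1e-9)
  expect_lt(abs(sum(f2$factor * log10(m2))), 1e-9)

  # rescaling all variances shifts the intercept, not the residuals
  f3 <- fit_variability_factor(m2, 10 * v2)
  expect_equal(f3$factor, f2$factor, tolerance = 1e-9)
  expect_equal(f3$alpha, f2$alpha + 1, tolerance = 1e-9)

  expect_error(fit_variability_factor(c(1, 2), c(1, 2)), ">= 3")
  expect_error(fit_variability_factor(rep(0.1, 5), runif(5)),
               "unidentifiable")
})

test_that("power-law parameter recovery succeeds at the simulated effect", {
  sim <- simulate_power_law(n = 200, beta = 1.6, sigma = 0.3, seed = 5)
  fit <- fit_variability_factor(sim$m, sim$v)
  lx <- log10(sim$m)
  se <- sqrt(sum(fit$factor^2) / (198)) / (sd(lx) * sqrt(199))
  expect_lt(abs(fit$beta - 1.6), 1.96 * se)
  expect_lt(abs(sd(fit$factor) - 0.3) / 0.3, 0.15) # injected residual SD
})

test_that("nested ANOVA equals the dense design-matrix oracle", {
  set.seed(42)
  for (rep in 1:8) {
    pat <- rep(1:5, each = 2 * 3 * 4)
    phs <- rep(rep(1:2, each = 3 * 4), 5)
    spt <- rep(rep(1:3, each = 4), 10)
    mu <- rnorm(5)[pat] + rnorm(10, 0, 0.5)[2 * (pat - 1) + phs]
    y <- mu + rnorm(length(pat))
    ours <- nested_anova(y, list(patient = pat, phase = phs, spot = spt))
    ref <- oracle_nested_anova(y, list(pat, phs, spt))
    expect_equal(ours$ss[1:3], ref$`Sum Sq`[1:3], tolerance = 1e-8)
    expect_equal(ours$f[1:3], ref$`F value`[1:3], tolerance = 1e-8)
    expect_equal(ours$ss[4], ref$`Sum Sq`[4], tolerance = 1e-8)
  }
})

test_that("one-factor balanced ANOVA recovers F = t^2 and degenerate data is
           flagged", {
  set.seed(43)
  g <- rep(c("a", "b"), each = 15)
  y <- rnorm(30) + (g == "b") * 0.8
  out <- nested_anova(y, list(group = g))
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(out$f[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(out$p[1], tt$p.value, tolerance = 1e-10)

  flat <- nested_anova(rep(2, 12), list(g = rep(1:3, each = 4)))
  expect_equal(flat$ss, c(0, 0))
  expect_true(is.na(flat$f[1]))
})

test_that("precision is the positive-call accuracy", {
  ann <- c(rep(TRUE, 88), rep(FALSE, 12), rep(TRUE, 20))
  prd <- c(rep(TRUE, 100), rep(FALSE, 20))
  p <- precision_score(ann, prd)
  expect_equal(p$precision, 0.88)
  expect_equal(precision_score(rep(TRUE, 5), rep(TRUE, 5))$precision, 1)
  expect_error(precision_score(ann, rep(FALSE, 120)), "undefined")

  set.seed(44)
  a <- runif(200) < 0.5; b <- runif(200) < 0.5
  cm <- table(pred = b, truth = a)
  expect_equal(precision_score(a, b)$precision,
               cm["TRUE", "TRUE"] / sum(cm["TRUE", ]))
})
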
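## Independent brute-force oracles. These deliberately re-derive each
## quantity from first principles (plain loops, dense linear algebra,
## closed forms) and never call the implementation paths they check.

# exhaustive 256-candidate Otsu: maximise between-class variance computed
# directly from class means
oracle_otsu <- function(x, n_bins = 256, range = NULL) {
  x <- as.numeric(x)
  if (is.null(range)) range <- c(min(x), max(x))
  bins <- pmin(pmax(floor((x - range[1]) / diff(range) * n_bins) + 1, 1), n_bins)
  mid <- (seq_len(n_bins) - 0.5) / n_bins
  best <- -Inf; best_t <- NA
  for (t in 1:(n_bins - 1)) {
    lo <- bins <= t
    w0 <- mean(lo); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- mean(mid[bins[lo]]); m1 <- mean(mid[bins[!lo]])
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best + 1e-15) { best <- v; best_t <- t }
  }
  range[1] + best_t / n_bins * diff(range)
}

# exhaustive Renyi-entropy threshold from the raw definition
oracle_renyi <- function(x, alpha, n_bins = 256) {
  bins <- pmin(pmax(floor(as.numeric(x) * n_bins) + 1, 1), n_bins)
  cnt <- tabulate(bins, n_bins)
  p <- cnt / sum(cnt)
  ent <- function(q) {
    q <- q[q > 0]
    q <- q / sum(q)
    if (abs(alpha - 1) < 1e-12) -sum(q * log(q))
    else log(sum(q^alpha)) / (1 - alpha)
  }
  best <- -Inf; best_t <- NA
  for (t in 1:(n_bins - 1)) {
    w0 <- sum(p[1:t]); w1 <- sum(p[(t + 1):n_bins])
    if (w0 == 0 || w1 == 0) next
    v <- ent(p[1:t]) + ent(p[(t + 1):n_bins])
    if (v > best + 1e-12) { best <- v; best_t <- t }
  }
  best_t / n_bins
}

# multivariate normal log density by dense solve
oracle_mvn_logpdf <- function(x, mu, sigma) {
  d <- length(mu)
  xc <- as.numeric(x - mu)
  -0.5 * (d * log(2 * pi) + determinant(sigma)$modulus[1] +
            sum(xc * solve(sigma, xc)))
}

# lattice points with x^2 + y^2 <= r^2
oracle_disk_count <- function(r) {
  g <- expand.grid(x = -ceiling(r):ceiling(r), y = -ceiling(r):ceiling(r))
  sum(g$x^2 + g$y^2 <= r^2)
}

# nearest-segment expansion by per-pixel scan over all labelled pixels
oracle_expand <- function(labels, classes, radii) {
  nr <- nrow(labels); nc <- ncol(labels)
  seed_px <- which(labels > 0, arr.ind = TRUE)
  seed_lab <- labels[labels > 0]
  seed_rad <- radii[classes[seed_lab]]
  seed_rad[is.na(seed_rad)] <- 0
  out <- labels
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (labels[i, j] != 0) next
    d2 <- (seed_px[, 1] - i)^2 + (seed_px[, 2] - j)^2
    ok <- d2 <= seed_rad^2
    if (!any(ok)) next
    dmin <- min(d2[ok])
    cand <- seed_lab[ok][d2[ok] == dmin]
    out[i, j] <- min(cand)
  }
  out
}

# dense-design nested ANOVA through R's own sequential least squares
oracle_nested_anova <- function(y, factors) {
  dat <- data.frame(y = y)
  for (k in seq_along(factors)) dat[[paste0("f", k)]] <- factor(factors[[k]])
  rhs <- paste0("f", seq_along(factors))
  terms <- vapply(seq_along(rhs), function(k)
    paste(rhs[1:k], collapse = ":"), character(1))
  fml <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  as.data.frame(stats::anova(stats::aov(fml, data = dat)))
}

# textbook k-sample log-rank from hypergeometric moments
oracle_logrank_2g <- function(time, event, group) {
  g <- as.integer(factor(group))
  ev_times <- sort(unique(time[event == 1]))
  o_minus_e <- 0; var_sum <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    e1 <- d * n1 / n
    v <- if (n > 1) d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1) else 0
    o_minus_e <- o_minus_e + (d1 - e1)
    var_sum <- var_sum + v
  }
  (o_minus_e^2) / var_sum
}

# disk-mean smoothing of log-posterior maps by direct spatial loops
oracle_smooth_at <- function(maps, centroids, radius, neutral) {
  nr <- nrow(maps[[1]]); nc <- ncol(maps[[1]])
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  out <- matrix(NA_real_, nrow(centroids), length(maps))
  for (ci in seq_len(nrow(centroids))) {
    r0 <- centroids[ci, 1]; c0 <- centroids[ci, 2]
    rr <- r0 + offs$dr; cc <- c0 + offs$dc
    inside <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    for (k in seq_along(maps)) {
      v <- rep(neutral, nrow(offs))
      v[inside] <- maps[[k]][cbind(rr[inside], cc[inside])]
      out[ci, k] <- mean(v)
    }
  }
  out
}
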
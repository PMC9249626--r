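## Morphology-based cell typing: four nuclear features, a quadratic
## Gaussian (QDA) classifier with uniform priors, posterior smoothing in
## log space across the tissue, and class-specific cytoplasmic expansion.

#' Extract morphology features per segmented nucleus
#'
#' One row per label: pixel area, mean counterstain intensity,
#' eccentricity of the moment-equivalent ellipse, and perimeter-to-area
#' ratio. Perimeter uses a boundary-step estimator: the 4-neighbour crack
#' length scaled by pi/4, which is exact in expectation for smooth convex
#' regions (the elliptical nuclei this targets).
#'
#' @param labels integer label matrix
#' @param channel nuclear channel matrix (same shape)
#' @return data.frame with columns `label`, `area`, `mean_intensity`,
#'   `eccentricity`, `perim_area`, `centroid_r`, `centroid_c`
#' @export
extract_features <- function(labels, channel) {
  stopifnot(all(dim(labels) == dim(channel)))
  n <- max(labels)
  empty <- data.frame(label = integer(0), area = numeric(0),
                      mean_intensity = numeric(0), eccentricity = numeric(0),
                      perim_area = numeric(0), centroid_r = numeric(0),
                      centroid_c = numeric(0))
  if (n == 0L) return(empty)
  idx <- which(labels > 0L)
  l <- labels[idx]
  nr <- nrow(labels)
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L

  area <- tabulate(l, nbins = n)
  present <- which(area > 0L)
  s_int <- rowsum(channel[idx], l)[, 1]
  s_r <- rowsum(as.numeric(r), l)[, 1]
  s_c <- rowsum(as.numeric(cc), l)[, 1]
  a <- area[present]
  mr <- s_r / a
  mc <- s_c / a
  # central second moments
  key <- match(l, present)
  dr <- r - mr[key]
  dc <- cc - mc[key]
  mu20 <- rowsum(dr * dr, l)[, 1] / a
  mu02 <- rowsum(dc * dc, l)[, 1] / a
  mu11 <- rowsum(dr * dc, l)[, 1] / a
  tr <- mu20 + mu02
  det_ <- mu20 * mu02 - mu11^2
  disc <- sqrt(pmax(tr^2 / 4 - det_, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  ecc <- ifelse(l1 > 0, sqrt(pmax(1 - l2 / pmax(l1, .Machine$double.eps), 0)), 0)

  # crack-length perimeter: count label/non-label 4-neighbour edges
  crack <- numeric(n)
  pad <- rbind(0L, cbind(0L, labels, 0L), 0L)
  for (sh in list(c(0, 1), c(2, 1), c(1, 0), c(1, 2))) {
    nb <- pad[(1:nrow(labels)) + sh[1], (1:ncol(labels)) + sh[2], drop = FALSE]
    diff_edge <- labels > 0L & nb != labels
    if (any(diff_edge)) {
      cr <- rowsum(rep(1, sum(diff_edge)), labels[diff_edge])
      crack[as.integer(rownames(cr))] <- crack[as.integer(rownames(cr))] + cr[, 1]
    }
  }
  perim <- crack[present] * pi / 4

  data.frame(label = present, area = as.numeric(a),
             mean_intensity = s_int / a, eccentricity = ecc,
             perim_area = perim / a, centroid_r = mr, centroid_c = mc)
}

.feature_cols <- c("area", "mean_intensity", "eccentricity", "perim_area")

.features_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  as.matrix(features[, .feature_cols, drop = FALSE])
}

#' Fit a quadratic Gaussian classifier
#'
#' Per class: sample mean and covariance of the four morphology features;
#' near-singular covariances are regularised by adding
#' `1e-6 * trace/4` to the diagonal. Priors are uniform by default, as the
#' classifier is typically trained on a class-balanced annotation set.
#' Features are used unscaled.
#'
#' @param features feature data.frame (from [extract_features()]) or
#'   numeric matrix with one row per training cell
#' @param classes character/factor of training classes; every level must
#'   have at least 5 cells
#' @param priors named prior vector (defaults to uniform over the classes)
#' @return object of class `qda_model`
#' @export
fit_qda <- function(features, classes, priors = NULL) {
  x <- .features_matrix(features)
  classes <- as.character(classes)
  lev <- unique(classes)
  cnt <- table(factor(classes, levels = lev))
  if (any(cnt < 5L))
    stop("need >= 5 training cells per class; too few for: ",
         paste(names(cnt)[cnt < 5L], collapse = ", "))
  if (is.null(priors)) priors <- setNames(rep(1 / length(lev), length(lev)), lev)
  priors <- priors[lev] / sum(priors[lev])
  d <- ncol(x)
  fit1 <- function(k) {
    xi <- x[classes == k, , drop = FALSE]
    mu <- colMeans(xi)
    S <- cov(xi)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch) || kappa(S) > 1e10) {
      eps <- 1e-6 * sum(diag(S)) / d
      S <- S + diag(eps, d)
      ch <- tryCatch(chol(S), error = function(e) NULL)
      if (is.null(ch))
        stop("degenerate training data for class '", k,
             "': singular covariance")
    }
    list(mu = mu, sigma = S, chol = ch,
         logdet = 2 * sum(log(diag(ch))))
  }
  structure(list(classes = lev, priors = priors,
                 pars = setNames(lapply(lev, fit1), lev), d = d),
            class = "qda_model")
}

#' Log class-conditional Gaussian densities
#'
#' @param model a `qda_model`
#' @param features feature table or matrix
#' @return matrix cells x classes of log densities (including the
#'   -d/2 log(2 pi) constant)
#' @export
qda_log_density <- function(model, features) {
  x <- .features_matrix(features)
  d <- model$d
  out <- sapply(model$classes, function(k) {
    p <- model$pars[[k]]
    xc <- sweep(x, 2, p$mu)
    z <- backsolve(p$chol, t(xc), transpose = TRUE)
    q <- colSums(z^2)
    -0.5 * (d * log(2 * pi) + p$logdet + q)
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(x))
  colnames(out) <- model$classes
  out
}

#' Class posterior probabilities
#'
#' p(k | x) proportional to prior_k |Sigma_k|^(-1/2)
#' exp(-(x-mu_k)' Sigma_k^-1 (x-mu_k) / 2), normalised per cell and
#' computed in log space (log-sum-exp) for stability.
#'
#' @inheritParams qda_log_density
#' @return matrix cells x classes; rows sum to 1
#' @export
qda_posteriors <- function(model, features) {
  ld <- qda_log_density(model, features)
  lp <- sweep(ld, 2, log(model$priors), "+")
  mx <- apply(lp, 1, max)
  w <- exp(lp - mx)
  w / rowSums(w)
}

#' Serialise / restore a fitted classifier as JSON
#'
#' @param model a `qda_model`
#' @param path file path
#' @return `qda_write_json` returns `path` invisibly;
#'   `qda_read_json` returns the restored `qda_model`
#' @export
qda_write_json <- function(model, path) {
  obj <- list(classes = model$classes, priors = as.list(model$priors),
              d = model$d,
              pars = lapply(model$pars, function(p)
                list(mu = p$mu, sigma = p$sigma)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname qda_write_json
#' @export
qda_read_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lev <- obj$classes
  pars <- setNames(lapply(lev, function(k) {
    mu <- as.numeric(obj$pars[[k]]$mu)
    S <- matrix(as.numeric(unlist(obj$pars[[k]]$sigma)), obj$d, obj$d)
    ch <- chol(S)
    list(mu = mu, sigma = S, chol = ch, logdet = 2 * sum(log(diag(ch))))
  }), lev)
  structure(list(classes = lev, priors = unlist(obj$priors)[lev],
                 pars = pars, d = obj$d),
            class = "qda_model")
}

#' Smooth class posteriors across the tissue
#'
#' Builds one raster map per class carrying each cell's log posterior on
#' its labelled pixels (background pixels hold the neutral value
#' log(1/K) so the filter pulls isolated cells toward the uniform
#' distribution rather than toward any class), low-pass filters each map
#' with a uniform disk mean of the given radius, reads the smoothed
#' values at the cell centroids, and renormalises across classes.
#' Cells co-localise by type, so this propagates label evidence to
#' uncertain neighbours while a confidently classified cell retains its
#' class. Disable for tissues where neighbouring cells are of diverse
#' types.
#'
#' @param post posterior matrix (cells x classes), rows summing to 1
#' @param features feature table with `label`, `centroid_r`, `centroid_c`
#' @param labels label matrix the posteriors refer to
#' @param radius disk kernel radius in pixels; `<= 0` skips smoothing
#'   with a warning
#' @return list with `posteriors` (smoothed, renormalised) and `class`
#'   (final argmax label per cell)
#' @export
spatial_smooth <- function(post, features, labels, radius = 100) {
  K <- ncol(post)
  cls <- colnames(post)
  if (radius <= 0) {
    warning("non-positive smoothing radius; smoothing skipped")
    return(list(posteriors = post,
                class = cls[max.col(post, ties.method = "first")]))
  }
  nr <- nrow(labels); nc <- ncol(labels)
  radius <- min(radius, floor((min(nr, nc) - 1) / 2))
  kern <- disk_kernel(radius)
  kern <- kern / sum(kern)
  neutral <- log(1 / K)
  lp <- log(pmax(post, 1e-300))
  idx <- which(labels > 0L)
  key <- match(labels[idx], features$label)
  sm <- matrix(0, nrow(post), K, dimnames = list(NULL, cls))
  ctr <- cbind(pmin(pmax(round(features$centroid_r), 1L), nr),
               pmin(pmax(round(features$centroid_c), 1L), nc))
  for (k in seq_len(K)) {
    mp <- matrix(neutral, nr, nc)
    mp[idx] <- lp[key, k]
    f <- .mat(EBImage::filter2(mp, kern, boundary = neutral))
    sm[, k] <- f[ctr]
  }
  mx <- apply(sm, 1, max)
  w <- exp(sm - mx)
  w <- w / rowSums(w)
  list(posteriors = w, class = cls[max.col(w, ties.method = "first")])
}

#' Expand nuclear segments to cover the cytoplasm
#'
#' Each cell's label grows into unlabelled pixels within its class radius
#' of the original segment (defaults 20/5/5 px for cancer/immune/stromal,
#' matching the larger cytoplasm of carcinoma cells). A contested pixel
#' goes to the cell whose original segment is nearest in exact Euclidean
#' distance; remaining ties go to the lower label id. Original labelled
#' pixels never change, so expanded regions are disjoint and contain
#' their nuclei. Artifact classes are not expanded.
#'
#' @param labels integer label matrix
#' @param classes character vector of cell classes indexed by label id,
#'   or a data.frame with columns `label` and `class`
#' @param radii named expansion radii per class (px); classes missing
#'   from `radii` (e.g. artifacts) are not expanded
#' @return expanded label matrix
#' @export
expand_segments <- function(labels, classes,
                            radii = c(cancer = 20, immune = 5, stromal = 5)) {
  n <- max(labels)
  if (n == 0L) return(labels)
  if (is.data.frame(classes)) {
    cl <- rep(NA_character_, n)
    cl[classes$label] <- as.character(classes$class)
  } else {
    cl <- as.character(classes)
    if (length(cl) != n)
      stop("'classes' must give a class for every label id")
  }
  if (anyNA(cl[tabulate(labels[labels > 0], nbins = n) > 0]))
    stop("every present label needs a class")
  max_dist <- unname(radii[cl])
  max_dist[is.na(max_dist)] <- 0
  claimed <- assign_nearest_label_cpp(labels, labels == 0L, max_dist)
  out <- labels
  sel <- claimed > 0L
  out[sel] <- claimed[sel]
  out
}
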
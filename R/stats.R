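## Expression statistics: area-weighted summaries, the mean-independent
## expression-variability factor, linear-time nested ANOVA, and
## classification precision.

#' Area-weighted mean expression
#'
#' m = sum_i (Area_i / sum Area) * (Intensity_i / Area_i)
#'   = sum Intensity / sum Area.
#' Weighting by cell area gives more weight to the larger cancer cells,
#' where the per-cell average is most reliable.
#'
#' @param area per-cell quantified areas (px^2), all > 0
#' @param intensity per-cell summed signal intensities
#' @return weighted mean in intensity units
#' @export
weighted_mean_expr <- function(area, intensity) {
  if (!length(area)) stop("no cells for summary")
  stopifnot(length(area) == length(intensity), all(area > 0))
  sum(intensity) / sum(area)
}

#' Area-weighted expression variance
#'
#' v = sum_i (Area_i / sum Area) * (Intensity_i / Area_i - m)^2
#' with m the weighted mean of the same cells.
#'
#' @inheritParams weighted_mean_expr
#' @param m optional precomputed weighted mean
#' @return weighted variance (intensity units squared)
#' @export
weighted_var_expr <- function(area, intensity, m = NULL) {
  if (!length(area)) stop("no cells for summary")
  stopifnot(length(area) == length(intensity), all(area > 0))
  if (is.null(m)) m <- weighted_mean_expr(area, intensity)
  w <- area / sum(area)
  sum(w * (intensity / area - m)^2)
}

#' Fit the expression-variability factor
#'
#' Expression variance is mean-linked, so raw variances are not
#' comparable across samples. The variability factor generalises the
#' Fano factor to a fitted power law: ordinary least squares of
#' log10 v on log10 m across samples (per gene), with the factor of
#' sample j defined as the residual
#' log10 v_j - (alpha + beta * log10 m_j). Samples with v = 0 cannot
#' enter the log-space fit; they are excluded and assigned the minimum
#' observed factor with a warning. Samples with m <= 0 are excluded and
#' reported as NA.
#'
#' @param m per-sample weighted means
#' @param v per-sample weighted variances
#' @return list with `alpha` (intercept), `beta` (slope), `factor`
#'   (per-sample residuals, same order as input), `used` (logical),
#'   `n_used`
#' @export
fit_variability_factor <- function(m, v) {
  stopifnot(length(m) == length(v))
  used <- is.finite(m) & is.finite(v) & m > 0 & v > 0
  if (sum(used) < 3L) stop("need >= 3 samples with positive mean and variance")
  lx <- log10(m[used])
  ly <- log10(v[used])
  if (sd(lx) == 0) stop("mean effect unidentifiable: zero spread in log mean")
  beta <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  alpha <- mean(ly) - beta * mean(lx)
  fac <- rep(NA_real_, length(m))
  fac[used] <- ly - (alpha + beta * lx)
  degenerate <- is.finite(m) & m > 0 & is.finite(v) & v == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " sample(s) with zero variance assigned the ",
            "minimum observed variability factor")
    fac[degenerate] <- min(fac[used])
  }
  list(alpha = alpha, beta = beta, factor = fac, used = used,
       n_used = sum(used))
}

#' Nested analysis of variance in linear time
#'
#' ANOVA for nested factorial designs (e.g. patient > phase > spot with
#' cell-level replicates). Sums of squares are computed from streaming
#' group means, one pass per nesting level, instead of a dense design
#' matrix - linear rather than cubic time in the number of levels. Each
#' factor's F statistic is taken against the within-innermost-group
#' residual mean square, matching a sequential least-squares fit of the
#' nested model. A factor contributing no additional levels is reported
#' as not estimable; with zero residual variance F is undefined and
#' flagged.
#'
#' @param y numeric response (e.g. per-cell intensities)
#' @param factors list of factors ordered coarse to fine; factor k+1 is
#'   read as nested within factors 1..k
#' @return data.frame with one row per factor plus a `residual` row:
#'   `term`, `df`, `ss`, `ms`, `f`, `p`, `estimable`
#' @export
nested_anova <- function(y, factors) {
  stopifnot(is.list(factors), length(factors) >= 1L)
  n <- length(y)
  for (f in factors) stopifnot(length(f) == n)
  labs <- names(factors) %||% paste0("factor", seq_along(factors))

  key <- rep("", n)
  grand <- mean(y)
  prev_fit <- rep(grand, n) # fitted values at the coarser level
  prev_levels <- 1L
  rows <- list()
  for (k in seq_along(factors)) {
    key <- paste(key, as.character(factors[[k]]), sep = "\r")
    g <- match(key, unique(key))
    gm <- rowsum(y, g)[, 1] / tabulate(g)
    fit <- gm[g]
    ss <- sum((fit - prev_fit)^2)
    df <- length(gm) - prev_levels
    rows[[k]] <- data.frame(term = labs[k], df = df, ss = ss)
    prev_fit <- fit
    prev_levels <- length(gm)
  }
  ss_res <- sum((y - prev_fit)^2)
  df_res <- n - prev_levels
  out <- do.call(rbind, rows)
  out$ms <- ifelse(out$df > 0, out$ss / out$df, NA_real_)
  ms_res <- if (df_res > 0) ss_res / df_res else NA_real_
  out$f <- ifelse(out$df > 0 & is.finite(ms_res) & ms_res > 0,
                  out$ms / ms_res, NA_real_)
  out$p <- ifelse(is.finite(out$f), pf(out$f, out$df, df_res, lower.tail = FALSE),
                  NA_real_)
  out$estimable <- out$df > 0
  rbind(out, data.frame(term = "residual", df = df_res, ss = ss_res,
                        ms = ms_res, f = NA_real_, p = NA_real_,
                        estimable = df_res > 0))
}

#' Classification precision
#'
#' Precision = TP / (TP + FP) of predicted positive calls against
#' annotations (e.g. predicted cancer cells vs pathologist-annotated
#' cancer cells).
#'
#' @param annotated logical vector: cell truly belongs to the target class
#' @param predicted logical vector: cell called as the target class
#' @return list with `tp`, `fp`, `precision`
#' @export
precision_score <- function(annotated, predicted) {
  stopifnot(length(annotated) == length(predicted))
  tp <- sum(predicted & annotated)
  fp <- sum(predicted & !annotated)
  if (tp + fp == 0) stop("undefined precision: no predicted positives")
  list(tp = tp, fp = fp, precision = tp / (tp + fp))
}

#' Summarise spots and patients from a cohort cell table
#'
#' Computes the per-spot and per-patient weighted mean and variance over
#' the quantified cells of the requested classes (cancer cells by
#' default). Patient summaries pool all QC-passing spots' cells, cells
#' weighted by area across spots.
#'
#' @param cells data.frame with `patient_id`, `spot_id`, `class`, `area`,
#'   `intensity`
#' @param classes cell classes included in the summaries
#' @param qc optional QC table from [spot_qc_ppib()]; failing spots are
#'   excluded from patient summaries
#' @return list with `spots` and `patients` data.frames (columns
#'   `m`, `v`, `n_cells`)
#' @export
summarize_expression <- function(cells, classes = "cancer", qc = NULL) {
  keep <- cells$class %in% classes & cells$area > 0
  cc <- cells[keep, , drop = FALSE]
  if (!nrow(cc)) stop("no cells for summary")
  spot_key <- interaction(cc$patient_id, cc$spot_id, drop = TRUE)
  spots <- do.call(rbind, lapply(split(cc, spot_key), function(d) {
    m <- weighted_mean_expr(d$area, d$intensity)
    data.frame(patient_id = d$patient_id[1], spot_id = d$spot_id[1],
               m = m, v = weighted_var_expr(d$area, d$intensity, m),
               n_cells = nrow(d))
  }))
  rownames(spots) <- NULL
  if (!is.null(qc)) {
    ok <- qc$spot_id[qc$pass]
    cc <- cc[cc$spot_id %in% ok, , drop = FALSE]
    if (!nrow(cc)) stop("no cells left after QC")
  }
  patients <- do.call(rbind, lapply(split(cc, cc$patient_id), function(d) {
    m <- weighted_mean_expr(d$area, d$intensity)
    data.frame(patient_id = d$patient_id[1], m = m,
               v = weighted_var_expr(d$area, d$intensity, m),
               n_spots = length(unique(d$spot_id)), n_cells = nrow(d))
  }))
  rownames(patients) <- NULL
  list(spots = spots, patients = patients)
}
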
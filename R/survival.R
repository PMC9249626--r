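## Survival analysis: Kaplan-Meier curves and log-rank tests (via the
## survival package) and expression grouping: median split and optimised
## three-way split with Benjamini-Hochberg control over the candidate
## family.

.surv_check <- function(time, event) {
  if (any(time < 0)) stop("negative survival times")
  stopifnot(length(time) == length(event))
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator; censored records reduce the risk set without
#' producing steps. The curve is right-continuous, non-increasing and
#' starts at 1.
#'
#' @param time follow-up times (months)
#' @param event event indicator (1 = progression/death observed)
#' @param group grouping factor (single group if omitted)
#' @return data.frame with `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`
#' @export
km_estimate <- function(time, event, group = NULL) {
  .surv_check(time, event)
  if (is.null(group)) group <- rep("all", length(time))
  fit <- survival::survfit(survival::Surv(time, event) ~ g,
                           data = data.frame(time = time, event = event,
                                             g = factor(group)))
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(levels(factor(group))[1], length(s$time))
         else sub("^g=", "", as.character(s$strata))
  data.frame(group = grp, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, n_censor = s$n.censor, surv = s$surv)
}

#' Log-rank test
#'
#' k-group observed-vs-expected statistic over pooled event times with
#' k - 1 degrees of freedom.
#'
#' @inheritParams km_estimate
#' @return list with `chisq`, `df`, `p`
#' @export
logrank_test <- function(time, event, group) {
  .surv_check(time, event)
  g <- factor(group)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (sum(event) < 1L) stop("test undefined: no events")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g,
                           data = data.frame(time = time, event = event,
                                             g = g))
  df <- length(sd$n) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Median split survival comparison
#'
#' Two groups at the median expression; a patient exactly at the median
#' goes to the low group (<= convention).
#'
#' @param values per-patient expression values (or variability factors)
#' @inheritParams km_estimate
#' @return list with `threshold`, `group`, `n`, test results `chisq`, `p`
#' @export
median_split <- function(values, time, event) {
  stopifnot(length(values) == length(time))
  if (length(values) < 2L) stop("need at least 2 patients")
  if (diff(range(values)) <= 0) stop("all values equal: no split possible")
  med <- median(values)
  grp <- ifelse(values <= med, "low", "high")
  if (length(unique(grp)) < 2L)
    stop("median split produced an empty group (ties at the median)")
  lr <- logrank_test(time, event, grp)
  list(threshold = med, group = grp, n = table(grp)[c("low", "high")],
       chisq = lr$chisq, p = lr$p)
}

#' Optimised three-way expression split
#'
#' Sorted expression values define candidate cut pairs from a lattice of
#' cut fractions (default 5%-spaced over (20%, 80%), t1 < t2, truncated
#' to at most `max_candidates` evenly chosen pairs). For each candidate,
#' patients are grouped low/mid/high by expression rank (ties to the
#' lower group) and a log-rank p-value computed. All nominal p-values
#' are Benjamini-Hochberg adjusted as one family of the candidate splits
#' - explicitly controlling for the effect of optimising the threshold -
#' and the chosen split minimises the adjusted p (ties to the smaller
#' first threshold).
#'
#' @param values per-patient expression values
#' @inheritParams km_estimate
#' @param fractions optional two-column matrix of cut-fraction pairs
#'   overriding the default lattice
#' @param max_candidates cap on the candidate family size
#' @return list with `candidates` (data.frame of all tested splits) and
#'   `best` (row of the chosen split), plus the chosen `group` vector
#' @export
optimize_three_way_split <- function(values, time, event, fractions = NULL,
                                     max_candidates = 20) {
  stopifnot(length(values) == length(time))
  n <- length(values)
  if (is.null(fractions)) {
    fr <- seq(0.25, 0.75, by = 0.05)
    fractions <- as.matrix(expand.grid(f1 = fr, f2 = fr))
    fractions <- fractions[fractions[, 1] < fractions[, 2], , drop = FALSE]
    fractions <- fractions[order(fractions[, 1], fractions[, 2]), , drop = FALSE]
  }
  if (nrow(fractions) > max_candidates) {
    pick <- unique(round(seq(1, nrow(fractions), length.out = max_candidates)))
    fractions <- fractions[pick, , drop = FALSE]
  }
  srt <- sort(values)
  cand <- list()
  for (i in seq_len(nrow(fractions))) {
    f1 <- fractions[i, 1]; f2 <- fractions[i, 2]
    n1 <- max(1L, round(f1 * n)); n2 <- max(n1 + 1L, round(f2 * n))
    if (n2 >= n) next
    t1 <- srt[n1]; t2 <- srt[n2]
    grp <- ifelse(values <= t1, "low", ifelse(values <= t2, "mid", "high"))
    if (length(unique(grp)) < 3L) next
    lr <- tryCatch(logrank_test(time, event, grp), error = function(e) NULL)
    if (is.null(lr)) next
    cand[[length(cand) + 1L]] <- data.frame(
      f1 = f1, f2 = f2, t1 = t1, t2 = t2,
      n_low = sum(grp == "low"), n_mid = sum(grp == "mid"),
      n_high = sum(grp == "high"), chisq = lr$chisq, p = lr$p)
  }
  if (!length(cand)) stop("no candidate split yields 3 non-empty groups")
  tab <- do.call(rbind, cand)
  tab$p_adj <- p.adjust(tab$p, method = "BH")
  o <- order(tab$p_adj, tab$t1, tab$t2)
  best <- tab[o[1], ]
  grp <- ifelse(values <= best$t1, "low",
                ifelse(values <= best$t2, "mid", "high"))
  list(candidates = tab, best = best, group = grp)
}
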
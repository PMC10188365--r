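# Cohort aggregation and the rank-based group statistics used for XRI
# summaries: peak normalization, mean/sd/sem bands, windowed metrics,
# peak finding on recovered-time traces, and Kruskal-Wallis with Dunn's
# post hoc test (or a two-sided Wilcoxon rank-sum test for two groups).

#' Normalize a trace to its peak
#'
#' @param trace numeric trace.
#' @return trace divided by its maximum (max of output is 1), or `NULL` with
#'   a warning when the peak is not positive (excluded from averages).
#' @export
normalizeToPeak <- function(trace) {
  pk <- max(trace, na.rm = TRUE)
  if (!is.finite(pk) || pk <= 0) {
    warning("nonpositive peak: trace excluded from normalization")
    return(NULL)
  }
  trace / pk
}

#' Pointwise summary band of a trace cohort
#'
#' @param traces list of numeric traces on a shared grid (NULL entries are
#'   dropped), or a matrix with one column per trace.
#' @param grid the shared grid (fraction or recovered time).
#' @return data.frame with `grid`, `mean`, `sd` (n-1 denominator), `sem` and
#'   `n`.
#' @export
aggregateTraces <- function(traces, grid) {
  if (is.list(traces)) {
    traces <- traces[!vapply(traces, is.null, TRUE)]
    if (!length(traces)) stop("no unflagged traces to aggregate")
    traces <- do.call(cbind, traces)
  }
  if (nrow(traces) != length(grid)) stop("traces do not match the grid")
  n <- ncol(traces)
  mu <- rowMeans(traces)
  sdv <- if (n > 1) apply(traces, 1, stats::sd) else rep(0, nrow(traces))
  data.frame(grid = grid, mean = mu, sd = sdv, sem = sdv / sqrt(n), n = n)
}

#' Windowed summary metrics of a trace versus time
#'
#' @param time,value numeric vectors (a trace on a time axis, days).
#' @param window length-2 numeric, the closed time window, days.
#' @return list with `average` (mean over the window), `peak` (max) and
#'   `slope` (ordinary-least-squares slope of value vs time, per day).
#' @export
windowMetrics <- function(time, value, window) {
  keep <- time >= window[1] & time <= window[2]
  if (!any(keep)) stop("empty window")
  tt <- time[keep]; vv <- value[keep]
  slope <- if (length(tt) > 1 && diff(range(tt)) > 0) {
    sum((tt - mean(tt)) * (vv - mean(vv))) / sum((tt - mean(tt))^2)
  } else NA_real_
  list(average = mean(vv), peak = max(vv), slope = slope)
}

#' Local maxima of a trace versus time
#'
#' Peaks above a prominence threshold, in time order; supports reading out
#' multiple induction events (e.g. two stimulation pulses) from one trace.
#'
#' @param time,value numeric vectors.
#' @param minProminence minimum peak prominence; default a quarter of the
#'   trace's dynamic range.
#' @return data.frame with `time` and `value` per peak (0 rows for a flat
#'   trace).
#' @export
findSignalPeaks <- function(time, value,
                            minProminence = 0.25 * diff(range(value))) {
  if (!is.finite(minProminence) || minProminence <= 0)
    return(data.frame(time = numeric(), value = numeric()))
  pk <- pracma::findpeaks(value)
  if (is.null(pk)) return(data.frame(time = numeric(), value = numeric()))
  idx <- sort(pk[, 2])
  n <- length(value)
  # topographic prominence: drop to the deepest valley crossed before
  # reaching higher terrain, on the better of the two sides
  prom <- vapply(idx, function(p) {
    higherL <- which(value[seq_len(max(p - 1, 1))] > value[p])
    lmin <- min(value[(if (length(higherL)) max(higherL) else 1):p])
    higherR <- which(value[(p + 1):n] > value[p]) + p
    rmin <- min(value[p:(if (length(higherR)) min(higherR) else n)])
    value[p] - max(lmin, rmin)
  }, 0)
  keep <- prom >= minProminence
  data.frame(time = time[idx[keep]], value = value[idx[keep]])
}

#' Dunn's post hoc test on rank sums
#'
#' Pairwise z statistics on mean ranks after a Kruskal-Wallis analysis, with
#' tie correction; two-sided p values, reported raw and Holm-adjusted.
#'
#' @param values numeric vector of metric samples.
#' @param groups group labels (coerced to factor).
#' @param control optional control group label: only comparisons against the
#'   control are reported; default all pairs.
#' @return data.frame with `group1`, `group2`, `z`, `p`, `p_holm`.
#' @export
dunnTest <- function(values, groups, control = NULL) {
  g <- factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(r)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tieCorr
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  if (!is.null(control)) {
    if (!control %in% lev) stop("control group not found")
    keep <- pairs[1, ] == control | pairs[2, ] == control
    pairs <- pairs[, keep, drop = FALSE]
  }
  z <- vapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt(s2 * (1 / n[[a]] + 1 / n[[b]]))
    if (se == 0) 0 else (rbar[[a]] - rbar[[b]]) / se
  }, 0)
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p_holm = stats::p.adjust(p, "holm"), row.names = NULL)
}

#' Rank-based group comparison of a cohort metric
#'
#' Omnibus Kruskal-Wallis analysis of variance with Dunn's post hoc test
#' (all pairs, or against a named control group). For exactly two groups a
#' two-sided Wilcoxon rank-sum test is used instead.
#'
#' @param values numeric vector of metric samples.
#' @param groups group labels.
#' @param control optional control group for the Dunn comparisons.
#' @return list with `method`, `statistic`, `p` (omnibus or rank-sum) and,
#'   for more than two groups, `dunn` (the pairwise table). When every value
#'   is tied across all groups the statistic is 0 and p is 1.
#' @export
compareGroups <- function(values, groups, control = NULL) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need >= 2 groups")
  if (any(tapply(values, g, length) < 2L)) stop("every group needs n >= 2")
  if (length(unique(values)) == 1L) {
    out <- list(method = "kruskal-wallis", statistic = 0, p = 1)
    if (nlevels(g) > 2L)
      out$dunn <- dunnTest(values, g, control)
    return(out)
  }
  if (nlevels(g) == 2L) {
    wt <- stats::wilcox.test(values[g == levels(g)[1]],
                             values[g == levels(g)[2]],
                             alternative = "two.sided", exact = NULL)
    list(method = "wilcoxon-rank-sum",
         statistic = unname(wt$statistic), p = wt$p.value)
  } else {
    kw <- stats::kruskal.test(values, g)
    list(method = "kruskal-wallis+dunn",
         statistic = unname(kw$statistic), p = kw$p.value,
         dunn = dunnTest(values, g, control))
  }
}
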
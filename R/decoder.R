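# The core readout mathematics: half-splitting, cumulative line integrals,
# the fraction-of-HA-line-integral clock, the derivative signal, the optimal
# split-point search, baseline statistics and onset estimation.
#
# Discretization follows the displayed summation formulas: line integrals are
# left-Riemann sums sum(H(d) * delta_d); the derivative signal is formed from
# difference quotients of the two cumulative integrals on native samples
# (right-edge assignment) and linearly interpolated onto a uniform fraction
# grid. Profile samples are cell midpoints: after a split at a cell boundary,
# d starts at delta/2 on each half and the boundary sample belongs to neither.

#' Uniform fraction grid
#'
#' @param n number of grid points (default 201).
#' @return numeric grid from 0 to 1.
#' @export
fractionGridPoints <- function(n = 201L) seq(0, 1, length.out = n)

#' Split a line profile into two half profiles
#'
#' Splits at the sample boundary nearest `splitArc`; each half measures
#' distance outward from the split, starting at `delta/2` (midpoint
#' convention).
#'
#' @param profile a [LineProfile-class]
#' @param splitArc split position, um of arc (0 < splitArc < length).
#' @return list of two halves, each a list with `d`, `intensities`, `delta`.
#' @export
splitProfile <- function(profile, splitArc) {
  n <- length(profile@d)
  dd <- profile@delta
  L <- n * dd
  if (splitArc <= 0 || splitArc >= L) stop("split outside the profile")
  k <- min(max(round(splitArc / dd), 1L), n - 1L)
  left <- list(d = (seq_len(k) - 0.5) * dd,
               intensities = profile@intensities[k:1, , drop = FALSE],
               delta = dd)
  right <- list(d = (seq_len(n - k) - 0.5) * dd,
                intensities = profile@intensities[(k + 1):n, , drop = FALSE],
                delta = dd)
  list(left = left, right = right, boundary = k)
}

#' Fraction of the constitutive line integral along a half profile
#'
#' Left-Riemann cumulative sum of the constitutive channel, normalized to 1
#' at the filament end: the molecular clock axis.
#'
#' @param half one half from [splitProfile()].
#' @param channel constitutive channel role (default `"HA"`).
#' @return numeric vector of fractions at the half's samples (right edges).
#' @export
fractionIntegral <- function(half, channel = "HA") {
  H <- half$intensities[, channel]
  cum <- cumsum(H) * half$delta
  tot <- cum[length(cum)]
  if (tot <= 0) stop("clock undefined: constitutive channel is all zero")
  cum / tot
}

# Derivative signal of one half on the shared fraction grid, or NULL when
# the clock is undefined. Clock increments below `minClockStep` (including
# zero increments) are merged forward into the following increments until
# each difference quotient carries at least that much of the clock; a
# trailing remainder folds into the last quotient. This regularizes the
# quotient where the constitutive channel is locally sparse.
halfSignal <- function(half, grid, constitutive, induced, minClockStep = 0.02) {
  H <- half$intensities[, constitutive]
  F <- half$intensities[, induced]
  if (length(H) < 3L) return(NULL)
  tot <- sum(H) * half$delta
  if (tot <= 0) return(NULL)
  x <- c(0, cumsum(H) * half$delta / tot)
  y <- c(0, cumsum(F) * half$delta)
  dx <- diff(x); dy <- diff(y)
  n <- length(dx)
  gx <- numeric(n); gy <- numeric(n)
  m <- 0L; ax <- 0; ay <- 0
  for (i in seq_len(n)) {
    ax <- ax + dx[i]; ay <- ay + dy[i]
    if ((ax > 0 && ax >= minClockStep) || (i == n && ax > 0 && m == 0L)) {
      m <- m + 1L
      gx[m] <- ax; gy[m] <- ay
      ax <- 0; ay <- 0
    }
  }
  if (m == 0L) return(NULL)
  if (ax > 0) {  # trailing remainder below the step: fold into last quotient
    gx[m] <- gx[m] + ax; gy[m] <- gy[m] + ay
  }
  xr <- cumsum(gx[seq_len(m)])
  q <- gy[seq_len(m)] / gx[seq_len(m)]
  if (length(xr) == 1L) return(rep(q, length(grid)))
  approx(xr, q, xout = grid, rule = 2)$y
}

#' Derivative signal of one half profile on a fraction grid
#'
#' The induced-channel intensity accumulation per unit of the fraction of the
#' constitutive line integral: difference quotients of the cumulative induced
#' integral with respect to the clock fraction, on native samples (right-edge
#' assignment, zero clock increments merged into the next nonzero one),
#' linearly interpolated onto the uniform grid.
#'
#' @param half one half from [splitProfile()].
#' @param grid uniform fraction grid.
#' @param constitutive,induced channel roles.
#' @param minClockStep minimum clock mass per difference quotient: native
#'   increments of the fraction axis below this (including zero increments,
#'   where the constitutive channel vanishes locally) are merged forward into
#'   the next quotient. Default 0.02 (each quotient carries at least 2% of
#'   the cumulative constitutive signal); 0 merges only zero increments.
#' @return numeric signal on `grid`.
#' @export
signalFromHalf <- function(half, grid = fractionGridPoints(),
                           constitutive = "HA", induced = "FLAG",
                           minClockStep = 0.02) {
  if (nrow(half$intensities) < 3L) stop("fewer than 3 native samples")
  s <- halfSignal(half, grid, constitutive, induced, minClockStep)
  if (is.null(s)) stop("clock undefined: constitutive channel is all zero")
  s
}

#' Decode the induced-tag signal of a line profile
#'
#' Searches every candidate split at native sample boundaries within
#' +/- 25% of the total length around the geometric center; for each split it
#' computes the derivative signal of both halves on the shared fraction grid
#' and their sum of squared differences (SSD); the split minimizing the SSD
#' wins (ties resolve to the split nearest the geometric center). The decoded
#' signal is the point-by-point mean of the two half signals at the optimal
#' split.
#'
#' @param profile a [LineProfile-class] with at least 8 samples.
#' @param constitutive constitutive channel role (default `"HA"`).
#' @param induced induced channel role (default `"FLAG"`).
#' @param grid uniform fraction grid (default [fractionGridPoints()]).
#' @param searchFraction half-width of the split search window as a fraction
#'   of the total length (default 0.25).
#' @param smoothSd optional Gaussian pre-smoothing of the raw profiles, in
#'   samples (default 0 = off).
#' @param minClockStep minimum clock mass per difference quotient (see
#'   [signalFromHalf()]).
#' @return a [DecodedSignal-class]
#' @export
decodeSignal <- function(profile, constitutive = "HA", induced = "FLAG",
                         grid = fractionGridPoints(), searchFraction = 0.25,
                         smoothSd = 0, minClockStep = 0.02) {
  n <- length(profile@d)
  if (n < 8L) stop("profile too short to decode (< 8 samples)")
  ints <- profile@intensities
  if (smoothSd > 0) {
    kw <- ceiling(3 * smoothSd)
    kern <- dnorm(-kw:kw, sd = smoothSd)
    kern <- kern / sum(kern)
    ints <- apply(ints, 2, function(v) {
      vv <- c(rep(v[1], kw), v, rep(v[length(v)], kw))
      as.numeric(stats::filter(vv, kern, sides = 2))[(kw + 1):(kw + n)]
    })
    colnames(ints) <- colnames(profile@intensities)
  }
  prof <- profile
  prof@intensities <- ints
  dd <- profile@delta
  L <- n * dd
  k0 <- round(n / 2)
  lo <- max(3L, ceiling((0.5 - searchFraction) * n))
  hi <- min(n - 3L, floor((0.5 + searchFraction) * n))
  if (lo > hi) stop("profile too short for the split search window")
  best <- NULL
  for (k in lo:hi) {
    halves <- splitProfile(prof, k * dd)
    s1 <- halfSignal(halves$left, grid, constitutive, induced, minClockStep)
    s2 <- halfSignal(halves$right, grid, constitutive, induced, minClockStep)
    if (is.null(s1) || is.null(s2)) next
    ssd <- sum((s1 - s2)^2)
    better <- is.null(best) || ssd < best$ssd - 1e-12 ||
      (abs(ssd - best$ssd) <= 1e-12 && abs(k - k0) < abs(best$k - k0))
    if (better) best <- list(k = k, ssd = ssd, s1 = s1, s2 = s2)
  }
  if (is.null(best))
    stop("no valid split: constitutive channel vanishes on every candidate half")
  new("DecodedSignal", grid = grid, values = (best$s1 + best$s2) / 2,
      tag = induced, splitArc = best$k * dd, splitIndex = as.integer(best$k),
      ssd = best$ssd, halves = cbind(left = best$s1, right = best$s2),
      meta = profile@meta)
}

#' Baseline of a decoded signal
#'
#' Mean of the decoded signal over the first `window` of the fraction grid
#' (the signal at the filament center, averaged over a short window for
#' noise robustness).
#'
#' @param signal a [DecodedSignal-class]
#' @param window fraction window width (default 0.05).
#' @return numeric baseline value.
#' @export
baselineValue <- function(signal, window = 0.05) {
  mean(signal@values[signal@grid <= window])
}

#' End/center ratio of a decoded signal
#'
#' Decoded induced signal near the filament end (fraction >= 1 - window)
#' divided by the baseline near the center. About 1 for uninduced filaments,
#' above 1 for late induction.
#'
#' @inheritParams baselineValue
#' @return numeric ratio; `NA` (with a warning) when the baseline is not
#'   positive.
#' @export
endCenterRatio <- function(signal, window = 0.05) {
  b <- baselineValue(signal, window)
  if (!is.finite(b) || b <= 0) {
    warning("nonpositive baseline: end/center ratio undefined")
    return(NA_real_)
  }
  mean(signal@values[signal@grid >= 1 - window]) / b
}

#' Relative change of a decoded signal from baseline
#'
#' `signal / baseline - 1` pointwise: 0 where expression matches the center
#' level. Invariant to overall intensity scaling.
#'
#' @inheritParams baselineValue
#' @return numeric trace on the fraction grid; `NA`s (with a warning) when
#'   the baseline is not positive.
#' @export
relativeChange <- function(signal, window = 0.05) {
  b <- baselineValue(signal, window)
  if (!is.finite(b) || b <= 0) {
    warning("nonpositive baseline: relative change undefined")
    return(rep(NA_real_, length(signal@grid)))
  }
  signal@values / b - 1
}

#' Estimate the onset fraction of an induced signal
#'
#' Subtracts the baseline, finds the peak of the net signal, fits an
#' ordinary-least-squares line to the initial rising phase (the portion of
#' the net signal between 10% and 50% of the peak immediately preceding it,
#' taken on the piecewise-linear decoded curve including the interpolated
#' 10% and 50% crossings) and extrapolates the line to net = 0. The crossing
#' fraction is the onset: the fraction of the HA line integral at which the
#' induced signal began to rise.
#'
#' @param signal a [DecodedSignal-class]
#' @param noiseFactor rise detection threshold: the net peak must exceed
#'   `noiseFactor` times the noise sd (default 3).
#' @param window baseline window on the fraction grid (default 0.05).
#' @param noiseFrom noise sd estimator. `"diff"`: robust sd (MAD/sqrt(2))
#'   of first differences of the decoded trace decimated to the native
#'   quotient spacing -- insensitive to the rising phase, which occupies a
#'   minority of steps. `"halves"`: half the sd of the difference between
#'   the two half-filament signals (can underestimate, since the optimal
#'   split is chosen to make the halves agree). `"window"`: sd of the
#'   first-window samples only. `"auto"` (default): the largest of the
#'   three -- each catches fluctuation structure the others miss (fast
#'   speckle, arm disagreement, baseline-window wander).
#' @param minRelRise minimum relative rise: when the baseline is positive
#'   (imaging profiles carry background and nonspecific staining), the net
#'   peak must also exceed `minRelRise * baseline` to count as an induction
#'   event (default 0.5). Inert for zero-baseline (noiseless density)
#'   profiles.
#' @return an [OnsetEstimate-class]; flagged `"no-rise"` when the peak does
#'   not clear the noise floor (e.g. uninduced controls), `"too-few-points"`
#'   or `"out-of-range"` when the fit is degenerate.
#' @export
estimateOnset <- function(signal, noiseFactor = 3, window = 0.05,
                          noiseFrom = c("auto", "diff", "halves", "window"),
                          minRelRise = 0.5) {
  noiseFrom <- match.arg(noiseFrom)
  g <- signal@grid
  v <- signal@values
  b <- mean(v[g <= window])
  sdDiff <- function() {
    dec <- max(1L, round(0.02 / (g[2] - g[1])))
    stats::mad(diff(v[seq(1L, length(v), by = dec)])) / sqrt(2)
  }
  sdHalves <- function() if (ncol(signal@halves) == 2L)
    stats::sd(signal@halves[, 1] - signal@halves[, 2]) / 2 else 0
  sdWindow <- function() stats::sd(v[g <= window])
  sdw <- switch(noiseFrom,
    auto = max(sdDiff(), sdHalves(), sdWindow(), na.rm = TRUE),
    diff = sdDiff(), halves = sdHalves(), window = sdWindow())
  if (!is.finite(sdw)) sdw <- 0
  net <- v - b
  peak <- max(net)
  flagged <- function(...) new("OnsetEstimate", fraction = NA_real_,
                               slope = NA_real_, intercept = NA_real_,
                               baseline = b, peak = peak,
                               flags = c(...))
  if (peak <= 0 || peak <= noiseFactor * sdw) return(flagged("no-rise"))
  if (b > 0 && peak <= minRelRise * b) return(flagged("no-rise"))
  ipk <- which.max(net)
  i <- ipk
  while (i > 1L && net[i - 1L] >= 0.5 * peak) i <- i - 1L
  xs <- numeric(); ys <- numeric()
  if (i > 1L) {  # 50%-of-peak crossing between i-1 and i
    x50 <- g[i - 1L] + (0.5 * peak - net[i - 1L]) /
      (net[i] - net[i - 1L]) * (g[i] - g[i - 1L])
    xs <- x50; ys <- 0.5 * peak
  }
  j <- i - 1L
  while (j >= 1L && net[j] >= 0.1 * peak && net[j] <= 0.5 * peak) {
    xs <- c(g[j], xs); ys <- c(net[j], ys)
    j <- j - 1L
  }
  if (j >= 1L && net[j] < 0.1 * peak) {  # 10%-of-peak crossing
    x10 <- g[j] + (0.1 * peak - net[j]) /
      (net[j + 1L] - net[j]) * (g[j + 1L] - g[j])
    xs <- c(x10, xs); ys <- c(0.1 * peak, ys)
  }
  if (length(xs) < 2L || diff(range(xs)) == 0) return(flagged("too-few-points"))
  mx <- mean(xs); my <- mean(ys)
  slope <- sum((xs - mx) * (ys - my)) / sum((xs - mx)^2)
  if (!is.finite(slope) || slope <= 0) return(flagged("no-rise"))
  intercept <- my - slope * mx
  onset <- -intercept / slope
  if (onset < 0 || onset > 1)
    return(new("OnsetEstimate", fraction = NA_real_, slope = slope,
               intercept = intercept, baseline = b, peak = peak,
               flags = "out-of-range"))
  new("OnsetEstimate", fraction = onset, slope = slope, intercept = intercept,
      baseline = b, peak = peak, flags = character())
}

#' Write decoded signals and their summaries to JSON
#'
#' Per XRI: the fraction grid, decoded signal, optimal split, half
#' disagreement, baseline, end/center ratio and the onset estimate with its
#' flags.
#'
#' @param signals list of [DecodedSignal-class]
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeDecoded <- function(signals, path) {
  if (is(signals, "DecodedSignal")) signals <- list(signals)
  entries <- lapply(signals, function(s) {
    est <- estimateOnset(s)
    list(tag = s@tag, grid = s@grid, signal = s@values,
         splitArc = s@splitArc, splitIndex = s@splitIndex, ssd = s@ssd,
         baseline = baselineValue(s),
         endCenterRatio = suppressWarnings(endCenterRatio(s)),
         onset = onsetValue(est), onsetFlags = as.list(onsetFlags(est)),
         meta = s@meta)
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
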
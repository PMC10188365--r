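# Monotone piecewise-linear map between experiment time and the fraction of
# the HA line integral, built from timed-induction cohorts: one knot per
# induction-time group at (time, mean onset fraction), anchored at fixation
# (fraction 1) and, by default, at the recording start (fraction 0).

#' Build a time calibration from timed-induction onset groups
#'
#' @param groups named list: induction time (days, as the name) ->
#'   numeric vector of unflagged onset-fraction estimates for that group.
#' @param tFix fixation day (terminal anchor at fraction 1).
#' @param tStart recording start day; when `originAnchor = TRUE` (default) an
#'   anchor knot (tStart, 0) is prepended so early fractions are mappable.
#' @param summary `"mean"` (default, matching the calibration construction)
#'   or `"median"`.
#' @param originAnchor include the (tStart, 0) anchor?
#' @return a [TimeCalibration-class]
#' @examples
#' cal <- buildCalibration(list(`3` = c(0.04, 0.06), `5` = 0.3), tFix = 7)
#' calibrationKnots(cal)
#' @export
buildCalibration <- function(groups, tFix, tStart = 3,
                             summary = c("mean", "median"),
                             originAnchor = TRUE) {
  summary <- match.arg(summary)
  groups <- groups[vapply(groups, length, 0L) > 0L]
  if (length(groups) < 2L) stop("need >= 2 induction-time groups")
  times <- as.numeric(names(groups))
  if (anyNA(times)) stop("group names must be induction times in days")
  ord <- order(times)
  times <- times[ord]
  fr <- vapply(groups[ord], function(v)
    if (summary == "mean") mean(v) else stats::median(v), 0)
  if (any(diff(fr) <= 0))
    stop("group mean fractions are not strictly increasing at time(s) ",
         paste(times[-1][diff(fr) <= 0], collapse = ", "))
  nvec <- vapply(groups[ord], length, 0L)
  times <- c(times, tFix); fr <- c(fr, 1); nvec <- c(nvec, 0L)
  if (originAnchor && tStart < times[1] && fr[1] > 0) {
    times <- c(tStart, times); fr <- c(0, fr); nvec <- c(0L, nvec)
  }
  new("TimeCalibration", times = times, fractions = fr,
      groupN = as.integer(nvec), tStart = tStart, tFix = tFix)
}

#' Convert onset fractions to recovered times
#'
#' Piecewise-linear interpolation between the calibration knots; outside the
#' knot span the terminal segments extend linearly, clamped to
#' `[tStart, tFix]`.
#'
#' @param calib a [TimeCalibration-class]
#' @param f onset fractions in [0, 1].
#' @return recovered times, days.
#' @export
fractionToTime <- function(calib, f) {
  t <- pwlin(calib@fractions, calib@times, f)
  pmin(pmax(t, calib@tStart), calib@tFix)
}

#' Convert times to expected onset fractions
#'
#' Exact inverse of [fractionToTime()] at and between the knots.
#'
#' @param calib a [TimeCalibration-class]
#' @param t times, days.
#' @return fractions in [0, 1].
#' @export
timeToFraction <- function(calib, t) {
  f <- pwlin(calib@times, calib@fractions, t)
  pmin(pmax(f, 0), 1)
}

# Piecewise-linear map through knots (x, y), with linear extension of the
# terminal segments outside the knot range.
pwlin <- function(x, y, xout) {
  n <- length(x)
  inner <- approx(x, y, xout = xout, rule = 2)$y
  sl1 <- (y[2] - y[1]) / (x[2] - x[1])
  sln <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  lo <- xout < x[1]
  hi <- xout > x[n]
  inner[lo] <- y[1] + sl1 * (xout[lo] - x[1])
  inner[hi] <- y[n] + sln * (xout[hi] - x[n])
  inner
}

#' Map a decoded signal onto the recovered-time axis
#'
#' Maps the fraction grid through [fractionToTime()] (values unchanged) and
#' resamples onto a uniform time grid for cohort averaging.
#'
#' @param signal a [DecodedSignal-class], or a numeric trace on `grid`.
#' @param calib a [TimeCalibration-class]
#' @param step uniform time-grid step, days (default 0.05).
#' @param grid fraction grid when `signal` is a plain numeric trace.
#' @return data.frame with `time` (days) and `value`.
#' @export
applyCalibration <- function(signal, calib, step = 0.05, grid = NULL) {
  if (is(signal, "DecodedSignal")) {
    grid <- signal@grid
    vals <- signal@values
  } else vals <- signal
  t <- fractionToTime(calib, grid)
  tg <- seq(calib@tStart, calib@tFix, by = step)
  data.frame(time = tg, value = approx(t, vals, xout = tg, rule = 2,
                                       ties = mean)$y)
}
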
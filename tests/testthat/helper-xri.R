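# Shared builders for the test suite. Everything is generated in code.

# A LineProfile with HA/FLAG channels from plain vectors.
mkProfile <- function(H, F, delta = 1, names = c("HA", "FLAG")) {
  mat <- cbind(H, F)
  colnames(mat) <- names
  new("LineProfile", d = (seq_along(H) - 0.5) * delta,
      intensities = mat, delta = delta, meta = list())
}

# A DecodedSignal wrapping given values on the default grid.
mkSignal <- function(values, grid = fractionGridPoints(length(values))) {
  new("DecodedSignal", grid = grid, values = values, tag = "FLAG",
      splitArc = 1, splitIndex = 1L, ssd = 0,
      halves = cbind(left = values, right = values), meta = list())
}

# Horizontal Gaussian ridge image: constant along x, Gaussian in y.
gaussRidge <- function(n = 100, px = 0.1, y0 = 5.05, sigma = 0.3,
                       amp = 100) {
  outer(seq_len(n), seq_len(n), function(i, j)
    amp * exp(-(((i - 0.5) * px - y0)^2) / (2 * sigma^2)))
}

# Standard constant-rate two-species program with induction at time ti.
stepProgram <- function(ti, r0 = 500, amp = r0 / 2) {
  list(speciesProgram("HA", "constitutive", r0),
       speciesProgram("FLAG", "induced", amp, tInduce = ti))
}

# Accelerating-clock program (exponential, a = 0.3/day).
accelProgram <- function(ti, r0 = 250, amp = r0 / 2) {
  list(speciesProgram("HA", "constitutive", r0, accel = "exponential",
                      accelRate = 0.3),
       speciesProgram("FLAG", "induced", amp, tInduce = ti))
}

# Ground-truth time calibration from the expected clock of a program.
exactCalibration <- function(constitutive, params, step = 0.2) {
  tt <- seq(params@tStart + step, params@tFix - step, by = step)
  fr <- vapply(tt, function(t) expectedOnsetFraction(
    list(constitutive, speciesProgram("probe", "induced", 1, tInduce = t)),
    params), 0)
  new("TimeCalibration", times = c(params@tStart, tt, params@tFix),
      fractions = c(0, fr, 1), groupN = integer(length(tt) + 2L),
      tStart = params@tStart, tFix = params@tFix)
}
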
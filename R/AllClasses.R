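#' @import methods
NULL

#' Expression program of one tagged monomer species
#'
#' Describes the incorporation-rate law of one epitope-tagged monomer species
#' feeding a growing XRI filament. Rates are per growing end, in monomers per
#' day. A species is either \emph{constitutive} (expressed from the start of
#' recording, optionally at an accelerating rate) or \emph{induced} (expressed
#' only after an induction event at \code{tInduce}).
#'
#' @slot tag character(1), epitope tag label (e.g. \code{"HA"}, \code{"FLAG"},
#'   \code{"V5"}).
#' @slot kind \code{"constitutive"} or \code{"induced"}.
#' @slot rate base rate r0 (constitutive) or amplitude (induced), monomers per
#'   day per growing end.
#' @slot accel acceleration form for constitutive species: \code{"constant"},
#'   \code{"linear"} or \code{"exponential"}.
#' @slot accelRate acceleration constant a (per day). For \code{"linear"} the
#'   rate is \code{r0 * (1 + a * (t - tStart))}; for \code{"exponential"} it is
#'   \code{r0 * exp(a * (t - tStart))} (rate r0 at recording onset).
#' @slot tInduce induction time (days after gene delivery) for induced species;
#'   \code{NA} for constitutive species.
#' @slot kernel induced-expression kernel: \code{"step"} (amplitude from
#'   \code{tInduce} onward) or \code{"alpha"} (pulse with finite rise and
#'   decay, peak-normalized to the amplitude).
#' @slot rise,decay alpha-kernel rise and decay constants (days).
#' @seealso [speciesProgram()]
#' @exportClass SpeciesProgram
setClass("SpeciesProgram",
  representation(
    tag = "character", kind = "character", rate = "numeric",
    accel = "character", accelRate = "numeric",
    tInduce = "numeric", kernel = "character",
    rise = "numeric", decay = "numeric"
  )
)

setValidity("SpeciesProgram", function(object) {
  msg <- character()
  if (length(object@tag) != 1L || !nzchar(object@tag))
    msg <- c(msg, "'tag' must be a single non-empty string")
  if (!object@kind %in% c("constitutive", "induced"))
    msg <- c(msg, "'kind' must be 'constitutive' or 'induced'")
  if (length(object@rate) != 1L || is.na(object@rate) || object@rate < 0)
    msg <- c(msg, "'rate' must be a single nonnegative number")
  if (object@kind == "constitutive" &&
      !object@accel %in% c("constant", "linear", "exponential"))
    msg <- c(msg, "'accel' must be 'constant', 'linear' or 'exponential'")
  if (object@kind == "induced") {
    if (length(object@tInduce) != 1L || is.na(object@tInduce))
      msg <- c(msg, "induced species needs a finite 'tInduce'")
    if (!object@kernel %in% c("step", "alpha"))
      msg <- c(msg, "'kernel' must be 'step' or 'alpha'")
    if (object@kernel == "alpha" && (object@rise <= 0 || object@decay <= 0))
      msg <- c(msg, "alpha kernel needs positive 'rise' and 'decay'")
  }
  if (length(msg)) msg else TRUE
})

#' Filament growth parameters
#'
#' Global parameters of XRI growth: the recording window and the monomer
#' geometry. Recording starts at \code{tStart} (the filament stabilizes about
#' 3 days after gene delivery) and ends at fixation \code{tFix}. Monomers sit
#' at a fixed longitudinal spacing (about 4 nm) and the filament grows from a
#' nucleation center on two sides.
#'
#' @slot tStart day recording starts (default 3).
#' @slot tFix fixation day (end of growth).
#' @slot spacing monomer-to-monomer distance, nm (default 4).
#' @slot dt simulation step, days (default 0.01).
#' @seealso [growthParams()]
#' @exportClass GrowthParams
setClass("GrowthParams",
  representation(tStart = "numeric", tFix = "numeric",
                 spacing = "numeric", dt = "numeric")
)

setValidity("GrowthParams", function(object) {
  msg <- character()
  if (!(object@tStart >= 0)) msg <- c(msg, "'tStart' must be >= 0")
  if (!(object@tFix > object@tStart)) msg <- c(msg, "'tFix' must exceed 'tStart'")
  if (!(object@dt > 0)) msg <- c(msg, "'dt' must be > 0")
  if (object@dt >= object@tFix - object@tStart)
    msg <- c(msg, "'dt' must be smaller than the recording window")
  if (!(object@spacing > 0)) msg <- c(msg, "'spacing' must be > 0")
  if (length(msg)) msg else TRUE
})

#' A simulated bidirectional monomer chain
#'
#' Ground-truth product of [simulateChain()]: the time-ordered tagged subunits
#' on the two sides of the nucleation center. On each side, the monomer at
#' integer index i (counting from 0 at the center) sits at physical position
#' (i + 0.5) * spacing nm from the center.
#'
#' @slot minus,plus data.frames with columns \code{tag}, \code{time} (day of
#'   addition) and \code{index} (0-based position index on that side).
#' @slot program list of [SpeciesProgram-class] objects used.
#' @slot params the [GrowthParams-class] used.
#' @slot seed integer seed the chain was drawn with.
#' @exportClass MonomerChain
setClass("MonomerChain",
  representation(minus = "data.frame", plus = "data.frame",
                 program = "list", params = "GrowthParams", seed = "integer")
)

setValidity("MonomerChain", function(object) {
  msg <- character()
  for (nm in c("minus", "plus")) {
    df <- slot(object, nm)
    if (!all(c("tag", "time", "index") %in% names(df))) {
      msg <- c(msg, sprintf("side '%s' needs columns tag/time/index", nm))
      next
    }
    if (nrow(df)) {
      if (!identical(df$index, seq_len(nrow(df)) - 1L))
        msg <- c(msg, sprintf("side '%s': indices must run 0,1,2,...", nm))
      if (is.unsorted(df$time))
        msg <- c(msg, sprintf("side '%s': addition times must be nondecreasing", nm))
      if (any(df$time < object@params@tStart))
        msg <- c(msg, sprintf("side '%s': additions before tStart", nm))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic imaging parameters
#'
#' Forward optics for rendering chains into images: pixel size, Gaussian PSF
#' width, per-channel gain, background level and noise model (Poisson shot
#' noise plus Gaussian read noise).
#'
#' @slot pixelSize um per pixel (default 0.1).
#' @slot psfSigma PSF standard deviation, um (default 0.15).
#' @slot gain intensity counts per monomer (default 25).
#' @slot background mean diffuse background counts per pixel (default 1).
#' @slot readNoise Gaussian read-noise sd, counts (default 2).
#' @slot bleed nonspecific staining fraction: every tag channel additionally
#'   receives this fraction of the total monomer density (antibody
#'   background binding tracks the protein filament), default 0.05.
#' @slot imageSize image side length, pixels (default 320).
#' @seealso [opticsParams()]
#' @exportClass OpticsParams
setClass("OpticsParams",
  representation(pixelSize = "numeric", psfSigma = "numeric", gain = "numeric",
                 background = "numeric", readNoise = "numeric",
                 bleed = "numeric", imageSize = "integer")
)

setValidity("OpticsParams", function(object) {
  msg <- character()
  if (!(object@pixelSize > 0)) msg <- c(msg, "'pixelSize' must be > 0")
  if (object@psfSigma < 0) msg <- c(msg, "'psfSigma' must be >= 0")
  if (object@gain < 0) msg <- c(msg, "'gain' must be >= 0")
  if (object@background < 0) msg <- c(msg, "'background' must be >= 0")
  if (object@readNoise < 0) msg <- c(msg, "'readNoise' must be >= 0")
  if (object@bleed < 0) msg <- c(msg, "'bleed' must be >= 0")
  if (object@imageSize < 16L) msg <- c(msg, "'imageSize' must be >= 16 px")
  if (length(msg)) msg else TRUE
})

#' Per-channel intensity profile along an XRI centerline
#'
#' The decoder's input: intensity versus arc distance along a drawn (or
#' traced) centerline, measured on a shared uniform arc grid for every
#' requested channel.
#'
#' @slot d arc positions, um, uniformly spaced.
#' @slot intensities numeric matrix, one column per channel (column names are
#'   channel roles, e.g. \code{"HA"}, \code{"FLAG"}).
#' @slot delta arc step, um.
#' @slot meta list of identifiers (cell id, xri id, measured width, ...).
#' @exportClass LineProfile
setClass("LineProfile",
  representation(d = "numeric", intensities = "matrix",
                 delta = "numeric", meta = "list")
)

setValidity("LineProfile", function(object) {
  msg <- character()
  n <- length(object@d)
  if (n < 2L) msg <- c(msg, "profile needs >= 2 samples")
  if (nrow(object@intensities) != n)
    msg <- c(msg, "'intensities' rows must match length(d)")
  if (is.null(colnames(object@intensities)))
    msg <- c(msg, "'intensities' columns must be named by channel role")
  if (!(object@delta > 0)) msg <- c(msg, "'delta' must be > 0")
  if (n >= 2L && max(abs(diff(object@d) - object@delta)) > 1e-6 * object@delta)
    msg <- c(msg, "'d' must be uniformly spaced with step 'delta'")
  if (length(msg)) msg else TRUE
})

#' Decoded induced-tag signal on the fraction-of-HA-line-integral grid
#'
#' The decoded expression-history trace: induced-tag intensity accumulation
#' per unit of the fraction of the constitutive (HA) line integral, on a
#' uniform grid over [0, 1] (0 = filament center / optimal split point,
#' 1 = filament end at fixation).
#'
#' @slot grid uniform fraction grid on [0, 1].
#' @slot values decoded signal values on the grid (point-by-point mean of the
#'   two half-filament signals).
#' @slot tag induced channel decoded.
#' @slot splitArc optimal split position, um of arc.
#' @slot splitIndex optimal split as a sample-boundary index.
#' @slot ssd sum of squared differences between the two half signals at the
#'   optimal split.
#' @slot halves two-column matrix of the two half signals on the grid.
#' @slot meta list of identifiers carried over from the profile.
#' @exportClass DecodedSignal
setClass("DecodedSignal",
  representation(grid = "numeric", values = "numeric", tag = "character",
                 splitArc = "numeric", splitIndex = "integer", ssd = "numeric",
                 halves = "matrix", meta = "list")
)

setValidity("DecodedSignal", function(object) {
  msg <- character()
  g <- object@grid
  if (length(g) < 3L || g[1] != 0 || g[length(g)] != 1 || any(diff(g) <= 0))
    msg <- c(msg, "'grid' must increase strictly from 0 to 1")
  if (length(object@values) != length(g))
    msg <- c(msg, "'values' must match the grid")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "'values' must be finite")
  if (length(msg)) msg else TRUE
})

#' Onset estimate of an induced expression event
#'
#' The fraction of the HA line integral at which the induced signal begins to
#' rise, obtained by fitting a line to the 10--50%-of-peak rising phase of the
#' baseline-subtracted signal and extrapolating it to zero.
#'
#' @slot fraction onset fraction in [0, 1] (NA when flagged).
#' @slot slope,intercept fitted rising-phase line (net signal vs fraction).
#' @slot baseline baseline value (signal near the filament center).
#' @slot peak peak of the net signal.
#' @slot flags character vector of quality flags; empty means a clean
#'   estimate. Possible flags: \code{"no-rise"}, \code{"too-few-points"},
#'   \code{"out-of-range"}.
#' @exportClass OnsetEstimate
setClass("OnsetEstimate",
  representation(fraction = "numeric", slope = "numeric", intercept = "numeric",
                 baseline = "numeric", peak = "numeric", flags = "character")
)

setValidity("OnsetEstimate", function(object) {
  if (length(object@flags) == 0L &&
      (is.na(object@fraction) || object@fraction < 0 || object@fraction > 1))
    "unflagged estimate must have 'fraction' in [0, 1]" else TRUE
})

#' Monotone map between experiment time and onset fraction
#'
#' Piecewise-linear calibration between time (days after gene delivery) and
#' the fraction of the HA line integral, built from timed-induction cohorts
#' and anchored at fixation (fraction 1) and optionally at the recording
#' start (fraction 0).
#'
#' @slot times knot times, days, strictly increasing.
#' @slot fractions knot fractions, strictly increasing, ending at 1 at tFix.
#' @slot groupN integer vector of per-knot sample sizes (0 for anchors).
#' @slot tStart,tFix recording window anchors, days.
#' @seealso [buildCalibration()]
#' @exportClass TimeCalibration
setClass("TimeCalibration",
  representation(times = "numeric", fractions = "numeric", groupN = "integer",
                 tStart = "numeric", tFix = "numeric")
)

setValidity("TimeCalibration", function(object) {
  msg <- character()
  if (length(object@times) != length(object@fractions) ||
      length(object@times) < 2L)
    msg <- c(msg, "need >= 2 matched knots")
  if (any(diff(object@times) <= 0))
    msg <- c(msg, "knot times must be strictly increasing")
  if (any(diff(object@fractions) <= 0))
    msg <- c(msg, "knot fractions must be strictly increasing")
  nk <- length(object@fractions)
  if (nk && abs(object@fractions[nk] - 1) > 1e-9)
    msg <- c(msg, "terminal knot fraction must be 1 (fixation)")
  if (nk && abs(object@times[nk] - object@tFix) > 1e-9)
    msg <- c(msg, "terminal knot time must be tFix")
  if (length(msg)) msg else TRUE
})
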
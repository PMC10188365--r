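# Accessor generics and show methods for the core classes.

#' Monomers on one side of a chain
#'
#' @param x a [MonomerChain-class]
#' @param side `"minus"` or `"plus"`
#' @return data.frame with columns `tag`, `time`, `index` and derived
#'   `position` (nm from the nucleation center).
#' @export
setGeneric("sideMonomers", function(x, side = c("minus", "plus"))
  standardGeneric("sideMonomers"))

#' @rdname sideMonomers
setMethod("sideMonomers", "MonomerChain", function(x, side = c("minus", "plus")) {
  side <- match.arg(side)
  df <- slot(x, side)
  df$position <- (df$index + 0.5) * x@params@spacing
  df
})

#' Number of monomers in a chain
#'
#' @param x a [MonomerChain-class]
#' @param tag optional tag label; when given, counts only that species.
#' @return integer count over both sides.
#' @export
setGeneric("monomerCount", function(x, tag = NULL) standardGeneric("monomerCount"))

#' @rdname monomerCount
setMethod("monomerCount", "MonomerChain", function(x, tag = NULL) {
  tags <- c(x@minus$tag, x@plus$tag)
  if (is.null(tag)) length(tags) else sum(tags == tag)
})

#' Tip-to-tip physical extent of a chain, nm
#' @param x a [MonomerChain-class]
#' @return numeric, nm (sum of both side lengths).
#' @export
setGeneric("chainExtent", function(x) standardGeneric("chainExtent"))

#' @rdname chainExtent
setMethod("chainExtent", "MonomerChain", function(x)
  (nrow(x@minus) + nrow(x@plus)) * x@params@spacing)

setMethod("show", "MonomerChain", function(object) {
  cat("MonomerChain:", nrow(object@minus), "monomers (-) /",
      nrow(object@plus), "monomers (+)\n")
  cat("  species:", paste(vapply(object@program, slot, "", "tag"),
                          collapse = ", "), "\n")
  cat(sprintf("  recording window: day %.2f to %.2f, spacing %.1f nm\n",
              object@params@tStart, object@params@tFix, object@params@spacing))
})

#' Arc positions of a line profile, um
#' @param x a [LineProfile-class]
#' @export
setGeneric("arcPositions", function(x) standardGeneric("arcPositions"))

#' @rdname arcPositions
setMethod("arcPositions", "LineProfile", function(x) x@d)

#' Arc step of a line profile, um
#' @param x a [LineProfile-class]
#' @export
setGeneric("arcStep", function(x) standardGeneric("arcStep"))

#' @rdname arcStep
setMethod("arcStep", "LineProfile", function(x) x@delta)

#' Total arc length of a line profile, um
#' @param x a [LineProfile-class]
#' @export
setGeneric("arcLength", function(x) standardGeneric("arcLength"))

#' @rdname arcLength
#' @details Samples are cell midpoints, so the covered length is
#'   `n * delta`.
setMethod("arcLength", "LineProfile", function(x) length(x@d) * x@delta)

#' Channel roles available in a profile
#' @param x a [LineProfile-class]
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname channelNames
setMethod("channelNames", "LineProfile", function(x) colnames(x@intensities))

#' Intensity trace of one channel
#' @param x a [LineProfile-class]
#' @param channel channel role name
#' @export
setGeneric("channelIntensity", function(x, channel)
  standardGeneric("channelIntensity"))

#' @rdname channelIntensity
setMethod("channelIntensity", "LineProfile", function(x, channel) {
  if (!channel %in% colnames(x@intensities))
    stop("unknown channel '", channel, "'")
  x@intensities[, channel]
})

setMethod("show", "LineProfile", function(object) {
  cat(sprintf("LineProfile: %d samples, step %.3f um, length %.2f um\n",
              length(object@d), object@delta, arcLength(object)))
  cat("  channels:", paste(colnames(object@intensities), collapse = ", "), "\n")
})

#' Fraction grid of a decoded signal
#' @param x a [DecodedSignal-class]
#' @export
setGeneric("fractionGrid", function(x) standardGeneric("fractionGrid"))

#' @rdname fractionGrid
setMethod("fractionGrid", "DecodedSignal", function(x) x@grid)

#' Values of a decoded signal on its fraction grid
#' @param x a [DecodedSignal-class]
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))

#' @rdname signalValues
setMethod("signalValues", "DecodedSignal", function(x) x@values)

#' Optimal split position of a decoded signal, um of arc
#' @param x a [DecodedSignal-class]
#' @export
setGeneric("splitArc", function(x) standardGeneric("splitArc"))

#' @rdname splitArc
setMethod("splitArc", "DecodedSignal", function(x) x@splitArc)

#' Half-disagreement (sum of squared differences) at the optimal split
#' @param x a [DecodedSignal-class]
#' @export
setGeneric("splitSSD", function(x) standardGeneric("splitSSD"))

#' @rdname splitSSD
setMethod("splitSSD", "DecodedSignal", function(x) x@ssd)

setMethod("show", "DecodedSignal", function(object) {
  cat(sprintf("DecodedSignal (%s): %d-point fraction grid\n",
              object@tag, length(object@grid)))
  cat(sprintf("  optimal split at %.2f um, SSD %.4g\n",
              object@splitArc, object@ssd))
})

#' Onset fraction of an estimate
#' @param x an [OnsetEstimate-class]
#' @export
setGeneric("onsetValue", function(x) standardGeneric("onsetValue"))

#' @rdname onsetValue
setMethod("onsetValue", "OnsetEstimate", function(x) x@fraction)

#' Quality flags of an onset estimate
#' @param x an [OnsetEstimate-class]
#' @return character vector; empty when the estimate is clean.
#' @export
setGeneric("onsetFlags", function(x) standardGeneric("onsetFlags"))

#' @rdname onsetFlags
setMethod("onsetFlags", "OnsetEstimate", function(x) x@flags)

setMethod("show", "OnsetEstimate", function(object) {
  if (length(object@flags)) {
    cat("OnsetEstimate: flagged (", paste(object@flags, collapse = ", "), ")\n")
  } else {
    cat(sprintf("OnsetEstimate: fraction %.4f (slope %.3g, baseline %.3g)\n",
                object@fraction, object@slope, object@baseline))
  }
})

#' Calibration knots
#' @param x a [TimeCalibration-class]
#' @return data.frame with columns `time`, `fraction`, `n`.
#' @export
setGeneric("calibrationKnots", function(x) standardGeneric("calibrationKnots"))

#' @rdname calibrationKnots
setMethod("calibrationKnots", "TimeCalibration", function(x)
  data.frame(time = x@times, fraction = x@fractions, n = x@groupN))

setMethod("show", "TimeCalibration", function(object) {
  cat(sprintf("TimeCalibration: %d knots over day %.2f..%.2f\n",
              length(object@times), object@times[1],
              object@times[length(object@times)]))
  print(calibrationKnots(object))
})
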
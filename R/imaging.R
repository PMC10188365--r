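# Synthetic multichannel microscopy: render simulated chains into image
# stacks with ground-truth manifests. Rendering is 2D (single optical slice):
# the decoder consumes 1D centerline profiles, so the volumetric stacks of a
# real confocal acquisition reduce to the analyzed in-plane profile.
#
# Image convention: matrices are [row = y, col = x]; the 1-based pixel
# (i, j) has its center at ((j - 0.5), (i - 0.5)) * pixelSize in um, i.e. at
# the 0-based pixel-center coordinate (j - 1, i - 1) used in centerline CSVs.

#' Construct synthetic imaging parameters
#'
#' @param pixelSize um per pixel.
#' @param psfSigma Gaussian PSF sd, um.
#' @param gain counts per monomer (default 25; bright antibody-amplified
#'   staining, filament ridge well above shot noise).
#' @param background mean diffuse background counts per pixel (default 1:
#'   confocal fields of immunostained tissue are nearly dark off the
#'   filament, so background is dominated by the filament-tracking
#'   nonspecific term `bleed`).
#' @param readNoise Gaussian read-noise sd, counts.
#' @param bleed nonspecific staining fraction: every tag channel receives
#'   this fraction of the total monomer density in addition to its own tag's
#'   density (immunostaining background binding tracks the dense protein
#'   filament). Default 0.05; set 0 for an ideal, perfectly specific stain.
#' @param imageSize image side, pixels (default 320, a 32 um field).
#' @return an [OpticsParams-class]
#' @export
opticsParams <- function(pixelSize = 0.1, psfSigma = 0.15, gain = 25,
                         background = 1, readNoise = 2, bleed = 0.05,
                         imageSize = 320L) {
  new("OpticsParams", pixelSize = pixelSize, psfSigma = psfSigma, gain = gain,
      background = background, readNoise = readNoise, bleed = bleed,
      imageSize = as.integer(imageSize))
}

#' Construct a smooth centerline curve from control points
#'
#' Fits interpolating splines through control points and returns a densely
#' sampled, arc-length-parameterized simple curve.
#'
#' @param control 2-column matrix of control points (x, y) in um.
#' @param n number of dense samples (default 1024).
#' @return list with `points` (dense polyline, um), `s` (cumulative arc
#'   length at each point) and `length` (total arc length, um).
#' @export
centerlineSpec <- function(control, n = 1024L) {
  if (nrow(control) < 2L) stop("need >= 2 control points")
  u <- seq(0, 1, length.out = nrow(control))
  uu <- seq(0, 1, length.out = n)
  x <- spline(u, control[, 1], xout = uu)$y
  y <- spline(u, control[, 2], xout = uu)$y
  pts <- cbind(x, y)
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  list(points = pts, s = s, length = s[length(s)])
}

# Position on the curve at arc length s (um), linear between dense samples.
curvePoint <- function(curve, s) {
  cbind(approx(curve$s, curve$points[, 1], xout = s, rule = 2)$y,
        approx(curve$s, curve$points[, 2], xout = s, rule = 2)$y)
}

#' Lay a chain out along a centerline curve
#'
#' Maps every monomer to a point mass on the curve: the nucleation center
#' lands at the curve's arc-length midpoint and the two sides extend in
#' opposite arc directions at the chain's physical spacing.
#'
#' @param chain a [MonomerChain-class]
#' @param curve a curve from [centerlineSpec()].
#' @param scale chain um per curve um (default 1, i.e. physical scale).
#' @return list with one element per tag: a 2-column matrix of point-mass
#'   coordinates (um); plus attributes `curve` and `centerArc`.
#' @export
layoutChain <- function(chain, curve, scale = 1) {
  sp <- chain@params@spacing / 1000 / scale  # um of curve per monomer step
  mid <- curve$length / 2
  need <- max(nrow(chain@minus), nrow(chain@plus)) * sp
  if (need > mid)
    stop("chain longer than curve: needs ", signif(2 * need, 3),
         " um of arc, curve has ", signif(curve$length, 3))
  tags <- unique(vapply(chain@program, slot, "", "tag"))
  out <- lapply(tags, function(tg) {
    sM <- mid - (chain@minus$index[chain@minus$tag == tg] + 0.5) * sp
    sP <- mid + (chain@plus$index[chain@plus$tag == tg] + 0.5) * sp
    curvePoint(curve, c(sM, sP))
  })
  names(out) <- tags
  attr(out, "curve") <- curve
  attr(out, "centerArc") <- mid
  out
}

# Accumulate point masses (um coords) into a pixel-count matrix.
binPoints <- function(pts, optics) {
  n <- optics@imageSize
  img <- matrix(0, n, n)
  if (!nrow(pts)) return(img)
  cc <- pmin(pmax(ceiling(pts[, 1] / optics@pixelSize), 1L), n)
  rr <- pmin(pmax(ceiling(pts[, 2] / optics@pixelSize), 1L), n)
  tab <- table(factor(rr, levels = seq_len(n)), factor(cc, levels = seq_len(n)))
  img + as.numeric(tab)
}

#' Render laid-out chain densities into a multichannel image
#'
#' Per channel: bin point masses to the pixel grid, convolve with the
#' Gaussian PSF, scale by the gain and add the background; then (unless
#' `noise = FALSE`) draw Poisson shot noise and add Gaussian read noise.
#' Channels are rendered independently.
#'
#' @param layout output of [layoutChain()], or a named list of point-mass
#'   matrices (um coordinates).
#' @param optics an [OpticsParams-class]
#' @param seed integer RNG seed for the noise draws.
#' @param noise draw noise? `FALSE` returns the expected image.
#' @param extraChannels named list of extra expected-intensity matrices to
#'   carry along (e.g. a soma-marker channel); they receive the same
#'   background and noise model.
#' @return named list of image matrices (counts).
#' @export
renderChannels <- function(layout, optics, seed = 1L, noise = TRUE,
                           extraChannels = list()) {
  sig <- optics@psfSigma / optics@pixelSize
  binned <- lapply(layout, binPoints, optics = optics)
  total <- Reduce(`+`, binned)
  expected <- lapply(binned, function(img) {
    img <- img + optics@bleed * total
    if (sig > 0 && any(img > 0)) img <- EBImage::gblur(img, sigma = sig)
    img * optics@gain + optics@background
  })
  for (nm in names(extraChannels))
    expected[[nm]] <- extraChannels[[nm]] + optics@background
  if (!noise) return(expected)
  withSeed(seed, lapply(expected, function(e) {
    matrix(rpois(length(e), pmax(e, 0)) +
             rnorm(length(e), sd = optics@readNoise), nrow(e), ncol(e))
  }))
}

# Soma-like blob (context channel) centered on the curve midpoint.
somaBlob <- function(curve, optics, amplitude = 60, sigmaUm = 3) {
  n <- optics@imageSize
  ctr <- curvePoint(curve, curve$length / 2)
  xs <- ((seq_len(n)) - 0.5) * optics@pixelSize
  dx2 <- outer(rep(1, n), (xs - ctr[1])^2)
  dy2 <- outer((xs - ctr[2])^2, rep(1, n))
  amplitude * exp(-(dx2 + dy2) / (2 * sigmaUm^2))
}

# Default growth/induction programs for the named fixture scenarios. The
# induced amplitude is half the constitutive rate, mirroring the diluted
# titer of the induced construct in the study designs; the 14-day in vivo
# scenario grows at a halved constant rate so filaments stay in the somatic
# size range over the doubled window.
scenarioProgram <- function(scenario, rate = 250, accel = "exponential",
                            accelRate = 0.3) {
  ha <- speciesProgram("HA", "constitutive", rate, accel = accel,
                       accelRate = accelRate)
  amp <- rate / 2
  if (grepl("^induction-day-[1-6]-of-7$", scenario)) {
    k <- as.numeric(sub("^induction-day-([1-6])-of-7$", "\\1", scenario))
    list(program = list(ha, speciesProgram("FLAG", "induced", amp,
                                           tInduce = k, kernel = "step")),
         params = growthParams(tFix = 7))
  } else if (scenario == "no-induction") {
    # the induced channel is still imaged (and is background-only)
    list(program = list(ha), params = growthParams(tFix = 7),
         channels = c("HA", "FLAG"))
  } else if (scenario == "cfos-single-pulse-day5") {
    list(program = list(ha, speciesProgram("V5", "induced", amp,
                                           tInduce = 5, kernel = "alpha")),
         params = growthParams(tFix = 7))
  } else if (scenario == "cfos-two-pulse-day5-day6") {
    list(program = list(ha,
           speciesProgram("V5", "induced", amp, tInduce = 5,
                          kernel = "alpha"),
           speciesProgram("V5", "induced", amp, tInduce = 6,
                          kernel = "alpha")),
         params = growthParams(tFix = 7))
  } else if (scenario == "invivo-day10-of-14") {
    list(program = list(
           speciesProgram("HA", "constitutive", rate / 2),
           speciesProgram("FLAG", "induced", rate / 4,
                          tInduce = 10, kernel = "step")),
         params = growthParams(tFix = 14))
  } else stop("unknown scenario '", scenario, "'")
}

# Gently curved fixture centerline spanning the image.
fixtureCurve <- function(optics, bend = 0.06, phase = 0) {
  span <- optics@imageSize * optics@pixelSize
  xs <- seq(0.1 * span, 0.9 * span, length.out = 9)
  ys <- span / 2 + bend * span * sin(seq(0, pi, length.out = 9) + phase)
  centerlineSpec(cbind(xs, ys))
}

#' Generate a named synthetic-microscopy fixture
#'
#' Simulates chains for a named experimental scenario, renders them into
#' multichannel TIFF images and writes the ground truth needed for parameter
#' recovery: chains (JSON), true centerlines (CSV, 0-based pixel-center
#' coordinates) and a manifest (JSON) with true induction times and expected
#' onset fractions.
#'
#' Scenarios mirror the study designs: timed chemical induction on day k of a
#' 7-day culture experiment (`"induction-day-k-of-7"`, k = 1..6), the
#' uninduced control (`"no-induction"`), activity-driven pulses
#' (`"cfos-single-pulse-day5"`, `"cfos-two-pulse-day5-day6"`) and the in vivo
#' design (`"invivo-day10-of-14"`, induction on day 10, fixation day 14).
#'
#' @param scenario scenario name (see Details).
#' @param seed master integer seed; per-chain streams are derived as
#'   `seed + 7919 * (chain index - 1)`.
#' @param dir output directory (created if missing).
#' @param nChains number of chains/images to render.
#' @param optics an [OpticsParams-class]
#' @param rate constitutive base rate, monomers/day/side.
#' @param accel,accelRate constitutive acceleration (defaults: exponential,
#'   a = 0.3 per day).
#' @param noise render with noise?
#' @return invisibly, the manifest as a list.
#' @export
makeFixture <- function(scenario, seed = 1L, dir, nChains = 5L,
                        optics = opticsParams(), rate = 250,
                        accel = "exponential", accelRate = 0.3,
                        noise = TRUE) {
  sc <- scenarioProgram(scenario, rate, accel, accelRate)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kinds <- vapply(sc$program, slot, "", "kind")
  induceTimes <- vapply(sc$program[kinds == "induced"], slot, 0, "tInduce")
  expFrac <- if (length(induceTimes)) vapply(induceTimes, function(ti) {
    pr <- list(sc$program[[which(kinds == "constitutive")[1]]],
               speciesProgram("tmp", "induced", 1, tInduce = ti))
    expectedOnsetFraction(pr, sc$params)
  }, 0) else numeric()
  tags <- sc$channels
  if (is.null(tags)) tags <- unique(vapply(sc$program, slot, "", "tag"))
  channelMap <- c(Nissl = 1L, stats::setNames(seq_along(tags) + 1L, tags))
  entries <- list()
  clines <- NULL
  for (i in seq_len(nChains)) {
    chSeed <- as.integer(seed + 7919 * (i - 1))
    chain <- simulateChain(sc$program, sc$params, seed = chSeed)
    curve <- fixtureCurve(optics, phase = (i %% 5) * 0.9)
    lay <- layoutChain(chain, curve)
    for (tg in setdiff(tags, c("Nissl", names(lay)))) {
      lay[[tg]] <- matrix(numeric(), 0, 2)
    }
    imgs <- renderChannels(lay, optics, seed = chSeed + 1L, noise = noise,
                           extraChannels = list(Nissl = somaBlob(curve, optics)))
    imgs <- imgs[names(channelMap)]
    imgFile <- file.path(dir, sprintf("chain%03d.tif", i))
    writeImageStack(imgs, imgFile)
    chainFile <- file.path(dir, sprintf("chain%03d.json", i))
    writeChains(chain, chainFile)
    vpix <- curve$points[seq(1, nrow(curve$points), by = 16), , drop = FALSE] /
      optics@pixelSize - 0.5
    clines <- rbind(clines, data.frame(
      cell_id = sprintf("cell%03d", i), xri_id = "xri1",
      vertex_index = seq_len(nrow(vpix)) - 1L,
      x_px = vpix[, 1], y_px = vpix[, 2],
      width_um = 2.3548 * optics@psfSigma))
    entries[[i]] <- list(
      image = basename(imgFile), chains = basename(chainFile),
      cell_id = sprintf("cell%03d", i),
      inductionTimes = induceTimes, expectedOnsetFractions = expFrac,
      channelMap = as.list(channelMap), seed = chSeed)
  }
  writeCenterlines(clines, file.path(dir, "centerlines.csv"))
  manifest <- list(scenario = scenario, seed = seed,
                   params = list(tStart = sc$params@tStart,
                                 tFix = sc$params@tFix,
                                 spacing = sc$params@spacing,
                                 dt = sc$params@dt),
                   optics = list(pixelSize = optics@pixelSize,
                                 psfSigma = optics@psfSigma,
                                 gain = optics@gain,
                                 background = optics@background,
                                 readNoise = optics@readNoise,
                                 imageSize = optics@imageSize),
                   xris = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
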
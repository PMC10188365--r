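# End-to-end convenience: run the readout pipeline over a rendered fixture
# directory (images -> centerlines -> profiles -> decoded signals -> onsets).

#' Analyze a rendered fixture directory
#'
#' Runs the full readout over every XRI in a [makeFixture()] directory:
#' obtain a centerline (automatically traced from the constitutive channel,
#' or the manifest's true centerline), measure the ridge width, extract
#' per-channel profiles, decode the induced signal and estimate the onset
#' fraction.
#'
#' @param dir fixture directory.
#' @param induced induced channel role to decode (default `"FLAG"`).
#' @param constitutive constitutive channel role (default `"HA"`).
#' @param traceLines `TRUE` (default): trace centerlines from the image,
#'   seeded at the true centerline midpoint; `FALSE`: use the true
#'   centerlines from the fixture CSV.
#' @param background,percentile background handling passed to
#'   [extractProfile()].
#' @param grid fraction grid for decoding.
#' @return list with `table` (data.frame: one row per XRI with the expected
#'   and estimated onset fraction, flags, end/center ratio, split SSD) and
#'   `signals` (list of [DecodedSignal-class]).
#' @export
analyzeFixture <- function(dir, induced = "FLAG", constitutive = "HA",
                           traceLines = TRUE,
                           background = "none", percentile = 0.5,
                           grid = fractionGridPoints()) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  pixelSize <- manifest$optics$pixelSize
  clines <- readCenterlines(file.path(dir, "centerlines.csv"))
  rows <- list()
  signals <- list()
  for (entry in manifest$xris) {
    chmap <- unlist(entry$channelMap)
    images <- readImageStack(file.path(dir, entry$image), chmap)
    truth <- clines[clines$cell_id == entry$cell_id, ]
    vtrue <- cbind(truth$x_px, truth$y_px)
    verts <- if (traceLines) {
      seedPt <- vtrue[ceiling(nrow(vtrue) / 2), ]
      traceCenterline(images[[constitutive]], seedPt)
    } else vtrue
    width <- measureWidth(images[[constitutive]], verts, pixelSize)
    prof <- extractProfile(images, verts, width, pixelSize,
                           channels = c(constitutive, induced),
                           background = background, percentile = percentile,
                           meta = list(cell_id = entry$cell_id))
    sig <- decodeSignal(prof, constitutive, induced, grid)
    est <- estimateOnset(sig)
    ratio <- suppressWarnings(endCenterRatio(sig))
    expFrac <- unlist(entry$expectedOnsetFractions)
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = entry$cell_id,
      expected = if (length(expFrac)) expFrac[1] else NA_real_,
      onset = onsetValue(est),
      flags = paste(onsetFlags(est), collapse = ";"),
      endCenterRatio = ratio,
      ssd = splitSSD(sig),
      stringsAsFactors = FALSE)
    signals[[entry$cell_id]] <- sig
  }
  list(table = do.call(rbind, rows), signals = signals)
}

#' Decode chains directly (noiseless density profiles)
#'
#' Decoder-only recovery path: bins each chain's monomer positions into
#' noiseless line-density profiles and decodes them, bypassing imaging.
#'
#' @param chains list of [MonomerChain-class].
#' @param induced induced tag to decode.
#' @param constitutive constitutive tag (default `"HA"`).
#' @param binWidth density bin width, nm.
#' @param grid fraction grid.
#' @return data.frame with one row per chain: `onset`, `flags`,
#'   `endCenterRatio`, plus the decoded signals as attribute `"signals"`.
#' @export
decodeChains <- function(chains, induced, constitutive = "HA",
                         binWidth = 200, grid = fractionGridPoints()) {
  sigs <- vector("list", length(chains))
  rows <- vector("list", length(chains))
  for (i in seq_along(chains)) {
    prof <- chainProfile(chains[[i]], binWidth)
    sig <- decodeSignal(prof, constitutive, induced, grid)
    est <- estimateOnset(sig)
    sigs[[i]] <- sig
    rows[[i]] <- data.frame(
      onset = onsetValue(est),
      flags = paste(onsetFlags(est), collapse = ";"),
      endCenterRatio = suppressWarnings(endCenterRatio(sig)))
  }
  out <- do.call(rbind, rows)
  attr(out, "signals") <- sigs
  out
}
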
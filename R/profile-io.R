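# Reading images and centerlines, the XRI selection rule, width measurement
# and per-channel intensity profile extraction along centerlines.

#' Write a multichannel image stack to a multipage TIFF
#'
#' Intensities are rounded to nonnegative integer counts (clamped at 65535)
#' and stored at 16 bits, so integer-valued stacks round-trip losslessly.
#'
#' @param images named list of matrices (counts), one page per channel.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeImageStack <- function(images, path) {
  pages <- lapply(images, function(m)
    pmin(pmax(round(m), 0), 65535) / 65535)
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                                   compression = "none"))
  invisible(path)
}

#' Read a multichannel image stack from a multipage TIFF
#'
#' @param path TIFF path (one page per channel).
#' @param channelMap named integer vector mapping channel roles to 1-based
#'   page numbers, e.g. `c(HA = 2, FLAG = 3)`.
#' @return named list of matrices (counts), indexed by role.
#' @export
readImageStack <- function(path, channelMap) {
  if (!file.exists(path)) stop("cannot read image '", path, "'")
  if (length(channelMap) < 1L || is.null(names(channelMap)))
    stop("'channelMap' must name at least one channel")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (any(channelMap < 1L | channelMap > length(pages)))
    stop("channel map references a page outside 1..", length(pages))
  out <- lapply(channelMap, function(i) {
    m <- pages[[i]]
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m * 65535
  })
  names(out) <- names(channelMap)
  out
}

#' Write centerlines to CSV
#'
#' Long format, one row per vertex:
#' `cell_id,xri_id,vertex_index,x_px,y_px,width_um` with 0-based
#' pixel-center coordinates.
#'
#' @param df data.frame in the format above.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCenterlines <- function(df, path) {
  need <- c("cell_id", "xri_id", "vertex_index", "x_px", "y_px", "width_um")
  if (!all(need %in% names(df))) stop("missing centerline columns")
  utils::write.csv(df[need], path, row.names = FALSE)
  invisible(path)
}

#' Read centerlines from CSV
#'
#' @param path CSV path in the [writeCenterlines()] format.
#' @return data.frame, ordered by cell, XRI and vertex index.
#' @export
readCenterlines <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "xri_id", "vertex_index", "x_px", "y_px", "width_um")
  if (!all(need %in% names(df))) stop("missing centerline columns")
  df[order(df$cell_id, df$xri_id, df$vertex_index), need]
}

#' Select XRIs for analysis by the longest-length rule
#'
#' Keeps the longest XRI in a soma plus any XRI whose length is strictly
#' above half of that longest length (ties at exactly half are excluded).
#'
#' @param lengths numeric vector of XRI lengths, um.
#' @return integer indices of the kept XRIs (always includes the argmax);
#'   invariant to input order.
#' @examples
#' selectXris(c(10, 6, 4))  # keeps 1 and 2
#' selectXris(c(10, 5, 1))  # keeps 1 only: 5 is not above 10/2
#' @export
selectXris <- function(lengths) {
  if (length(lengths) == 0L) stop("no XRI lengths given")
  mx <- max(lengths)
  sort(union(which.max(lengths), which(lengths > mx / 2)))
}

# Perpendicular cut samples through the image at one centerline point.
# Returns intensities at offsets (um) along the unit normal.
perpCut <- function(image, pt, normal, halfLen, step, pixelSize) {
  off <- seq(-halfLen, halfLen, by = step)
  xs <- pt[1] + off * normal[1]
  ys <- pt[2] + off * normal[2]
  list(offset = off,
       value = bilinear(image, ys / pixelSize + 0.5, xs / pixelSize + 0.5))
}

# Full width at half maximum of one cut (background = cut minimum), by
# linear interpolation of the half-max crossings around the peak.
cutFWHM <- function(off, val) {
  bg <- min(val)
  v <- val - bg
  pk <- which.max(v)
  if (v[pk] <= 0) return(NA_real_)
  half <- v[pk] / 2
  iL <- pk
  while (iL > 1 && v[iL] > half) iL <- iL - 1
  iR <- pk
  n <- length(v)
  while (iR < n && v[iR] > half) iR <- iR + 1
  if (v[iL] > half || v[iR] > half) return(NA_real_)
  xL <- off[iL] + (half - v[iL]) / (v[iL + 1] - v[iL]) *
    (off[iL + 1] - off[iL])
  xR <- off[iR - 1] + (half - v[iR - 1]) / (v[iR] - v[iR - 1]) *
    (off[iR] - off[iR - 1])
  xR - xL
}

#' Measure the width of an XRI ridge
#'
#' Median over arc samples of the full width at half maximum of the
#' background-subtracted intensity along cuts perpendicular to the
#' centerline, in the constitutive (HA) channel.
#'
#' @param image matrix, the HA channel.
#' @param vertices 2-column matrix of centerline vertices, 0-based
#'   pixel-center coordinates.
#' @param pixelSize um per pixel.
#' @param cutHalfLength half-length of each perpendicular cut, um.
#' @return width in um.
#' @export
measureWidth <- function(image, vertices, pixelSize,
                         cutHalfLength = 1.5) {
  v <- vertices * pixelSize + pixelSize / 2  # to um coordinates
  rs <- resamplePolyline(v, pixelSize * 2)
  tg <- polylineTangents(rs$points)
  widths <- vapply(seq_len(nrow(rs$points)), function(i) {
    cut <- perpCut(image, rs$points[i, ], c(-tg[i, 2], tg[i, 1]),
                   cutHalfLength, pixelSize / 2, pixelSize)
    cutFWHM(cut$offset, cut$value)
  }, 0)
  widths <- widths[is.finite(widths)]
  if (!length(widths)) stop("degenerate ridge: no measurable width")
  stats::median(widths)
}

#' Extract per-channel intensity profiles along a centerline
#'
#' Resamples the centerline to a uniform arc step equal to the pixel size;
#' at every arc sample the reported intensity is the mean of bilinear
#' interpolations along the perpendicular segment of total length
#' `width / 2` (the centerline breadth is half the XRI width). All requested
#' channels share the same arc grid.
#'
#' @param images named list of channel matrices (from [readImageStack()]).
#' @param vertices 2-column matrix of centerline vertices, 0-based
#'   pixel-center coordinates.
#' @param width XRI width, um (profile breadth is `width/2`).
#' @param pixelSize um per pixel.
#' @param channels channel roles to extract (default: all in `images`).
#' @param background `"none"` (default) or `"percentile"`: subtract a
#'   per-channel constant estimated as the given image percentile.
#' @param percentile background percentile when `background = "percentile"`
#'   (default 0.5, the image median; most pixels are background).
#' @param meta list of identifiers copied into the profile.
#' @return a [LineProfile-class]
#' @export
extractProfile <- function(images, vertices, width, pixelSize,
                           channels = names(images),
                           background = c("none", "percentile"),
                           percentile = 0.5, meta = list()) {
  background <- match.arg(background)
  if (width <= 0) stop("'width' must be > 0")
  missing <- setdiff(channels, names(images))
  if (length(missing)) stop("missing channels: ", paste(missing, collapse = ", "))
  dims <- dim(images[[channels[1]]])
  v <- vertices * pixelSize + pixelSize / 2
  if (any(v < 0) || any(v[, 1] > dims[2] * pixelSize) ||
      any(v[, 2] > dims[1] * pixelSize))
    stop("centerline exits the image bounds")
  rs <- resamplePolyline(v, pixelSize)
  tg <- polylineTangents(rs$points)
  half <- width / 4  # breadth width/2, so +/- width/4 around the centerline
  off <- seq(-half, half, by = pixelSize / 2)
  if (length(off) < 3L) off <- seq(-half, half, length.out = 3L)
  mat <- do.call(cbind, lapply(channels, function(ch) {
    img <- images[[ch]]
    bg <- if (background == "percentile")
      as.numeric(stats::quantile(img, percentile)) else 0
    vals <- vapply(seq_len(nrow(rs$points)), function(i) {
      nx <- -tg[i, 2]; ny <- tg[i, 1]
      xs <- rs$points[i, 1] + off * nx
      ys <- rs$points[i, 2] + off * ny
      mean(bilinear(img, ys / pixelSize + 0.5, xs / pixelSize + 0.5))
    }, 0)
    pmax(vals - bg, 0)
  }))
  colnames(mat) <- channels
  new("LineProfile", d = rs$s, intensities = mat, delta = pixelSize,
      meta = c(meta, list(width = width)))
}

#' Trace an XRI centerline automatically
#'
#' Convenience tracer for synthetic fixtures (real centerlines are drawn
#' manually and read from CSV): robust background threshold on the HA
#' channel (image median plus `k` median absolute deviations -- in a sparse
#' field almost all pixels are background, so this keeps dim,
#' constitutive-diluted filament segments that a global Otsu threshold would
#' cut), largest connected component containing the seed point,
#' morphological skeleton, longest geodesic path, smoothed polyline.
#'
#' @param image matrix, the HA channel.
#' @param seedPoint length-2 vector (x, y), 0-based pixel-center coordinates,
#'   inside the ridge.
#' @param smoothWindow smoothing window for the final polyline, samples.
#' @param k threshold in median absolute deviations above the image median
#'   (default 4).
#' @return 2-column matrix of ordered vertices (x, y), 0-based pixel-center
#'   coordinates.
#' @export
traceCenterline <- function(image, seedPoint, smoothWindow = 7L, k = 4) {
  bg <- stats::median(image)
  noise <- stats::mad(image)
  rngI <- max(image) - bg
  thr <- if (noise > 0.001 * rngI) bg + k * noise else
    bg + 0.05 * max(rngI, .Machine$double.eps)
  mask <- image > thr
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labm <- EBImage::imageData(lab)
  sr <- round(seedPoint[2]) + 1L
  sc <- round(seedPoint[1]) + 1L
  if (sr < 1L || sc < 1L || sr > nrow(labm) || sc > ncol(labm) ||
      labm[sr, sc] == 0)
    stop("seed point is not on a supra-threshold ridge")
  comp <- labm == labm[sr, sc]
  skel <- zhangSuenThin(comp)
  path <- skeletonLongestPath(skel)
  if (nrow(path) < 2L) stop("ridge too small to trace")
  # thinning erodes band ends by about the half-width: extend the path along
  # its end tangents while the component continues
  path <- extendPathEnds(path, comp)
  sm <- smoothPolyline(cbind(path[, 2], path[, 1]), smoothWindow)
  sm - 1  # back to 0-based pixel-center coordinates
}

# Extend a (row, col) pixel path at both ends along the local tangent while
# the binary component continues (up to maxStep pixels each side).
extendPathEnds <- function(path, comp, span = 6L, maxStep = 40L) {
  extend <- function(pts, endIdx, refIdx) {
    dir <- pts[endIdx, ] - pts[refIdx, ]
    nrm <- sqrt(sum(dir^2))
    if (nrm == 0) return(NULL)
    dir <- dir / nrm
    out <- NULL
    pos <- pts[endIdx, ]
    for (s in seq_len(maxStep)) {
      cand <- pts[endIdx, ] + dir * s
      rc <- round(cand)
      if (rc[1] < 1 || rc[2] < 1 || rc[1] > nrow(comp) ||
          rc[2] > ncol(comp) || !comp[rc[1], rc[2]]) break
      out <- rbind(out, cand)
      pos <- cand
    }
    out
  }
  n <- nrow(path)
  span <- min(span, n - 1L)
  headExt <- extend(path, 1L, 1L + span)
  tailExt <- extend(path, n, n - span)
  if (!is.null(headExt)) path <- rbind(headExt[rev(seq_len(nrow(headExt))), ,
                                               drop = FALSE], path)
  if (!is.null(tailExt)) path <- rbind(path, tailExt)
  path
}

#' Write line profiles to a long-format CSV
#'
#' One row per (sample, channel):
#' `cell_id,xri_id,d_um,channel,intensity`.
#'
#' @param profiles a [LineProfile-class] or list of them; `cell_id`/`xri_id`
#'   are taken from each profile's `meta` (defaulting to its list name).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeProfiles <- function(profiles, path) {
  if (is(profiles, "LineProfile")) profiles <- list(profiles)
  if (is.null(names(profiles)))
    names(profiles) <- sprintf("xri%03d", seq_along(profiles))
  rows <- lapply(names(profiles), function(nm) {
    p <- profiles[[nm]]
    cid <- if (!is.null(p@meta$cell_id)) p@meta$cell_id else nm
    xid <- if (!is.null(p@meta$xri_id)) p@meta$xri_id else "xri1"
    do.call(rbind, lapply(colnames(p@intensities), function(ch)
      data.frame(cell_id = cid, xri_id = xid, d_um = p@d, channel = ch,
                 intensity = p@intensities[, ch])))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read line profiles from a long-format CSV
#'
#' @param path CSV in the [writeProfiles()] format.
#' @return named list of [LineProfile-class] (one per `cell_id`/`xri_id`).
#' @export
readProfiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  keys <- unique(df[c("cell_id", "xri_id")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$cell_id == keys$cell_id[i] & df$xri_id == keys$xri_id[i], ]
    chs <- unique(sub$channel)
    d <- sort(unique(sub$d_um))
    mat <- sapply(chs, function(ch) {
      s <- sub[sub$channel == ch, ]
      s$intensity[order(s$d_um)]
    })
    if (is.null(dim(mat))) mat <- matrix(mat, ncol = length(chs))
    colnames(mat) <- chs
    new("LineProfile", d = d, intensities = mat,
        delta = stats::median(diff(d)),
        meta = list(cell_id = keys$cell_id[i], xri_id = keys$xri_id[i]))
  })
  names(out) <- paste(keys$cell_id, keys$xri_id, sep = "/")
  out
}
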
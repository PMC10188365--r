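# Internal numerics shared across modules.

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(oldseed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", oldseed, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Bilinear interpolation on a matrix at fractional (row, col) positions
# (1-based, integer values hit pixel centers). Out-of-range positions clamp
# to the border.
bilinear <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  img[i00] * (1 - fr) * (1 - fc) + img[i10] * fr * (1 - fc) +
    img[i01] * (1 - fr) * fc + img[i11] * fr * fc
}

# Cumulative arc length of a polyline given as a 2-column matrix.
polylineLength <- function(v) {
  if (nrow(v) < 2L) return(0)
  sum(sqrt(rowSums(diff(v)^2)))
}

# Resample a polyline to points at uniform arc spacing `step`, placed at
# cell midpoints: positions step/2, 3*step/2, ... along the arc.
resamplePolyline <- function(v, step) {
  seg <- sqrt(rowSums(diff(v)^2))
  cs <- c(0, cumsum(seg))
  L <- cs[length(cs)]
  n <- max(2L, floor(L / step))
  s <- (seq_len(n) - 0.5) * step
  s <- s[s <= L]
  x <- approx(cs, v[, 1], xout = s)$y
  y <- approx(cs, v[, 2], xout = s)$y
  list(points = cbind(x, y), s = s, length = L)
}

# Unit tangents of a resampled polyline by central differences.
polylineTangents <- function(pts) {
  n <- nrow(pts)
  tx <- c(pts[2, 1] - pts[1, 1], pts[3:n, 1] - pts[1:(n - 2), 1],
          pts[n, 1] - pts[n - 1, 1])
  ty <- c(pts[2, 2] - pts[1, 2], pts[3:n, 2] - pts[1:(n - 2), 2],
          pts[n, 2] - pts[n - 1, 2])
  nrm <- sqrt(tx^2 + ty^2)
  nrm[nrm == 0] <- 1
  cbind(tx / nrm, ty / nrm)
}

# Zhang-Suen morphological thinning of a binary matrix (TRUE = foreground).
# Returns a 1-pixel-wide skeleton. EBImage has no skeletonization, so this
# classic two-subiteration scheme is implemented directly.
zhangSuenThin <- function(mask) {
  m <- mask
  m[is.na(m)] <- FALSE
  pad <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  nr <- nrow(pad); nc <- ncol(pad)
  shift <- function(M, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- M[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      # neighbors P2..P9 clockwise starting north
      p2 <- shift(pad, 1, 0);  p3 <- shift(pad, 1, -1)
      p4 <- shift(pad, 0, -1); p5 <- shift(pad, -1, -1)
      p6 <- shift(pad, -1, 0); p7 <- shift(pad, -1, 1)
      p8 <- shift(pad, 0, 1);  p9 <- shift(pad, 1, 1)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (phase == 1) {
        cond <- pad & bsum >= 2 & bsum <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- pad & bsum >= 2 & bsum <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        pad[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)]
}

# Longest geodesic path through a skeleton (8-connectivity): double BFS.
# Returns a matrix of (row, col) pixel coordinates in path order.
skeletonLongestPath <- function(skel) {
  idx <- which(skel, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(idx)
  key <- paste(idx[, 1], idx[, 2])
  lut <- seq_len(nrow(idx))
  names(lut) <- key
  nbrOffsets <- expand.grid(dr = -1:1, dc = -1:1)
  nbrOffsets <- nbrOffsets[!(nbrOffsets$dr == 0 & nbrOffsets$dc == 0), ]
  neighbors <- function(i) {
    rr <- idx[i, 1] + nbrOffsets$dr
    cc <- idx[i, 2] + nbrOffsets$dc
    hit <- lut[paste(rr, cc)]
    hit[!is.na(hit)]
  }
  bfs <- function(start) {
    dist <- rep(NA_integer_, nrow(idx))
    parent <- rep(NA_integer_, nrow(idx))
    dist[start] <- 0L
    q <- start
    while (length(q)) {
      cur <- q[1]; q <- q[-1]
      for (nb in neighbors(cur)) {
        if (is.na(dist[nb])) {
          dist[nb] <- dist[cur] + 1L
          parent[nb] <- cur
          q <- c(q, nb)
        }
      }
    }
    list(dist = dist, parent = parent)
  }
  b1 <- bfs(1L)
  a <- which.max(b1$dist)
  b2 <- bfs(a)
  b <- which.max(b2$dist)
  path <- integer()
  cur <- b
  while (!is.na(cur)) {
    path <- c(cur, path)
    cur <- b2$parent[cur]
  }
  idx[path, , drop = FALSE]
}

# Moving-average smoothing of a polyline (reflective ends).
smoothPolyline <- function(v, window = 5L) {
  if (nrow(v) <= window) return(v)
  k <- rep(1 / window, window)
  sm <- function(x) as.numeric(stats::filter(x, k, sides = 2))
  out <- cbind(sm(v[, 1]), sm(v[, 2]))
  h <- (window - 1L) %/% 2L
  out[seq_len(h), ] <- v[seq_len(h), ]
  n <- nrow(v)
  out[(n - h + 1):n, ] <- v[(n - h + 1):n, ]
  out
}
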
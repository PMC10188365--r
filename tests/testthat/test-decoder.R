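test_that("profile splitting follows the midpoint convention", {
  pr <- mkProfile(rep(1, 8), rep(0, 8), delta = 1)
  sp <- splitProfile(pr, 4)
  expect_equal(sp$left$d, c(0.5, 1.5, 2.5, 3.5))
  expect_equal(sp$right$d, c(0.5, 1.5, 2.5, 3.5))
  expect_equal(length(sp$left$d) + length(sp$right$d), 8)
  # 25% split -> 1:3 length ratio
  sp2 <- splitProfile(pr, 2)
  expect_equal(length(sp2$left$d) / length(sp2$right$d), 1 / 3)
  # symmetric profile: halves identical sample by sample
  prs <- mkProfile(c(1, 2, 3, 3, 2, 1), c(0, 1, 5, 5, 1, 0), delta = 1)
  sps <- splitProfile(prs, 3)
  expect_equal(sps$left$intensities, sps$right$intensities,
               ignore_attr = TRUE)
  expect_error(splitProfile(pr, 0), "outside")
  expect_error(splitProfile(pr, 8), "outside")
})

test_that("the clock axis is the normalized cumulative constitutive sum", {
  half <- list(d = c(0.5, 1.5, 2.5),
               intensities = cbind(HA = c(1, 1, 2), FLAG = c(0, 0, 0)),
               delta = 1)
  expect_equal(fractionIntegral(half), c(0.25, 0.5, 1.0))
  # constant H over length L: fraction = p/L at right edges
  halfc <- list(d = (1:10 - 0.5) * 0.4,
                intensities = cbind(HA = rep(2.5, 10), FLAG = rep(0, 10)),
                delta = 0.4)
  expect_equal(fractionIntegral(halfc), (1:10) / 10)
  halfz <- list(d = c(0.5, 1.5), intensities = cbind(HA = c(0, 0),
                                                     FLAG = c(1, 1)),
                delta = 1)
  expect_error(fractionIntegral(halfz), "all zero")
})

test_that("the derivative signal reproduces hand difference quotients", {
  half <- list(d = (1:4) - 0.5,
               intensities = cbind(HA = rep(1, 4), FLAG = c(0, 0, 2, 2)),
               delta = 1)
  g <- fractionGridPoints()
  s <- signalFromHalf(half, g, minClockStep = 0)
  # native right edges 0.25/0.5/0.75/1 with quotients 0/0/8/8
  expect_equal(s[g %in% c(0, 0.125, 0.25, 0.5)], rep(0, 4))
  expect_equal(s[g %in% c(0.75, 0.9, 1)], rep(8, 3))
  expect_equal(s[g == 0.625], 4)  # linear interpolation between 0.5 and 0.75
  expect_error(signalFromHalf(list(d = 0.5,
                                   intensities = cbind(HA = 1, FLAG = 1),
                                   delta = 1), g), "fewer than 3")
})

test_that("proportional channels decode to the constant k * H_total", {
  set.seed(21)
  Hl <- runif(20, 0.5, 2)
  H <- c(Hl, rev(Hl))
  k <- 3.7
  pr <- mkProfile(H, k * H, delta = 0.25)
  sig <- decodeSignal(pr)
  htot <- sum(Hl) * 0.25  # per-half line integral at the central split
  expect_lt(max(abs(signalValues(sig) - k * htot)), 1e-6)
  # H constant h, F constant f over length L: signal = f * L_half
  pr2 <- mkProfile(rep(2, 30), rep(5, 30), delta = 0.5)
  sig2 <- decodeSignal(pr2)
  expect_lt(max(abs(signalValues(sig2) - 5 * 7.5)), 1e-6)
})

test_that("symmetric profiles split at the geometric center with zero SSD", {
  set.seed(31)
  Hl <- runif(16, 0.5, 2); Fl <- runif(16, 0, 1)
  pr <- mkProfile(c(Hl, rev(Hl)), c(Fl, rev(Fl)), delta = 1)
  sig <- decodeSignal(pr)
  expect_identical(sig@splitIndex, 16L)
  expect_equal(splitSSD(sig), 0)
  expect_equal(sig@halves[, 1], sig@halves[, 2])
})

test_that("a mirror plane at 60% of arc is found by the split search", {
  # left pad of zeros shifts the effective mirror plane to sample 24 of 40
  set.seed(41)
  Hc <- runif(16, 0.5, 2); Fc <- runif(16, 0, 1)
  H <- c(rep(0, 8), rev(Hc), Hc)
  F <- c(rep(0, 8), rev(Fc), Fc)
  sig <- decodeSignal(mkProfile(H, F, delta = 1))
  expect_lte(abs(sig@splitIndex - 24L), 1L)
  expect_equal(splitSSD(sig), 0, tolerance = 1e-18)
})

test_that("the split search equals an exhaustive brute-force oracle", {
  # independent literal reimplementation of the decoder definition
  oracleHalf <- function(H, F, delta, grid, minStep = 0.02) {
    if (sum(H) * delta <= 0) return(NULL)
    x <- cumsum(H) * delta / (sum(H) * delta)
    y <- cumsum(F) * delta
    dx <- diff(c(0, x)); dy <- diff(c(0, y))
    gx <- c(); gy <- c(); ax <- 0; ay <- 0
    for (i in seq_along(dx)) {
      ax <- ax + dx[i]; ay <- ay + dy[i]
      if (ax > 0 && ax >= minStep) {
        gx <- c(gx, ax); gy <- c(gy, ay); ax <- 0; ay <- 0
      }
    }
    if (!length(gx)) {
      if (ax > 0) { gx <- ax; gy <- ay; ax <- 0; ay <- 0 }
      else return(NULL)
    }
    if (ax > 0) {
      gx[length(gx)] <- gx[length(gx)] + ax
      gy[length(gy)] <- gy[length(gy)] + ay
    }
    if (length(gx) == 1) return(rep(gy / gx, length(grid)))
    approx(cumsum(gx), gy / gx, xout = grid, rule = 2)$y
  }
  oracleSplit <- function(H, F, delta, grid) {
    n <- length(H)
    k0 <- round(n / 2)
    cand <- max(3, ceiling(0.25 * n)):min(n - 3, floor(0.75 * n))
    best <- NULL
    for (k in cand) {
      s1 <- oracleHalf(rev(H[1:k]), rev(F[1:k]), delta, grid)
      s2 <- oracleHalf(H[(k + 1):n], F[(k + 1):n], delta, grid)
      if (is.null(s1) || is.null(s2)) next
      ssd <- sum((s1 - s2)^2)
      if (is.null(best) || ssd < best$ssd - 1e-12 ||
          (abs(ssd - best$ssd) <= 1e-12 && abs(k - k0) < abs(best$k - k0)))
        best <- list(k = k, ssd = ssd)
    }
    best
  }
  grid <- fractionGridPoints()
  set.seed(51)
  for (i in 1:50) {
    n <- sample(16:48, 1)
    H <- runif(n, 0.2, 1.2)
    F <- runif(n, 0, 1)
    pr <- mkProfile(H, F, delta = 0.1)
    sig <- decodeSignal(pr)
    orc <- oracleSplit(H, F, 0.1, grid)
    expect_identical(sig@splitIndex, as.integer(orc$k))
    expect_equal(splitSSD(sig), orc$ssd, tolerance = 1e-9)
  }
})

test_that("baseline, end/center ratio and relative change follow the windows", {
  g <- fractionGridPoints()
  sig <- mkSignal(rep(3, 201))
  expect_equal(baselineValue(sig), 3)
  expect_equal(endCenterRatio(sig), 1)
  expect_equal(relativeChange(sig), rep(0, 201))
  # hand values: 1 on the first 5%, 9 elsewhere
  v <- ifelse(g <= 0.05, 1, 9)
  expect_equal(baselineValue(mkSignal(v)), 1)
  # center level 1, end level 3
  v2 <- 1 + 2 * (g >= 0.95)
  expect_equal(endCenterRatio(mkSignal(v2)), 3)
  # linear 1 -> 2: window means ratio by hand
  v3 <- 1 + g
  hand <- mean(v3[g >= 0.95]) / mean(v3[g <= 0.05])
  expect_equal(endCenterRatio(mkSignal(v3)), hand)
  # center 2, end 3: relative change 0.5 at the end
  v4 <- 2 + 1 * (g >= 0.95)
  expect_equal(relativeChange(mkSignal(v4))[201], 0.5)
  # scale invariance of the relative change
  expect_equal(relativeChange(mkSignal(7 * v4)),
               relativeChange(mkSignal(v4)))
  expect_warning(endCenterRatio(mkSignal(rep(0, 201))), "baseline")
})

test_that("onset extrapolation is exact on a piecewise-linear rise", {
  g <- fractionGridPoints()
  v <- 2 + pmax(0, (g - 0.4)) / 0.4 * 10  # baseline 2, rise 0.4 -> peak 12
  v[g > 0.8] <- 12
  est <- estimateOnset(mkSignal(v))
  expect_length(onsetFlags(est), 0)
  expect_equal(onsetValue(est), 0.4, tolerance = 1e-6)
  # flat trace flags no-rise
  expect_equal(onsetFlags(estimateOnset(mkSignal(rep(4, 201)))), "no-rise")
})

test_that("onset equals an independent least-squares refit oracle", {
  g <- fractionGridPoints()
  v <- 1 + 10 / (1 + exp(-(g - 0.6) / 0.05))  # logistic rise at 0.6
  sig <- mkSignal(v)
  est <- estimateOnset(sig)
  expect_length(onsetFlags(est), 0)
  # oracle: rebuild the fit set (crossings + in-band grid points) and lm()
  b <- mean(v[g <= 0.05])
  net <- v - b
  peak <- max(net)
  i <- which.max(net)
  while (i > 1 && net[i - 1] >= 0.5 * peak) i <- i - 1
  xs <- c(); ys <- c()
  if (i > 1) {
    x50 <- approx(net[(i - 1):i], g[(i - 1):i], xout = 0.5 * peak)$y
    xs <- x50; ys <- 0.5 * peak
  }
  j <- i - 1
  while (j >= 1 && net[j] >= 0.1 * peak && net[j] <= 0.5 * peak) {
    xs <- c(g[j], xs); ys <- c(net[j], ys); j <- j - 1
  }
  if (j >= 1 && net[j] < 0.1 * peak) {
    x10 <- approx(net[j:(j + 1)], g[j:(j + 1)], xout = 0.1 * peak)$y
    xs <- c(x10, xs); ys <- c(0.1 * peak, ys)
  }
  fit <- lm(ys ~ xs)
  oracle <- -coef(fit)[[1]] / coef(fit)[[2]]
  expect_equal(onsetValue(est), oracle, tolerance = 1e-9)
})

test_that("decoding is scale-equivariant and onset scale-invariant", {
  set.seed(61)
  n <- 60
  H <- runif(n, 0.8, 1.2)
  F <- 0.5 + 5 * (seq_len(n) %in% c(1:10, 51:60))
  pr1 <- mkProfile(H, F, delta = 0.2)
  pr9 <- mkProfile(H, 9 * F, delta = 0.2)
  s1 <- decodeSignal(pr1); s9 <- decodeSignal(pr9)
  expect_equal(signalValues(s9), 9 * signalValues(s1), tolerance = 1e-9)
  e1 <- estimateOnset(s1); e9 <- estimateOnset(s9)
  expect_equal(onsetValue(e9), onsetValue(e1), tolerance = 1e-9)
})

test_that("the decoded signal is invariant to arc reparameterization", {
  # smooth profiles; re-express them under a smooth arc warp phi and check
  # the fraction-of-integral axis absorbs it
  L <- 10
  n1 <- 160
  d1 <- (seq_len(n1) - 0.5) * (L / n1)
  Hf <- function(d) 1 + 0.5 * sin(2 * pi * d / L)
  Ff <- function(d) exp(-((d - 7)^2) / 2)
  pr <- mkProfile(Hf(d1), Ff(d1), delta = L / n1)
  # warped axis u on [0, L]: phi(u) strictly increasing onto [0, L]
  phi <- function(u) L * (u / L + 0.12 * sin(pi * u / L) * (u / L) *
                            (1 - u / L) * 4)
  n2 <- 200
  du <- L / n2
  edges <- (0:n2) * du
  fine <- seq(0, L, length.out = 8001)
  CH <- approxfun(fine, cumsum(Hf(fine)) * (L / 8000), rule = 2)
  CF <- approxfun(fine, cumsum(Ff(fine)) * (L / 8000), rule = 2)
  H2 <- (CH(phi(edges[-1])) - CH(phi(edges[-(n2 + 1)]))) / du
  F2 <- (CF(phi(edges[-1])) - CF(phi(edges[-(n2 + 1)]))) / du
  pr2 <- mkProfile(H2, F2, delta = du)
  s1 <- decodeSignal(pr)
  s2 <- decodeSignal(pr2)
  rel <- max(abs(signalValues(s1) - signalValues(s2))) /
    max(abs(signalValues(s1)))
  expect_lt(rel, 0.05)
})

test_that("half agreement improves as noise decreases", {
  set.seed(71)
  base <- rep(1, 60)
  Fbase <- c(rep(0.2, 40), rep(2, 20))
  Hl <- base
  mk <- function(noise) {
    H <- c(rev(Hl), Hl) + rnorm(120, sd = noise)
    F <- c(rev(Fbase), Fbase) + rnorm(120, sd = noise)
    decodeSignal(mkProfile(pmax(H, 0.01), pmax(F, 0), delta = 0.2))
  }
  ssdHi <- median(vapply(1:5, function(i) splitSSD(mk(0.3)), 0))
  ssdLo <- median(vapply(1:5, function(i) splitSSD(mk(0.03)), 0))
  expect_lt(ssdLo, ssdHi)
  expect_equal(splitSSD(mk(0)), 0, tolerance = 1e-12)
})

test_that("decoding errors are raised for degenerate profiles", {
  expect_error(decodeSignal(mkProfile(rep(1, 5), rep(1, 5))), "too short")
  pr <- mkProfile(rep(0, 20), rep(1, 20))
  expect_error(decodeSignal(pr), "no valid split")
})

test_that("decoded output survives the JSON writer", {
  set.seed(81)
  Hl <- runif(20, 0.5, 2)
  pr <- mkProfile(c(Hl, rev(Hl)), c(Hl, rev(Hl)) * 2, delta = 0.5)
  sig <- decodeSignal(pr)
  f <- withr::local_tempfile(fileext = ".json")
  writeDecoded(list(sig), f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$splitIndex, 20)
  expect_equal(unlist(back$signal[[1]]), signalValues(sig),
               tolerance = 1e-9)
})
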
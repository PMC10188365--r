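optNN <- function(...) opticsParams(background = 0, readNoise = 0,
                                    bleed = 0, imageSize = 64L, ...)

test_that("layout maps monomers symmetrically along a straight curve", {
  curve <- centerlineSpec(cbind(c(0, 6), c(3, 3)))
  mk <- function(n) data.frame(tag = rep("HA", n), time = 3.5 + seq_len(n) / 10,
                               index = seq_len(n) - 1L)
  ch <- new("MonomerChain", minus = mk(5), plus = mk(5),
            program = list(speciesProgram("HA", "constitutive", 1)),
            params = growthParams(), seed = 1L)
  lay <- layoutChain(ch, curve)
  expect_equal(nrow(lay$HA), 10)  # mass conservation
  # symmetric about the curve midpoint x = 3
  expect_equal(sort(lay$HA[, 1] - 3), sort(3 - lay$HA[, 1]))
  expect_true(all(abs(lay$HA[, 2] - 3) < 1e-9))
})

test_that("a single monomer lands at the curve midpoint", {
  curve <- centerlineSpec(cbind(c(0, 6), c(3, 3)))
  ch <- new("MonomerChain",
            minus = data.frame(tag = character(), time = numeric(),
                               index = integer()),
            plus = data.frame(tag = "HA", time = 3.5, index = 0L),
            program = list(speciesProgram("HA", "constitutive", 1)),
            params = growthParams(), seed = 1L)
  lay <- layoutChain(ch, curve)
  expect_equal(as.numeric(lay$HA), c(3 + 0.002, 3), tolerance = 1e-6)
})

test_that("chains longer than the curve are rejected", {
  curve <- centerlineSpec(cbind(c(0, 1), c(0, 0)))  # 1 um curve
  ch <- simulateChain(stepProgram(5), growthParams(), seed = 1)
  expect_error(layoutChain(ch, curve), "longer than")
})

test_that("a point mass renders to a mass-conserving Gaussian PSF spot", {
  o <- optNN()
  lay <- list(HA = matrix(c(3.2, 3.2), 1))
  img <- renderChannels(lay, o, noise = FALSE)$HA
  expect_equal(sum(img) / o@gain, 1, tolerance = 1e-6)
  # second moment of the spot = PSF sd + pixelation variance, in pixels
  xs <- (seq_len(64) - 0.5) * o@pixelSize
  sdx <- sqrt(sum(img * outer(rep(1, 64), (xs - 3.2)^2)) / sum(img)) /
    o@pixelSize
  pixVar <- 1 / 12 + 1 / 12  # binning of the point + pixel integration
  expect_equal(sdx, sqrt((o@psfSigma / o@pixelSize)^2 + pixVar),
               tolerance = 0.05)
})

test_that("background-only rendering draws Poisson counts at the set mean", {
  o <- opticsParams(background = 9, readNoise = 0, bleed = 0, imageSize = 64L)
  img <- renderChannels(list(HA = matrix(numeric(), 0, 2)), o, seed = 5)$HA
  se <- sd(img) / sqrt(length(img))
  expect_lt(abs(mean(img) - 9), 3 * se)
})

test_that("expected rendering is linear in the density", {
  o <- optNN()
  pts <- matrix(runif(40, 1, 5), ncol = 2)
  one <- renderChannels(list(HA = pts), o, noise = FALSE)$HA
  two <- renderChannels(list(HA = rbind(pts, pts)), o, noise = FALSE)$HA
  expect_equal(two, 2 * one, tolerance = 1e-9)
})

test_that("rendering conserves expected intensity per channel", {
  ch <- simulateChain(stepProgram(5, r0 = 100, amp = 50), growthParams(),
                      seed = 2)
  o <- opticsParams(background = 3, readNoise = 0, bleed = 0, imageSize = 96L)
  curve <- centerlineSpec(cbind(c(1, 8.6), c(4.8, 4.8)))
  lay <- layoutChain(ch, curve)
  imgs <- renderChannels(lay, o, noise = FALSE)
  for (tg in c("HA", "FLAG"))
    expect_equal(sum(imgs[[tg]] - o@background) / o@gain,
                 monomerCount(ch, tg), tolerance = 1e-3)
})

test_that("fixtures are reproducible byte-for-byte from the same seed", {
  o <- opticsParams(imageSize = 128L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  makeFixture("induction-day-5-of-7", seed = 5, dir = d1, nChains = 1,
              rate = 120, optics = o)
  makeFixture("induction-day-5-of-7", seed = 5, dir = d2, nChains = 1,
              rate = 120, optics = o)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("fixture manifests carry the scenario ground truth", {
  o <- opticsParams(imageSize = 128L)
  d <- withr::local_tempdir()
  m <- makeFixture("no-induction", seed = 2, dir = d, nChains = 1,
                   rate = 120, optics = o)
  expect_length(m$xris[[1]]$inductionTimes, 0)
  d2 <- withr::local_tempdir()
  m2 <- makeFixture("induction-day-5-of-7", seed = 2, dir = d2, nChains = 1,
                    rate = 120, accel = "constant", optics = o)
  expect_equal(m2$xris[[1]]$expectedOnsetFractions, 0.5, tolerance = 1e-9)
  d3 <- withr::local_tempdir()
  m3 <- makeFixture("cfos-two-pulse-day5-day6", seed = 2, dir = d3,
                    nChains = 1, rate = 120, optics = o)
  expect_equal(m3$xris[[1]]$inductionTimes, c(5, 6))
  expect_error(makeFixture("mystery", seed = 1, dir = d), "unknown scenario")
})

test_that("noiseless ridge extraction matches a 1D convolution oracle", {
  ch <- simulateChain(stepProgram(5, r0 = 200, amp = 100), growthParams(),
                      seed = 4)
  o <- opticsParams(background = 0, readNoise = 0, bleed = 0,
                    imageSize = 128L)
  curve <- centerlineSpec(cbind(c(0.6, 12.2), c(6.4, 6.4)))
  lay <- layoutChain(ch, curve)
  imgs <- renderChannels(lay, o, noise = FALSE)
  # true centerline: the horizontal row through y = 6.4 um
  verts <- cbind(seq(6, 121, by = 1), rep(6.4 / o@pixelSize - 0.5, 116))
  prof <- extractProfile(imgs, verts, width = 4 * 2.3548 * o@psfSigma,
                         pixelSize = o@pixelSize, channels = "HA")
  got <- channelIntensity(prof, "HA")
  # oracle: bin arc positions at pixel pitch, convolve with a discrete
  # Gaussian, scale by gain
  s0 <- attr(lay, "curve")$s
  arc <- lay$HA[, 1]  # straight horizontal curve: arc == x
  edges <- seq(0.6, 12.2, by = o@pixelSize)
  hist1 <- hist(arc, breaks = edges, plot = FALSE)$counts
  kw <- 25
  kern <- dnorm(-kw:kw, sd = o@psfSigma / o@pixelSize)
  kern <- kern / sum(kern)
  expv <- as.numeric(stats::filter(c(rep(0, kw), hist1, rep(0, kw)), kern,
                                   sides = 2))[(kw + 1):(kw + length(hist1))]
  expv <- expv * o@gain
  # compare on the shared interior (the profile starts at x = 0.6 + offset)
  x0 <- (verts[1, 1] + 0.5) * o@pixelSize
  idx <- round((x0 - 0.6) / o@pixelSize) + seq_along(got) - 1
  ok <- idx >= kw & idx <= length(expv) - kw
  # the perpendicular width-average rescales by a constant factor on a
  # straight ridge; compare mean-normalized shapes
  a <- got[ok] / mean(got[ok])
  b <- expv[idx[ok]] / mean(expv[idx[ok]])
  expect_lt(sqrt(mean((a - b)^2)) / max(b), 0.02)
})
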
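# Stochastic forward model of bidirectional XRI chain growth.
#
# Monomer incorporation is modeled as independent Poisson processes per
# species and per growing end: in each time step of width dt, the number of
# monomers of species s added to one end is Poisson with mean r_s(t) * dt.
# Species draw from separate RNG streams keyed by the tag label, so the
# constitutive species' trajectory is bit-identical whether or not an induced
# species is present -- the no-competition postulate holds by construction.

#' Construct a species expression program
#'
#' @param tag epitope tag label, e.g. `"HA"`.
#' @param kind `"constitutive"` or `"induced"`.
#' @param rate base incorporation rate (constitutive) or pulse amplitude
#'   (induced), monomers per day per growing end.
#' @param accel acceleration form of a constitutive rate: `"constant"`,
#'   `"linear"` (`r0 * (1 + a*(t - tStart))`) or `"exponential"`
#'   (`r0 * exp(a*(t - tStart))`, rate `r0` at recording onset).
#' @param accelRate acceleration constant `a`, per day.
#' @param tInduce induction time for induced species, days.
#' @param kernel induced kernel: `"step"` or `"alpha"` (pulse with finite
#'   rise and decay, peak-normalized to `rate`).
#' @param rise,decay alpha-kernel time constants, days.
#' @return a [SpeciesProgram-class]
#' @examples
#' ha <- speciesProgram("HA", "constitutive", rate = 250)
#' fl <- speciesProgram("FLAG", "induced", rate = 250, tInduce = 5)
#' @export
speciesProgram <- function(tag, kind = c("constitutive", "induced"), rate,
                           accel = "constant", accelRate = 0.3,
                           tInduce = NA_real_, kernel = "step",
                           rise = 0.1, decay = 1) {
  kind <- match.arg(kind)
  new("SpeciesProgram", tag = as.character(tag), kind = kind,
      rate = as.numeric(rate), accel = accel, accelRate = accelRate,
      tInduce = as.numeric(tInduce), kernel = kernel,
      rise = rise, decay = decay)
}

#' Construct growth parameters
#'
#' @param tStart day recording starts (filament stabilization, default 3).
#' @param tFix fixation day (default 7; use 14 for the in vivo scenario).
#' @param spacing monomer spacing, nm (default 4).
#' @param dt simulation step, days (default 0.01).
#' @return a [GrowthParams-class]
#' @export
growthParams <- function(tStart = 3, tFix = 7, spacing = 4, dt = 0.01) {
  new("GrowthParams", tStart = tStart, tFix = tFix, spacing = spacing, dt = dt)
}

# Incorporation rate r_s(t), vectorized over t.
rateAt <- function(species, t, params) {
  if (species@kind == "constitutive") {
    r <- switch(species@accel,
      constant = rep(species@rate, length(t)),
      linear = species@rate *
        pmax(0, 1 + species@accelRate * (t - params@tStart)),
      exponential = species@rate *
        exp(species@accelRate * (t - params@tStart)))
    r[t < params@tStart] <- 0
  } else {
    t0 <- max(params@tStart, species@tInduce)
    x <- t - t0
    if (species@kernel == "step") {
      r <- ifelse(x >= 0, species@rate, 0)
    } else {
      # alpha pulse (1 - exp(-x/rise)) * exp(-x/decay), peak-normalized;
      # the peak sits at x* = rise * log(1 + decay/rise) (closed form).
      xs <- species@rise * log(1 + species@decay / species@rise)
      pk <- (1 - exp(-xs / species@rise)) * exp(-xs / species@decay)
      r <- ifelse(x >= 0,
                  species@rate * (1 - exp(-x / species@rise)) *
                    exp(-x / species@decay) / pk, 0)
    }
  }
  r
}

# Deterministic RNG stream seed for (master seed, tag label): insensitive to
# which other species are in the program.
streamSeed <- function(seed, tag) {
  h <- Reduce(function(a, b) (a * 31 + b) %% 1977326743, utf8ToInt(tag), 7)
  as.integer((abs(seed) %% 65011 * 30241 + h) %% 2147483629)
}

#' Simulate one bidirectional monomer chain
#'
#' Draws monomer incorporations per time step, per side and per species from
#' independent Poisson laws with mean `r_s(t) * dt` (rates evaluated at step
#' midpoints), with no competition between species. New monomers are appended
#' in species order within a step.
#'
#' @param program list of [SpeciesProgram-class] objects (at least one with a
#'   nonzero rate).
#' @param params a [GrowthParams-class].
#' @param seed integer; identical `(program, params, seed)` give identical
#'   chains, and a species' draws do not depend on the other species present.
#' @return a [MonomerChain-class]
#' @examples
#' ch <- simulateChain(list(speciesProgram("HA", "constitutive", 100)),
#'                     growthParams(), seed = 1)
#' monomerCount(ch, "HA")
#' @export
simulateChain <- function(program, params = growthParams(), seed = 1L) {
  if (length(program) == 0L) stop("empty species program")
  validObject(params)
  if (!any(vapply(program, function(s) s@rate > 0, TRUE)))
    for (s in program) validObject(s)
  tags <- vapply(program, slot, "", "tag")
  # Duplicate tags are allowed (e.g. two pulses feeding the same channel);
  # each occurrence gets its own RNG stream.
  occ <- stats::ave(seq_along(tags), tags, FUN = seq_along)
  edges <- seq(params@tStart, params@tFix, by = params@dt)
  if (edges[length(edges)] < params@tFix) edges <- c(edges, params@tFix)
  tm <- (edges[-1] + edges[-length(edges)]) / 2
  widths <- diff(edges)
  nstep <- length(tm)
  nsp <- length(program)
  countsM <- countsP <- matrix(0L, nrow = nsp, ncol = nstep)
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldseed)) assign(".Random.seed", oldseed, envir = globalenv())
  })
  for (k in seq_len(nsp)) {
    validObject(program[[k]])
    lam <- rateAt(program[[k]], tm, params) * widths
    key <- if (occ[k] == 1L) tags[k] else paste0(tags[k], "#", occ[k])
    set.seed(streamSeed(seed, key))
    countsM[k, ] <- rpois(nstep, lam)
    countsP[k, ] <- rpois(nstep, lam)
  }
  buildSide <- function(counts) {
    cnt <- as.vector(counts)  # column-major: species fastest within a step
    tg <- rep(rep(tags, nstep), times = cnt)
    tt <- rep(rep(tm, each = nsp), times = cnt)
    data.frame(tag = tg, time = tt, index = seq_along(tg) - 1L,
               stringsAsFactors = FALSE)
  }
  new("MonomerChain", minus = buildSide(countsM), plus = buildSide(countsP),
      program = program, params = params, seed = as.integer(seed))
}

#' Expected onset fraction of an induced event
#'
#' The ground-truth fraction of the constitutive cumulative expression at
#' the induction time: `C(tInduce) / C(tFix)` with
#' `C(t) = integral of the constitutive rate from tStart to t`, evaluated on
#' the simulation grid. Under the filament clock model this is the fraction
#' of the HA line integral at which the induced signal begins to rise.
#'
#' @param program list with exactly one constitutive and one induced species.
#' @param params a [GrowthParams-class].
#' @return fraction in [0, 1].
#' @export
expectedOnsetFraction <- function(program, params = growthParams()) {
  kinds <- vapply(program, slot, "", "kind")
  const <- program[kinds == "constitutive"]
  indu <- program[kinds == "induced"]
  if (length(const) != 1L || length(indu) != 1L)
    stop("program must contain exactly one constitutive and one induced species")
  ti <- indu[[1]]@tInduce
  if (is.na(ti) || ti < params@tStart || ti > params@tFix)
    stop("induction time outside [tStart, tFix]")
  edges <- seq(params@tStart, params@tFix, by = params@dt)
  if (edges[length(edges)] < params@tFix) edges <- c(edges, params@tFix)
  tm <- (edges[-1] + edges[-length(edges)]) / 2
  cum <- c(0, cumsum(rateAt(const[[1]], tm, params) * diff(edges)))
  ci <- approx(edges, cum, xout = ti, rule = 2)$y
  ci / cum[length(cum)]
}

#' Line density of one tag along a chain
#'
#' Histogram of monomer positions (signed: minus side negative, plus side
#' positive, nm from the nucleation center) divided by the bin width.
#'
#' @param chain a [MonomerChain-class]
#' @param tag tag label present in the chain's program.
#' @param binWidth bin width, nm (default 200).
#' @return data.frame with `position` (bin center, nm) and `density`
#'   (monomers per um). The full symmetric extent of the chain is covered, so
#'   `sum(density) * binWidth / 1000` equals the monomer count of the tag.
#' @export
chainDensity <- function(chain, tag, binWidth = 50) {
  if (binWidth <= 0) stop("'binWidth' must be > 0")
  tags <- vapply(chain@program, slot, "", "tag")
  if (!tag %in% tags) stop("unknown tag '", tag, "'")
  sp <- chain@params@spacing
  pos <- c(-(chain@minus$index[chain@minus$tag == tag] + 0.5) * sp,
           (chain@plus$index[chain@plus$tag == tag] + 0.5) * sp)
  ext <- max((nrow(chain@minus)) * sp, (nrow(chain@plus)) * sp, binWidth)
  nb <- ceiling(ext / binWidth)
  breaks <- seq(-nb * binWidth, nb * binWidth, by = binWidth)
  cnt <- if (length(pos)) {
    hist(pos, breaks = breaks, plot = FALSE)$counts
  } else rep(0L, length(breaks) - 1L)
  data.frame(position = (breaks[-1] + breaks[-length(breaks)]) / 2,
             density = cnt / binWidth * 1000)
}

#' Noiseless line profile of a chain
#'
#' Bridge from a simulated chain to the decoder: bins every tag's monomer
#' positions into a shared arc grid and returns the per-tag line densities as
#' a [LineProfile-class] (arc position measured from the minus-side tip).
#'
#' @param chain a [MonomerChain-class]
#' @param binWidth bin width, nm (default 200).
#' @return a [LineProfile-class] with one channel per tag, intensities in
#'   monomers per um.
#' @export
chainProfile <- function(chain, binWidth = 200) {
  tags <- unique(vapply(chain@program, slot, "", "tag"))
  dens <- lapply(tags, function(tg) chainDensity(chain, tg, binWidth))
  mat <- do.call(cbind, lapply(dens, function(d) d$density))
  colnames(mat) <- tags
  pos <- dens[[1]]$position
  new("LineProfile", d = (pos - min(pos)) / 1000 + binWidth / 2000,
      intensities = mat, delta = binWidth / 1000,
      meta = list(source = "chainDensity", seed = chain@seed))
}

#' Write chains to a JSON file
#'
#' @param chains list of [MonomerChain-class] (or a single chain).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeChains <- function(chains, path) {
  if (is(chains, "MonomerChain")) chains <- list(chains)
  p <- chains[[1]]@params
  hdr <- list(
    params = list(tStart = p@tStart, tFix = p@tFix, spacing = p@spacing,
                  dt = p@dt),
    program = lapply(chains[[1]]@program, function(s) list(
      tag = s@tag, kind = s@kind, rate = s@rate, accel = s@accel,
      accelRate = s@accelRate, tInduce = s@tInduce, kernel = s@kernel,
      rise = s@rise, decay = s@decay)))
  colwise <- function(df) list(tag = df$tag, time = df$time, index = df$index)
  body <- lapply(chains, function(ch) list(
    seed = ch@seed, minus = colwise(ch@minus), plus = colwise(ch@plus)))
  jsonlite::write_json(list(header = hdr, chains = body), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read chains from a JSON file written by [writeChains()]
#'
#' @param path JSON path.
#' @return list of [MonomerChain-class]
#' @export
readChains <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  p <- x$header$params
  params <- growthParams(p$tStart, p$tFix, p$spacing, p$dt)
  prog <- lapply(x$header$program, function(s)
    speciesProgram(s$tag, s$kind, s$rate, s$accel, s$accelRate,
                   if (is.null(s$tInduce)) NA_real_ else s$tInduce,
                   s$kernel, s$rise, s$decay))
  fixSide <- function(lst) {
    if (is.null(lst) || length(lst$tag) == 0L)
      return(data.frame(tag = character(), time = numeric(),
                        index = integer(), stringsAsFactors = FALSE))
    data.frame(tag = unlist(lst$tag), time = unlist(lst$time),
               index = as.integer(unlist(lst$index)),
               stringsAsFactors = FALSE)
  }
  lapply(x$chains, function(ch)
    new("MonomerChain", minus = fixSide(ch$minus), plus = fixSide(ch$plus),
        program = prog, params = params, seed = as.integer(ch$seed)))
}
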
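---
title: "Decoding expression histories from protein-filament recorders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding expression histories from protein-filament recorders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xritrace)
```

## The recording model

An expression recording island (XRI) is an intracellular protein filament
that self-assembles from epitope-tagged monomers and grows from a nucleation
center in two directions. Monomers are incorporated at the two growing ends
in the order the cell expresses them, at a fixed longitudinal spacing of
about 4 nm, so position along each arm is a monotone function of time. Two
kinds of species share the filament:

* a **constitutive** species (tag HA), expressed continuously from the time
  the filament stabilizes (`tStart`, about day 3 after gene delivery) until
  fixation (`tFix`) — possibly at a slowly accelerating rate as the viral
  expression ramps up;
* one or more **induced** species (tags FLAG, V5), expressed only after an
  event: a chemical induction (modeled as a step) or an activity-driven
  promoter pulse (modeled as an alpha-shaped kernel with a fast rise and
  ~1-day decay).

The central modeling postulate is **no competition**: each species is added
at its own rate regardless of which other species are present, the others
merely spacing it out along the filament. Under this postulate the
cumulative amount of constitutive tag laid down from the center to a
position — normalized to 1 at the filament end, the *fraction of the HA
line integral* — is a calibratable surrogate for time: an event at time
$t^\*$ starts to appear at clock fraction

$$f^\* = \frac{\int_{t_{\rm start}}^{t^\*} r_{\rm HA}(\tau)\,d\tau}
             {\int_{t_{\rm start}}^{t_{\rm fix}} r_{\rm HA}(\tau)\,d\tau}.$$

`simulateChain()` draws monomer incorporations per time step (`dt` = 0.01
day), per side and per species from independent Poisson laws with mean
$r_s(t)\,dt$. Each species draws from its own RNG stream keyed by the tag
label, so the constitutive trajectory is *bit-identical* with or without an
induced species in the program — the postulate holds by construction rather
than only in expectation, and the test suite asserts it on simulated
cohorts. `expectedOnsetFraction()` evaluates $f^\*$ on the simulation grid
and is the ground truth for all recovery experiments.

## The decoder

Given per-channel intensity profiles $H(d)$, $F(d)$ on a uniform arc grid
(step $\Delta d$), the profile is split into its two growth halves; per
half, with $d$ measured outward from the split,

$$H\_{\rm integral}(p) = \sum_{d=0}^{p} H(d)\,\Delta d,\qquad
  H\_{\rm fraction\_integral}(p) = H\_{\rm integral}(p) / H\_{\rm integral}({\rm End}),$$

$$F\_{\rm integral}(p) = \sum_{d=0}^{p} F(d)\,\Delta d,\qquad
  F\_{\rm signal} = \frac{\Delta F\_{\rm integral}}{\Delta H\_{\rm fraction\_integral}}.$$

The sums are left-Riemann, exactly as displayed; the derivative is a
difference quotient on native samples with right-edge assignment, linearly
interpolated onto a uniform 201-point grid on $[0,1]$. Because the filament
is symmetric, the two halves carry the same history: `decodeSignal()`
searches every candidate split at sample boundaries within ±25% of the
length around the geometric center, picks the split minimizing the sum of
squared differences (SSD) between the two half signals (ties resolve to the
center), and returns their point-by-point mean.

The **onset** of an induced event is the clock fraction where the signal
begins to rise: the portion of the baseline-subtracted signal between 10%
and 50% of its peak — taken on the piecewise-linear decoded curve,
including the interpolated 10% and 50% crossing points — is fit by ordinary
least squares and extrapolated to zero. Including the crossings makes the
fit well-posed even when a sharp rise spans fewer than two grid samples;
for signals whose rise is resolved it changes nothing, because the
crossings lie on the same line as the in-band samples.

### Numerical choices

* **Minimum clock step** (`minClockStep = 0.02`). The raw difference
  quotient is unbounded where the constitutive channel is locally sparse
  (a near-zero clock increment under a finite induced increment). The
  zero-increment merge rule is therefore generalized: native increments are
  merged forward until each quotient carries at least 2% of the cumulative
  constitutive integral, a trailing remainder folding into the last
  quotient. Setting it to 0 recovers the literal zero-merge rule; all
  analytic identities hold under both.
* **Baseline and end windows.** "The signal at the center/end" uses
  5%-wide windows of the fraction grid rather than single grid points, for
  noise robustness.
* **Rise detection.** A peak counts as a rise only if it clears a noise
  floor of 3 noise-sd. The default noise sd is the largest of three
  estimators — decimated first-difference MAD of the trace, half the sd of
  the difference between the two half signals, and the sd of the
  baseline-window samples — because each misses fluctuation structure the
  others catch (the split search is chosen to make the halves agree, and
  the 201-point grid oversamples the ~50 independent quotients). When the
  baseline is positive (imaging data), the peak must additionally exceed
  half the baseline: every induction design the recorder targets rises to
  at least ~2x baseline, while the filament's discrete-monomer speckle
  produces smooth pseudo-rises of ~20-40% of baseline. Uninduced controls
  are flagged `no-rise` rather than given an onset.
* **Pre-smoothing** of raw profiles (Gaussian, in samples) exists but
  defaults to off; every analytic test passes without it.

## Time calibration

`buildCalibration()` places one knot per timed-induction group at (time,
mean onset fraction), appends the fixation anchor (fraction 1 at `tFix`)
and, by default, an origin anchor (fraction 0 at `tStart`) so early
fractions are mappable; interpolation is piecewise linear and
`fractionToTime()`/`timeToFraction()` are exact inverses on the knot span.
Group summaries are arithmetic means of unflagged onsets (medians
optional). `applyCalibration()` moves a decoded trace onto a uniform
recovered-time grid (step 0.05 day) for cohort averaging, after which
`windowMetrics()` (average/peak/OLS slope over day windows),
`findSignalPeaks()` (local maxima above a topographic-prominence
threshold, for multi-pulse readout) and `compareGroups()`
(Kruskal–Wallis + Dunn, or two-sided Wilcoxon rank-sum for two groups;
Dunn p-values reported raw and Holm-adjusted) summarize cohorts.

## The synthetic microscope

`makeFixture()` renders simulated chains into multipage TIFFs with a truth
manifest. The forward optics are: point masses per monomer laid along a
smooth centerline curve at physical scale, binned at 0.1 µm pixels,
convolved with a Gaussian PSF (sd 0.15 µm), scaled by a gain, plus a
diffuse background; then Poisson shot noise and Gaussian read noise. Two
features matter beyond the obvious:

* **Nonspecific filament-tracking staining** (`bleed`, default 0.05): every
  tag channel receives 5% of the *total* monomer density. Immunostaining
  background binds the dense protein filament, not just the coverslip; an
  induced channel with purely diffuse background would decode to a signal
  proportional to 1/HA and an end/center ratio systematically above 1,
  contradicting the flat uninduced control that motivates the method.
* **Imaging regime**: gain 25 counts/monomer over a background of 1
  count/pixel emulates bright antibody-amplified confocal fields that are
  nearly dark off the filament. The uninduced control (end/center ratio
  ≈ 1, `no-rise` flags) only reproduces in this regime, which matches the
  source images.

Default growth parameters are chosen once, on physical grounds: constant
constitutive rates of 500 monomers/day/side (or 250/day/side at recording
onset with exponential acceleration a = 0.3/day) give filaments of roughly
15–25 µm by fixation — somatic-scale XRIs — so that the 0.15 µm PSF is
about 2% of a half-filament and the rising-phase extrapolation can resolve
onsets at the few-percent level. Induced amplitudes default to half the
constitutive rate, mirroring the diluted titer of the induced construct.
The 14-day in vivo scenario grows at a halved constant rate so filaments
stay in the somatic size range over the doubled window.

What the generator does **not** emulate: 3D image stacks (a single optical
slice is rendered; the decoder consumes 1D profiles either way), chromatic
aberration, expansion-microscopy distortions, crossing or bundled
filaments, soma segmentation, and any systematic deviation from the
no-competition postulate. Passing recovery tests therefore validates the
readout mathematics and its robustness to optics and counting noise — not
the biological postulate itself, which only real timed-induction data can
test.

## Automatic centerline tracing

Real centerlines are drawn by hand and read from CSV; for fixtures,
`traceCenterline()` thresholds the constitutive channel at the image median
plus 4 MAD (a robust background split — a global Otsu threshold lands
between dim, constitutive-diluted segments and bright segments and severs
the ridge), keeps the connected component at the seed, thins it to a
skeleton (Zhang–Suen), takes the longest geodesic path, extends the path
ends along their tangents to undo the end-erosion of thinning, and smooths.
Widths are measured as the median FWHM of perpendicular cuts;
the profile breadth is half the measured width. Profiles are extracted at
arc step = pixel size by averaging bilinear samples along perpendicular
segments. Background subtraction before integration is off by default (the
decoder's ratios rely on the filament-tracking background; a percentile
mode, default the median, is available).

## Validation by parameter recovery

The test suite ties every stage to an oracle: hand-computed cumulative sums
and difference quotients; closed-form FWHM and PSF moments; brute-force
exhaustive split search on random profiles; independent least-squares
refits of the rising phase; exact rank-sum permutation enumeration. On top
sit recovery experiments at the study designs: step inductions at clock
fractions 0.3/0.5/0.7 recovered from noiseless chain densities (cohort
mean error ≲ 0.01) and from rendered noisy images end to end (mean error
≈ 0.02–0.03); a calibration built from day-3..6 cohorts under an
accelerating clock recovering a held-out day-4.5 induction to ±0.25 day;
two c-fos-like pulses at days 5 and 6 both recovered to ±0.5 day; and a
100-chain uninduced control decoding flat. Problem sizes (8–20 chains per
cohort, 100-chain controls, 320-pixel fields) keep the full suite and the
acceptance script to a few minutes on one CPU while leaving the Monte
Carlo standard errors well below the tolerances being asserted.

## Known limitations

* The onset extrapolation inherits a small early bias from PSF blur
  (≈1.6 PSF-sd in clock units) and a small late bias from right-edge
  assignment; at the default geometry these are ≲0.02–0.03 and are
  absorbed by calibration in real use, exactly as in the source protocol.
* Onsets very near 0 (induction at recording onset) are degenerate: the
  signal has no pre-rise baseline, and such chains are flagged rather than
  estimated. Calibrations handle this through the origin anchor.
* One induced channel is decoded per pass; multi-tag joint decoding is out
  of scope (run per channel).
* The end/center ratio is undefined (flagged) when the baseline is not
  positive, e.g. on noiseless densities of an uninduced species.
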
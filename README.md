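# xritrace

Decoding gene-expression histories from expression recording islands (XRIs).

XRIs are intracellular, bidirectionally growing protein filaments whose
self-assembling monomers carry epitope tags. Monomers are added to the two
growing ends in the order they are expressed, so the spatial order of tags
along the filament is a permanent record of the temporal order of expression:
a constitutively expressed tag (HA) lays down a molecular clock, and tags
driven by events of interest (FLAG behind a chemically inducible Cre, V5
behind the activity-dependent c-fos promoter) write those events onto the
filament. After fixation, immunostaining and confocal imaging, the history
can be read back from the per-channel intensity profiles along the filament.

`xritrace` implements that readout end to end, together with a stochastic
forward simulator and a synthetic microscopy renderer, so every stage can be
validated by parameter recovery against known ground truth:

1. **Forward model** — monomer incorporation as independent Poisson
   processes per species and growing end (no competition between species),
   with constitutive, accelerating and induced (step or pulse) rate laws.
2. **Synthetic imaging** — chains laid along smooth centerline curves,
   rendered through a Gaussian PSF with gain, background, nonspecific
   filament-tracking staining, Poisson shot noise and Gaussian read noise.
3. **Profile measurement** — centerline tracing (threshold, skeleton,
   longest path), FWHM width measurement, and per-channel intensity
   profiles along the centerline with the breadth set to half the width.
4. **Decoder** — the core readout mathematics. Each profile is split into
   its two growth halves; per half the clock axis is the fraction of the
   cumulative HA line integral,

   `H_fraction_integral(p) = Σ_{d=0}^{p} H(d)Δd / Σ_{d=0}^{End} H(d)Δd ∈ [0, 1]`,

   and the decoded signal is the derivative of the cumulative induced-tag
   integral with respect to that fraction,

   `F_signal = ΔF_integral / ΔH_fraction_integral`.

   The split point is optimized within ±25% of the length around the
   geometric center to minimize the sum of squared differences between the
   two half signals, which are then averaged point by point. The onset of an
   induced event is found by fitting a line to the 10–50%-of-peak rising
   phase of the baseline-subtracted signal and extrapolating to zero.
5. **Calibration** — a monotone piecewise-linear map between induction time
   and mean onset fraction, anchored at fraction 1 = fixation, used to
   convert decoded traces onto a recovered-time axis.
6. **Cohort analysis** — peak normalization, mean/sd/sem bands, windowed
   average/peak/slope metrics, multi-peak readout, and rank-based group
   statistics (Kruskal–Wallis with Dunn's post hoc test; two-sided Wilcoxon
   rank-sum for two groups).

## Worked example

Simulate a 7-day culture experiment with chemical induction on day 5,
render it to a multichannel image, and read the onset back:

```r
library(xritrace)

dir <- tempfile()
makeFixture("induction-day-5-of-7", seed = 11, dir = dir, nChains = 1,
            rate = 500, accel = "constant")
res <- analyzeFixture(dir, induced = "FLAG")
res$table[, c("expected", "onset", "endCenterRatio")]
#>   expected     onset endCenterRatio
#> 1      0.5 0.4765723        9.99363
```

With a constant constitutive rate, induction on day 5 of a day-3-to-day-7
recording window sits at fraction (5−3)/(7−3) = 0.5 of the HA line
integral; the decoded onset recovers it to ~0.02 despite PSF blur, shot
noise and automatic centerline tracing. The end/center ratio ≫ 1 says the
induced tag is concentrated at the filament ends, i.e. expressed late — an
uninduced control decodes to a ratio near 1 and a `no-rise` flag.

Converting onsets to times uses a calibration built from timed-induction
cohorts:

```r
cal <- buildCalibration(list(`4` = 0.139, `5` = 0.354, `6` = 0.651),
                        tFix = 7, tStart = 3)
fractionToTime(cal, 0.25)
#> [1] 4.516279
```

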
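---
title: "Models and methods: FCS simulation, autocorrelation fitting, and 22q11.2 enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fcscnv)
```

# Scope

`fcscnv` reimplements, as tested code, the quantitative analyses behind a
live-cell study of LZTR1 mobility and the 22q11.2 microduplication in
bladder exstrophy: fluorescence correlation spectroscopy (FCS) from raw
photon counts to fitted diffusion parameters and concentrations, pooled
case-control enrichment statistics, and duplication-interval arithmetic.
Because no raw instrument data are deposited anywhere, a synthetic-data
generator stands in for the confocal instrument; every printed quantity the
package reproduces is recomputed, not transcribed.

# The FCS model

The normalized temporal autocorrelation of the fluorescence intensity
$I(t)$ is

$$G(\tau) = 1 + \frac{\langle \delta I(t)\,\delta I(t+\tau)\rangle}
                    {\langle I(t)\rangle^{2}},
  \qquad \delta I(t) = I(t) - \langle I(t)\rangle ,$$

and is fitted with the standard model for free 3D diffusion of $i$
components with a triplet contribution,

$$G(\tau) = 1 + \frac{1}{N}\sum_i y_i
 \left(1+\frac{\tau}{\tau_{Di}}\right)^{-1}
 \left(1+\frac{w_{xy}^2}{w_z^2}\frac{\tau}{\tau_{Di}}\right)^{-1/2}
 \left(1+\frac{T}{1-T}e^{-\tau/\tau_T}\right),$$

with $N$ the mean number of molecules in the effective observation volume,
$\tau_{Di}$ and $y_i$ ($\sum y_i = 1$) the diffusion time and relative
amplitude of component $i$, $T$ and $\tau_T$ the equilibrium triplet
fraction and relaxation time, and $w_{xy}, w_z$ the radial and axial
$e^{-2}$ radii of the Gaussian detection volume.  The geometry enters only
through $(w_{xy}/w_z)^2 = 1/S^2$; the structure parameter $S^2 = 7$ and the
rhodamine 6G reference diffusion time $\tau_D = 27\ \mu s$ fix
$w_{xy} = \sqrt{4 D_{\mathrm{ref}} \tau_{D,\mathrm{ref}}} \approx 0.211\
\mu m$ and $V_{\mathrm{eff}} = \pi^{3/2} w_{xy}^2 w_z \approx 1.39 \times
10^{-16}$ L, whence one molecule in the volume corresponds to
$C = 1/(N_A V_{\mathrm{eff}}) \approx 12$ nmol/L.  The reference
$D_{\mathrm{ref}} = 414\ \mu m^2/s$ is the 25&nbsp;°C literature value for
Rh6G in water; the source study does not state the value it used, so it is
an explicit, overridable argument of `calibrate()`.

# The synthetic instrument

`simulate_trace()` emulates the recording scheme of a confocal FCS
instrument: arrays of consecutive fixed-length measurements (default ten
1-s segments) of binned photon counts.  Molecules perform Brownian steps
(per-axis Gaussian displacements of variance $2D\,dt$) in a periodic cubic
box whose edge is at least $10\,w_z$, so boundary artifacts stay below the
statistical noise; the expected count per bin sums each molecule's
brightness over the Gaussian profile, gated by the blinking state, and
realized counts are Poisson draws.  Segments are contiguous slices of one
long trajectory, matching consecutive instrument measurements.  All
randomness flows from the single `seed` in `sim_config()` through R's RNG
stream (the compiled inner loop draws from the same stream), so traces are
bit-reproducible.

Choices the source study leaves open, fixed here once:

* **Brightness** 10,000 counts/s per molecule at beam center, background 0
  — a realistic count rate for a bright fluorescent protein under gentle
  live-cell excitation.
* **Triplet defaults** $T = 0.15$, $\tau_T = 3\ \mu s$ when blinking is
  enabled; blinking is off by default.  The blinking chain uses the exact
  discretization of the two-state Markov process (switching probabilities
  $T(1-e^{-dt/\tau_T})$ and $(1-T)(1-e^{-dt/\tau_T})$), so its stationary
  dark fraction is exactly $T$ and its relaxation time exactly $\tau_T$ at
  any step size.
* **Time step** equals the bin width, refined to 4 substeps per bin when
  the fastest diffusion time spans fewer than 10 bins, and further when a
  blinking species needs $dt \le \tau_T/5$.
* **Molecule counts** may be given directly or derived from a molar
  concentration via $n = C N_A L^3$.

What the generator does *not* emulate: detector afterpulsing and dead time,
photobleaching, saturation, anomalous or membrane (2D) diffusion, and
optical aberrations of the real point-spread function.  Passing
recovery tests therefore validates the estimator/fitter chain against an
idealized instrument, not against every artifact of real hardware.

# Correlators

`autocorrelate_direct()` is the literal estimator of the definition above
on a linear lag grid; it doubles as the brute-force oracle.  The default
*symmetric* normalization recomputes the means over the two overlapping
windows at each lag ($G = \langle I_1 I_2\rangle / \langle I_1\rangle
\langle I_2\rangle$), which suppresses drift bias; the textbook *plain*
variant (one global mean) is retained as a documented option, and both are
pinned by a 4-bin hand-computed example in the tests.

`autocorrelate_multitau()` is the hardware-correlator layout: 16 linear
channels at the native bin width, then 8 channels per further level with
counts re-binned by pairwise summation and the bin width doubling per
level, covering microseconds to seconds in ~100 points.  At the finest
level it agrees with the direct estimator to $10^{-10}$ (tested on random
traces).  Lags are reported at the window start time.  `average_series()`
averages segment curves and attaches the segment-to-segment standard error
of the mean — scatter between measurements, not photon statistics.
`normalize_amplitude()` implements the amplitude normalization
$G_n(\tau) = (G(\tau)-1)/(G(\tau_{\mathrm{ref}})-1)$ at a 10-µs reference
used to compare decay shapes across concentrations.

Finite segments bias the estimator slightly downward at lags approaching
the segment length (the means are estimated from the same window).  The
pipeline driver therefore fits only lags up to 20 ms — two orders of
magnitude below the 1-s segments — and the tests check the long-lag return
to baseline where the generating model itself is flat.

# Fitting and model selection

`fit_curve()` performs weighted least squares with the Levenberg–Marquardt
algorithm (`minpack.lm::nls.lm`) under box bounds, with multi-start
initialization of the diffusion times around the half-decay lag.  $N$ and
the $\tau_{Di}$ are optimized on a log scale; the geometry ratio is always
fixed from the calibration (it is an instrument property, not a sample
property).  Triplet bounds $0 \le T < 0.5$ and
$1\,\mu s \le \tau_T \le 20\,\mu s$ keep the triplet term from trading
places with a fast diffusive component.  Weights default to
$1/\mathrm{sem}^2$ when the curve carries per-lag errors.  When the sems
come from only ~10 segments they are themselves noisy, and weighting by
their raw inverse squares biases fits toward lags whose scatter was small
by chance; `smoothed_weights()` regularizes them with a loess fit of
$\log \mathrm{sem}$ against $\log \tau$ before weighting, which is what the
pipeline driver uses.  Standard errors come from the covariance at the
converged solution (delta method for log-scale parameters); non-convergence
is flagged, never silent, and exactly flat curves are rejected.

The convention of always using the model with the lowest number of
components is operationalized in `select_model()` as a nested-model F-test
on the weighted residual sum of squares at $\alpha = 0.05$: component count
$i+1$ replaces $i$ only when the improvement is significant, and the first
accepted (lowest) count is returned.  On synthetic curves this selects one
component for one-component data and two for data generated with the
well-separated 340 µs / 27 ms pair in ≥ 90% of seeds (tested at 50 seeds
each).

The slow-fraction notation of the source ($x_2$) is identified with the
fitted relative amplitude $y_2$; the study's notation switch between its
model equation and its results is noted but cannot be resolved further from
the text.  Whether its instrument software floated or fixed the triplet per
fit is also unstated; the recovery experiments float the triplet for the
trace pipeline (where the model nominally includes it) and disable it for
the analytic-curve experiment whose generating curves contain none.

# Recovery experiments (the headline numbers)

Two experiments connect the package to the study's printed FCS values; both
are run by `scripts/acceptance.R` and the analysis drivers.

1. **Pipeline recovery** (`recover_tauD_pipeline()`): ten 1-s segments of
   2-µs bins for a species generated with $\tau_D = 220\ \mu s$, 200
   molecules in a 6-µm box; multi-tau correlation, segment averaging, a
   one-component fit with floated triplet, median over 5 replicate seeds.
   The scale (10 s of recording rather than the instrument's 100 s, and a
   20-ms fit window) keeps a full 5-replicate run in minutes on one CPU
   while leaving the median comfortably inside the study's ±20 µs band;
   per-seed estimates scatter by roughly ±10%.
2. **Two-component recovery** (`recover_two_component()`): analytic curves
   from the model with $N = 3$, $\tau_{D1} = 340\ \mu s$,
   $\tau_{D2} = 27$ ms, $y_2 = 0.32$, $S^2 = 7$, i.i.d. Gaussian noise of
   sd 0.005 on a 16-points-per-decade grid from 1 µs to 1 s, refitted with
   two components; medians over 20 seeds land within the study's printed
   uncertainties (±50 µs, ±3 ms, ±0.05).

# Enrichment statistics

The pooled case-control table (11 carriers / 422 cases vs 1 / 1,219
controls) is shipped as a data file and reproduces the printed values
exactly: carrier frequencies 2.61% vs 0.08%, cross-product odds ratio 32.6,
and Woolf log-normal 95% CI 4.2–253.3
($\exp(\ln \mathrm{OR} \pm z_{0.975}\sqrt{\sum 1/\mathrm{cell}})$).  The
carrier counts are reconstructed from the printed pooled frequencies
because the per-study carrier narration (2 + 7 + 3 = 12) does not reconcile
with 2.61% of 422; the pooled frequencies are treated as authoritative.
The Haldane–Anscombe +0.5 correction handles zero cells.  The significance
test is a two-sided conditional Fisher exact test (point-probability rule),
verified against a full enumeration oracle on every table with margins up
to 30; the source does not name its test, so its exact printed p-value is
reported but not asserted.  `two_proportion_test()` (Pearson chi-square,
1 df, no continuity correction) supports cohort-vs-cohort comparisons; the
0.25 threshold in `count_from_percent()` flags printed percentages that do
not cleanly identify an integer count.

# Interval arithmetic

Duplication coordinates are treated as 1-based inclusive (array-CGH
reporting convention), so length is $end - start + 1$; at the 2-decimal-Mb
scale reported (all three calls round to 2.57 Mb) the ±1 convention
ambiguity is invisible.  Mb values round half-up, matching how such sizes
are printed.  The parser accepts comma separators, hyphen or en/em dashes,
and tolerates a doubled chromosome token (a typo present in one published
call) with a warning.  BED interchange shifts to 0-based half-open
coordinates and back, with malformed lines reported by line number.
Intersection is the usual (max start, min end), empty on disjoint input.

# Problem sizes and numerical choices

Test-suite simulations use segments of 0.05–3.2 s with 60–300 molecules so
the full suite runs in well under half an hour; the headline pipeline
recovery uses the 10 × 1 s, 200-molecule configuration above.  Degenerate
inputs error early: all-zero traces (undefined normalization), flat curves
(nothing to fit), inverted genomic coordinates, carrier counts exceeding
arm totals.  Fit results sort components by diffusion time and renormalize
amplitudes to sum exactly to 1; exact ties after sorting (possible in
deliberately over-parameterized fits) are separated by one part in $10^9$.

# Known limitations

* The simulator's idealizations listed above; in particular, recovery
  tolerances say nothing about afterpulsing-dominated instruments.
* The periodic box holds the total molecule number fixed, so very-long-lag
  number fluctuations are mildly suppressed relative to an open volume;
  with the box ≥ $10 w_z$ this is far below the fitted-lag window.
* Fisher's exact test and the Woolf interval are conditional/asymptotic
  conventions; other CI constructions (exact conditional, score) would not
  reproduce the printed 4.2–253.3.
* Per-cell statistics of the source ("more than 25 cells per group") are
  not reproducible from the text and are out of scope, as are penetrance
  estimates and the unlabeled cohort-comparison p-values.
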
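# fcscnv

Quantitative re-analysis toolkit for a live-cell genetics workflow that
combines **fluorescence correlation spectroscopy (FCS)** with **22q11.2
microduplication case-control statistics** in the bladder
exstrophy-epispadias complex (BEEC). The package is aimed at readers who
want to verify, rerun, or extend the numbers such a study prints: fitted
diffusion times and molecule numbers from autocorrelation curves, pooled
carrier-frequency enrichment, and duplication-interval sizes. Since no raw
instrument data are deposited, a Brownian-dynamics synthetic instrument
generates photon-count traces so the whole chain is testable end to end.

## What it computes

**FCS.** The normalized temporal autocorrelation of a photon-count trace,

    G(tau) = 1 + <dI(t) dI(t+tau)> / <I>^2,

estimated directly (brute force) or with a multi-tau correlator
(16 channels, then 8 per doubling level), is fitted by weighted
Levenberg–Marquardt least squares with the free 3D diffusion + triplet
model

    G(tau) = 1 + (1/N) * sum_i y_i * (1 + tau/tau_Di)^-1
             * (1 + (w_xy/w_z)^2 tau/tau_Di)^-1/2
             * (1 + T/(1-T) * exp(-tau/tau_T)),

with the component count chosen by a nested F-test ("simplest adequate
model"). Geometry comes from a rhodamine 6G calibration
(tau_D = 27 µs, S² = (w_z/w_xy)² = 7), giving w_xy ≈ 0.211 µm,
V_eff = π^(3/2) w_xy² w_z ≈ 1.39e-16 L, and the concentration conversion
C = N/(N_A·V_eff) ≈ 12 nmol/L per molecule.

**Enrichment.** Pooled 2×2 carrier counts (11/422 BEEC cases vs 1/1,219
controls) give carrier frequencies, the cross-product odds ratio
(Haldane–Anscombe on zero cells), the Woolf log-normal CI, and a two-sided
Fisher exact test verified against an enumeration oracle.

**Intervals.** 1-based inclusive duplication coordinates (hg19) are
parsed, measured (half-up Mb rounding), intersected, and exchanged as BED
(0-based half-open).

## Worked example

The numbered scripts under `analysis/` run the whole study; each is a thin
driver over the package functions and writes under `results/`.

```sh
Rscript analysis/01_simulate_traces.R      # synthetic 10 x 1 s recording
Rscript analysis/02_correlate_and_fit.R    # correlate, average, fit
Rscript analysis/03_two_component_recovery.R
Rscript analysis/04_enrichment.R
Rscript analysis/05_cnv_intervals.R
```

Output of stages 2–5 on this machine:

```
1-component fit: tau_D = 208.4 us (stderr 11.9), N = 0.128
F-test component selection chose i = 1
implied concentration: 1.52 nmol/L

median fast tau_D : 339.4 us (generated 340 us)
median slow tau_D : 27.46 ms (generated 27 ms)
median slow frac  : 0.320    (generated 0.32)

carrier frequency: 2.61% cases vs 0.08% controls
OR = 32.6; 95% CI = 4.2-253.3; Fisher p = 2.7e-06

 patient    region                       inheritance length_bp length_mb
 Patient_1  chr22:18,938,160-21,505,425  maternal      2567266      2.57
 Patient_2  chr22:18,890,264-21,464,056  unknown       2573793      2.57
 Patient_3  chr22:18,890,264-21,461,788  de novo       2571525      2.57
shared duplicated core: chr22:18,938,160-21,461,788 (2.52 Mb)
```

Reading: the simulated trace was generated with tau_D = 220 µs and 200
molecules in a 6 µm box (box concentration 1.54 nmol/L); the single-seed
fit lands within one standard error of the generating diffusion time, the
fitted N reproduces the box concentration, and the two-component experiment
recovers the fast/slow times and the slow fraction. The enrichment and
interval numbers are exact reproductions of the pooled published counts and
the three array-CGH calls bundled under `inst/extdata/`.

A single entry point, `run_repro(seed)`, executes every stage and returns
one JSON-compatible report; see `?run_repro`.

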
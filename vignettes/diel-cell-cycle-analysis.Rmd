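---
title: "Quantifying the diel cell cycle of L/D-synchronized picocyanobacteria"
author: "dielcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the diel cell cycle of L/D-synchronized picocyanobacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological setting and the measurement problem

Marine picocyanobacteria such as *Prochlorococcus marinus* grown under a
modulated 12 h light / 12 h dark cycle synchronize their cell cycle to the
light program: chromosome replication (S phase) starts in the afternoon,
peaks around the light-to-dark transition (LDT), and division completes
during the night, so that by dawn nearly every cell is back in G1 with a
single chromosome copy. Because these cells follow the slow-growth regime
of the prokaryotic cell cycle — at most one replication round per division
cycle, and here at most one per day — a cell's DNA content identifies its
phase: one genome equivalent in G1, two in G2, intermediate in S.

Flow cytometry of DNA-stained cells therefore turns population snapshots
into phase compositions. Three quantitative steps stand between raw
fluorescence events and growth parameters, and this package implements all
three plus the simulator needed to test them end-to-end:

1. **DNA-histogram deconvolution** into fractions $f_{G1}, f_S, f_{G2}$
   (`fitDNAHistogram()`, `fractionsSeries()`);
2. **phase timing and durations** from the diel fraction curves
   (`findPhasePeaks()`, `estimatePhaseDurations()`, `estimateDelay()`);
3. **growth rates** from either the fraction curves (`muCC()`) or cell
   counts (`muNb()`).

A comparative-CT module (`ddct()`) covers the companion qPCR design of
such experiments (reference gene *rnpB*, calibrator sample HL 06:00).

## The histogram model

A measured DNA histogram is modeled as a constrained Gaussian mixture in
the Dean–Jett–Fox tradition:

$$
g(x) = f_{G1}\,\mathcal{N}(x;\, m,\, c\,m)
     + f_{G2}\,\mathcal{N}(x;\, r\,m,\, c\,r\,m)
     + \frac{f_S}{k} \sum_{j=1}^{k}
       \mathcal{N}\!\big(x;\, \mu_j,\, c\,\mu_j\big),
$$

with $\mu_j = m\,(1 + (j - \tfrac12)(r-1)/k)$ evenly spaced between the G1
position $m$ and the G2 position $r\,m$. All components share one
fractional coefficient of variation $c$; the S phase is a "single
rectangle" of $k$ equal-weight segments (default $k = 8$). The ratio $r$
is fixed at exactly 2 by default — the two-chromosome-copy constraint —
and may optionally float in $[1.9, 2.1]$ (`r_free = TRUE`), a range wide
enough to absorb small stain or compensation nonlinearities while
preserving identifiability.

Parameters are estimated by minimizing the Poisson deviance of the bin
counts. Poisson deviance is the right likelihood for the low-count bins
that dominate night-time histograms; a Pearson chi-square objective with
variance $\max(\text{count}, 1)$ is available for parity with legacy
cell-cycle software. Expected bin masses are exact Gaussian integrals over
the bin edges, and model mass falling outside the binning range is *not*
renormalized away: a parameter set that pushes a component out of range
loses expected counts and is penalized, which keeps the weight of an
absent G2 population identifiable.

### Anchoring the G1 position across a series

At timepoints in mid replication wave nearly no G1 cells remain, and with
a free $m$ the optimizer can lock onto the S-phase smear. The G1 peak
position is an instrument property (stain dose, laser power, gain) that
does not move between consecutive samples, so `fractionsSeries()` fits in
two passes: independent fits first, then a robust reference position
(median fitted $m$ over converged timepoints with $f_{G1} \ge 0.3$) is
imposed on every timepoint (`fix_m`). This mirrors how practitioners run
interactive cell-cycle software on diel series. The anchoring can be
disabled (`common_m = FALSE`) when instrument drift is a real concern.

### What the fit can and cannot resolve

S cells that have just entered carry ≈ 1 genome equivalent and S cells
about to finish carry ≈ 2; at a 3% CV neither can be distinguished from
G1 or G2 by *any* mixture model. Errors therefore concentrate at the wave
front and back (single-timepoint errors on $f_S + f_{G2}$ up to ≈ 0.1 in
our tests, cycle-averaged error ≈ 0.01). Two things keep this benign:
the misattribution largely cancels in the sum $f_S + f_{G2}$, which is
exactly the quantity the growth estimator consumes, and it is symmetric
between conditions, so between-condition timing contrasts are unaffected.
The package's tests assert these measured guarantees rather than an
idealized per-fraction accuracy. Aggregates/doublets and multi-ploidy
(> 2C) populations are not modeled; debris can optionally be simulated
but is off by default, as appropriate for axenic cultures.

## Phase timing, durations, and the peak-delay rule

The diel curves $f_S(t)$ and $f_{G2}(t)$ are collapsed to one mean cycle
(circular in clock time, converged fits only), lightly smoothed (centered
circular moving average, default window 3 points; use 1 for exact
simulator truth), and each peak is located by argmax with quadratic
refinement through the three surrounding points. A contiguous plateau of
tied maxima — the signature of perfectly synchronous (degenerate) waves —
resolves to its circular midpoint, which makes the peak-delay rule exact
in that limit; separated equal maxima break toward the earlier time. All
time arithmetic is modulo 24 h, so waves crossing midnight are never
clipped.

Durations follow from two identities:

* **Peak-delay rule**: $T_S + T_{G2} = 2\,\Delta t$ where
  $\Delta t = t_{G2max} - t_{Smax}$ (circular). The package splits the sum
  into $T_S$ and $T_{G2}$ proportionally to the areas under the
  baseline-subtracted $f_S$ and $f_{G2}$ curves — a deterministic,
  testable convention, since the rule itself fixes only the sum.
* **Generation-time identity**: $T_{G1} = 24\ln 2 / \mu_{cc} - (T_S +
  T_{G2})$, i.e. the generation time implied by the growth rate minus the
  replication-division block. Applied to published growth-parameter
  tables for these cultures (`referenceGrowthParams()`), this
  reconstruction reproduces the printed $T_{G1}$ values to ≈ 0.1–0.2 h in
  8 of 10 columns, and the remaining two agree once the rounding of the
  printed $\mu_{cc}$ is propagated; the test suite carries this as a
  regression check.

The synchronization index `syncIndex()` is 100 × the circular angular
deviation (as a fraction of 24 h) of the diel $f_S$ mass: 0 for a
delta-like wave, maximal ($100\sqrt2/2\pi \approx 22.5$) for a uniform
curve, strictly increasing with entry spread. The index definition used
with legacy software is unpublished, so ours is a labeled, swappable
convention and is deliberately excluded from numerical comparisons with
published $S_r$ values.

Between-condition timing shifts are estimated by circular
cross-correlation of the mean-subtracted fraction curves with quadratic
sub-grid refinement (`estimateDelay()`; positive lag = second condition
later, antisymmetric by construction).

## Growth rates

Two estimators, deliberately independent:

* $\mu_{nb} = \ln(N_2/N_1)\cdot 24/\Delta t$ from cell counts across a
  no-division window — by default the 06:00 samples of consecutive days,
  early morning being when the population sits in G1 even for waves that
  run past midnight. Replicate counts are averaged before the ratio.
* $\mu_{cc} = \dfrac{24}{n\,(T_S+T_{G2})} \sum_{i=1}^{n}
  \ln\!\big(1 + f_S(t_i) + f_{G2}(t_i)\big)$ from $n$ samples at fixed
  intervals over one diel cycle. Multi-day series give per-day estimates,
  reported as mean ± mean absolute deviation (the convention used for
  duplicate cultures); whether to pool days instead is not specified
  anywhere authoritative, so per-day-then-average is implemented and
  labeled.

On simulated truth fractions the estimator recovers the per-day division
rate $\ln(2(1-f) + f)$ exactly for perfectly synchronous populations and
within a few percent under realistic entry spread. Run end-to-end through
measured events, $\mu_{cc}$ comes out ≈ 9–10% above $\mu_{nb}$. This bias
is *emergent*, not programmed: the growing-population denominator skews
the fraction curves and shortens the apparent peak delay. Field
measurements of these cultures report the same systematic ≈ 10% excess,
which is why the package compares the two estimators
(`compareMu()`) rather than correcting either.

## The population simulator

`simulatePopulation()` is an exact per-cell bookkeeping model, not a
stepper. Each day every non-arrested cell draws an S-entry clock time
from $\mathcal{N}(\texttt{s\_onset\_clock}, \sigma_{sync})$ and
per-traversal durations around $T_S$ and $T_{G2}$; entry, S-end and
division times are stored as absolute hours, daughters carry their birth
times, and phase state at any sample time is a closed-form lookup. This
is both faster and more accurate than sub-hourly integration: given the
per-cell draws, progression is deterministic, so discretizing it would
only add error. Randomness beyond the per-cell draws enters solely in the
measurement model `measureEvents()` (fluorescence
$= \text{gain} \cdot \text{DNA} \cdot (1+\varepsilon)$,
$\varepsilon \sim \mathcal{N}(0, cv)$, optional low-signal debris), and
every stage is seeded explicitly, making outputs bit-reproducible.

Key modeling decisions, each open in principle:

* **Clock gating, not dose gating.** S entry is gated by clock time (an
  entrainment model); irradiance (`lightSchedule()`, half-sine PAR/UV-A/
  UV-B bands, measured noon maximum 875 µmol photons m⁻² s⁻¹ with the
  nominal 900 available as an alias) is carried as scenario metadata. No
  published dose–response for S-onset exists to calibrate anything
  richer, and the clock-gated model already reproduces the observed phase
  patterns.
* **Stock scenarios.** `scenarioHL()`: entry mean 16:00, σ = 1 h, so the
  earliest cells enter ≈ 14:00 (4 h before the LDT) and — because under a
  symmetric entry model the $f_S$ peak falls at entry mean + $T_S/2$ —
  the S peak lands exactly at the 18:00 LDT and the G2 peak 4 h later.
  `scenarioHLUV()` encodes UV acclimation as a 2 h entrainment delay of
  the same wave (entry mean 18:00): replication pushed ≈ 2 h into the
  dark period. The UV-shortened phase durations reported for acclimated
  cultures can be set through `simParams()` but are not defaulted: the
  stock scenarios isolate the timing effect, which is the contrast the
  delay estimator is meant to recover.
* **Arrest fraction 0.05.** Five percent of cells skipping division each
  day gives a per-day division rate $\ln(2 - 0.05) \approx 0.67$ d⁻¹,
  matching the growth rates these cultures sustain; it also exercises the
  doubling-factor invariant $2(1-f)+f$ in tests.
* **Burn-in day.** One unsampled entrained cycle precedes sampling
  (`burnin_days = 1`). Without it the first sampled morning lacks the
  tail of the previous night's wave, which visibly corrupts the circular
  mean diel curve (G2 peak pulled ~1 h early) and biases $\mu_{cc}$ —
  an artifact of starting from an all-G1 state no acclimated culture is
  ever in. `burnin_days = 0` restores the raw start for degenerate-case
  oracles.
* **Continuous mode.** Dilution is applied as per-day Bernoulli survival
  $e^{-D}$ at day boundaries. Within-day count decay is not modeled;
  phase *fractions* are unbiased by uniform thinning, which is what the
  continuous-culture analyses consume. Excessive dilution extinguishes
  the population and raises an explicit error.
* **Two-component onset mixtures** (the small pre-dusk S "shoulder"
  occasionally seen in continuous UV cultures) are not modeled; one
  component is the default and only implementation, because no published
  quantification of the subpopulation exists to parameterize a second
  component honestly.

What the simulator does *not* emulate, and what passing tests therefore
do not show about real data: photodamage/ROS physiology, dose-dependent
arrest, gene expression, aggregates/doublets, stain variability between
samples, or instrument drift. Tests demonstrate the *estimators* are
correct for populations obeying the stated cell-cycle model, not that the
model captures every feature of a real cyclostat culture.

## qPCR quantification

`ddct()` implements comparative-CT relative quantification with the
canonical efficiency assumption (exactly 2 per cycle, as no efficiency
calibration is available for these assays): technical duplicates are
averaged on the CT scale, $\Delta CT$ is taken against *rnpB*,
$\Delta\Delta CT$ against the HL 06:00 calibrator, $RQ = 2^{-\Delta\Delta
CT}$. Duplicate mean absolute deviations propagate to an RQ interval by
interval arithmetic. Whether biological replicates should be averaged on
the CT or the RQ scale is unstated in the source protocols; CT-scale is
implemented and labeled. Differential-expression calls use
$|\log_2 FC| > 1$ with a strict inequality, so the band $[-1, +1]$ is
"not differentially expressed". The bundled primer table
(`primerTable()`) exists for input validation only.

## Numerical choices and degenerate inputs

* Optimizer: Nelder–Mead, max 2000 iterations, relative tolerance 1e-10;
  a stalled fit returns `converged = FALSE` rather than raising, and
  non-converged timepoints are excluded from peak detection.
* CV is parameterized as $5\times10^{-4} + e^\theta$, so noiseless spike
  histograms are representable without degeneracy; fits with all mass in
  a single bin are rejected outright.
* Histogram range defaults to $[0, 1.02\max(x)]$, which makes the whole
  chain invariant to global rescaling of fluorescence units; out-of-range
  events are counted and reported, never silently dropped.
* Fractions are softmax-parameterized, so normalization
  $f_{G1}+f_S+f_{G2}=1$ holds to machine precision by construction.
* Flat fraction curves (no peak above baseline + 2 × point-to-point noise)
  fail peak detection with an explicit "no replication wave" error;
  identical S and G2 curves give $\Delta t = 0$ and duration estimation
  refuses to proceed.
* A negative reconstructed $T_{G1}$ (inconsistent $\mu_{cc}$ vs
  durations) is an error with a diagnostic, not a silent clamp.

## Problem sizes

The simulation scale used throughout the tests and the acceptance script
— 10⁴ cells, 10⁵ events per timepoint, hourly sampling over two diel
cycles per condition — matches the scale at which the corresponding wet
experiments are analyzed, and runs the full two-condition pipeline in
well under a minute. Oracle and property tests use smaller populations
(a few hundred to a few thousand cells) where exactness, not realism, is
the point.

```{r example}
library(dielcycle)
res <- runScenario(pipelineConfig(seed = 1))
res$summary     # per-condition growth parameters
res$lag_s_h     # S-wave lag, HL+UV relative to HL (hours)
```
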
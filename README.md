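# dielcycle

Quantitative analysis of the **diel cell cycle** of light/dark-synchronized
picophytoplankton (e.g. *Prochlorococcus marinus*) from DNA-content flow
cytometry — for microbial oceanographers and photobiologists who need phase
fractions, phase timings, phase durations and growth rates out of diel
cytometry series, plus the companion qPCR (ΔΔCT) quantification.

Cultures entrained to a modulated 12 h/12 h light cycle replicate their
single chromosome once per day: G1 cells carry one genome equivalent, G2
cells two, S cells intermediate amounts. The package covers the full chain
from fluorescence events to growth parameters:

* **Histogram deconvolution** — a constrained Gaussian mixture in the
  Dean–Jett–Fox tradition: G1 at position *m*, G2 fixed at *2m* (two
  chromosome copies), S as equal-weight Gaussian segments spanning
  (*m*, 2*m*), one shared fractional CV, fit by Poisson deviance
  (`fitDNAHistogram()`, `fractionsSeries()`).
* **Phase timing and durations** — circular peak detection on the diel
  f_S and f_G2 curves; the peak-delay rule *T*_S + *T*_G2 = 2Δ*t* with
  Δ*t* = *t*_G2max − *t*_Smax; *T*_G1 from the generation-time identity
  24·ln2/μ_cc − (*T*_S + *T*_G2); between-condition lags by circular
  cross-correlation (`findPhasePeaks()`, `estimatePhaseDurations()`,
  `estimateDelay()`).
* **Growth rates** — the cell-cycle-based estimator
  μ_cc = 24/(n·(T_S+T_G2)) · Σᵢ ln(1 + f_S(tᵢ) + f_G2(tᵢ))
  and the count-based μ_nb = ln(N₂/N₁)·24/Δt over a no-division window,
  with their systematic ≈10% comparison (`muCC()`, `muNb()`,
  `compareMu()`).
* **A seeded population simulator** — per-cell slow-growth traversal model
  under a half-sine PAR/UV light schedule, with stock scenarios for
  high-light (`scenarioHL()`: S peak at the 18:00 light-to-dark
  transition) and high-light + UV (`scenarioHLUV()`: replication delayed
  2 h into the dark period), plus a flow-cytometer measurement model
  (`simulatePopulation()`, `measureEvents()`).
* **ΔΔCT qPCR quantification** — *rnpB*-normalized, HL 06:00 calibrator,
  RQ = 2^−ΔΔCT with duplicate-deviation intervals and the strict
  |log₂FC| > 1 differential-expression call (`ddct()`, `qpcrAnalyze()`).

See the methods vignette (`vignettes/diel-cell-cycle-analysis.Rmd`) for
the models, conventions and their rationale.

## Worked example

Simulate the two stock conditions (10⁴ cells, 10⁵ events per timepoint,
hourly sampling over two diel cycles), deconvolve every histogram, and
extract timings, durations and growth rates:

```r
library(dielcycle)
res <- runScenario(pipelineConfig(seed = 1))
res$summary
#>   condition mu_cc mu_nb   t_g1   t_s  t_g2   s_r t_smax t_g2max
#> 1        HL 0.731 0.668 15.568 3.367 3.807 5.451 17.962  21.549
#> 2     HL+UV 0.732 0.668 15.558 3.373 3.793 5.465 19.968  23.550
res$lag_s_h
#> [1] 2.005482
```

Reading the output: under HL the S-phase wave peaks at 17.96 h — the
light-to-dark transition — and the G2 wave ~3.6 h later; under HL+UV both
waves sit ≈2 h later, and the cross-correlation lag of the two f_S curves
(`lag_s_h`) recovers that 2 h shift of chromosome replication into the
dark period. Count-based growth (μ_nb ≈ 0.67 d⁻¹) matches the simulated
per-day division rate ln(2 − 0.05); the cell-cycle-based μ_cc runs ≈9%
higher, reproducing the systematic bias known for this estimator (the
growing-population denominator skews the fraction curves). S_r is the
package's synchronization index (lower = tighter synchrony).

The qPCR side, with the calibrator identity and a two-cycle shift:

```r
ct <- data.frame(gene = rep(rep(c("recA", "rnpB"), each = 2), 2),
                 condition = "HL", time_h = rep(c(6, 18), each = 4),
                 replicate = rep(1:2, 4),
                 ct = c(24, 24, 18, 18, 22, 22, 18, 18))
ddct(ct, "recA")
#>   gene condition time_h d_ct dd_ct rq rq_lo rq_hi log2_fc de_call
#> 1 recA        HL      6    6     0  1     1     1       0   FALSE
#> 2 recA        HL     18    4    -2  4     4     4       2    TRUE
```

A thin command-line wrapper over the same functions lives at
`inst/scripts/dielcycle-cli.R` (subcommands `config`, `simulate`,
`analyze`, `run`, `qpcr`).

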
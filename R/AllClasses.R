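#' @import methods
NULL

#' Modulated diel light schedule
#'
#' Describes the half-sine modulated irradiance program of a 12 h / 12 h
#' light/dark cyclostat: photosynthetically available radiation (PAR) plus
#' optional UV-A and UV-B bands. Irradiance in each band rises from zero at
#' dawn to its noon maximum and back to zero at dusk (the light-to-dark
#' transition, LDT), and is zero throughout the dark period.
#'
#' @slot t_dawn clock hour of dawn (hours since midnight).
#' @slot photoperiod_h length of the photoperiod in hours (0 < x < 24).
#' @slot e_max_par maximum PAR at virtual noon, umol photons m-2 s-1.
#' @slot e_max_uva maximum UV-A (320-400 nm) irradiance, W m-2.
#' @slot e_max_uvb maximum UV-B (280-320 nm) irradiance, W m-2.
#'
#' @seealso [lightSchedule()], [irradianceAt()]
#' @export
setClass("LightSchedule",
  representation(
    t_dawn = "numeric",
    photoperiod_h = "numeric",
    e_max_par = "numeric",
    e_max_uva = "numeric",
    e_max_uvb = "numeric"
  ),
  prototype(
    t_dawn = 6, photoperiod_h = 12,
    e_max_par = 875, e_max_uva = 7.59, e_max_uvb = 0.57
  )
)

setValidity("LightSchedule", function(object) {
  msg <- character()
  if (length(object@t_dawn) != 1L || object@t_dawn < 0 || object@t_dawn >= 24)
    msg <- c(msg, "t_dawn must be a single clock hour in [0, 24)")
  if (length(object@photoperiod_h) != 1L ||
      object@photoperiod_h <= 0 || object@photoperiod_h >= 24)
    msg <- c(msg, "photoperiod_h must be in (0, 24)")
  if (any(c(object@e_max_par, object@e_max_uva, object@e_max_uvb) < 0))
    msg <- c(msg, "irradiance maxima must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Parameters of the L/D-synchronized population simulator
#'
#' Encodes the slow-growth diel cell cycle: each cell traverses at most one
#' G1 -> S -> G2 -> division round per 24 h. Non-arrested cells draw their
#' S-entry time each day from Normal(`s_onset_clock`, `sigma_sync`), then
#' per-traversal S and G2 durations around `t_s` and `t_g2`.
#'
#' @slot n0 initial number of cells (interpreted as cells mL-1).
#' @slot s_onset_clock mean clock hour of S entry (hours since midnight).
#' @slot sigma_sync between-cell SD of the S-entry time, hours.
#' @slot t_s mean S duration, hours.
#' @slot t_g2 mean G2 duration, hours.
#' @slot jitter_s per-cell SD of the S duration, hours.
#' @slot jitter_g2 per-cell SD of the G2 duration, hours.
#' @slot frac_arrested fraction of cells that skip division on a given day.
#' @slot mode `"batch"` or `"continuous"`.
#' @slot dilution dilution rate (d-1) in continuous mode; ignored in batch.
#' @slot seed integer seed driving all randomness of the simulation.
#'
#' @seealso [simParams()], [simulatePopulation()], [scenarioHL()]
#' @export
setClass("SimParams",
  representation(
    n0 = "numeric",
    s_onset_clock = "numeric",
    sigma_sync = "numeric",
    t_s = "numeric",
    t_g2 = "numeric",
    jitter_s = "numeric",
    jitter_g2 = "numeric",
    frac_arrested = "numeric",
    mode = "character",
    dilution = "numeric",
    seed = "numeric"
  ),
  prototype(
    n0 = 10000, s_onset_clock = 16, sigma_sync = 1,
    t_s = 4, t_g2 = 4, jitter_s = 0, jitter_g2 = 0,
    frac_arrested = 0.05, mode = "batch", dilution = 0, seed = 1
  )
)

setValidity("SimParams", function(object) {
  msg <- character()
  if (object@n0 < 1) msg <- c(msg, "n0 must be >= 1")
  if (object@t_s <= 0) msg <- c(msg, "t_s must be > 0")
  if (object@t_g2 <= 0) msg <- c(msg, "t_g2 must be > 0")
  if (object@sigma_sync < 0) msg <- c(msg, "sigma_sync must be >= 0")
  if (object@jitter_s < 0 || object@jitter_g2 < 0)
    msg <- c(msg, "duration jitters must be >= 0")
  if (object@frac_arrested < 0 || object@frac_arrested >= 1)
    msg <- c(msg, "frac_arrested must be in [0, 1)")
  if (!object@mode %in% c("batch", "continuous"))
    msg <- c(msg, "mode must be 'batch' or 'continuous'")
  if (object@mode == "continuous" && object@dilution < 0)
    msg <- c(msg, "dilution must be >= 0")
  if (object@s_onset_clock < 0 || object@s_onset_clock >= 24)
    msg <- c(msg, "s_onset_clock must be a clock hour in [0, 24)")
  if (length(msg)) msg else TRUE
})

#' Flow-cytometer measurement model for the DNA stain signal
#'
#' Converts true per-cell DNA content (genome equivalents, 1 for G1 cells,
#' 2 for G2 cells, intermediate in S) into a measured fluorescence value:
#' `fl = gain * dna * (1 + eps)` with `eps ~ Normal(0, cv)`. Optionally a
#' fraction of low-signal debris events is appended. The expected G2 peak
#' position is therefore exactly twice the G1 peak position.
#'
#' @slot gain fluorescence units (a.u.) per genome equivalent.
#' @slot cv fractional coefficient of variation of the measured signal.
#' @slot bead_position position (a.u.) of an optional internal reference
#'   bead population; `NA_real_` disables it.
#' @slot debris_frac fraction of returned events that are low-signal debris.
#'
#' @seealso [instrumentModel()], [measureEvents()]
#' @export
setClass("InstrumentModel",
  representation(
    gain = "numeric",
    cv = "numeric",
    bead_position = "numeric",
    debris_frac = "numeric"
  ),
  prototype(gain = 200, cv = 0.03, bead_position = NA_real_, debris_frac = 0)
)

setValidity("InstrumentModel", function(object) {
  msg <- character()
  if (object@gain <= 0) msg <- c(msg, "gain must be > 0")
  if (object@cv <= 0) msg <- c(msg, "cv must be > 0")
  if (object@debris_frac < 0 || object@debris_frac >= 1)
    msg <- c(msg, "debris_frac must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Single-timepoint DNA-fluorescence event sample
#'
#' Per-cell DNA-stain fluorescence values recorded at one sampling time of
#' the diel cycle, with condition/replicate metadata.
#'
#' @slot t clock hour of sampling in [0, 24).
#' @slot day day index (0-based) of the sampling within a multi-day series.
#' @slot events numeric vector of fluorescence values, all > 0.
#' @slot condition condition label (e.g. "HL", "HL+UV").
#' @slot replicate replicate identifier.
#'
#' @seealso [eventSample()], [buildHistogram()]
#' @export
setClass("EventSample",
  representation(
    t = "numeric",
    day = "integer",
    events = "numeric",
    condition = "character",
    replicate = "character"
  ),
  prototype(t = 0, day = 0L, events = numeric(),
            condition = NA_character_, replicate = NA_character_)
)

setValidity("EventSample", function(object) {
  msg <- character()
  if (length(object@t) != 1L || object@t < 0 || object@t >= 24)
    msg <- c(msg, "t must be a single clock hour in [0, 24)")
  if (length(object@events) && any(object@events <= 0))
    msg <- c(msg, "all event values must be > 0")
  if (length(msg)) msg else TRUE
})

#' Binned DNA-content histogram
#'
#' Linear-binned histogram of DNA-fluorescence events. Events falling
#' outside the binning range are counted in `n_below` / `n_above` rather
#' than silently dropped.
#'
#' @slot bin_edges strictly increasing bin edges (a.u.), length = bins + 1.
#' @slot counts non-negative integer counts per bin.
#' @slot n_events number of in-range events, `sum(counts)`.
#' @slot n_below events below the range.
#' @slot n_above events at or above the upper range limit.
#'
#' @seealso [buildHistogram()], [fitDNAHistogram()]
#' @export
setClass("DNAHistogram",
  representation(
    bin_edges = "numeric",
    counts = "numeric",
    n_events = "numeric",
    n_below = "numeric",
    n_above = "numeric"
  )
)

setValidity("DNAHistogram", function(object) {
  msg <- character()
  if (length(object@counts) != length(object@bin_edges) - 1L)
    msg <- c(msg, "length(counts) must equal length(bin_edges) - 1")
  if (any(diff(object@bin_edges) <= 0))
    msg <- c(msg, "bin_edges must be strictly increasing")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (!isTRUE(all.equal(sum(object@counts), object@n_events)))
    msg <- c(msg, "sum(counts) must equal n_events")
  if (length(msg)) msg else TRUE
})

#' Result of the constrained DNA-histogram mixture fit
#'
#' G1/S/G2 fractions from a Dean-Jett-Fox-style constrained Gaussian
#' mixture: a G1 Gaussian at position `m`, a G2 Gaussian at `r * m`
#' (`r` fixed at 2 by default, the two-chromosome-copy constraint), and an
#' S component made of `n_s_segments` equal-weight Gaussians with means
#' evenly spaced between the two peaks, all sharing the fractional CV.
#'
#' @slot m fitted G1 peak position (a.u.).
#' @slot r fitted (or fixed) G2/G1 position ratio.
#' @slot cv fitted shared fractional coefficient of variation.
#' @slot f_g1,f_s,f_g2 phase fractions, non-negative, summing to 1.
#' @slot n_s_segments number of Gaussian segments in the S component.
#' @slot gof reduced goodness-of-fit statistic (objective / d.o.f.).
#' @slot objective `"poisson"` (deviance) or `"chisq"`.
#' @slot converged logical optimizer convergence flag.
#'
#' @seealso [fitDNAHistogram()], [phaseFractions()]
#' @export
setClass("HistFitResult",
  representation(
    m = "numeric",
    r = "numeric",
    cv = "numeric",
    f_g1 = "numeric",
    f_s = "numeric",
    f_g2 = "numeric",
    n_s_segments = "integer",
    gof = "numeric",
    objective = "character",
    converged = "logical"
  )
)

setValidity("HistFitResult", function(object) {
  msg <- character()
  fr <- c(object@f_g1, object@f_s, object@f_g2)
  if (any(fr < -1e-9) || any(fr > 1 + 1e-9))
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (abs(sum(fr) - 1) > 1e-9)
    msg <- c(msg, "fractions must sum to 1")
  if (object@r < 1.9 - 1e-9 || object@r > 2.1 + 1e-9)
    msg <- c(msg, "G2/G1 ratio must lie in [1.9, 2.1]")
  if (length(msg)) msg else TRUE
})

#' Diel phase-fraction time series
#'
#' Fractions of cells in G1, S and G2 at each sampling time of one or more
#' diel cycles, either the simulator's exact truth or assembled from
#' per-timepoint histogram fits (in which case fit diagnostics are carried
#' in extra columns and non-converged points are flagged).
#'
#' @slot data data.frame with at least columns `time_h` (clock hours),
#'   `day_index` (0-based), `f_G1`, `f_S`, `f_G2` and logical `converged`.
#' @slot condition condition label.
#'
#' @seealso [fractionsSeries()], [findPhasePeaks()], [muCC()]
#' @export
setClass("PhaseFractionSeries",
  representation(data = "data.frame", condition = "character"),
  prototype(condition = NA_character_)
)

setValidity("PhaseFractionSeries", function(object) {
  d <- object@data
  need <- c("time_h", "day_index", "f_G1", "f_S", "f_G2", "converged")
  if (!all(need %in% names(d)))
    return(paste("data must have columns:", paste(need, collapse = ", ")))
  fr <- as.matrix(d[, c("f_G1", "f_S", "f_G2")])
  msg <- character()
  if (any(fr < -1e-9) || any(fr > 1 + 1e-9))
    msg <- c(msg, "fractions must lie in [0, 1]")
  ok <- d$converged
  if (any(ok) && any(abs(rowSums(fr[ok, , drop = FALSE]) - 1) > 1e-6))
    msg <- c(msg, "fractions must sum to 1 at converged points")
  if (any(d$time_h < 0 | d$time_h >= 24))
    msg <- c(msg, "time_h must be clock hours in [0, 24)")
  for (day in unique(d$day_index)) {
    tt <- d$time_h[d$day_index == day]
    if (any(diff(tt) <= 0)) {
      msg <- c(msg, "time_h must be strictly increasing within each day")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Peak timing of the S and G2 fraction waves
#'
#' Clock times of the diel maxima of the S and G2 phase-fraction curves and
#' their circular delay; the basis of the twice-the-peak-delay duration
#' rule T_S + T_G2 = 2 * delta_t.
#'
#' @slot t_smax clock hour of the f_S maximum.
#' @slot t_g2max clock hour of the f_G2 maximum.
#' @slot delta_t circular delay (t_g2max - t_smax) mod 24, hours.
#' @slot smoothing_window moving-average window (points) used.
#'
#' @seealso [findPhasePeaks()], [estimatePhaseDurations()]
#' @export
setClass("PhaseTiming",
  representation(
    t_smax = "numeric",
    t_g2max = "numeric",
    delta_t = "numeric",
    smoothing_window = "integer"
  )
)

setValidity("PhaseTiming", function(object) {
  msg <- character()
  if (object@delta_t < 0 || object@delta_t >= 24)
    msg <- c(msg, "delta_t must lie in [0, 24)")
  if (length(msg)) msg else TRUE
})

#' Cell-cycle phase durations and synchronization index
#'
#' @slot t_s S duration, hours.
#' @slot t_g2 G2 duration, hours.
#' @slot t_g1 G1 duration, hours (from the generation-time identity).
#' @slot t_s_plus_g2 T_S + T_G2, hours (= 2 * delta_t).
#' @slot s_r synchronization index (lower = better synchronized);
#'   `NA_real_` when not computed.
#' @slot s_r_metric label of the synchronization metric used.
#'
#' @seealso [estimatePhaseDurations()], [syncIndex()]
#' @export
setClass("PhaseDurations",
  representation(
    t_s = "numeric",
    t_g2 = "numeric",
    t_g1 = "numeric",
    t_s_plus_g2 = "numeric",
    s_r = "numeric",
    s_r_metric = "character"
  ),
  prototype(s_r = NA_real_, s_r_metric = NA_character_)
)

setValidity("PhaseDurations", function(object) {
  msg <- character()
  if (abs(object@t_s + object@t_g2 - object@t_s_plus_g2) > 1e-9)
    msg <- c(msg, "t_s + t_g2 must equal t_s_plus_g2")
  if (any(c(object@t_s, object@t_g2, object@t_g1) <= 0))
    msg <- c(msg, "all durations must be > 0")
  if (length(msg)) msg else TRUE
})

#' Paired growth-rate estimates
#'
#' Holds the cell-cycle-based estimate `mu_cc` (Carpenter-Chang, from diel
#' S+G2 fraction curves) and the count-based estimate `mu_nb` (log ratio of
#' cell counts across a no-division window), with their relative bias.
#'
#' @slot mu_cc cell-cycle-based growth rate, d-1 (mean across days).
#' @slot mu_cc_per_day per-day estimates, d-1.
#' @slot mu_cc_dev mean absolute deviation of the per-day estimates.
#' @slot mu_nb count-based growth rate, d-1 (`NA_real_` if unavailable).
#' @slot n samples per diel cycle used by the cell-cycle estimator.
#' @slot bias_pct 100 * (mu_cc / mu_nb - 1); `NA_real_` without mu_nb.
#'
#' @seealso [muCC()], [muNb()], [compareMu()]
#' @export
setClass("GrowthEstimate",
  representation(
    mu_cc = "numeric",
    mu_cc_per_day = "numeric",
    mu_cc_dev = "numeric",
    mu_nb = "numeric",
    n = "integer",
    bias_pct = "numeric"
  ),
  prototype(mu_nb = NA_real_, bias_pct = NA_real_, mu_cc_dev = NA_real_)
)

setValidity("GrowthEstimate", function(object) {
  if (!is.na(object@mu_cc) && object@mu_cc < 0)
    "mu_cc must be >= 0" else TRUE
})
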
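#' Simulate an L/D-synchronized picocyanobacterial population
#'
#' Cohort simulation of the slow-growth diel cell cycle: every day each
#' non-arrested cell draws an S-entry time from
#' Normal(`s_onset_clock`, `sigma_sync`) and per-traversal S and G2
#' durations; division at entry + T_S + T_G2 replaces one G2 cell with two
#' G1 daughters. Cells execute at most one replication round per 24 h.
#' Progression is exact given the per-cell draws (per-cell entry, S-end and
#' division times are kept as absolute hours, so divisions that straddle
#' midnight are counted correctly); stochasticity beyond the per-cell draws
#' enters only at measurement ([measureEvents()]).
#'
#' In `"continuous"` mode cells are removed uniformly at random with
#' per-day survival probability `exp(-dilution)`, applied at day
#' boundaries; phase fractions are unbiased by this thinning. A population
#' that thins to zero raises an error.
#'
#' @param params a [SimParams-class] object.
#' @param schedule a [LightSchedule-class] object. The schedule is carried
#'   as scenario metadata: S entry is gated by clock time (an entrainment
#'   model), not by instantaneous irradiance dose.
#' @param sample_times clock hours in [0, 24) at which to sample, applied
#'   on every simulated day.
#' @param n_days number of sampled diel cycles (>= 1).
#' @param burnin_days unsampled cycles simulated before sampling starts
#'   (default 1), so that the first sampled day already carries the tail
#'   of a previous replication wave — an entrained, acclimated culture.
#'   Set to 0 to sample from the all-G1 initial state.
#' @return a list with elements
#'   \describe{
#'     \item{truth}{a [PhaseFractionSeries-class] of exact phase fractions,}
#'     \item{counts}{a data.frame `day_index`, `time_h`, `t_abs`, `n_cells`,}
#'     \item{snapshots}{a list (one per sample, in time order) of
#'       data.frames `phase`, `phase_age`, `dna_content`,}
#'     \item{sample_index}{a data.frame mapping snapshot index to
#'       `day_index` and `time_h`.}
#'   }
#' @examples
#' sim <- simulatePopulation(simParams(n0 = 500, seed = 42),
#'                           sample_times = seq(0, 22, by = 2), n_days = 1)
#' head(phaseFractions(sim$truth))
#' @export
simulatePopulation <- function(params, schedule = lightSchedule(),
                               sample_times = 0:23, n_days = 2,
                               burnin_days = 1L) {
  stopifnot(is(params, "SimParams"), is(schedule, "LightSchedule"))
  validObject(params); validObject(schedule)
  if (n_days < 1) stop("n_days must be >= 1")
  if (burnin_days < 0) stop("burnin_days must be >= 0")
  sample_times <- sort(as.numeric(sample_times))
  if (any(sample_times < 0 | sample_times >= 24))
    stop("sample_times must be clock hours in [0, 24)")

  set.seed(as.integer(params@seed))
  survival <- if (params@mode == "continuous") exp(-params@dilution) else 1

  total_days <- n_days + burnin_days
  cohorts <- vector("list", total_days + 1L)
  born <- rep(0, params@n0)
  for (k in 0:total_days) {
    n_k <- length(born)
    if (n_k == 0L)
      stop("population extinct (continuous-mode dilution removed all cells)")
    arrested <- if (params@frac_arrested > 0)
      stats::runif(n_k) < params@frac_arrested else rep(FALSE, n_k)
    entry <- 24 * k + stats::rnorm(n_k, params@s_onset_clock,
                                   params@sigma_sync)
    entry <- pmax(entry, born + 1e-6)
    ts <- pmax(params@t_s +
                 (if (params@jitter_s > 0)
                    stats::rnorm(n_k, 0, params@jitter_s) else 0), 0.1)
    tg2 <- pmax(params@t_g2 +
                  (if (params@jitter_g2 > 0)
                     stats::rnorm(n_k, 0, params@jitter_g2) else 0), 0.1)
    s_end <- entry + ts
    div <- s_end + tg2
    cover_end <- ifelse(arrested, 24 * (k + 1), div)
    cohorts[[k + 1L]] <- data.frame(
      born = born, arrested = arrested, entry = entry, ts = ts,
      s_end = s_end, div = div, cover_end = cover_end)

    # next generation: arrested cells persist, dividers leave two daughters
    born <- c(rep(24 * (k + 1), sum(arrested)),
              rep(div[!arrested], each = 2L))
    if (survival < 1 && length(born))
      born <- born[stats::runif(length(born)) < survival]
  }

  grid <- expand.grid(time_h = sample_times, day_index = 0:(n_days - 1L))
  grid <- grid[order(grid$day_index, grid$time_h), c("day_index", "time_h")]
  grid$t_abs <- 24 * (grid$day_index + burnin_days) + grid$time_h
  n_samp <- nrow(grid)

  snapshots <- vector("list", n_samp)
  fr <- matrix(NA_real_, n_samp, 3,
               dimnames = list(NULL, c("f_G1", "f_S", "f_G2")))
  n_cells <- integer(n_samp)
  for (i in seq_len(n_samp)) {
    t <- grid$t_abs[i]
    parts <- lapply(cohorts, function(co) {
      pres <- co$born <= t & t < co$cover_end
      if (!any(pres)) return(NULL)
      co <- co[pres, , drop = FALSE]
      phase <- ifelse(co$arrested | t < co$entry, "G1",
                      ifelse(t < co$s_end, "S", "G2"))
      age <- ifelse(phase == "G1", t - co$born,
                    ifelse(phase == "S", t - co$entry, t - co$s_end))
      dna <- ifelse(phase == "G1", 1,
                    ifelse(phase == "S", 1 + (t - co$entry) / co$ts, 2))
      data.frame(phase = phase, phase_age = age, dna_content = dna)
    })
    snap <- do.call(rbind, parts)
    snapshots[[i]] <- snap
    n_cells[i] <- nrow(snap)
    fr[i, ] <- c(mean(snap$phase == "G1"), mean(snap$phase == "S"),
                 mean(snap$phase == "G2"))
  }

  truth <- phaseFractionSeries(
    data.frame(time_h = grid$time_h, day_index = grid$day_index,
               f_G1 = fr[, 1], f_S = fr[, 2], f_G2 = fr[, 3],
               converged = TRUE))
  counts <- data.frame(day_index = grid$day_index, time_h = grid$time_h,
                       t_abs = grid$t_abs, n_cells = n_cells)
  list(truth = truth, counts = counts, snapshots = snapshots,
       sample_index = grid[, c("day_index", "time_h")])
}

#' Measure DNA-stain fluorescence events from a cell snapshot
#'
#' Applies the instrument model to true per-cell DNA content:
#' `fl = gain * dna * (1 + eps)` with `eps ~ Normal(0, cv)`; a
#' `debris_frac` share of the returned events is replaced by low-signal
#' debris drawn uniformly below the G1 position. Deterministic under
#' `seed`.
#'
#' @param cells a snapshot data.frame from [simulatePopulation()] (needs a
#'   `dna_content` column).
#' @param instrument an [InstrumentModel-class] object.
#' @param n_events number of events to record.
#' @param seed integer seed for the measurement draw.
#' @param replace sample cells with replacement (default TRUE; with
#'   `FALSE`, `n_events` must not exceed the population size).
#' @param t,day,condition metadata stored on the returned sample.
#' @return an [EventSample-class] object.
#' @export
measureEvents <- function(cells, instrument, n_events, seed = 1,
                          replace = TRUE, t = 0, day = 0L,
                          condition = NA_character_) {
  stopifnot(is(instrument, "InstrumentModel"))
  validObject(instrument)
  n_pop <- nrow(cells)
  if (is.null(n_pop) || n_pop == 0L) stop("empty population")
  if (!replace && n_events > n_pop)
    stop("n_events exceeds population size; use replace = TRUE")
  set.seed(as.integer(seed))
  n_debris <- round(instrument@debris_frac * n_events)
  n_cell <- n_events - n_debris
  idx <- sample.int(n_pop, n_cell, replace = replace)
  dna <- cells$dna_content[idx]
  fl <- instrument@gain * dna *
    (1 + stats::rnorm(n_cell, 0, instrument@cv))
  fl[fl <= 0] <- instrument@gain * 1e-6
  if (n_debris > 0) {
    fl <- c(fl, instrument@gain * stats::runif(n_debris, 0.02, 0.7))
  }
  eventSample(t = t, events = fl, day = day, condition = condition)
}

#' Simulate a condition and measure events at every sample time
#'
#' Convenience wrapper chaining [simulatePopulation()] and
#' [measureEvents()]: one event sample per sampling time, with measurement
#' seeds derived deterministically from `seed_measure`.
#'
#' @inheritParams simulatePopulation
#' @param instrument an [InstrumentModel-class] object.
#' @param n_events events recorded per timepoint.
#' @param seed_measure base seed for the measurement draws (timepoint i
#'   uses `seed_measure + i`).
#' @param condition condition label stored on each sample.
#' @return a list with `samples` (list of [EventSample-class]), plus the
#'   `truth`, `counts` and `sample_index` elements of
#'   [simulatePopulation()].
#' @export
simulateMeasuredSeries <- function(params, schedule = lightSchedule(),
                                   sample_times = 0:23, n_days = 2,
                                   burnin_days = 1L,
                                   instrument = instrumentModel(),
                                   n_events = 1e5,
                                   seed_measure = params@seed + 5000,
                                   condition = NA_character_) {
  sim <- simulatePopulation(params, schedule, sample_times, n_days,
                            burnin_days = burnin_days)
  samples <- vector("list", length(sim$snapshots))
  for (i in seq_along(samples)) {
    samples[[i]] <- measureEvents(
      sim$snapshots[[i]], instrument, n_events,
      seed = seed_measure + i, t = sim$sample_index$time_h[i],
      day = sim$sample_index$day_index[i], condition = condition)
  }
  list(samples = samples, truth = sim$truth, counts = sim$counts,
       sample_index = sim$sample_index)
}
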
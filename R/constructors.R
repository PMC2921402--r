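#' Create a modulated diel light schedule
#'
#' @param t_dawn clock hour of dawn (default 6, i.e. 06:00).
#' @param photoperiod_h photoperiod length in hours (default 12).
#' @param e_max_par maximum PAR at virtual noon, umol photons m-2 s-1.
#'   Default 875, the measured cyclostat value; the nominal alias 900 can be
#'   requested with `e_max_par = "nominal"`.
#' @param e_max_uva maximum UV-A irradiance, W m-2 (default 7.59).
#' @param e_max_uvb maximum UV-B irradiance, W m-2 (default 0.57).
#' @return a [LightSchedule-class] object.
#' @examples
#' sched <- lightSchedule()
#' irradianceAt(12, sched) # noon maximum
#' @export
lightSchedule <- function(t_dawn = 6, photoperiod_h = 12,
                          e_max_par = 875, e_max_uva = 7.59,
                          e_max_uvb = 0.57) {
  if (identical(e_max_par, "nominal")) e_max_par <- 900
  new("LightSchedule", t_dawn = t_dawn, photoperiod_h = photoperiod_h,
      e_max_par = as.numeric(e_max_par), e_max_uva = e_max_uva,
      e_max_uvb = e_max_uvb)
}

#' Create simulator parameters
#'
#' Defaults describe a high-light (HL) acclimated batch culture: S entry
#' centred at 16:00 with 1 h spread (so the earliest cells enter around
#' 14:00 and the S-fraction peak falls at the 18:00 light-to-dark
#' transition), T_S = T_G2 = 4 h, and 5% of cells skipping division so the
#' per-day division rate ln(2 - frac_arrested) is about 0.67 d-1.
#'
#' @param n0 initial number of cells (cells mL-1).
#' @param s_onset_clock mean clock hour of S entry.
#' @param sigma_sync SD of the per-cell S-entry time, hours.
#' @param t_s,t_g2 mean S and G2 durations, hours.
#' @param jitter_s,jitter_g2 per-cell duration SDs, hours.
#' @param frac_arrested fraction of cells skipping division each day.
#' @param mode `"batch"` or `"continuous"`.
#' @param dilution dilution rate (d-1), continuous mode only.
#' @param seed integer seed.
#' @return a [SimParams-class] object.
#' @export
simParams <- function(n0 = 10000, s_onset_clock = 16, sigma_sync = 1,
                      t_s = 4, t_g2 = 4, jitter_s = 0, jitter_g2 = 0,
                      frac_arrested = 0.05, mode = c("batch", "continuous"),
                      dilution = 0, seed = 1) {
  mode <- match.arg(mode)
  new("SimParams", n0 = n0, s_onset_clock = s_onset_clock,
      sigma_sync = sigma_sync, t_s = t_s, t_g2 = t_g2,
      jitter_s = jitter_s, jitter_g2 = jitter_g2,
      frac_arrested = frac_arrested, mode = mode, dilution = dilution,
      seed = seed)
}

#' Create a flow-cytometer measurement model
#'
#' @param gain fluorescence units per genome equivalent (a.u.).
#' @param cv fractional CV of the measured fluorescence.
#' @param bead_position optional internal-reference bead position (a.u.).
#' @param debris_frac fraction of low-signal debris events.
#' @return an [InstrumentModel-class] object.
#' @export
instrumentModel <- function(gain = 200, cv = 0.03, bead_position = NA_real_,
                            debris_frac = 0) {
  new("InstrumentModel", gain = gain, cv = cv,
      bead_position = bead_position, debris_frac = debris_frac)
}

#' Create an event sample
#'
#' @param t clock hour of sampling in [0, 24).
#' @param events numeric vector of fluorescence values (a.u.), all > 0.
#' @param day 0-based day index within a multi-day series.
#' @param condition,replicate metadata labels.
#' @return an [EventSample-class] object.
#' @export
eventSample <- function(t, events, day = 0L, condition = NA_character_,
                        replicate = NA_character_) {
  new("EventSample", t = t, day = as.integer(day), events = as.numeric(events),
      condition = condition, replicate = replicate)
}

#' Assemble a phase-fraction series from a data.frame
#'
#' @param data data.frame with columns `time_h`, `day_index`, `f_G1`,
#'   `f_S`, `f_G2` and optionally `converged` (defaults to TRUE).
#' @param condition condition label.
#' @return a [PhaseFractionSeries-class] object.
#' @export
phaseFractionSeries <- function(data, condition = NA_character_) {
  if (is.null(data$converged)) data$converged <- TRUE
  if (is.null(data$day_index)) data$day_index <- 0L
  data <- data[order(data$day_index, data$time_h), , drop = FALSE]
  rownames(data) <- NULL
  new("PhaseFractionSeries", data = data, condition = condition)
}

#' Pair growth-rate estimates
#'
#' @param mu_cc result of [muCC()] (or a single numeric value).
#' @param mu_nb result of [muNb()] (optional).
#' @return a [GrowthEstimate-class] object; see [compareMu()].
#' @export
growthEstimate <- function(mu_cc, mu_nb = NA_real_) {
  if (is.numeric(mu_cc) && is.null(names(mu_cc)) && length(mu_cc) == 1L)
    mu_cc <- list(mu = mu_cc, per_day = mu_cc, dev = NA_real_, n = NA_integer_)
  bias <- if (is.na(mu_nb)) NA_real_ else 100 * (mu_cc$mu / mu_nb - 1)
  new("GrowthEstimate", mu_cc = mu_cc$mu, mu_cc_per_day = mu_cc$per_day,
      mu_cc_dev = mu_cc$dev, mu_nb = mu_nb,
      n = as.integer(mu_cc$n), bias_pct = bias)
}

#' Extract the phase-fraction table
#'
#' @param x a [PhaseFractionSeries-class] object.
#' @param ... unused.
#' @return the underlying data.frame.
#' @export
setMethod("phaseFractions", "PhaseFractionSeries", function(x, ...) x@data)

#' Accessors for dielcycle result objects
#'
#' @param x a dielcycle S4 object.
#' @name accessors
#' @return the requested scalar or vector.
NULL

#' @rdname accessors
#' @export
setMethod("conditionLabel", "PhaseFractionSeries", function(x) x@condition)

#' @rdname accessors
#' @export
setMethod("muCCvalue", "GrowthEstimate", function(x) x@mu_cc)

#' @rdname accessors
#' @export
setMethod("muNbValue", "GrowthEstimate", function(x) x@mu_nb)

#' @rdname accessors
#' @export
setMethod("deltaT", "PhaseTiming", function(x) x@delta_t)

#' @rdname accessors
#' @export
setMethod("durations", "PhaseDurations", function(x)
  c(T_S = x@t_s, T_G2 = x@t_g2, T_G1 = x@t_g1, T_S_plus_G2 = x@t_s_plus_g2))

setMethod("show", "LightSchedule", function(object) {
  cat(sprintf(
    "LightSchedule: dawn %02.0f:00, photoperiod %g h, E_max PAR %g umol m-2 s-1 (UVA %g, UVB %g W m-2)\n",
    object@t_dawn, object@photoperiod_h, object@e_max_par,
    object@e_max_uva, object@e_max_uvb))
})

setMethod("show", "SimParams", function(object) {
  cat(sprintf(
    "SimParams: n0 = %g, S entry ~ N(%.2f h, %.2f h), T_S = %g h, T_G2 = %g h, arrested %.0f%%, mode %s, seed %d\n",
    object@n0, object@s_onset_clock, object@sigma_sync, object@t_s,
    object@t_g2, 100 * object@frac_arrested, object@mode,
    as.integer(object@seed)))
})

setMethod("show", "EventSample", function(object) {
  cat(sprintf("EventSample: %d events at %05.2f h (day %d)",
              length(object@events), object@t, object@day))
  if (!is.na(object@condition)) cat(", condition", object@condition)
  cat("\n")
})

setMethod("show", "DNAHistogram", function(object) {
  cat(sprintf(
    "DNAHistogram: %d bins over [%g, %g] a.u., %d events (%d below, %d above range)\n",
    length(object@counts), min(object@bin_edges), max(object@bin_edges),
    as.integer(object@n_events), as.integer(object@n_below),
    as.integer(object@n_above)))
})

setMethod("show", "HistFitResult", function(object) {
  cat(sprintf(
    "HistFitResult: f_G1 = %.3f, f_S = %.3f, f_G2 = %.3f | m = %.1f a.u., r = %.3f, cv = %.3f | gof = %.2f (%s), converged = %s\n",
    object@f_g1, object@f_s, object@f_g2, object@m, object@r, object@cv,
    object@gof, object@objective, object@converged))
})

setMethod("show", "PhaseFractionSeries", function(object) {
  d <- object@data
  cat(sprintf("PhaseFractionSeries: %d timepoints over %d day(s)",
              nrow(d), length(unique(d$day_index))))
  if (!is.na(object@condition)) cat(", condition", object@condition)
  cat(sprintf("; %d converged\n", sum(d$converged)))
  print(utils::head(d, 4))
  if (nrow(d) > 4) cat("...\n")
})

setMethod("show", "PhaseTiming", function(object) {
  cat(sprintf(
    "PhaseTiming: S peak %05.2f h, G2 peak %05.2f h, delta_t = %.2f h (window %d)\n",
    object@t_smax, object@t_g2max, object@delta_t, object@smoothing_window))
})

setMethod("show", "PhaseDurations", function(object) {
  cat(sprintf(
    "PhaseDurations: T_S = %.2f h, T_G2 = %.2f h, T_G1 = %.2f h (T_S+T_G2 = %.2f h)",
    object@t_s, object@t_g2, object@t_g1, object@t_s_plus_g2))
  if (!is.na(object@s_r))
    cat(sprintf("; S_r = %.1f [%s]", object@s_r, object@s_r_metric))
  cat("\n")
})

setMethod("show", "GrowthEstimate", function(object) {
  cat(sprintf("GrowthEstimate: mu_cc = %.3f d-1", object@mu_cc))
  if (!is.na(object@mu_cc_dev))
    cat(sprintf(" +/- %.3f (mean dev., %d d)", object@mu_cc_dev,
                length(object@mu_cc_per_day)))
  if (!is.na(object@mu_nb))
    cat(sprintf(", mu_nb = %.3f d-1, bias = %.1f%%", object@mu_nb,
                object@bias_pct))
  cat("\n")
})
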
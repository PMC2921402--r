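#' Irradiance of the modulated light cycle at a clock time
#'
#' Half-sine diel modulation: within the photoperiod the irradiance is
#' `E(t) = e_max * sin(pi * (t - t_dawn) / photoperiod_h)`, and zero
#' throughout the dark period. Vectorized over `t`.
#'
#' @param t clock hours (any real; reduced mod 24).
#' @param schedule a [LightSchedule-class] object.
#' @param band which irradiance band: `"PAR"`, `"UVA"` or `"UVB"`.
#' @return irradiance in the band's units (umol photons m-2 s-1 for PAR,
#'   W m-2 for the UV bands); 0 outside the photoperiod.
#' @examples
#' sched <- lightSchedule()
#' irradianceAt(12, sched)          # 875 at virtual noon
#' irradianceAt(0, sched)           # 0 at midnight
#' irradianceAt(9, sched)           # 875 * sin(pi/4)
#' @export
irradianceAt <- function(t, schedule, band = c("PAR", "UVA", "UVB")) {
  stopifnot(is(schedule, "LightSchedule"))
  validObject(schedule)
  band <- match.arg(band)
  e_max <- switch(band,
    PAR = schedule@e_max_par,
    UVA = schedule@e_max_uva,
    UVB = schedule@e_max_uvb)
  tt <- (t - schedule@t_dawn) %% 24
  inside <- tt < schedule@photoperiod_h
  out <- numeric(length(tt))
  out[inside] <- e_max * sin(pi * tt[inside] / schedule@photoperiod_h)
  # sin() can go numerically negative at the dusk boundary
  pmax(out, 0)
}
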
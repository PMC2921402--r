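test_that("S and G2 peaks at 18:00 and 22:00 give the 4 h delay", {
  ser <- makeBumpSeries(s_center = 18, g2_center = 22)
  tm <- findPhasePeaks(ser)
  expect_equal(tm@t_smax, 18, tolerance = 0.05)
  expect_equal(tm@t_g2max, 22, tolerance = 0.05)
  expect_equal(deltaT(tm), 4, tolerance = 0.1)
})

test_that("a wave crossing midnight is located circularly", {
  ser <- makeBumpSeries(s_center = 20, g2_center = 0.5)
  tm <- findPhasePeaks(ser)
  expect_equal(tm@t_g2max, 0.5, tolerance = 0.3)
  expect_equal(deltaT(tm), 4.5, tolerance = 0.3)
})

test_that("identical S and G2 curves give delta_t = 0 and durations then fail", {
  t <- 0:23
  f <- 0.5 * exp(-pmin(abs(t - 18), 24 - abs(t - 18))^2 / 4)
  ser <- phaseFractionSeries(
    data.frame(time_h = t, day_index = 0L, f_G1 = 1 - 2 * f, f_S = f,
               f_G2 = f))
  tm <- findPhasePeaks(ser)
  expect_equal(deltaT(tm), 0, tolerance = 1e-9)
  expect_error(estimatePhaseDurations(tm, ser, mu_cc = 0.67), "degenerate")
})

test_that("flat series are rejected as having no replication wave", {
  ser <- phaseFractionSeries(
    data.frame(time_h = 0:23, day_index = 0L, f_G1 = 0.8, f_S = 0.1,
               f_G2 = 0.1))
  expect_error(findPhasePeaks(ser), "no replication wave")
  expect_error(estimateDelay(ser, ser), "flat")
  no_s <- phaseFractionSeries(
    data.frame(time_h = 0:23, day_index = 0L, f_G1 = 0.9, f_S = 0,
               f_G2 = 0.1))
  expect_error(syncIndex(no_s), "flat")
})

test_that("durations follow the 2*delta_t rule and the generation-time identity", {
  ser <- makeBumpSeries(s_center = 18, g2_center = 22)  # equal S/G2 areas
  tm <- new("PhaseTiming", t_smax = 18, t_g2max = 22, delta_t = 4,
            smoothing_window = 1L)
  dur <- estimatePhaseDurations(tm, ser, mu_cc = 0.67)
  expect_equal(dur@t_s_plus_g2, 8)
  expect_equal(dur@t_s, 4, tolerance = 0.05)
  expect_equal(dur@t_g2, 4, tolerance = 0.05)
  expect_equal(dur@t_g1, 24 * log(2) / 0.67 - 8, tolerance = 1e-9)
  expect_equal(round(dur@t_g1, 1), 16.8)

  tm3 <- new("PhaseTiming", t_smax = 18, t_g2max = 21, delta_t = 3,
             smoothing_window = 1L)
  dur3 <- estimatePhaseDurations(tm3, ser, mu_cc = 0.68)
  expect_equal(dur3@t_g1, 24 * log(2) / 0.68 - 6, tolerance = 1e-9)
  expect_equal(dur3@t_g1, 18.46, tolerance = 0.005)

  # 24 h generation time minus 8 h of S+G2 leaves 16 h of G1
  dur24 <- estimatePhaseDurations(tm, ser, mu_cc = 24 * log(2) / 24)
  expect_equal(dur24@t_g1, 16, tolerance = 1e-9)

  # inconsistent inputs: fast growth with long S+G2 -> negative T_G1
  expect_error(estimatePhaseDurations(tm, ser, mu_cc = 3), "negative T_G1")
})

test_that("sync index is zero for a delta wave, maximal for uniform, monotone in spread", {
  t <- 0:23
  delta_wave <- phaseFractionSeries(
    data.frame(time_h = t, day_index = 0L,
               f_S = ifelse(t == 18, 0.9, 0),
               f_G2 = 0, f_G1 = ifelse(t == 18, 0.1, 1)))
  expect_lt(as.numeric(syncIndex(delta_wave)), 1e-6)

  widths <- c(0.8, 1.5, 2.5, 3.5)
  s_r <- vapply(widths, function(w)
    as.numeric(syncIndex(makeBumpSeries(width = w))), numeric(1))
  expect_true(all(diff(s_r) > 0))

  # uniform f_S over the cycle: no synchrony, metric at its maximum
  unif <- phaseFractionSeries(
    data.frame(time_h = t, day_index = 0L, f_S = 0.5, f_G2 = 0,
               f_G1 = 0.5))
  expect_equal(as.numeric(syncIndex(unif)), 100 * sqrt(2) / (2 * pi),
               tolerance = 1e-9)
})

test_that("delay estimator recovers constructed shifts and is antisymmetric", {
  a <- makeBumpSeries(s_center = 18, g2_center = 22)
  expect_equal(estimateDelay(a, a), 0, tolerance = 1e-9)

  # rotate the same curve by exactly 2 grid hours
  da <- phaseFractions(a)
  rot <- function(x, k) x[((seq_along(x) - 1 - k) %% length(x)) + 1]
  b <- phaseFractionSeries(
    data.frame(time_h = da$time_h, day_index = 0L,
               f_G1 = rot(da$f_G1, 2), f_S = rot(da$f_S, 2),
               f_G2 = rot(da$f_G2, 2)))
  expect_equal(estimateDelay(a, b), 2, tolerance = 1e-6)
  expect_equal(estimateDelay(b, a), -2, tolerance = 1e-6)

  # off-grid shift via the analytic curve, sub-grid refinement
  c_half <- makeBumpSeries(s_center = 19.5, g2_center = 23.5)
  lag <- estimateDelay(a, c_half)
  expect_equal(lag, 1.5, tolerance = 0.2)
  expect_equal(estimateDelay(c_half, a), -lag, tolerance = 1e-9)
})
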
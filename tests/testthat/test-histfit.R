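test_that("binning is exact, range-aware and reports out-of-range events", {
  h <- buildHistogram(rep(200, 10), n_bins = 256, range = c(0, 512),
                      min_events = 0)
  expect_equal(sum(h@counts > 0), 1L)
  expect_equal(max(h@counts), 10)
  h2 <- buildHistogram(c(rep(200, 7), rep(400, 3)), n_bins = 256,
                       range = c(0, 512), min_events = 0)
  expect_equal(sum(h2@counts > 0), 2L)
  h3 <- buildHistogram(c(rep(100, 50), 600, 700), n_bins = 64,
                       range = c(50, 500), min_events = 0)
  expect_equal(h3@n_above, 2)
  expect_equal(h3@n_events, 50)
  expect_error(buildHistogram(rep(200, 10)), "too few events: 10")
})

test_that("noiseless two-spike histogram is recovered exactly", {
  ev <- c(rep(200, 6000), rep(400, 4000))
  fit <- fitDNAHistogram(buildHistogram(ev, range = c(0, 512),
                                        min_events = 0))
  expect_equal(fit@f_g1, 0.6, tolerance = 1e-3)
  expect_equal(fit@f_g2, 0.4, tolerance = 1e-3)
  expect_lt(fit@f_s, 1e-3)
  expect_true(fit@converged)
})

test_that("simulated G1/S/G2 mixture fractions are recovered within 0.02", {
  f_true <- c(0.60, 0.25, 0.15)
  ev <- makeMixtureEvents(1e5, f_true, gain = 200, cv = 0.03, seed = 7)
  fit <- fitDNAHistogram(buildHistogram(ev))
  expect_lt(abs(fit@f_g1 - f_true[1]), 0.02)
  expect_lt(abs(fit@f_s - f_true[2]), 0.02)
  expect_lt(abs(fit@f_g2 - f_true[3]), 0.02)
  expect_equal(fit@m, 200, tolerance = 0.02)
  expect_equal(fit@cv, 0.03, tolerance = 0.2)
})

test_that("an all-G1 sample is called nearly pure G1", {
  ev <- makeMixtureEvents(5e4, c(1, 0, 0), seed = 12)
  fit <- fitDNAHistogram(buildHistogram(ev))
  expect_gte(fit@f_g1, 0.98)
})

test_that("fit is invariant to a global rescaling of fluorescence units", {
  ev <- makeMixtureEvents(5e4, c(0.5, 0.3, 0.2), seed = 21)
  f1 <- fitDNAHistogram(buildHistogram(ev))
  f2 <- fitDNAHistogram(buildHistogram(ev * 3.7))
  expect_equal(f1@f_g1, f2@f_g1, tolerance = 1e-4)
  expect_equal(f1@f_s, f2@f_s, tolerance = 1e-4)
  expect_equal(f2@m / f1@m, 3.7, tolerance = 1e-4)
})

test_that("degenerate single-bin histograms and free-ratio bounds are handled", {
  expect_error(fitDNAHistogram(buildHistogram(rep(200, 6000),
                                              range = c(0, 512))),
               "degenerate")
  ev <- makeMixtureEvents(3e4, c(0.6, 0.1, 0.3), seed = 2)
  fit <- fitDNAHistogram(buildHistogram(ev), r_free = TRUE)
  expect_gte(fit@r, 1.9)
  expect_lte(fit@r, 2.1)
  expect_lt(abs(fit@r - 2), 0.05)
  # chi-square objective agrees closely with the Poisson default
  fit_chi <- fitDNAHistogram(buildHistogram(ev), objective = "chisq")
  expect_lt(abs(fit_chi@f_g1 - fit@f_g1), 0.02)
})

test_that("more events tighten fraction recovery (RMSE at 1e5 <= 1e4)", {
  f_true <- c(0.6, 0.25, 0.15)
  rmse <- function(n, seeds) {
    errs <- vapply(seeds, function(s) {
      fit <- fitDNAHistogram(buildHistogram(makeMixtureEvents(n, f_true,
                                                              seed = s)))
      sqrt(mean((c(fit@f_g1, fit@f_s, fit@f_g2) - f_true)^2))
    }, numeric(1))
    mean(errs)
  }
  seeds <- 1:8
  expect_lte(rmse(1e5, seeds), rmse(1e4, seeds))
})

test_that("fraction series assembles in time order with duplicate determinism", {
  samples <- lapply(c(6, 9, 12, 15, 18, 21), function(t)
    eventSample(t, makeMixtureEvents(8000, c(0.7, 0.2, 0.1),
                                     seed = 100 + t)))
  ser <- fractionsSeries(samples, min_events = 5000)
  d <- phaseFractions(ser)
  expect_equal(d$time_h, c(6, 9, 12, 15, 18, 21))
  expect_true(all(abs(d$f_G1 + d$f_S + d$f_G2 - 1) < 1e-6))
  ser2 <- fractionsSeries(samples, min_events = 5000)
  expect_identical(phaseFractions(ser), phaseFractions(ser2))
  # all-G1 samples give a flat f_G1 ~ 1 curve
  flat <- lapply(c(6, 12, 18, 22), function(t)
    eventSample(t, makeMixtureEvents(8000, c(1, 0, 0), seed = 200 + t)))
  dflat <- phaseFractions(fractionsSeries(flat))
  expect_true(all(dflat$f_G1 > 0.97))
  expect_error(fractionsSeries(samples[1:3]), "fewer than 4")
})
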
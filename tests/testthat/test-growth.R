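test_that("count-based rate matches its closed forms", {
  expect_equal(muNb(1e7, 2e7, 24), log(2), tolerance = 1e-12)
  expect_equal(muNb(5e6, 5e6, 24), 0)
  expect_equal(muNb(1e7, 1.822e7, 24), log(1.822), tolerance = 1e-12)
  expect_equal(round(muNb(1e7, 1.822e7, 24), 2), 0.60)
  # duplicate cultures averaged before the ratio
  expect_equal(muNb(c(1e7, 1.2e7), c(2.0e7, 2.4e7), 24), log(2),
               tolerance = 1e-12)
  expect_error(muNb(0, 1e7), "positive")
  expect_error(muNb(1e7, 2e7, dt_h = 0), "dt_h")
})

test_that("cell-cycle rate matches its closed forms", {
  flat <- function(fs, fg2) phaseFractionSeries(
    data.frame(time_h = 0:23, day_index = 0L, f_G1 = 1 - fs - fg2,
               f_S = fs, f_G2 = fg2))
  expect_equal(muCC(flat(0, 0), 8)$mu, 0)
  expect_equal(muCC(flat(0.15, 0.10), 8)$mu, (24 / 8) * log(1.25),
               tolerance = 1e-12)
  expect_equal(round(muCC(flat(0.15, 0.10), 8)$mu, 3), 0.669)
  single <- phaseFractionSeries(
    data.frame(time_h = 0:23, day_index = 0L,
               f_S = ifelse(0:23 == 18, 1, 0), f_G2 = 0,
               f_G1 = ifelse(0:23 == 18, 0, 1)))
  expect_equal(muCC(single, 8)$mu, 24 / (24 * 8) * log(2), tolerance = 1e-12)
  expect_equal(round(muCC(single, 8)$mu, 4), 0.0866)
})

test_that("cell-cycle rate rejects malformed series", {
  irregular <- phaseFractionSeries(
    data.frame(time_h = c(0, 3, 6, 12, 18, 20), day_index = 0L,
               f_G1 = 0.8, f_S = 0.1, f_G2 = 0.1))
  expect_error(muCC(irregular, 8), "irregular sampling grid")
  # fractions exceeding unity are already rejected at construction
  expect_error(phaseFractionSeries(
    data.frame(time_h = 0:23, day_index = 0L, f_G1 = 0, f_S = 0.6,
               f_G2 = 0.6)), "sum to 1")
  ok <- phaseFractionSeries(
    data.frame(time_h = 0:23, day_index = 0L, f_G1 = 0.8, f_S = 0.1,
               f_G2 = 0.1))
  expect_error(muCC(ok, 0), "t_s_plus_g2")
})

test_that("mu_cc is invariant to rotation of the sampling grid and monotone in S+G2", {
  set.seed(31)
  fs <- pmin(pmax(stats::runif(24, 0, 0.4), 0), 1)
  fg2 <- pmin(pmax(stats::runif(24, 0, 0.3), 0), 1)
  mk <- function(fs, fg2) phaseFractionSeries(
    data.frame(time_h = 0:23, day_index = 0L, f_G1 = 1 - fs - fg2,
               f_S = fs, f_G2 = fg2))
  base <- muCC(mk(fs, fg2), 8)$mu
  rotated <- muCC(mk(c(fs[-(1:5)], fs[1:5]), c(fg2[-(1:5)], fg2[1:5])), 8)$mu
  expect_equal(base, rotated, tolerance = 1e-12)
  bumped <- fs
  bumped[10] <- bumped[10] + 0.05
  expect_gt(muCC(mk(bumped, fg2), 8)$mu, base)
})

test_that("multi-day series give per-day estimates with mean absolute deviation", {
  d <- rbind(
    data.frame(time_h = 0:23, day_index = 0L, f_G1 = 0.75, f_S = 0.15,
               f_G2 = 0.10),
    data.frame(time_h = 0:23, day_index = 1L, f_G1 = 0.70, f_S = 0.18,
               f_G2 = 0.12))
  res <- muCC(phaseFractionSeries(d), 8)
  expect_length(res$per_day, 2)
  expect_equal(res$mu, mean(res$per_day))
  expect_equal(res$dev, mean(abs(res$per_day - mean(res$per_day))))
  expect_equal(res$n, 24L)
})

test_that("bias between the two estimators matches its definition", {
  expect_equal(compareMu(growthEstimate(0.67, 0.60)), 100 * (0.67 / 0.60 - 1),
               tolerance = 1e-12)
  expect_equal(round(compareMu(growthEstimate(0.67, 0.60)), 1), 11.7)
  expect_equal(compareMu(growthEstimate(0.5, 0.5)), 0)
  expect_error(compareMu(growthEstimate(0.5)), "mu_nb")
  est <- growthEstimate(muCC(phaseFractionSeries(
    data.frame(time_h = 0:23, day_index = 0L, f_G1 = 0.75, f_S = 0.15,
               f_G2 = 0.10)), 8), mu_nb = 0.6)
  expect_s4_class(est, "GrowthEstimate")
  expect_equal(est@bias_pct, 100 * (est@mu_cc / 0.6 - 1))
})

test_that("mu_nb pairing picks the early-morning no-division window", {
  counts <- data.frame(day_index = rep(0:1, each = 3),
                       time_h = rep(c(0, 6, 12), 2),
                       n_cells = c(1000, 1000, 1000, 1500, 1950, 1950))
  # at 00:00 the wave has not finished in this toy series; 06:00 is safe
  expect_equal(muNbFromSeries(counts), log(1.95), tolerance = 1e-12)
  expect_equal(muNbFromSeries(counts, at = 12), log(1.95), tolerance = 1e-12)
  expect_error(muNbFromSeries(counts[counts$day_index == 0, ]),
               "consecutive days")
})
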
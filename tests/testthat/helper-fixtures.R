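# Independent event-construction oracle: builds a G1/S/G2 mixture directly
# from the stated fractions (S-phase DNA uniform on (1, 2)), bypassing the
# simulator and measureEvents() so fit-recovery tests do not depend on the
# code paths they check.
makeMixtureEvents <- function(n, f, gain = 200, cv = 0.03, seed = 1) {
  stopifnot(abs(sum(f) - 1) < 1e-9)
  set.seed(seed)
  n_g1 <- round(f[1] * n)
  n_g2 <- round(f[3] * n)
  n_s <- n - n_g1 - n_g2
  dna <- c(rep(1, n_g1), stats::runif(n_s, 1, 2), rep(2, n_g2))
  fl <- gain * dna * (1 + stats::rnorm(n, 0, cv))
  fl[fl <= 0] <- gain * 1e-6
  fl
}

# Analytic diel fraction curves: Gaussian S and G2 bumps centred at given
# clock hours, remainder in G1.
makeBumpSeries <- function(t = 0:23, s_center = 18, g2_center = 22,
                           width = 1.5, amp = 0.8, condition = "synthetic") {
  dcirc <- function(t, c) {
    d <- abs(t - c)
    pmin(d, 24 - d)
  }
  f_s <- amp * exp(-dcirc(t, s_center)^2 / (2 * width^2))
  f_g2 <- amp * exp(-dcirc(t, g2_center)^2 / (2 * width^2))
  tot <- pmax(f_s + f_g2, 1)
  f_s <- f_s / pmax(tot, 1)
  f_g2 <- f_g2 / pmax(tot, 1)
  phaseFractionSeries(
    data.frame(time_h = t, day_index = 0L, f_G1 = 1 - f_s - f_g2,
               f_S = f_s, f_G2 = f_g2),
    condition = condition)
}

# Small qPCR CT table with exact duplicate structure.
makeCtTable <- function() {
  data.frame(
    gene = rep(rep(c("recA", "rnpB"), each = 2), times = 2),
    condition = "HL",
    time_h = rep(c(6, 18), each = 4),
    replicate = rep(1:2, 4),
    ct = c(24, 24, 18, 18,   # calibrator: dCT = 6
           22, 22, 18, 18))  # 18:00: dCT = 4 -> ddCT = -2 -> RQ = 4
}
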
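#' Bin DNA-fluorescence events into a histogram
#'
#' Linear binning over a fixed range. Events outside the range are counted
#' in the `n_below` / `n_above` slots of the result, never silently
#' dropped. The default range `c(0, 1.02 * max(events))` scales with the
#' data, which makes downstream fits invariant to a global rescaling of
#' fluorescence units.
#'
#' @param sample an [EventSample-class] object or a numeric event vector.
#' @param n_bins number of bins (default 256).
#' @param range length-2 numeric binning range; `NULL` for the data-driven
#'   default.
#' @param min_events minimum acceptable event count (default 5000);
#'   fewer events raise an error reporting the count.
#' @return a [DNAHistogram-class] object.
#' @export
buildHistogram <- function(sample, n_bins = 256, range = NULL,
                           min_events = 5000) {
  x <- if (is(sample, "EventSample")) sample@events else as.numeric(sample)
  if (length(x) < min_events)
    stop(sprintf("too few events: %d < minimum %d", length(x), min_events))
  if (is.null(range)) range <- c(0, 1.02 * max(x))
  stopifnot(length(range) == 2L, range[2] > range[1], n_bins >= 2)
  edges <- seq(range[1], range[2], length.out = n_bins + 1L)
  below <- sum(x < range[1])
  above <- sum(x >= range[2])
  inr <- x[x >= range[1] & x < range[2]]
  idx <- findInterval(inr, edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = n_bins)
  new("DNAHistogram", bin_edges = edges, counts = as.numeric(counts),
      n_events = sum(counts), n_below = below, n_above = above)
}

# Component means and sds of the constrained mixture: G1 at m, G2 at r*m,
# and n_s equal-weight S segments with means evenly spaced in (m, r*m),
# all with the same fractional CV.
.mixtureComponents <- function(m, r, cv, n_s) {
  mu_s <- m * (1 + (seq_len(n_s) - 0.5) * (r - 1) / n_s)
  mu <- c(m, mu_s, r * m)
  list(mu = mu, sd = cv * mu)
}

# Expected bin probabilities for weights w = (f_g1, f_s, f_g2); the S mass
# is spread equally over its segments. Probabilities are NOT renormalized
# over the binning range: mixture mass a parameter set places outside the
# range shows up as an expected-total deficit that the objective penalizes,
# which keeps weights on out-of-range components identifiable.
.mixtureBinProbs <- function(edges, m, r, cv, n_s, w) {
  comp <- .mixtureComponents(m, r, cv, n_s)
  wts <- c(w[1], rep(w[2] / n_s, n_s), w[3])
  p <- numeric(length(edges) - 1L)
  for (j in seq_along(comp$mu)) {
    if (wts[j] <= 0) next
    cdf <- stats::pnorm(edges, comp$mu[j], comp$sd[j])
    p <- p + wts[j] * diff(cdf)
  }
  p
}

.poissonDeviance <- function(obs, expd) {
  expd <- pmax(expd, 1e-12)
  term <- ifelse(obs > 0, obs * log(obs / expd), 0)
  2 * sum(term - (obs - expd))
}

.chisqStat <- function(obs, expd) {
  sum((obs - expd)^2 / pmax(obs, 1))
}

# Initial G1 position and CV guess from the two largest local maxima of
# the lightly smoothed histogram; falls back to the single dominant peak.
.initFromPeaks <- function(mids, counts) {
  k <- 5L
  sm <- stats::filter(counts, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- 0
  n <- length(sm)
  is_max <- sm > c(-Inf, sm[-n]) & sm >= c(sm[-1], -Inf) & sm > 0
  peaks <- which(is_max)
  if (!length(peaks)) peaks <- which.max(counts)
  ord <- peaks[order(sm[peaks], decreasing = TRUE)]
  p1 <- mids[ord[1]]
  m0 <- p1
  for (p in ord[-1]) {
    ratio <- max(p1, mids[p]) / min(p1, mids[p])
    if (ratio > 1.6 && ratio < 2.5 && sm[p] > 0.05 * sm[ord[1]]) {
      m0 <- min(p1, mids[p])
      break
    }
  }
  # CV guess from the spread of mass within +/-25% of the G1 candidate
  sel <- mids > 0.75 * m0 & mids < 1.25 * m0 & counts > 0
  cv0 <- if (sum(counts[sel]) > 1) {
    mu <- sum(mids[sel] * counts[sel]) / sum(counts[sel])
    sqrt(sum(counts[sel] * (mids[sel] - mu)^2) / sum(counts[sel])) / mu
  } else 0.05
  list(m0 = m0, cv0 = min(max(cv0, 0.005), 0.25))
}

#' Deconvolve a DNA histogram into G1/S/G2 fractions
#'
#' Fits the constrained mixture of [HistFitResult-class]: a G1 Gaussian at
#' `m`, a G2 Gaussian at `r * m`, and an S component of `n_s_segments`
#' equal-weight Gaussians evenly spaced between the peaks (a
#' single-rectangle Dean-Jett-Fox S model), all sharing one fractional CV.
#' Parameters are estimated by minimizing the Poisson deviance of the bin
#' counts (Pearson chi-square with variance `max(count, 1)` available for
#' parity with legacy cell-cycle software). The G2/G1 ratio is fixed at
#' exactly 2 by default (two chromosome copies); `r_free = TRUE` lets it
#' vary within [1.9, 2.1]. Initialization comes from the two largest local
#' maxima of the smoothed histogram. A stalled optimizer is reported via
#' `converged = FALSE`, not an error.
#'
#' @param hist a [DNAHistogram-class] object.
#' @param n_s_segments number of S-phase Gaussian segments (default 8).
#' @param r fixed G2/G1 position ratio (default 2).
#' @param r_free allow the ratio to vary within [1.9, 2.1].
#' @param objective `"poisson"` (default) or `"chisq"`.
#' @param maxit optimizer iteration budget.
#' @param m_init optional starting value for the G1 position, overriding
#'   the peak-based initialization.
#' @param fix_m hold the G1 position fixed at `m_init` instead of fitting
#'   it. The G1 position is an instrument property that barely moves
#'   between timepoints of a series, and fixing it keeps the fit
#'   identifiable at timepoints where almost no G1 cells remain (mid
#'   replication wave); see [fractionsSeries()].
#' @return a [HistFitResult-class] object.
#' @examples
#' ev <- c(rnorm(6000, 200, 6), rnorm(4000, 400, 12))
#' h <- buildHistogram(ev)
#' fitDNAHistogram(h)
#' @export
fitDNAHistogram <- function(hist, n_s_segments = 8L, r = 2,
                            r_free = FALSE,
                            objective = c("poisson", "chisq"),
                            maxit = 2000L, m_init = NULL, fix_m = FALSE) {
  stopifnot(is(hist, "DNAHistogram"))
  validObject(hist)
  objective <- match.arg(objective)
  counts <- hist@counts
  edges <- hist@bin_edges
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  n <- sum(counts)
  if (n == 0) stop("empty histogram")
  if (max(counts) == n)
    stop("degenerate histogram: all events in a single bin")

  init <- .initFromPeaks(mids, counts)
  if (!is.null(m_init)) init$m0 <- m_init
  if (fix_m && is.null(m_init))
    stop("fix_m = TRUE requires m_init")
  # initial fractions: bin mass assigned to the nearest component centre
  d_g1 <- abs(mids - init$m0)
  d_g2 <- abs(mids - 2 * init$m0)
  d_s <- abs(mids - 1.5 * init$m0)
  nearest <- max.col(-cbind(d_g1, d_s, d_g2))
  w0 <- vapply(1:3, function(j) sum(counts[nearest == j]), numeric(1)) / n
  w0 <- pmax(w0, 1e-3)

  lossFun <- if (objective == "poisson") .poissonDeviance else .chisqStat
  unpack <- function(th) {
    if (fix_m) th <- c(log(init$m0), th)
    list(m = exp(th[1]), cv = 5e-4 + exp(th[2]),
         w = {w <- exp(c(0, th[3], th[4])); w / sum(w)},
         r = if (r_free) 1.9 + 0.2 * stats::plogis(th[5]) else r)
  }
  obj <- function(th) {
    pp <- unpack(th)
    if (!is.finite(pp$m) || pp$cv > 0.6) return(1e12)
    p <- .mixtureBinProbs(edges, pp$m, pp$r, pp$cv, n_s_segments, pp$w)
    lossFun(counts, n * p)
  }

  th0 <- c(log(init$m0), log(init$cv0),
           log(w0[2] / w0[1]), log(w0[3] / w0[1]))
  if (fix_m) th0 <- th0[-1]
  if (r_free) th0 <- c(th0, 0)
  opt <- stats::optim(th0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))

  pp <- unpack(opt$par)
  m <- pp$m; cv <- pp$cv; w <- pp$w; rr <- pp$r
  n_par <- length(opt$par) + 0L
  dof <- max(sum(counts > 0) - n_par, 1L)
  new("HistFitResult", m = m, r = rr, cv = cv,
      f_g1 = w[1], f_s = w[2], f_g2 = w[3],
      n_s_segments = as.integer(n_s_segments),
      gof = opt$value / dof, objective = objective,
      converged = opt$convergence == 0L && is.finite(opt$value))
}

#' Fit a time series of event samples into a phase-fraction series
#'
#' Builds and fits one DNA histogram per timepoint and assembles the
#' fitted G1/S/G2 fractions in time order. By default a two-pass scheme is
#' used: after independent per-timepoint fits, a robust reference G1
#' position is taken (median fitted `m` over converged timepoints with a
#' clear G1 population) and every timepoint is refit with `m` fixed there.
#' The G1 position is an instrument property and essentially constant
#' across a series; anchoring it keeps the deconvolution identifiable at
#' timepoints in mid replication wave, where almost no G1 cells remain
#' and a free `m` can drift onto the S-phase smear. Non-converged fits are
#' kept but flagged (`converged = FALSE`); downstream peak detection
#' excludes them.
#'
#' @param samples list of [EventSample-class] objects covering at least
#'   one diel cycle.
#' @param n_bins,min_events passed to [buildHistogram()].
#' @param condition condition label for the series (defaults to the first
#'   sample's label).
#' @param common_m anchor all timepoints to a shared G1 position
#'   (default TRUE).
#' @param ... passed to [fitDNAHistogram()].
#' @return a [PhaseFractionSeries-class] whose data also carries `m`,
#'   `cv`, `gof` columns from the per-timepoint fits.
#' @export
fractionsSeries <- function(samples, n_bins = 256, min_events = 5000,
                            condition = NULL, common_m = TRUE, ...) {
  stopifnot(length(samples) >= 1)
  if (is.null(condition)) condition <- samples[[1]]@condition
  hists <- lapply(samples, buildHistogram, n_bins = n_bins,
                  min_events = min_events)
  fitOne <- function(h, s, ...) {
    fit <- fitDNAHistogram(h, ...)
    data.frame(time_h = s@t, day_index = s@day,
               f_G1 = fit@f_g1, f_S = fit@f_s, f_G2 = fit@f_g2,
               m = fit@m, cv = fit@cv, gof = fit@gof,
               converged = fit@converged)
  }
  d <- do.call(rbind, Map(fitOne, hists, samples, ...))
  if (common_m) {
    anchored <- d$converged & d$f_G1 >= 0.3
    if (!any(anchored)) anchored <- d$converged
    if (any(anchored)) {
      m_ref <- stats::median(d$m[anchored])
      d <- do.call(rbind, Map(fitOne, hists, samples,
                              m_init = m_ref, fix_m = TRUE, ...))
    }
  }
  per_day <- table(d$day_index[d$converged])
  if (!length(per_day) || max(per_day) < 4L)
    stop("fewer than 4 usable timepoints per cycle")
  phaseFractionSeries(d, condition = condition)
}
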
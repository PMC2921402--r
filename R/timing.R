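# Collapse a (possibly multi-day) series to one mean diel curve on the
# clock-time grid, using converged points only.
.dielCurve <- function(series) {
  d <- series@data[series@data$converged, , drop = FALSE]
  if (!nrow(d)) stop("no usable (converged) timepoints")
  ag <- stats::aggregate(d[, c("f_G1", "f_S", "f_G2")],
                         by = list(time_h = d$time_h), FUN = mean)
  ag[order(ag$time_h), , drop = FALSE]
}

# Centered circular moving average, window w (odd).
.circSmooth <- function(y, w) {
  if (w <= 1L) return(y)
  n <- length(y)
  half <- (w - 1L) %/% 2L
  idx <- outer(seq_len(n), -half:half, "+")
  idx <- ((idx - 1L) %% n) + 1L
  rowMeans(matrix(y[idx], nrow = n))
}

# Peak clock time of a circular curve: argmax with quadratic refinement
# through the three points around the maximum. A contiguous plateau of
# tied maxima resolves to its circular midpoint; ties between separated
# equal maxima break toward the earlier clock time.
.circPeak <- function(t, y) {
  n <- length(y)
  top <- which(y > max(y) - 1e-12)
  if (length(top) == n) return(t[1])
  if (length(top) > 1L) {
    # find the maximal circular run of tied indices
    is_top <- seq_len(n) %in% top
    runs <- rle(c(is_top, is_top))  # doubled to catch wrap-around runs
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    cand <- which(runs$values & runs$lengths < 2L * n)
    best <- cand[which.max(runs$lengths[cand])]
    i1 <- starts[best]; i2 <- ends[best]
    if (i2 - i1 + 1L >= n) return(t[1])
    tt1 <- t[((i1 - 1L) %% n) + 1L]
    span <- i2 - i1
    tt <- numeric(span + 1L)
    tt[1] <- tt1
    for (j in seq_len(span)) {  # unwrap plateau times circularly
      tn <- t[((i1 + j - 1L) %% n) + 1L]
      while (tn < tt[j]) tn <- tn + 24
      tt[j + 1L] <- tn
    }
    return(mean(range(tt)) %% 24)
  }
  i <- top[1]
  im <- ((i - 2L) %% n) + 1L
  ip <- (i %% n) + 1L
  t0 <- t[i]
  tm <- t[im]; while (tm > t0) tm <- tm - 24
  tp <- t[ip]; while (tp < t0) tp <- tp + 24
  xs <- c(tm, t0, tp); ys <- y[c(im, i, ip)]
  den <- (xs[1] - xs[2]) * (xs[1] - xs[3]) * (xs[2] - xs[3])
  if (abs(den) < 1e-12) return(t0 %% 24)
  a <- (xs[3] * (ys[2] - ys[1]) + xs[2] * (ys[1] - ys[3]) +
          xs[1] * (ys[3] - ys[2])) / den
  b <- (xs[3]^2 * (ys[1] - ys[2]) + xs[2]^2 * (ys[3] - ys[1]) +
          xs[1]^2 * (ys[2] - ys[3])) / den
  if (a >= 0) return(t0 %% 24)  # not a local maximum of the parabola
  tv <- -b / (2 * a)
  if (tv < xs[1] || tv > xs[3]) tv <- t0
  tv %% 24
}

.flatCheck <- function(y, what) {
  noise <- stats::sd(diff(c(y, y[1]))) / sqrt(2)
  if (!is.finite(noise)) noise <- 0
  if (max(y) - stats::median(y) <= 2 * noise + 1e-12)
    stop(sprintf("no replication wave detected in the %s curve", what))
}

#' Locate the diel peaks of the S and G2 fraction curves
#'
#' Collapses the series to its mean diel curve (converged points only),
#' applies a centered circular moving average, and locates each phase peak
#' by argmax with quadratic sub-sample refinement through the three points
#' around the maximum. Time arithmetic is circular (mod 24 h), so a
#' replication wave crossing midnight is never clipped. A flat curve (no
#' peak above baseline + 2x point-to-point noise) raises an error.
#'
#' @param series a [PhaseFractionSeries-class] object.
#' @param window moving-average window in points (default 3; use 1 for
#'   exact truth series from the simulator).
#' @return a [PhaseTiming-class] object.
#' @export
findPhasePeaks <- function(series, window = 3L) {
  stopifnot(is(series, "PhaseFractionSeries"))
  cur <- .dielCurve(series)
  if (nrow(cur) < 6L) stop("need at least 6 usable points per cycle")
  fs <- .circSmooth(cur$f_S, window)
  fg2 <- .circSmooth(cur$f_G2, window)
  .flatCheck(fs, "f_S")
  .flatCheck(fg2, "f_G2")
  t_s <- .circPeak(cur$time_h, fs)
  t_g2 <- .circPeak(cur$time_h, fg2)
  new("PhaseTiming", t_smax = t_s, t_g2max = t_g2,
      delta_t = (t_g2 - t_s) %% 24, smoothing_window = as.integer(window))
}

# Circular (wrap-around) trapezoidal area of a baseline-subtracted curve.
.circArea <- function(t, y) {
  y <- pmax(y - min(y), 0)
  n <- length(t)
  dt <- diff(c(t, t[1] + 24))
  sum((y + y[c(2:n, 1)]) / 2 * dt)
}

#' Phase durations from peak timing and the generation-time identity
#'
#' Applies the twice-the-peak-delay rule `T_S + T_G2 = 2 * delta_t`, splits
#' the sum into T_S and T_G2 proportionally to the areas under the
#' baseline-subtracted f_S and f_G2 diel curves (a documented convention:
#' the peak-delay rule itself fixes only the sum), and reconstructs
#' `T_G1 = 24 * ln(2) / mu_cc - (T_S + T_G2)` from the generation-time
#' identity.
#'
#' @param timing a [PhaseTiming-class] object with `delta_t > 0`.
#' @param series the [PhaseFractionSeries-class] the timing came from.
#' @param mu_cc cell-cycle-based growth rate, d-1 (see [muCC()]).
#' @param s_r optional synchronization index to carry along (see
#'   [syncIndex()]).
#' @return a [PhaseDurations-class] object.
#' @examples
#' # printed-precision check: delta_t = 4 h, mu_cc = 0.67 d-1
#' tm <- new("PhaseTiming", t_smax = 18, t_g2max = 22, delta_t = 4,
#'           smoothing_window = 1L)
#' @export
estimatePhaseDurations <- function(timing, series, mu_cc, s_r = NA_real_) {
  stopifnot(is(timing, "PhaseTiming"))
  if (timing@delta_t <= 0)
    stop("degenerate timing: delta_t must be > 0 to apply the 2*delta_t rule")
  if (timing@delta_t >= 12)
    stop("delta_t >= 12 h: G2 peak does not follow the S peak within one wave")
  if (mu_cc <= 0) stop("mu_cc must be > 0")
  t_sum <- 2 * timing@delta_t
  cur <- .dielCurve(series)
  a_s <- .circArea(cur$time_h, cur$f_S)
  a_g2 <- .circArea(cur$time_h, cur$f_G2)
  if (a_s + a_g2 <= 0) stop("no S/G2 signal to split the duration sum")
  t_s <- t_sum * a_s / (a_s + a_g2)
  t_g2 <- t_sum - t_s
  t_g1 <- 24 * log(2) / mu_cc - t_sum
  if (t_g1 <= 0)
    stop(sprintf(
      "inconsistent inputs: 24*ln2/mu_cc = %.2f h <= T_S+T_G2 = %.2f h gives negative T_G1",
      24 * log(2) / mu_cc, t_sum))
  new("PhaseDurations", t_s = t_s, t_g2 = t_g2, t_g1 = t_g1,
      t_s_plus_g2 = t_sum, s_r = s_r,
      s_r_metric = if (is.na(s_r)) NA_character_ else
        "circular_angular_deviation_pct24")
}

#' Synchronization index of the diel S wave
#'
#' Default metric: 100 times the circular angular deviation (expressed as
#' a fraction of the 24 h cycle) of the diel f_S mass, read as a proxy for
#' the S-entry time distribution. A delta-like S wave gives 0; a uniform
#' f_S curve gives the metric's maximum (100 * sqrt(2) / (2 * pi) ~ 22.5);
#' wider S-entry spread strictly increases the index. Lower = better
#' synchronized. The exact index definition used with legacy cell-cycle
#' software is unpublished, so this is a labeled, swappable convention
#' (`metric` attribute on the result), not a reproduction.
#'
#' @param series a [PhaseFractionSeries-class] object.
#' @param metric `"angular"` (bounded angular deviation, default) or
#'   `"circsd"` (classic circular SD, unbounded as the curve flattens).
#' @return numeric index with attribute `metric`.
#' @export
syncIndex <- function(series, metric = c("angular", "circsd")) {
  metric <- match.arg(metric)
  cur <- .dielCurve(series)
  w <- cur$f_S
  if (sum(w) <= 0) stop("flat f_S curve: no replication wave detected")
  theta <- 2 * pi * cur$time_h / 24
  R <- sqrt(sum(w * cos(theta))^2 + sum(w * sin(theta))^2) / sum(w)
  disp <- switch(metric,
    angular = sqrt(2 * (1 - R)),
    circsd = sqrt(-2 * log(max(R, 1e-12))))
  out <- 100 * disp / (2 * pi)
  attr(out, "metric") <- paste0("circular_", metric, "_deviation_pct24")
  out
}

#' Phase lag between two conditions by circular cross-correlation
#'
#' Maximizes the circular cross-correlation of the two mean-subtracted
#' diel fraction curves over grid shifts, with quadratic sub-grid
#' refinement. Positive lag means `series_b` is later than `series_a`;
#' `estimateDelay(a, b) == -estimateDelay(b, a)` (mod 24). Both series
#' must share a common clock-time grid (or be resampled onto `grid` by
#' circular linear interpolation).
#'
#' @param series_a,series_b [PhaseFractionSeries-class] objects.
#' @param phase which fraction curve to correlate: `"S"` or `"G2"`.
#' @param grid optional clock-hour grid to resample both series onto.
#' @return lag in hours, in (-12, 12].
#' @export
estimateDelay <- function(series_a, series_b, phase = c("S", "G2"),
                          grid = NULL) {
  phase <- match.arg(phase)
  col <- if (phase == "S") "f_S" else "f_G2"
  ca <- .dielCurve(series_a)
  cb <- .dielCurve(series_b)
  if (!is.null(grid)) {
    ca <- .resampleDiel(ca, grid)
    cb <- .resampleDiel(cb, grid)
  } else if (!isTRUE(all.equal(ca$time_h, cb$time_h))) {
    stop("series are on different sampling grids; supply `grid` to resample")
  }
  tt <- ca$time_h
  dt <- diff(tt)
  if (max(abs(dt - dt[1])) > 1e-6)
    stop("delay estimation requires a fixed-interval grid; supply `grid`")
  x <- ca[[col]] - mean(ca[[col]])
  y <- cb[[col]] - mean(cb[[col]])
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
    stop("flat fraction curve: cannot estimate a delay")
  n <- length(x)
  cc <- vapply(0:(n - 1L), function(k) {
    sum(x * y[((seq_len(n) - 1L + k) %% n) + 1L])
  }, numeric(1))
  k <- which.max(cc) - 1L
  cm <- cc[((k - 1L) %% n) + 1L]
  c0 <- cc[k + 1L]
  cp <- cc[((k + 1L) %% n) + 1L]
  den <- cm - 2 * c0 + cp
  frac <- if (abs(den) > 1e-12) 0.5 * (cm - cp) / den else 0
  if (!is.finite(frac) || abs(frac) > 1) frac <- 0
  lag <- (k + frac) * dt[1]
  lag <- lag %% 24
  if (lag > 12) lag <- lag - 24
  lag
}

# Circular linear interpolation of a diel curve onto a new clock grid.
.resampleDiel <- function(cur, grid) {
  grid <- sort(grid %% 24)
  t0 <- cur$time_h
  res <- data.frame(time_h = grid)
  for (col in c("f_G1", "f_S", "f_G2")) {
    y <- cur[[col]]
    tx <- c(t0, t0[1] + 24)
    yx <- c(y, y[1])
    res[[col]] <- stats::approx(tx, yx, xout = ifelse(grid < t0[1],
                                                      grid + 24, grid))$y
  }
  res
}
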
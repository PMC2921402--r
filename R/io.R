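#' Build a pipeline configuration
#'
#' Self-contained description of an end-to-end run: per-condition
#' scenarios (simulator parameters + light schedule), the sampling grid,
#' the instrument model, histogram/fit options and explicit seeds for
#' every stochastic stage. Round-trips losslessly through YAML
#' ([writeScenarioConfig()] / [readScenarioConfig()]).
#'
#' @param seed base integer seed; per-condition population seeds and
#'   per-timepoint measurement seeds are derived from it deterministically.
#' @param conditions character vector of stock scenario names among
#'   `"HL"`, `"HL+UV"`.
#' @param n0 initial cells per condition.
#' @param sample_times clock-hour sampling grid.
#' @param n_days number of diel cycles.
#' @param n_events events measured per timepoint.
#' @param gain,cv instrument model settings.
#' @param n_bins histogram bins.
#' @return a list of class `"dielcycle_config"`.
#' @export
pipelineConfig <- function(seed = 1, conditions = c("HL", "HL+UV"),
                           n0 = 10000, sample_times = 0:23, n_days = 2,
                           n_events = 1e5, gain = 200, cv = 0.03,
                           n_bins = 256) {
  seed <- as.integer(seed)
  scen <- list()
  for (i in seq_along(conditions)) {
    nm <- conditions[i]
    base <- switch(nm, "HL" = scenarioHL(), "HL+UV" = scenarioHLUV(),
                   stop(sprintf("unknown stock scenario '%s'", nm)))
    p <- base$params
    scen[[nm]] <- list(
      s_onset_clock = p@s_onset_clock, sigma_sync = p@sigma_sync,
      t_s = p@t_s, t_g2 = p@t_g2, jitter_s = p@jitter_s,
      jitter_g2 = p@jitter_g2, frac_arrested = p@frac_arrested,
      mode = p@mode, dilution = p@dilution,
      seed = seed + 1000L * i)
  }
  structure(list(
    seed = seed,
    scenarios = scen,
    schedule = list(t_dawn = 6, photoperiod_h = 12, e_max_par = 875,
                    e_max_uva = 7.59, e_max_uvb = 0.57),
    n0 = n0, sample_times = as.numeric(sample_times), n_days = n_days,
    n_events = n_events,
    instrument = list(gain = gain, cv = cv, debris_frac = 0),
    n_bins = n_bins
  ), class = "dielcycle_config")
}

.validateConfig <- function(config) {
  if (is.null(config$seed))
    stop("invalid config: missing top-level seed")
  for (nm in names(config$scenarios)) {
    if (is.null(config$scenarios[[nm]]$seed))
      stop(sprintf("invalid config: scenario '%s' has no seed", nm))
  }
  need <- c("scenarios", "schedule", "n0", "sample_times", "n_days",
            "n_events", "instrument", "n_bins")
  missing_f <- setdiff(need, names(config))
  if (length(missing_f))
    stop(sprintf("invalid config: missing field(s) %s",
                 paste(missing_f, collapse = ", ")))
  invisible(config)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `readScenarioConfig()` returns the validated config list;
#'   `writeScenarioConfig()` returns `path` invisibly.
#' @export
readScenarioConfig <- function(path) {
  config <- yaml::read_yaml(path)
  class(config) <- "dielcycle_config"
  .validateConfig(config)
  config
}

#' @rdname readScenarioConfig
#' @param config a config list from [pipelineConfig()].
#' @export
writeScenarioConfig <- function(config, path) {
  .validateConfig(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.paramsFromConfig <- function(config, condition) {
  sc <- config$scenarios[[condition]]
  if (is.null(sc)) stop(sprintf("condition '%s' not in config", condition))
  simParams(n0 = config$n0, s_onset_clock = sc$s_onset_clock,
            sigma_sync = sc$sigma_sync, t_s = sc$t_s, t_g2 = sc$t_g2,
            jitter_s = sc$jitter_s, jitter_g2 = sc$jitter_g2,
            frac_arrested = sc$frac_arrested, mode = sc$mode,
            dilution = sc$dilution, seed = sc$seed)
}

.scheduleFromConfig <- function(config) {
  s <- config$schedule
  lightSchedule(t_dawn = s$t_dawn, photoperiod_h = s$photoperiod_h,
                e_max_par = s$e_max_par, e_max_uva = s$e_max_uva,
                e_max_uvb = s$e_max_uvb)
}

.instrumentFromConfig <- function(config) {
  i <- config$instrument
  instrumentModel(gain = i$gain, cv = i$cv,
                  debris_frac = if (is.null(i$debris_frac)) 0
                                else i$debris_frac)
}

#' Write / read event samples as TSV
#'
#' Plain-text event interchange: columns `day_index`, `time_h` (clock
#' hours) and `fl_au` (fluorescence, a.u.).
#'
#' @param samples list of [EventSample-class] objects.
#' @param path TSV file path.
#' @return `writeEventsTSV()` returns `path` invisibly;
#'   `readEventsTSV()` returns a list of [EventSample-class] in time
#'   order.
#' @export
writeEventsTSV <- function(samples, path) {
  d <- do.call(rbind, lapply(samples, function(s)
    data.frame(day_index = s@day, time_h = s@t, fl_au = s@events)))
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeEventsTSV
#' @param condition condition label applied to the read samples.
#' @export
readEventsTSV <- function(path, condition = NA_character_) {
  d <- utils::read.delim(path)
  need <- c("day_index", "time_h", "fl_au")
  if (!all(need %in% names(d)))
    stop(sprintf("malformed events TSV: missing column(s) %s",
                 paste(setdiff(need, names(d)), collapse = ", ")))
  key <- interaction(d$day_index, d$time_h, drop = TRUE)
  parts <- split(d, key)
  ord <- order(vapply(parts, function(p) 24 * p$day_index[1] + p$time_h[1],
                      numeric(1)))
  lapply(parts[ord], function(p)
    eventSample(t = p$time_h[1], events = p$fl_au, day = p$day_index[1],
                condition = condition))
}

#' Write a phase-fraction series as TSV
#'
#' Columns `time_h`, `day_index`, `f_G1`, `f_S`, `f_G2` plus any fit
#' diagnostics present (`m`, `cv`, `gof`, `converged`).
#'
#' @param series a [PhaseFractionSeries-class] object.
#' @param path TSV file path.
#' @return `path`, invisibly. `readFractionsTSV()` returns the series.
#' @export
writeFractionsTSV <- function(series, path) {
  utils::write.table(series@data, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeFractionsTSV
#' @param condition condition label for the read series.
#' @export
readFractionsTSV <- function(path, condition = NA_character_) {
  phaseFractionSeries(utils::read.delim(path), condition = condition)
}

#' Simulate one configured condition and write its files
#'
#' Runs the simulator + measurement model for one condition of a
#' [pipelineConfig()] and writes `events_<cond>.tsv`, `truth_<cond>.tsv`,
#' `counts_<cond>.tsv` and a JSON manifest recording the seeds, the config
#' hash and the package version. Byte-identical outputs under identical
#' config + seeds.
#'
#' @param config a pipeline config.
#' @param condition condition name present in the config.
#' @param outdir output directory (created if needed).
#' @return invisible list of written file paths plus the in-memory
#'   simulation results.
#' @export
simulateScenario <- function(config, condition, outdir) {
  .validateConfig(config)
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory '%s'", outdir))
  params <- .paramsFromConfig(config, condition)
  res <- simulateMeasuredSeries(
    params, schedule = .scheduleFromConfig(config),
    sample_times = config$sample_times, n_days = config$n_days,
    instrument = .instrumentFromConfig(config), n_events = config$n_events,
    seed_measure = params@seed + 5000L, condition = condition)
  tag <- gsub("[^A-Za-z0-9]+", "_", condition)
  files <- list(
    events = file.path(outdir, sprintf("events_%s.tsv", tag)),
    truth = file.path(outdir, sprintf("truth_%s.tsv", tag)),
    counts = file.path(outdir, sprintf("counts_%s.tsv", tag)),
    manifest = file.path(outdir, sprintf("manifest_%s.json", tag)))
  writeEventsTSV(res$samples, files$events)
  writeFractionsTSV(res$truth, files$truth)
  utils::write.table(res$counts, files$counts, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cfg_file <- tempfile(fileext = ".yaml")
  writeScenarioConfig(config, cfg_file)
  manifest <- list(
    package = "dielcycle",
    version = as.character(utils::packageVersion("dielcycle")),
    condition = condition,
    config_md5 = unname(tools::md5sum(cfg_file)),
    seed_population = params@seed,
    seed_measure_base = params@seed + 5000L,
    n_events = config$n_events,
    files = lapply(files[c("events", "truth", "counts")], basename))
  unlink(cfg_file)
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(files, list(result = res)))
}

#' Analyze event samples end-to-end
#'
#' Histogram fit per timepoint, peak timing, phase durations, growth
#' rates: the full DNA-histogram analysis chain for one condition.
#'
#' @param samples list of [EventSample-class] objects, or a path to an
#'   events TSV (see [readEventsTSV()]).
#' @param counts optional cell-count data.frame (`day_index`, `time_h`,
#'   `n_cells`) enabling the count-based rate mu_nb.
#' @param n_bins,min_events histogram options.
#' @param window smoothing window for peak detection.
#' @param condition condition label.
#' @param ... passed to [fitDNAHistogram()].
#' @return list with `series` ([PhaseFractionSeries-class]), `timing`
#'   ([PhaseTiming-class]), `durations` ([PhaseDurations-class]), `growth`
#'   ([GrowthEstimate-class]) and `summary` (one-row data.frame mirroring
#'   the standard growth-parameter table: mu_cc, mu_nb, T_G1, T_S, T_G2,
#'   S_r).
#' @export
analyzeEvents <- function(samples, counts = NULL, n_bins = 256,
                          min_events = 5000, window = 3L,
                          condition = NULL, ...) {
  if (is.character(samples)) {
    if (!file.exists(samples))
      stop(sprintf("no event input found at '%s'", samples))
    samples <- readEventsTSV(samples, condition = condition %||% NA_character_)
  }
  series <- tryCatch(
    fractionsSeries(samples, n_bins = n_bins, min_events = min_events,
                    condition = condition, ...),
    error = function(e) stop("histogram-fit stage failed: ",
                             conditionMessage(e)))
  timing <- tryCatch(findPhasePeaks(series, window = window),
                     error = function(e)
                       stop("peak-timing stage failed: ",
                            conditionMessage(e)))
  mu <- tryCatch(muCC(series, t_s_plus_g2 = 2 * timing@delta_t),
                 error = function(e)
                   stop("growth-rate stage failed: ", conditionMessage(e)))
  s_r <- as.numeric(syncIndex(series))
  dur <- estimatePhaseDurations(timing, series, mu_cc = mu$mu, s_r = s_r)
  # mu_nb needs the same clock time on >= 2 days; otherwise unavailable
  mu_nb <- if (!is.null(counts) && length(unique(counts$day_index)) >= 2L)
    muNbFromSeries(counts) else NA_real_
  growth <- growthEstimate(mu, mu_nb = mu_nb)
  summary <- data.frame(
    condition = conditionLabel(series),
    mu_cc = growth@mu_cc, mu_cc_dev = growth@mu_cc_dev, mu_nb = growth@mu_nb,
    t_g1 = dur@t_g1, t_s = dur@t_s, t_g2 = dur@t_g2, s_r = s_r,
    t_smax = timing@t_smax, t_g2max = timing@t_g2max,
    delta_t = timing@delta_t)
  list(series = series, timing = timing, durations = dur, growth = growth,
       summary = summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full two-condition scenario pipeline
#'
#' Simulates every condition in the config, analyses each end-to-end, and
#' estimates the between-condition lag of the S-phase wave by circular
#' cross-correlation (positive = second condition later). With an
#' `outdir`, all stage outputs and a combined summary TSV are written.
#'
#' @param config a [pipelineConfig()] list.
#' @param outdir optional output directory.
#' @return list with per-condition `analyses`, the combined `summary`
#'   data.frame and `lag_s_h` (hours; `NA` with fewer than 2 conditions).
#' @export
runScenario <- function(config = pipelineConfig(), outdir = NULL) {
  .validateConfig(config)
  conds <- names(config$scenarios)
  analyses <- list()
  for (nm in conds) {
    if (!is.null(outdir)) {
      sim <- simulateScenario(config, nm, outdir)$result
    } else {
      params <- .paramsFromConfig(config, nm)
      sim <- simulateMeasuredSeries(
        params, schedule = .scheduleFromConfig(config),
        sample_times = config$sample_times, n_days = config$n_days,
        instrument = .instrumentFromConfig(config),
        n_events = config$n_events, seed_measure = params@seed + 5000L,
        condition = nm)
    }
    analyses[[nm]] <- analyzeEvents(sim$samples, counts = sim$counts,
                                    n_bins = config$n_bins, condition = nm)
  }
  summary <- do.call(rbind, lapply(analyses, `[[`, "summary"))
  rownames(summary) <- NULL
  lag <- if (length(conds) >= 2L)
    estimateDelay(analyses[[1]]$series, analyses[[2]]$series, phase = "S")
  else NA_real_
  if (!is.null(outdir)) {
    for (nm in conds)
      writeFractionsTSV(analyses[[nm]]$series,
                        file.path(outdir, sprintf("fractions_%s.tsv",
                                  gsub("[^A-Za-z0-9]+", "_", nm))))
    out <- summary
    out$lag_s_h <- lag
    utils::write.table(out, file.path(outdir, "growth_summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(analyses = analyses, summary = summary, lag_s_h = lag)
}

#' qPCR relative-quantification convenience wrapper
#'
#' Reads a CT CSV, runs [ddct()] for each requested target and optionally
#' writes the combined RQ table as TSV.
#'
#' @param ct_csv path to the CT CSV (see [readCtTable()]).
#' @param targets target gene names; default: every gene except the
#'   reference.
#' @param out optional output TSV path.
#' @inheritParams ddct
#' @return combined RQ data.frame.
#' @export
qpcrAnalyze <- function(ct_csv, targets = NULL, reference_gene = "rnpB",
                        calibrator = list(condition = "HL", time_h = 6),
                        threshold_log2 = 1.0, out = NULL) {
  records <- readCtTable(ct_csv)
  if (is.null(targets))
    targets <- setdiff(unique(records$gene), reference_gene)
  res <- do.call(rbind, lapply(targets, function(g)
    ddct(records, g, reference_gene = reference_gene,
         calibrator = calibrator, threshold_log2 = threshold_log2)))
  rownames(res) <- NULL
  if (!is.null(out))
    utils::write.table(res, out, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  res
}
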
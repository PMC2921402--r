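#' Read a qPCR CT table
#'
#' Expects CSV columns `gene`, `condition`, `time_h`, `replicate`, `ct`
#' (threshold cycles, 0 < CT < 45). A missing column raises a schema error
#' naming it.
#'
#' @param path CSV file path.
#' @return validated data.frame of CT records.
#' @export
readCtTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "condition", "time_h", "replicate", "ct")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop(sprintf("malformed CT table: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")))
  if (any(!is.finite(d$ct)) || any(d$ct <= 0 | d$ct >= 45))
    stop("ct values must lie in (0, 45)")
  d
}

# Mean CT and mean absolute deviation per (gene, condition, time_h),
# technical duplicates averaged on the CT scale.
.aggregateCt <- function(records) {
  key <- interaction(records$gene, records$condition, records$time_h,
                     drop = TRUE)
  agg <- do.call(rbind, lapply(split(records, key), function(g) {
    data.frame(gene = g$gene[1], condition = g$condition[1],
               time_h = g$time_h[1], ct = mean(g$ct),
               ct_dev = mean(abs(g$ct - mean(g$ct))))
  }))
  rownames(agg) <- NULL
  agg
}

#' Comparative-CT (delta-delta-CT) relative quantification
#'
#' For each sample (condition x time): `dCT = mean CT_target - mean
#' CT_reference` (technical duplicates averaged on the CT scale),
#' `ddCT = dCT - dCT(calibrator)`, `RQ = 2^-ddCT`,
#' `log2_fc = -ddCT`. Assumes the canonical amplification efficiency of
#' 2.0 per cycle. The calibrator's own RQ is exactly 1. Mean absolute
#' deviations of the duplicate CTs are propagated to an RQ range by
#' interval arithmetic (`rq_lo`, `rq_hi`).
#'
#' @param records CT data.frame with columns `gene`, `condition`,
#'   `time_h`, `replicate`, `ct` (see [readCtTable()]).
#' @param target target gene name.
#' @param reference_gene internal-standard gene (default `"rnpB"`).
#' @param calibrator list/vector with `condition` and `time_h` of the
#'   reference sample (default HL at 06:00).
#' @param threshold_log2 differential-expression threshold on |log2 FC|
#'   (strict inequality; default 1).
#' @return data.frame: `gene`, `condition`, `time_h`, `d_ct`, `dd_ct`,
#'   `rq`, `rq_lo`, `rq_hi`, `log2_fc`, `de_call`.
#' @examples
#' ct <- data.frame(
#'   gene = rep(c("recA", "rnpB"), each = 2),
#'   condition = "HL", time_h = 6, replicate = 1:2,
#'   ct = c(24.0, 24.0, 18.0, 18.0))
#' ddct(ct, target = "recA")  # calibrator row: RQ = 1
#' @export
ddct <- function(records, target, reference_gene = "rnpB",
                 calibrator = list(condition = "HL", time_h = 6),
                 threshold_log2 = 1.0) {
  need <- c("gene", "condition", "time_h", "ct")
  if (!all(need %in% names(records)))
    stop(sprintf("malformed CT table: missing column(s) %s",
                 paste(setdiff(need, names(records)), collapse = ", ")))
  if (!nrow(records))
    stop(sprintf("no CT records for target gene '%s'", target))
  agg <- .aggregateCt(records)
  tgt <- agg[agg$gene == target, , drop = FALSE]
  ref <- agg[agg$gene == reference_gene, , drop = FALSE]
  if (!nrow(tgt)) stop(sprintf("no CT records for target gene '%s'", target))
  if (!nrow(ref))
    stop(sprintf("no CT records for reference gene '%s'", reference_gene))
  key <- function(d) paste(d$condition, d$time_h)
  m <- match(key(tgt), key(ref))
  if (anyNA(m)) {
    bad <- which(is.na(m))[1]
    stop(sprintf("missing reference-gene CT for sample %s %g h",
                 tgt$condition[bad], tgt$time_h[bad]))
  }
  d_ct <- tgt$ct - ref$ct[m]
  d_dev <- tgt$ct_dev + ref$ct_dev[m]
  cal <- which(tgt$condition == calibrator$condition &
                 abs(tgt$time_h - calibrator$time_h) < 1e-9)
  if (!length(cal))
    stop(sprintf("calibrator sample (%s, %g h) absent for target '%s'",
                 calibrator$condition, calibrator$time_h, target))
  dd_ct <- d_ct - d_ct[cal[1]]
  dev_tot <- d_dev + d_dev[cal[1]]
  out <- data.frame(
    gene = target, condition = tgt$condition, time_h = tgt$time_h,
    d_ct = d_ct, dd_ct = dd_ct,
    rq = 2^(-dd_ct),
    rq_lo = 2^(-(dd_ct + dev_tot)),
    rq_hi = 2^(-(dd_ct - dev_tot)),
    log2_fc = -dd_ct)
  out$de_call <- deCall(out$log2_fc, threshold_log2)
  out[order(out$condition, out$time_h), , drop = FALSE]
}

#' Differential-expression call on the log2 fold-change scale
#'
#' TRUE iff `|log2_fc| > threshold_log2` (strict): fold changes within the
#' band \[-1, +1\] on the log2 scale are called not differentially
#' expressed.
#'
#' @param log2_fc numeric log2 fold changes (or a data.frame with a
#'   `log2_fc` column).
#' @param threshold_log2 threshold (default 1).
#' @return logical vector.
#' @export
deCall <- function(log2_fc, threshold_log2 = 1.0) {
  if (is.data.frame(log2_fc)) log2_fc <- log2_fc$log2_fc
  abs(log2_fc) > threshold_log2
}

#' Bundled qPCR primer metadata
#'
#' The primer sets used for diel qPCR of selected PCC9511 cell-cycle, DNA
#' repair, and regulatory genes, shipped for input validation (gene-name
#' lookup) only.
#'
#' @return data.frame: `locus_tag`, `gene`, `forward_primer`,
#'   `reverse_primer`.
#' @export
primerTable <- function() {
  path <- system.file("extdata", "pcc9511_qpcr_primers.tsv",
                      package = "dielcycle", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
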
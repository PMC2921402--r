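test_that("calibrator identity and the two-cycle shift worked example", {
  res <- ddct(makeCtTable(), target = "recA")
  cal <- res[res$time_h == 6, ]
  expect_equal(cal$dd_ct, 0)
  expect_equal(cal$rq, 1)
  shifted <- res[res$time_h == 18, ]
  expect_equal(shifted$dd_ct, -2)
  expect_equal(shifted$rq, 4)
  expect_equal(shifted$log2_fc, 2)
  expect_true(shifted$de_call)
  expect_false(cal$de_call)
})

test_that("randomized CT tables match an independent spreadsheet-style recomputation", {
  set.seed(17)
  genes <- c("ftsZ", "dnaA", "rnpB")
  grid <- expand.grid(gene = genes, condition = c("HL", "HL+UV"),
                      time_h = c(6, 12, 18, 22), replicate = 1:2,
                      stringsAsFactors = FALSE)
  grid$ct <- round(stats::runif(nrow(grid), 15, 30), 2)
  # ensure the calibrator exists for every gene (it does by construction)
  res <- ddct(grid, target = "ftsZ")

  # oracle: plain nested-loop recomputation from first principles
  meanCt <- function(g, cond, t)
    mean(grid$ct[grid$gene == g & grid$condition == cond &
                   grid$time_h == t])
  dct_cal <- meanCt("ftsZ", "HL", 6) - meanCt("rnpB", "HL", 6)
  for (i in seq_len(nrow(res))) {
    dct <- meanCt("ftsZ", res$condition[i], res$time_h[i]) -
      meanCt("rnpB", res$condition[i], res$time_h[i])
    expect_equal(res$dd_ct[i], dct - dct_cal, tolerance = 1e-12)
    expect_equal(res$rq[i], 2^-(dct - dct_cal), tolerance = 1e-12)
    expect_equal(res$log2_fc[i], log2(res$rq[i]), tolerance = 1e-12)
  }
})

test_that("RQ is invariant to a constant CT offset across the run", {
  tab <- makeCtTable()
  res0 <- ddct(tab, target = "recA")
  tab_off <- transform(tab, ct = ct + 3.25)
  res1 <- ddct(tab_off, target = "recA")
  expect_equal(res0$rq, res1$rq, tolerance = 1e-12)
  expect_equal(res0$dd_ct, res1$dd_ct, tolerance = 1e-12)
})

test_that("relative quantities are transitive on the CT scale", {
  set.seed(23)
  tab <- data.frame(
    gene = rep(c("g", "rnpB"), each = 3),
    condition = "HL", time_h = rep(c(6, 12, 18), 2), replicate = 1,
    ct = stats::runif(6, 16, 28))
  rq_rel <- function(cal_t) {
    r <- ddct(tab, target = "g", calibrator = list(condition = "HL",
                                                   time_h = cal_t))
    stats::setNames(r$rq, r$time_h)
  }
  rqA <- rq_rel(6)    # relative to 06:00
  rqB <- rq_rel(12)   # relative to 12:00
  # RQ(18 vs 12) * RQ(12 vs 6) = RQ(18 vs 6)
  expect_equal(rqB[["18"]] * rqA[["12"]], rqA[["18"]], tolerance = 1e-12)
})

test_that("DE calls use a strict threshold on |log2 FC|", {
  expect_false(deCall(0.5))
  expect_true(deCall(-1.5))
  expect_false(deCall(1.0))   # boundary: strictly greater than
  expect_false(deCall(-1.0))
  expect_true(deCall(1.0 + 1e-9))
})

test_that("duplicate deviations propagate to an RQ interval", {
  tab <- makeCtTable()
  tab$ct[tab$gene == "recA" & tab$time_h == 18] <- c(21.8, 22.2)
  res <- ddct(tab, target = "recA")
  r18 <- res[res$time_h == 18, ]
  expect_lt(r18$rq_lo, r18$rq)
  expect_gt(r18$rq_hi, r18$rq)
  expect_equal(r18$rq_hi / r18$rq, 2^0.2, tolerance = 1e-9)
})

test_that("missing reference or calibrator raise named errors", {
  tab <- makeCtTable()
  expect_error(ddct(tab[tab$gene != "rnpB", ], target = "recA"),
               "reference gene")
  expect_error(ddct(tab, target = "recA",
                    calibrator = list(condition = "HL", time_h = 9)),
               "calibrator")
  expect_error(ddct(tab[0, ], target = "recA"), "target gene")
  expect_error(ddct(tab[, -5], target = "recA"), "missing column")
})

test_that("CT tables read with schema validation; primer metadata loads", {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(makeCtTable(), f, row.names = FALSE)
  tab <- readCtTable(f)
  expect_equal(nrow(tab), 8)
  bad <- makeCtTable()
  names(bad)[5] <- "value"
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(readCtTable(f), "missing column\\(s\\) ct")
  prim <- primerTable()
  expect_true("rnpB" %in% prim$gene)
  expect_equal(ncol(prim), 4)
  res <- qpcrAnalyze(local({
    utils::write.csv(makeCtTable(), f, row.names = FALSE); f
  }))
  expect_equal(res$rq[res$time_h == 6], 1)
  unlink(f)
})
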
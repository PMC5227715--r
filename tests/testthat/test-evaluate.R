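tinyGrid <- list(costGrid = c(1, 100), gammaGrid = 0.05, cvFolds = 2L)

tinyEval <- function(fun, windows, ...) {
  fun(windows, seed = 1, costGrid = tinyGrid$costGrid,
      gammaGrid = tinyGrid$gammaGrid, cvFolds = tinyGrid$cvFolds, ...)
}

test_that("metric formulas are exact, with an independent MCC route", {
  perfect <- computeMetrics(c(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(perfect[c("Sn", "Sp", "Acc", "MCC")],
               list(Sn = 1, Sp = 1, Acc = 1, MCC = 1))
  chance <- computeMetrics(c(TP = 25, TN = 25, FP = 25, FN = 25))
  expect_equal(chance$Acc, 0.5)
  expect_equal(chance$MCC, 0)

  m <- computeMetrics(c(TP = 50, TN = 40, FP = 20, FN = 10))
  expect_equal(m$Sn, 50 / 60)
  expect_equal(m$Sp, 40 / 60)
  expect_equal(m$Acc, 0.75)
  # independent second route: MCC is the Pearson correlation of the binary
  # truth/prediction indicator vectors
  truth <- rep(c(1, 0), c(60, 60))
  pred <- c(rep(1, 50), rep(0, 10), rep(1, 20), rep(0, 40))
  expect_equal(m$MCC, cor(truth, pred))
  expect_equal(m$MCC, 0.5070926, tolerance = 1e-6)
})

test_that("degenerate marginals error or flag as configured", {
  expect_error(computeMetrics(c(TP = 0, TN = 5, FP = 5, FN = 0)),
               "Sn undefined")
  expect_error(computeMetrics(c(TP = 5, TN = 0, FP = 0, FN = 5)),
               "Sp undefined")
  expect_warning(
    z <- computeMetrics(c(TP = 0, TN = 5, FP = 5, FN = 0),
                        degenerate = "zero"),
    "MCC")
  expect_equal(z$Sn, 0)
  expect_equal(z$MCC, 0)
  expect_true(z$degenerateMCC)
  expect_error(computeMetrics(c(TP = 0, TN = 0, FP = 0, FN = 0)), "empty")
})

test_that("confusion counts aggregate truth against predictions", {
  truth <- c("m6A", "m6A", "non-m6A", "non-m6A", "m6A")
  pred <- c("m6A", "non-m6A", "non-m6A", "m6A", "m6A")
  cm <- confusionCounts(truth, pred)
  expect_identical(unname(cm), c(2L, 1L, 1L, 1L))
  expect_identical(sum(cm), length(truth))
})

test_that("jackknife runs n rounds and its records recount to the metrics", {
  ds <- syntheticWindows(5, 5, plantProb = 1, jitter = 0, seed = 2,
                         strictNegatives = TRUE)
  r <- tinyEval(jackknifeEvaluate, ds)
  expect_identical(nrow(r$records), 10L)
  expect_identical(sum(r$confusion), 10L)
  expect_identical(sort(unique(r$records$fold)), 1:10)
  # brute recount from the per-window records
  cm2 <- confusionCounts(r$records$truth, r$records$predicted)
  expect_identical(r$confusion, cm2)
  expect_equal(r$metrics$Acc,
               mean(r$records$truth == r$records$predicted))
  expect_error(tinyEval(jackknifeEvaluate, ds[1:3]), "n >= 4")
})

test_that("jackknife recovers a strongly planted, class-exclusive motif", {
  # separability is verified on the training data first; on held-out
  # windows the sequence-level voters (motif, gkm) carry the ensemble.
  # The PseDNC voter is signal-free here and, as in any leave-one-out
  # design with a balanced set, degenerates toward the training-fold
  # majority, i.e. the wrong class, so perfect ensemble accuracy is not
  # attainable; the majority of the two informative voters is.
  ds <- syntheticWindows(30, 30, plantProb = 1, jitter = 0, seed = 2,
                         strictNegatives = TRUE)
  for (kind in c("motif", "gkm")) {
    clf <- trainBaseClassifier(ds, kind, seed = 1, costGrid = c(1, 512),
                               gammaGrid = c(0.05, 0.5), cvFolds = 2)
    expect_identical(as.character(predictBaseClassifier(clf, ds)),
                     windowLabels(ds))
  }
  r <- jackknifeEvaluate(ds, seed = 1, costGrid = c(1, 512),
                         gammaGrid = c(0.05, 0.5), cvFolds = 2)
  rec <- r$records
  expect_gte(mean(rec$motif == rec$truth), 0.9)
  expect_gte(mean(rec$gkm == rec$truth), 0.85)
  expect_gte(r$metrics$Acc, 0.8)
})

test_that("k = n folding reduces exactly to the jackknife", {
  ds <- syntheticWindows(4, 4, plantProb = 1, jitter = 0, seed = 6,
                         strictNegatives = TRUE)
  rj <- tinyEval(jackknifeEvaluate, ds)
  rk <- tinyEval(kfoldEvaluate, ds, k = length(ds))
  expect_identical(rk$confusion, rj$confusion)
  expect_identical(rk$records$predicted, rj$records$predicted)
  expect_error(tinyEval(kfoldEvaluate, ds, k = 20), "config error")
})

test_that("fold evaluation is reproducible under the seed", {
  ds <- syntheticWindows(6, 6, seed = 4)
  r1 <- tinyEval(kfoldEvaluate, ds, k = 3)
  r2 <- tinyEval(kfoldEvaluate, ds, k = 3)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$confusion, r2$confusion)
})

test_that("a fold losing one class entirely is reported by round", {
  # the single negative sits in one fold; that round's training split is
  # one-class
  ds <- syntheticWindows(4, 1, seed = 5)
  expect_error(
    kfoldEvaluate(ds, k = 4, seed = 1, costGrid = 1, gammaGrid = 0.05,
                  cvFolds = 2),
    "fold error")
})

test_that("evaluation reports serialize metrics and audit records", {
  ds <- syntheticWindows(4, 4, plantProb = 1, jitter = 0, seed = 10,
                         strictNegatives = TRUE)
  r <- tinyEval(kfoldEvaluate, ds, k = 4)
  tf <- tempfile(fileext = ".tsv"); tr <- tempfile(fileext = ".tsv")
  writeEvaluationReport(r, tf, tr)
  m <- utils::read.delim(tf)
  expect_identical(m$metric,
                   c("TP", "TN", "FP", "FN", "Sn", "Sp", "Acc", "MCC"))
  expect_equal(m$value[m$metric == "Acc"], r$metrics$Acc)
  recs <- utils::read.delim(tr)
  expect_identical(nrow(recs), nrow(r$records))
})
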
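# small grids keep these contract tests fast; grid contents are arguments,
# not part of the contracts under test
fastGrid <- list(costGrid = c(1, 100), gammaGrid = c(0.01, 0.1),
                 cvFolds = 3L)

separableSet <- function(n = 12, seed = 21) {
  syntheticWindows(n, n, plantProb = 1, jitter = 0, seed = seed,
                   strictNegatives = TRUE)
}

trainFast <- function(windows, kind, config = NULL, seed = 1L) {
  trainBaseClassifier(windows, kind, config, seed = seed,
                      costGrid = fastGrid$costGrid,
                      gammaGrid = fastGrid$gammaGrid,
                      cvFolds = fastGrid$cvFolds)
}

test_that("each base classifier separates a strongly planted motif", {
  ds <- separableSet()
  for (kind in c("psednc", "motif", "gkm")) {
    clf <- trainFast(ds, kind)
    expect_s4_class(clf, "BaseClassifier")
    expect_true(clf@cvAccuracy >= 0 && clf@cvAccuracy <= 1)
    pred <- predictBaseClassifier(clf, ds)
    if (kind != "psednc") {
      # motif and string views are fully separable by construction
      expect_identical(as.character(pred), windowLabels(ds))
    }
  }
  # the ensemble reproduces the training labels on the separable set
  mod <- trainEnsemble(ds, seed = 21, costGrid = fastGrid$costGrid,
                       gammaGrid = fastGrid$gammaGrid,
                       cvFolds = fastGrid$cvFolds)
  rep <- predictSites(mod, ds)
  expect_identical(rep$predicted, windowLabels(ds))
})

test_that("training is deterministic under a fixed seed", {
  ds <- separableSet(10, seed = 33)
  held <- syntheticWindows(8, 8, seed = 34)
  m1 <- trainEnsemble(ds, seed = 5, costGrid = fastGrid$costGrid,
                      gammaGrid = fastGrid$gammaGrid, cvFolds = 3)
  m2 <- trainEnsemble(ds, seed = 5, costGrid = fastGrid$costGrid,
                      gammaGrid = fastGrid$gammaGrid, cvFolds = 3)
  expect_identical(predictSites(m1, held), predictSites(m2, held))
  expect_identical(cvAccuracy(m1), cvAccuracy(m2))
})

test_that("degenerate training inputs raise informative errors", {
  ds <- separableSet(6)
  onlyPos <- ds[windowLabels(ds) == "m6A"]
  expect_error(trainFast(onlyPos, "psednc"), "training error")
  expect_error(trainFast(ds, "psednc", config = GkmParams()), "config error")
  expect_error(trainFast(ds, "gkm", config = PseDncConfig()), "config error")
  unlabeled <- ds
  windowLabels(unlabeled) <- NA_character_
  expect_error(trainFast(unlabeled, "motif"), "training error")
})

test_that("ensemble weights follow the chosen policy", {
  ds <- separableSet(10, seed = 8)
  mu <- trainEnsemble(ds, weighting = "uniform", seed = 8,
                      costGrid = fastGrid$costGrid,
                      gammaGrid = fastGrid$gammaGrid, cvFolds = 3)
  expect_equal(unname(votingWeights(mu)), rep(1 / 3, 3))
  mc <- trainEnsemble(ds, weighting = "cv_accuracy", seed = 8,
                      costGrid = fastGrid$costGrid,
                      gammaGrid = fastGrid$gammaGrid, cvFolds = 3)
  a <- cvAccuracy(mc)
  expect_equal(unname(votingWeights(mc)), unname(a / sum(a)))
  expect_equal(sum(votingWeights(mc)), 1)
  # the normalization arithmetic itself: accuracies (0.6, 0.6, 0.8)
  expect_equal(c(0.6, 0.6, 0.8) / sum(c(0.6, 0.6, 0.8)), c(0.3, 0.3, 0.4))
})

test_that("models survive a save/load round trip", {
  ds <- separableSet(8, seed = 13)
  mod <- trainEnsemble(ds, seed = 13, costGrid = fastGrid$costGrid,
                       gammaGrid = fastGrid$gammaGrid, cvFolds = 2)
  tf <- tempfile(fileext = ".rds")
  saveEnsembleModel(mod, tf)
  back <- loadEnsembleModel(tf)
  expect_identical(predictSites(back, ds), predictSites(mod, ds))
  expect_identical(back@meta$fingerprint, mod@meta$fingerprint)
  # non-model archives are rejected
  saveRDS(list(1), tf)
  expect_error(loadEnsembleModel(tf), "input-format")
})

test_that("ensemble calls are invariant to classifier listing order", {
  ds <- separableSet(8, seed = 17)
  mod <- trainEnsemble(ds, seed = 17, costGrid = fastGrid$costGrid,
                       gammaGrid = fastGrid$gammaGrid, cvFolds = 2)
  shuffled <- new("EnsembleModel",
                  classifiers = mod@classifiers[c("gkm", "psednc", "motif")],
                  weights = mod@weights[c("gkm", "psednc", "motif")],
                  tieBreak = mod@tieBreak, meta = mod@meta)
  expect_identical(predictSites(shuffled, ds)$predicted,
                   predictSites(mod, ds)$predicted)
})

test_that("the predict generic dispatches to predictSites", {
  ds <- separableSet(6, seed = 19)
  mod <- trainEnsemble(ds, seed = 19, costGrid = fastGrid$costGrid,
                       gammaGrid = fastGrid$gammaGrid, cvFolds = 2)
  one <- ds[1]
  rec <- predict(mod, one)
  expect_identical(nrow(rec), 1L)
  expect_true(all(c("psednc", "motif", "gkm") %in% colnames(rec)))
  expect_true(all(rec[, c("psednc", "motif", "gkm")] %in%
                    c("m6A", "non-m6A")))
})
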
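# Jackknife (leave-one-out) and stratified k-fold evaluation with the four
# standard metrics: Sn, Sp, Acc, MCC.

#' Confusion matrix from truth and predictions
#'
#' @param truth,predicted character or factor vectors of \code{"m6A"} /
#'   \code{"non-m6A"} labels, same length.
#' @return named integer vector with components TP, TN, FP, FN.
#' @export
confusionCounts <- function(truth, predicted) {
  truth <- asLabelFactor(truth)
  predicted <- asLabelFactor(predicted)
  stopifnot(length(truth) == length(predicted), !anyNA(truth),
            !anyNA(predicted))
  c(TP = sum(truth == LABEL_POS & predicted == LABEL_POS),
    TN = sum(truth == LABEL_NEG & predicted == LABEL_NEG),
    FP = sum(truth == LABEL_NEG & predicted == LABEL_POS),
    FN = sum(truth == LABEL_POS & predicted == LABEL_NEG))
}

#' Sensitivity, specificity, accuracy and MCC
#'
#' Standard formulas: \eqn{Sn = TP/(TP+FN)}, \eqn{Sp = TN/(TN+FP)},
#' \eqn{Acc = (TP+TN)/N}, \eqn{MCC = (TP \cdot TN - FP \cdot FN) /
#' \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.
#'
#' @param cm named numeric vector with TP, TN, FP, FN (e.g. from
#'   \code{\link{confusionCounts}}).
#' @param degenerate what to do when a marginal needed by Sn or Sp is zero:
#'   \code{"error"} (default) or \code{"zero"} (report 0, batch-friendly).
#'   MCC with any zero marginal is always reported as 0 with a warning and
#'   flagged.
#' @return list with \code{Sn}, \code{Sp}, \code{Acc}, \code{MCC} and
#'   \code{degenerateMCC} (logical flag).
#' @examples
#' computeMetrics(c(TP = 50, TN = 40, FP = 20, FN = 10))
#' @export
computeMetrics <- function(cm, degenerate = c("error", "zero")) {
  degenerate <- match.arg(degenerate)
  need <- c("TP", "TN", "FP", "FN")
  stopifnot(all(need %in% names(cm)))
  cm <- as.numeric(cm[need])
  if (anyNA(cm) || any(cm < 0))
    stop("confusion counts must be non-negative", call. = FALSE)
  TP <- cm[1]; TN <- cm[2]; FP <- cm[3]; FN <- cm[4]
  n <- TP + TN + FP + FN
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  marg <- function(x, what) {
    if (x == 0) {
      if (degenerate == "error")
        stop(what, " undefined error: its marginal is zero", call. = FALSE)
      return(NA_real_)
    }
    x
  }
  Sn <- TP / marg(TP + FN, "Sn"); if (is.na(Sn)) Sn <- 0
  Sp <- TN / marg(TN + FP, "Sp"); if (is.na(Sp)) Sp <- 0
  Acc <- (TP + TN) / n
  denom <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  degenerateMCC <- denom == 0
  if (degenerateMCC) {
    warning("MCC marginal is zero; reporting MCC = 0", call. = FALSE)
    MCC <- 0
  } else {
    MCC <- (TP * TN - FP * FN) / sqrt(denom)
  }
  list(Sn = Sn, Sp = Sp, Acc = Acc, MCC = MCC, degenerateMCC = degenerateMCC)
}

# Shared engine: evaluate the full training recipe over a fold assignment.
# Honest mode re-mines the motif vocabulary and re-runs the hyperparameter
# search inside every training fold; fast mode shares a vocabulary mined on
# the full data (leakage-prone, for exploration only). The gkm Gram matrix
# is precomputed once: kernel values are data-independent functions of the
# sequence pairs, so subsetting it per fold leaks nothing.
evaluateFolds <- function(windows, fold, seed, refitVocabulary, weighting,
                          psedncConfig, gkmParams, motifMinLen, motifMaxLen,
                          motifMinimalOnly, costGrid, gammaGrid, cvFolds,
                          verbose = FALSE) {
  labels <- asLabelFactor(windowLabels(windows))
  if (anyNA(labels)) stop("all windows must be labeled", call. = FALSE)
  seqs <- as.character(windows)
  n <- length(seqs)
  Kfull <- gkmKernelMatrix(seqs, gkmParams, normalize = TRUE)
  sharedVocab <- if (!refitVocabulary) {
    mineDiscriminativeSubstrings(seqs[labels == LABEL_POS],
                                 seqs[labels == LABEL_NEG],
                                 minLen = motifMinLen, maxLen = motifMaxLen,
                                 minimalOnly = motifMinimalOnly)
  } else NULL
  predicted <- character(n)
  baseLab <- matrix(NA_character_, n, 3L,
                    dimnames = list(NULL, c("psednc", "motif", "gkm")))
  vPos <- numeric(n); vNeg <- numeric(n)
  for (fd in sort(unique(fold))) {
    te <- which(fold == fd); tr <- which(fold != fd)
    if (length(unique(labels[tr])) < 2L)
      stop("fold error: round ", fd, " loses one class entirely",
           call. = FALSE)
    trWin <- windows[tr]
    if (refitVocabulary) {
      model <- trainEnsemble(trWin, psedncConfig = psedncConfig,
                             gkmParams = gkmParams, motifMinLen = motifMinLen,
                             motifMaxLen = motifMaxLen,
                             motifMinimalOnly = motifMinimalOnly,
                             weighting = weighting,
                             seed = deriveSeed(seed, 100L + fd),
                             costGrid = costGrid, gammaGrid = gammaGrid,
                             cvFolds = cvFolds,
                             gkmKernelTrain = Kfull[tr, tr, drop = FALSE])
    } else {
      clfs <- list(
        psednc = trainBaseClassifier(trWin, "psednc", psedncConfig,
                                     deriveSeed(seed, 100L + fd),
                                     costGrid, gammaGrid, cvFolds),
        motif = trainBaseClassifier(trWin, "motif", sharedVocab,
                                    deriveSeed(seed, 100L + fd),
                                    costGrid, gammaGrid, cvFolds),
        gkm = trainBaseClassifier(trWin, "gkm", gkmParams,
                                  deriveSeed(seed, 100L + fd),
                                  costGrid, gammaGrid, cvFolds,
                                  gkmKernelTrain = Kfull[tr, tr, drop = FALSE]))
      w <- if (weighting == "uniform") rep(1 / 3, 3) else {
        a <- vapply(clfs, cvAccuracy, numeric(1)); a / sum(a)
      }
      names(w) <- names(clfs)
      model <- new("EnsembleModel", classifiers = clfs, weights = w,
                   tieBreak = "max-weight",
                   meta = list(package = "ramESVM",
                               version = as.character(
                                 utils::packageVersion("ramESVM")),
                               archiveVersion = 1L,
                               seed = deriveSeed(seed, 100L + fd),
                               weighting = weighting,
                               fingerprint = ""))
    }
    rec <- predictSites(model, windows[te],
                        gkmKernelCross = Kfull[te, tr, drop = FALSE])
    predicted[te] <- rec$predicted
    baseLab[te, ] <- as.matrix(rec[, c("psednc", "motif", "gkm")])
    vPos[te] <- rec$V_m6A; vNeg[te] <- rec$V_non_m6A
    if (verbose)
      message(sprintf("INFO fold %d/%d: %d held out, %d correct",
                      fd, length(unique(fold)), length(te),
                      sum(predicted[te] == as.character(labels[te]))))
  }
  records <- data.frame(
    transcript_id = transcriptId(windows),
    center_pos = centerPos(windows),
    fold = fold, truth = as.character(labels), predicted = predicted,
    V_m6A = vPos, V_non_m6A = vNeg,
    psednc = baseLab[, "psednc"], motif = baseLab[, "motif"],
    gkm = baseLab[, "gkm"], stringsAsFactors = FALSE)
  cm <- confusionCounts(labels, predicted)
  list(confusion = cm,
       metrics = computeMetrics(cm, degenerate = "zero"),
       records = records)
}

#' Jackknife (leave-one-out) evaluation
#'
#' Runs exactly n rounds; round i trains the full recipe — motif vocabulary
#' mining, hyperparameter cross-validation, all three base classifiers and
#' the voting weights — on the other n-1 windows and predicts window i. The
#' confusion matrix aggregates all n held-out predictions.
#'
#' @param windows a labeled \linkS4class{SiteWindowSet} (n >= 4, both
#'   classes present).
#' @param seed master seed for fold-internal randomness.
#' @param refitVocabulary re-mine the motif vocabulary inside every training
#'   fold (default TRUE, the statistically honest protocol). \code{FALSE}
#'   shares one vocabulary mined on the full data: faster but leakage-prone;
#'   never use it to report performance.
#' @param weighting \code{"uniform"} or \code{"cv_accuracy"}.
#' @param psedncConfig,gkmParams,motifMinLen,motifMaxLen,motifMinimalOnly
#'   recipe configuration (see \code{\link{trainEnsemble}}).
#' @param costGrid,gammaGrid,cvFolds hyperparameter search settings.
#' @param verbose emit one INFO line per fold (default FALSE).
#' @return list with \code{confusion} (TP/TN/FP/FN), \code{metrics}
#'   (Sn/Sp/Acc/MCC) and \code{records} (one audit row per window: truth,
#'   final and per-classifier labels, voting scores, fold index).
#' @export
jackknifeEvaluate <- function(windows, seed = 1L, refitVocabulary = TRUE,
                              weighting = c("uniform", "cv_accuracy"),
                              psedncConfig = PseDncConfig(),
                              gkmParams = GkmParams(), motifMinLen = 4L,
                              motifMaxLen = 12L, motifMinimalOnly = TRUE,
                              costGrid = defaultCostGrid(),
                              gammaGrid = defaultGammaGrid(), cvFolds = 10L,
                              verbose = FALSE) {
  weighting <- match.arg(weighting)
  n <- length(windows)
  if (n < 4L) stop("config error: jackknife needs n >= 4", call. = FALSE)
  evaluateFolds(windows, fold = seq_len(n), seed = seed,
                refitVocabulary = refitVocabulary, weighting = weighting,
                psedncConfig = psedncConfig, gkmParams = gkmParams,
                motifMinLen = motifMinLen, motifMaxLen = motifMaxLen,
                motifMinimalOnly = motifMinimalOnly, costGrid = costGrid,
                gammaGrid = gammaGrid, cvFolds = cvFolds, verbose = verbose)
}

#' Stratified k-fold cross-validated evaluation
#'
#' Windows are partitioned into k folds, stratified by class under the
#' seed; each fold is predicted by the full recipe trained on the others
#' (identical in scope to a jackknife round). \code{k = n} with singleton
#' folds reduces exactly to the jackknife.
#'
#' @inheritParams jackknifeEvaluate
#' @param k number of folds (default 10; must not exceed n).
#' @return as \code{\link{jackknifeEvaluate}}.
#' @export
kfoldEvaluate <- function(windows, k = 10L, seed = 1L,
                          refitVocabulary = TRUE,
                          weighting = c("uniform", "cv_accuracy"),
                          psedncConfig = PseDncConfig(),
                          gkmParams = GkmParams(), motifMinLen = 4L,
                          motifMaxLen = 12L, motifMinimalOnly = TRUE,
                          costGrid = defaultCostGrid(),
                          gammaGrid = defaultGammaGrid(), cvFolds = 10L,
                          verbose = FALSE) {
  weighting <- match.arg(weighting)
  k <- as.integer(k)
  n <- length(windows)
  if (k > n) stop("config error: k = ", k, " exceeds n = ", n, call. = FALSE)
  fold <- if (k == n) seq_len(n) else
    stratifiedFolds(windowLabels(windows), k, deriveSeed(seed, 7L))
  evaluateFolds(windows, fold = fold, seed = seed,
                refitVocabulary = refitVocabulary, weighting = weighting,
                psedncConfig = psedncConfig, gkmParams = gkmParams,
                motifMinLen = motifMinLen, motifMaxLen = motifMaxLen,
                motifMinimalOnly = motifMinimalOnly, costGrid = costGrid,
                gammaGrid = gammaGrid, cvFolds = cvFolds, verbose = verbose)
}

#' Write an evaluation report
#'
#' Tab-delimited \code{metric <tab> value} file (TP/TN/FP/FN counts plus
#' Sn/Sp/Acc/MCC) and, optionally, the per-window audit records.
#'
#' @param result a list from \code{\link{jackknifeEvaluate}} or
#'   \code{\link{kfoldEvaluate}}.
#' @param path metrics output path.
#' @param recordsPath optional per-window records output path.
#' @return invisibly, \code{path}.
#' @export
writeEvaluationReport <- function(result, path, recordsPath = NULL) {
  m <- result$metrics
  df <- data.frame(
    metric = c(names(result$confusion), "Sn", "Sp", "Acc", "MCC"),
    value = c(as.numeric(result$confusion),
              m$Sn, m$Sp, m$Acc, m$MCC))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(recordsPath))
    utils::write.table(result$records, recordsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
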
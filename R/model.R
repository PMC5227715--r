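# Training of the three SVM base classifiers and the voting ensemble.
#
# Kernels per feature view: radial basis for dense PseDNC vectors, linear
# for sparse Boolean motif vectors, precomputed normalized gkm kernel for
# the string classifier. Hyperparameters are selected by stratified 10-fold
# cross-validated grid search inside the training fold only.

defaultCostGrid <- function() 2^seq(-3, 9, by = 4)
# The gamma grid serves only the radial PseDNC view. PseDNC vectors lie on
# the probability simplex (components ~1/22), so typical squared distances
# are ~4e-3 and the median-heuristic gamma is ~2^8; the grid brackets it.
defaultGammaGrid <- function() 2^seq(0, 8, by = 4)

# Generic CV grid search over a list of hyperparameter settings.
# fitFun(trainIdx, pars) -> model; predFun(model, testIdx) -> factor labels.
cvGridSearch <- function(labels, grid, folds, seed, fitFun, predFun) {
  fold <- stratifiedFolds(labels, folds, seed)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    pars <- as.list(grid[g, , drop = FALSE])
    mean(vapply(seq_len(folds), function(fd) {
      tr <- which(fold != fd); te <- which(fold == fd)
      fit <- fitFun(tr, pars)
      mean(predFun(fit, te, tr) == labels[te])
    }, numeric(1)))
  }, numeric(1))
  best <- which.max(acc)  # ties: first (deterministic grid order)
  list(pars = as.list(grid[best, , drop = FALSE]), accuracy = acc[best],
       grid = cbind(grid, accuracy = acc))
}

#' Train one base classifier
#'
#' Fits one of the three ensemble voters on labeled windows: a radial-kernel
#' SVM on PseDNC vectors, a linear SVM on Boolean motif vectors, or a
#' precomputed-kernel SVM on the normalized gapped k-mer Gram matrix.
#' Hyperparameters (cost; kernel width for the radial view) are chosen by
#' stratified \code{cvFolds}-fold cross-validated grid search within the
#' training windows only, and the winning setting's CV accuracy is stored.
#'
#' @param windows a labeled \linkS4class{SiteWindowSet} with both classes
#'   present (>= 2 windows per class).
#' @param kind \code{"psednc"}, \code{"motif"} or \code{"gkm"}.
#' @param config kind-matched configuration: a \linkS4class{PseDncConfig},
#'   a \linkS4class{MotifVocabulary} (when omitted, one is mined from the
#'   training windows), or \linkS4class{GkmParams}.
#' @param seed integer seed controlling fold assignment (the SVM fits
#'   themselves are deterministic).
#' @param costGrid,gammaGrid hyperparameter candidates (defaults
#'   \code{2^seq(-3, 9, 3)} and \code{2^seq(-9, 0, 3)}).
#' @param cvFolds folds for the hyperparameter search (default 10).
#' @param gkmKernelTrain optional precomputed normalized gkm Gram matrix of
#'   the training windows (a function of the sequences only), to avoid
#'   recomputation across evaluation folds.
#' @return a \linkS4class{BaseClassifier}.
#' @export
trainBaseClassifier <- function(windows, kind = c("psednc", "motif", "gkm"),
                                config = NULL, seed = 1L,
                                costGrid = defaultCostGrid(),
                                gammaGrid = defaultGammaGrid(),
                                cvFolds = 10L, gkmKernelTrain = NULL) {
  kind <- match.arg(kind)
  labels <- asLabelFactor(windowLabels(windows))
  if (anyNA(labels))
    stop("training error: all windows must be labeled", call. = FALSE)
  if (any(table(labels) < 2L))
    stop("training error: need >= 2 windows per class", call. = FALSE)
  seqs <- as.character(windows)
  cvFolds <- min(as.integer(cvFolds), min(table(labels)))
  searchSeed <- deriveSeed(seed, match(kind, c("psednc", "motif", "gkm")))

  if (kind == "psednc") {
    if (is.null(config)) config <- PseDncConfig()
    if (!is(config, "PseDncConfig"))
      stop("config error: psednc classifier needs a PseDncConfig", call. = FALSE)
    table <- standardizeProperties(builtinPropertyTable())
    X <- psedncMatrix(seqs, config, table)
    grid <- expand.grid(cost = costGrid, gamma = gammaGrid,
                        KEEP.OUT.ATTRS = FALSE)
    sr <- cvGridSearch(labels, grid, cvFolds, searchSeed,
      fitFun = function(tr, p) e1071::svm(X[tr, , drop = FALSE], labels[tr],
        kernel = "radial", cost = p$cost, gamma = p$gamma, scale = FALSE),
      predFun = function(fit, te, tr) predict(fit, X[te, , drop = FALSE]))
    fit <- e1071::svm(X, labels, kernel = "radial", cost = sr$pars$cost,
                      gamma = sr$pars$gamma, scale = FALSE)
    encoder <- list(config = config, table = table)
  } else if (kind == "motif") {
    if (is.null(config))
      config <- mineDiscriminativeSubstrings(seqs[labels == LABEL_POS],
                                             seqs[labels == LABEL_NEG])
    if (!is(config, "MotifVocabulary"))
      stop("config error: motif classifier needs a MotifVocabulary", call. = FALSE)
    X <- encodeMotifMatrix(seqs, config)
    if (ncol(X) == 0L)
      stop("training error: empty motif vocabulary", call. = FALSE)
    # Boolean motif vectors are very sparse; fit in sparse representation
    Xs <- SparseM::as.matrix.csr(X)
    grid <- expand.grid(cost = costGrid, KEEP.OUT.ATTRS = FALSE)
    sr <- cvGridSearch(labels, grid, cvFolds, searchSeed,
      fitFun = function(tr, p) e1071::svm(Xs[tr, ], labels[tr],
        kernel = "linear", cost = p$cost, scale = FALSE),
      predFun = function(fit, te, tr) predict(fit, Xs[te, ]))
    fit <- e1071::svm(Xs, labels, kernel = "linear", cost = sr$pars$cost,
                      scale = FALSE)
    encoder <- list(vocab = config)
  } else {
    if (is.null(config)) config <- GkmParams()
    if (!is(config, "GkmParams"))
      stop("config error: gkm classifier needs GkmParams", call. = FALSE)
    counts <- gkmCountMatrix(seqs, config)
    K <- if (is.null(gkmKernelTrain)) {
      Kf <- as.matrix(Matrix::tcrossprod(counts$F))
      Kf / sqrt(outer(counts$self, counts$self))
    } else gkmKernelTrain
    grid <- expand.grid(cost = costGrid, KEEP.OUT.ATTRS = FALSE)
    sr <- cvGridSearch(labels, grid, cvFolds, searchSeed,
      fitFun = function(tr, p) kernlab::ksvm(
        kernlab::as.kernelMatrix(K[tr, tr, drop = FALSE]), labels[tr],
        kernel = "matrix", C = p$cost),
      predFun = function(fit, te, tr) predict(fit, kernlab::as.kernelMatrix(
        K[te, tr[kernlab::SVindex(fit)], drop = FALSE])))
    fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K), labels,
                         kernel = "matrix", C = sr$pars$cost)
    encoder <- list(params = config, trainCounts = counts, trainSeqs = seqs)
  }
  new("BaseClassifier", kind = kind, encoder = encoder, fit = fit,
      hyper = sr$pars, cvAccuracy = sr$accuracy)
}

#' @rdname trainBaseClassifier
#' @param clf a trained \linkS4class{BaseClassifier}.
#' @param seqs character vector, string set or \linkS4class{SiteWindowSet}
#'   of windows to score.
#' @param gkmKernelCross optional precomputed normalized cross kernel
#'   (rows: \code{seqs}, columns: the classifier's training windows).
#' @return \code{predictBaseClassifier}: factor of predicted labels.
#' @export
predictBaseClassifier <- function(clf, seqs, gkmKernelCross = NULL) {
  stopifnot(is(clf, "BaseClassifier"))
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  seqs <- unname(seqs)
  if (clf@kind == "psednc") {
    X <- psedncMatrix(seqs, clf@encoder$config, clf@encoder$table)
    p <- predict(clf@fit, X)
  } else if (clf@kind == "motif") {
    X <- encodeMotifMatrix(seqs, clf@encoder$vocab)
    p <- predict(clf@fit, SparseM::as.matrix.csr(X))
  } else {
    Kc <- if (is.null(gkmKernelCross)) {
      crossFromCounts(gkmCountMatrix(seqs, clf@encoder$params),
                      clf@encoder$trainCounts)
    } else gkmKernelCross
    sv <- kernlab::SVindex(clf@fit)
    p <- predict(clf@fit, kernlab::as.kernelMatrix(Kc[, sv, drop = FALSE]))
  }
  asLabelFactor(p)
}

#' @rdname trainBaseClassifier
#' @export
setMethod("cvAccuracy", "BaseClassifier", function(x) x@cvAccuracy)

setMethod("show", "BaseClassifier", function(object) {
  cat(sprintf("BaseClassifier '%s': CV accuracy %.3f; hyperparameters: %s\n",
              object@kind, object@cvAccuracy,
              paste(names(object@hyper), unlist(object@hyper), sep = "=",
                    collapse = ", ")))
  invisible(NULL)
})

#' Train the voting ensemble
#'
#' Trains the three base classifiers (PseDNC, motif, gkm) on the same
#' labeled windows — mining the motif vocabulary from those windows only —
#' and combines them with non-negative voting weights summing to 1:
#' uniform (1/3 each; the default, matching the three-voter majority
#' analysis) or proportional to each classifier's cross-validated accuracy.
#'
#' @param windows a labeled \linkS4class{SiteWindowSet}.
#' @param psedncConfig a \linkS4class{PseDncConfig}.
#' @param gkmParams a \linkS4class{GkmParams}.
#' @param motifMinLen,motifMaxLen,motifMinimalOnly vocabulary bounds passed
#'   to \code{\link{mineDiscriminativeSubstrings}}.
#' @param weighting \code{"uniform"} or \code{"cv_accuracy"}.
#' @param seed master seed; all training randomness derives from it.
#' @param costGrid,gammaGrid,cvFolds hyperparameter search settings (see
#'   \code{\link{trainBaseClassifier}}).
#' @param gkmKernelTrain optional precomputed normalized gkm Gram matrix of
#'   \code{windows}.
#' @return an \linkS4class{EnsembleModel}.
#' @examples
#' \donttest{
#' ds <- syntheticWindows(25, 25, seed = 7)
#' mod <- trainEnsemble(ds, seed = 7, cvFolds = 5)
#' votingWeights(mod)
#' }
#' @export
trainEnsemble <- function(windows, psedncConfig = PseDncConfig(),
                          gkmParams = GkmParams(), motifMinLen = 4L,
                          motifMaxLen = 12L, motifMinimalOnly = TRUE,
                          weighting = c("uniform", "cv_accuracy"), seed = 1L,
                          costGrid = defaultCostGrid(),
                          gammaGrid = defaultGammaGrid(), cvFolds = 10L,
                          gkmKernelTrain = NULL) {
  weighting <- match.arg(weighting)
  labels <- asLabelFactor(windowLabels(windows))
  seqs <- as.character(windows)
  vocab <- mineDiscriminativeSubstrings(seqs[labels == LABEL_POS],
                                        seqs[labels == LABEL_NEG],
                                        minLen = motifMinLen,
                                        maxLen = motifMaxLen,
                                        minimalOnly = motifMinimalOnly)
  clfs <- list(
    psednc = trainBaseClassifier(windows, "psednc", psedncConfig, seed,
                                 costGrid, gammaGrid, cvFolds),
    motif = trainBaseClassifier(windows, "motif", vocab, seed,
                                costGrid, gammaGrid, cvFolds),
    gkm = trainBaseClassifier(windows, "gkm", gkmParams, seed,
                              costGrid, gammaGrid, cvFolds,
                              gkmKernelTrain = gkmKernelTrain))
  w <- if (weighting == "uniform") rep(1 / 3, 3) else {
    a <- vapply(clfs, cvAccuracy, numeric(1))
    if (sum(a) == 0) rep(1 / 3, 3) else a / sum(a)
  }
  names(w) <- names(clfs)
  new("EnsembleModel", classifiers = clfs, weights = w,
      tieBreak = "max-weight",
      meta = list(package = "ramESVM",
                  version = as.character(utils::packageVersion("ramESVM")),
                  archiveVersion = 1L, seed = as.integer(seed),
                  weighting = weighting,
                  fingerprint = datasetFingerprint(seqs, labels)))
}

#' @rdname EnsembleModel
#' @export
setMethod("votingWeights", "EnsembleModel", function(x) x@weights)

#' @rdname EnsembleModel
#' @export
setMethod("cvAccuracy", "EnsembleModel",
          function(x) vapply(x@classifiers, cvAccuracy, numeric(1)))

setMethod("show", "EnsembleModel", function(object) {
  cat("EnsembleModel (3 SVM voters)\n")
  for (nm in names(object@classifiers))
    cat(sprintf("  %-6s weight %.3f, CV accuracy %.3f\n", nm,
                object@weights[nm], cvAccuracy(object@classifiers[[nm]])))
  cat(sprintf("  weighting: %s; tie-break: %s; seed: %d\n",
              object@meta$weighting, object@tieBreak, object@meta$seed))
  invisible(NULL)
})

#' Weighted vote of the three base classifiers
#'
#' The voting score for class i is \eqn{V_i = \sum_k w_k f(pre(C_k),
#' Class_i)} with f = 1 on agreement and 0 otherwise; the final call is the
#' argmax. An exact tie (possible only with non-uniform weights) follows the
#' label of the largest-weight classifier (the first such, in argument
#' order).
#'
#' @param labels character or factor of the 3 per-classifier labels
#'   (\code{"m6A"} / \code{"non-m6A"}).
#' @param weights 3 non-negative reals summing to 1 (default uniform, i.e.
#'   simple majority).
#' @param tieBreak tie-break rule (only \code{"max-weight"}).
#' @return list with \code{label}, \code{V_m6A}, \code{V_non_m6A}.
#' @examples
#' vote(c("m6A", "m6A", "non-m6A"))
#' @export
vote <- function(labels, weights = rep(1 / 3, 3), tieBreak = "max-weight") {
  labels <- as.character(labels)
  stopifnot(length(labels) == 3L, length(weights) == 3L,
            all(weights >= 0), abs(sum(weights) - 1) < 1e-9,
            tieBreak == "max-weight")
  vPos <- sum(weights[labels == LABEL_POS])
  vNeg <- sum(weights[labels == LABEL_NEG])
  lab <- if (vPos > vNeg) LABEL_POS
         else if (vNeg > vPos) LABEL_NEG
         else labels[which.max(weights)]
  list(label = lab, V_m6A = vPos, V_non_m6A = vNeg)
}

#' Score windows with a trained ensemble
#'
#' Each window is encoded by every base classifier's stored encoder (PseDNC
#' table and config, motif vocabulary, gkm cross kernel against the training
#' windows) and the three labels are combined by \code{\link{vote}}.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param windows a \linkS4class{SiteWindowSet} (labels, if any, are
#'   ignored).
#' @param gkmKernelCross optional precomputed normalized cross kernel
#'   (rows: \code{windows}, columns: the gkm classifier's training windows).
#' @return data.frame with one row per window: \code{transcript_id},
#'   \code{center_pos}, per-classifier labels \code{psednc}, \code{motif},
#'   \code{gkm}, voting scores \code{V_m6A}, \code{V_non_m6A} and the final
#'   \code{predicted} label.
#' @export
predictSites <- function(model, windows, gkmKernelCross = NULL) {
  stopifnot(is(model, "EnsembleModel"))
  kinds <- vapply(model@classifiers, function(x) x@kind, character(1))
  base <- lapply(seq_along(model@classifiers), function(i) {
    as.character(predictBaseClassifier(model@classifiers[[i]], windows,
      gkmKernelCross = if (kinds[i] == "gkm") gkmKernelCross else NULL))
  })
  names(base) <- kinds
  w <- model@weights[order(match(kinds, c("psednc", "motif", "gkm")))]
  n <- length(windows)
  votes <- lapply(seq_len(n), function(i)
    vote(c(base$psednc[i], base$motif[i], base$gkm[i]), w, model@tieBreak))
  data.frame(
    transcript_id = transcriptId(windows),
    center_pos = centerPos(windows),
    predicted = vapply(votes, `[[`, "", "label"),
    V_m6A = vapply(votes, `[[`, 0, "V_m6A"),
    V_non_m6A = vapply(votes, `[[`, 0, "V_non_m6A"),
    psednc = base$psednc, motif = base$motif, gkm = base$gkm,
    stringsAsFactors = FALSE)
}

#' @rdname predictSites
#' @param object an \linkS4class{EnsembleModel}.
#' @param ... passed through to \code{predictSites}.
#' @export
setMethod("predict", "EnsembleModel",
          function(object, windows, ...) predictSites(object, windows, ...))

#' Save / load an ensemble model archive
#'
#' A single self-contained, version-stamped archive holding the property
#' table, PseDNC config, motif vocabulary, gkm parameters, all learned
#' decision states, the voting weights and the training-set fingerprint.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param path archive path.
#' @return \code{saveEnsembleModel}: invisibly, \code{path};
#'   \code{loadEnsembleModel}: the restored \linkS4class{EnsembleModel}.
#' @export
saveEnsembleModel <- function(model, path) {
  stopifnot(is(model, "EnsembleModel"))
  saveRDS(model, path, version = 3L)
  invisible(path)
}

#' @rdname saveEnsembleModel
#' @export
loadEnsembleModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "EnsembleModel"))
    stop("input-format error: not an ensemble model archive: ", path,
         call. = FALSE)
  if (is.null(model@meta$archiveVersion) || model@meta$archiveVersion > 1L)
    stop("input-format error: unsupported archive version", call. = FALSE)
  validObject(model)
  model
}
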
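#' SiteWindowSet: candidate m6A windows
#'
#' A set of fixed-width RNA windows, each centered on an adenosine, stored as
#' an \link[Biostrings]{RNAStringSet} with per-window metadata columns
#' \code{transcriptId}, \code{centerPos} (1-based position of the central A on
#' the source transcript) and \code{label} (\code{"m6A"}, \code{"non-m6A"} or
#' \code{NA} when unlabeled). All windows share an odd width (51 by default)
#' and carry \code{A} at the central offset \code{(width+1)/2}.
#'
#' @slot windowLen common window width (odd integer).
#' @exportClass SiteWindowSet
setClass("SiteWindowSet",
  contains = "RNAStringSet",
  representation(windowLen = "integer")
)

setValidity("SiteWindowSet", function(object) {
  n <- length(object)
  wl <- object@windowLen
  if (length(wl) != 1L || is.na(wl) || wl < 1L || wl %% 2L == 0L)
    return("windowLen must be a single odd positive integer")
  if (n == 0L) return(TRUE)
  if (!all(Biostrings::width(object) == wl))
    return(sprintf("all windows must have width %d", wl))
  mc <- S4Vectors::mcols(object)
  need <- c("transcriptId", "centerPos", "label")
  if (is.null(mc) || !all(need %in% colnames(mc)))
    return("metadata columns transcriptId, centerPos, label are required")
  ctr <- (wl + 1L) %/% 2L
  mid <- substr(as.character(object), ctr, ctr)
  if (!all(mid == "A"))
    return(sprintf("window(s) %s lack A at the central offset %d",
                   paste(utils::head(which(mid != "A"), 5L), collapse = ","), ctr))
  lab <- mc$label
  if (!all(is.na(lab) | lab %in% LABEL_LEVELS))
    return(sprintf("labels must be NA, '%s' or '%s'", LABEL_POS, LABEL_NEG))
  TRUE
})

#' PropertyTable: dinucleotide physicochemical properties
#'
#' Enthalpy (kcal/mol), entropy (cal/(mol K)) and free energy (kcal/mol) for
#' the 16 RNA dinucleotides, raw or standardized (each property column
#' centered by its mean and scaled by its standard deviation over the 16
#' dinucleotides). These three properties quantify RNA secondary-structure
#' stability, whose formation antagonizes m6A deposition.
#'
#' @slot values 16 x v numeric matrix, rows named AA..UU in lexicographic
#'   order, columns named by property.
#' @slot standardized logical flag.
#' @exportClass PropertyTable
setClass("PropertyTable",
  representation(values = "matrix", standardized = "logical")
)

setValidity("PropertyTable", function(object) {
  v <- object@values
  if (!is.numeric(v) || nrow(v) != 16L)
    return("values must be a numeric matrix with 16 rows")
  if (!identical(rownames(v), DINUCLEOTIDES))
    return("rownames must be the 16 dinucleotides AA..UU in lexicographic order")
  if (ncol(v) < 1L || is.null(colnames(v)))
    return("values needs at least one named property column")
  if (anyNA(v)) return("values must not contain NA")
  if (isTRUE(object@standardized)) {
    mu <- colMeans(v)
    sdev <- apply(v, 2L, stats::sd)
    if (any(abs(mu) > 1e-9) || any(abs(sdev - 1) > 1e-9))
      return("standardized table must have column means 0 and SDs 1 (tol 1e-9)")
  }
  TRUE
})

#' PseDncConfig: pseudo dinucleotide composition parameters
#'
#' @slot lambda number of correlation tiers (default 6).
#' @slot w weight factor in [0, 1] (default 0.9).
#' @slot countingMode \code{"overlapping"} (all adjacent pairs; the
#'   established PseDNC convention and the default) or
#'   \code{"nonoverlapping"} (pairs 1-2, 3-4, ...).
#' @exportClass PseDncConfig
setClass("PseDncConfig",
  representation(lambda = "integer", w = "numeric", countingMode = "character")
)

setValidity("PseDncConfig", function(object) {
  if (length(object@lambda) != 1L || is.na(object@lambda) || object@lambda < 0L)
    return("lambda must be a single non-negative integer")
  if (length(object@w) != 1L || is.na(object@w) || object@w < 0 || object@w > 1)
    return("w must be a single number in [0, 1]")
  if (!object@countingMode %in% c("overlapping", "nonoverlapping"))
    return("countingMode must be 'overlapping' or 'nonoverlapping'")
  TRUE
})

#' MotifVocabulary: class-discriminative substrings
#'
#' Substrings (length within \code{[minLen, maxLen]}) occurring in training
#' sequences of exactly one class. Entries are sorted by (length,
#' lexicographic) so identical inputs always give byte-identical
#' vocabularies.
#'
#' @slot entries data.frame with columns \code{substring} and \code{side}
#'   (\code{"positive_only"} or \code{"negative_only"}).
#' @slot minLen,maxLen inclusive length bounds (defaults 4 and 12).
#' @slot minimalOnly whether entries whose proper substring (within bounds)
#'   is already in the vocabulary on the same side were dropped.
#' @exportClass MotifVocabulary
setClass("MotifVocabulary",
  representation(entries = "data.frame", minLen = "integer",
                 maxLen = "integer", minimalOnly = "logical")
)

setValidity("MotifVocabulary", function(object) {
  e <- object@entries
  if (!all(c("substring", "side") %in% colnames(e)))
    return("entries needs columns substring, side")
  if (nrow(e)) {
    if (!all(e$side %in% c("positive_only", "negative_only")))
      return("side must be positive_only or negative_only")
    len <- nchar(e$substring)
    if (any(len < object@minLen | len > object@maxLen))
      return("substring lengths must lie in [minLen, maxLen]")
    o <- order(len, e$substring)
    if (!identical(o, seq_len(nrow(e))))
      return("entries must be sorted by (length, lexicographic)")
  }
  if (object@minLen < 1L || object@maxLen < object@minLen)
    return("config error: need 1 <= minLen <= maxLen")
  TRUE
})

#' GkmParams: gapped k-mer kernel parameters
#'
#' @slot l word length (default 10).
#' @slot k number of informative (non-wildcard) positions (default 6).
#' @exportClass GkmParams
setClass("GkmParams", representation(l = "integer", k = "integer"))

setValidity("GkmParams", function(object) {
  if (length(object@l) != 1L || length(object@k) != 1L)
    return("l and k must be single integers")
  if (object@k < 1L || object@k > object@l || object@l > 51L)
    return("need 1 <= k <= l <= 51")
  TRUE
})

#' BaseClassifier: one trained SVM voter
#'
#' One of the three ensemble members: a soft-margin SVM over PseDNC vectors
#' (radial kernel), Boolean motif vectors (linear kernel) or the precomputed
#' normalized gapped k-mer string kernel. The object carries everything
#' needed to encode and score new windows.
#'
#' @slot kind \code{"psednc"}, \code{"motif"} or \code{"gkm"}.
#' @slot encoder kind-specific encoding state (property table + config,
#'   motif vocabulary, or gkm parameters + training count matrix).
#' @slot fit fitted SVM object (\pkg{e1071} or \pkg{kernlab}).
#' @slot hyper selected hyperparameters (named list).
#' @slot cvAccuracy 10-fold cross-validated accuracy on the training fold.
#' @exportClass BaseClassifier
setClass("BaseClassifier",
  representation(kind = "character", encoder = "list", fit = "ANY",
                 hyper = "list", cvAccuracy = "numeric")
)

setValidity("BaseClassifier", function(object) {
  if (!object@kind %in% c("psednc", "motif", "gkm"))
    return("kind must be psednc, motif or gkm")
  if (length(object@cvAccuracy) != 1L || is.na(object@cvAccuracy) ||
      object@cvAccuracy < 0 || object@cvAccuracy > 1)
    return("cvAccuracy must be in [0, 1]")
  TRUE
})

#' EnsembleModel: three voters plus voting weights
#'
#' @slot classifiers named list of the three \linkS4class{BaseClassifier}
#'   objects (psednc, motif, gkm).
#' @slot weights non-negative voting weights summing to 1, one per
#'   classifier.
#' @slot tieBreak tie-break rule; \code{"max-weight"} follows the label of
#'   the largest-weight classifier (first such, in stored order).
#' @slot meta provenance: package version, seed, weighting policy and
#'   training-set fingerprint.
#' @exportClass EnsembleModel
setClass("EnsembleModel",
  representation(classifiers = "list", weights = "numeric",
                 tieBreak = "character", meta = "list")
)

setValidity("EnsembleModel", function(object) {
  if (length(object@classifiers) != 3L)
    return("exactly 3 base classifiers required")
  kinds <- unname(vapply(object@classifiers, function(x) x@kind, character(1)))
  if (!identical(sort(kinds), c("gkm", "motif", "psednc")))
    return("classifiers must be one each of psednc, motif, gkm")
  w <- object@weights
  if (length(w) != 3L || any(w < 0) || abs(sum(w) - 1) > 1e-9)
    return("weights must be 3 non-negative reals summing to 1")
  if (!object@tieBreak %in% c("max-weight"))
    return("unknown tieBreak rule")
  TRUE
})
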
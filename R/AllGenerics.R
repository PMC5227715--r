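#' @rdname SiteWindowSet
#' @param object,x a \linkS4class{SiteWindowSet}.
#' @export
setGeneric("transcriptId", function(x) standardGeneric("transcriptId"))

#' @rdname SiteWindowSet
#' @export
setGeneric("centerPos", function(x) standardGeneric("centerPos"))

#' @rdname SiteWindowSet
#' @export
setGeneric("windowLabels", function(x) standardGeneric("windowLabels"))

#' @rdname SiteWindowSet
#' @param value replacement labels (character or factor; \code{NA} allowed).
#' @export
setGeneric("windowLabels<-", function(x, value) standardGeneric("windowLabels<-"))

#' @rdname SiteWindowSet
#' @export
setGeneric("windowLen", function(x) standardGeneric("windowLen"))

#' @rdname BaseClassifier
#' @param x a trained classifier or ensemble.
#' @export
setGeneric("cvAccuracy", function(x) standardGeneric("cvAccuracy"))

#' @rdname EnsembleModel
#' @param x an \linkS4class{EnsembleModel}.
#' @export
setGeneric("votingWeights", function(x) standardGeneric("votingWeights"))
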
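# Discriminative substring (motif) features: substrings of length >= minLen
# occurring in training sequences of exactly one class, encoded as Boolean
# presence vectors.

# All distinct substrings of a given length across a set of sequences.
substringSet <- function(seqs, len) {
  out <- unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < len) return(character(0))
    substring(s, seq_len(L - len + 1L), seq_len(L - len + 1L) + len - 1L)
  }), use.names = FALSE)
  unique(out)
}

#' Mine class-discriminative substrings
#'
#' Enumerates every substring with length in \code{[minLen, maxLen]} that
#' occurs in at least one sequence of exactly one class (the other class
#' containing it nowhere), equivalent to a brute-force all-substrings set
#' difference. With \code{minimalOnly} (the default) a substring is dropped
#' when a proper substring of it, within the length bounds, is already in
#' the vocabulary on the same side; this controls dimensionality because on
#' the training data a superstring's presence implies its substring's
#' presence.
#'
#' @param positives,negatives character vectors of training residues (both
#'   non-empty). Mining must only ever see the training fold; the resulting
#'   vocabulary is passed explicitly to \code{\link{encodeMotifs}}.
#' @param minLen minimum substring length (default 4).
#' @param maxLen maximum substring length (default 12; set to the window
#'   length for the uncapped reading).
#' @param minimalOnly apply the minimality filter (default TRUE).
#' @return a \linkS4class{MotifVocabulary}, entries sorted by (length,
#'   lexicographic) so identical inputs give byte-identical vocabularies.
#' @examples
#' v <- mineDiscriminativeSubstrings("ACGUA", "ACGGA", minLen = 4)
#' motifEntries(v)
#' @export
mineDiscriminativeSubstrings <- function(positives, negatives, minLen = 4L,
                                         maxLen = 12L, minimalOnly = TRUE) {
  if (length(positives) == 0L || length(negatives) == 0L)
    stop("both classes must contribute at least one training sequence",
         call. = FALSE)
  minLen <- as.integer(minLen); maxLen <- as.integer(maxLen)
  if (minLen < 1L || maxLen < minLen)
    stop("config error: need 1 <= minLen <= maxLen", call. = FALSE)
  subsChar <- character(0); sideChar <- character(0)
  # exclusive substrings of the previous length, per side, for the
  # minimality shortcut: a candidate has a retained proper substring iff one
  # of its two (len-1)-substrings was exclusive on the same side.
  prevPos <- character(0); prevNeg <- character(0)
  for (len in seq.int(minLen, maxLen)) {
    ps <- substringSet(positives, len)
    ns <- substringSet(negatives, len)
    posOnly <- sort(setdiff(ps, ns))
    negOnly <- sort(setdiff(ns, ps))
    keepPos <- posOnly; keepNeg <- negOnly
    if (minimalOnly && len > minLen) {
      hasMinimal <- function(x, prev) {
        if (!length(x) || !length(prev)) return(rep(FALSE, length(x)))
        substr(x, 1L, len - 1L) %in% prev | substr(x, 2L, len) %in% prev
      }
      keepPos <- posOnly[!hasMinimal(posOnly, prevPos)]
      keepNeg <- negOnly[!hasMinimal(negOnly, prevNeg)]
    }
    subsChar <- c(subsChar, keepPos, keepNeg)
    sideChar <- c(sideChar, rep("positive_only", length(keepPos)),
                  rep("negative_only", length(keepNeg)))
    prevPos <- posOnly; prevNeg <- negOnly
  }
  entries <- data.frame(substring = subsChar, side = sideChar,
                        stringsAsFactors = FALSE)
  o <- order(nchar(entries$substring), entries$substring)
  entries <- entries[o, , drop = FALSE]
  rownames(entries) <- NULL
  new("MotifVocabulary", entries = entries, minLen = minLen, maxLen = maxLen,
      minimalOnly = minimalOnly)
}

#' @rdname mineDiscriminativeSubstrings
#' @param vocab a \linkS4class{MotifVocabulary}.
#' @return \code{motifEntries}: the entries data.frame.
#' @export
motifEntries <- function(vocab) vocab@entries

setMethod("show", "MotifVocabulary", function(object) {
  e <- object@entries
  cat(sprintf("MotifVocabulary: %d entries (%d positive_only, %d negative_only), lengths %d-%d%s\n",
              nrow(e), sum(e$side == "positive_only"),
              sum(e$side == "negative_only"), object@minLen, object@maxLen,
              if (object@minimalOnly) ", minimal-only" else ""))
  if (nrow(e)) print(utils::head(e, 5L))
  invisible(NULL)
})

#' Boolean motif encoding
#'
#' Component i is 1 iff the i-th vocabulary substring occurs anywhere in the
#' sequence, else 0.
#'
#' @param seq residues (character scalar).
#' @param vocab a \linkS4class{MotifVocabulary}.
#' @return integer 0/1 vector of length \code{nrow(motifEntries(vocab))},
#'   named by substring.
#' @export
encodeMotifs <- function(seq, vocab) {
  encodeMotifMatrix(seq, vocab)[1L, ]
}

#' @rdname encodeMotifs
#' @param seqs character vector, \link[Biostrings]{RNAStringSet} or
#'   \linkS4class{SiteWindowSet}.
#' @return \code{encodeMotifMatrix}: 0/1 integer matrix, one row per
#'   sequence.
#' @export
encodeMotifMatrix <- function(seqs, vocab) {
  stopifnot(is(vocab, "MotifVocabulary"))
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  seqs <- unname(seqs)
  subs <- vocab@entries$substring
  m <- matrix(0L, nrow = length(seqs), ncol = length(subs),
              dimnames = list(NULL, subs))
  for (j in seq_along(subs))
    m[, j] <- as.integer(grepl(subs[j], seqs, fixed = TRUE))
  m
}

#' Read / write a motif vocabulary as tab-delimited text
#'
#' @param vocab a \linkS4class{MotifVocabulary}.
#' @param path file path; format: header plus one \code{substring <tab>
#'   side} row per entry, with the bounds and minimality flag on comment
#'   lines.
#' @return \code{writeMotifVocabulary}: invisibly, \code{path};
#'   \code{readMotifVocabulary}: the \linkS4class{MotifVocabulary}.
#' @export
writeMotifVocabulary <- function(vocab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# minLen=%d maxLen=%d minimalOnly=%s",
                     vocab@minLen, vocab@maxLen, vocab@minimalOnly), con)
  utils::write.table(vocab@entries, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeMotifVocabulary
#' @export
readMotifVocabulary <- function(path) {
  hdr <- readLines(path, n = 1L)
  pars <- regmatches(hdr, gregexpr("[A-Za-z]+=[^ ]+", hdr))[[1L]]
  kv <- strsplit(pars, "=", fixed = TRUE)
  opts <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  entries <- utils::read.delim(path, comment.char = "#",
                               stringsAsFactors = FALSE,
                               colClasses = c("character", "character"))
  new("MotifVocabulary", entries = entries,
      minLen = as.integer(opts[["minLen"]]),
      maxLen = as.integer(opts[["maxLen"]]),
      minimalOnly = as.logical(opts[["minimalOnly"]]))
}
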
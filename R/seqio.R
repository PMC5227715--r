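#' Read RNA sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped) FASTA file and normalizes each record to
#' the RNA alphabet: lowercase is folded to uppercase and \code{T} is mapped
#' to \code{U}. Record order is preserved and each id is the header token up
#' to the first whitespace.
#'
#' @param path path to an existing, non-empty FASTA file.
#' @return an \link[Biostrings]{RNAStringSet}, one element per record.
#' @details Degenerate IUPAC codes (e.g. \code{N}) are rejected with an error
#'   naming the record id and offset, rather than being resampled, so that
#'   downstream feature vectors stay well defined.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "acgt"), tf)
#' readRnaFasta(tf)
#' @export
readRnaFasta <- function(path) {
  if (!file.exists(path)) stop("input-format error: no such file: ", path, call. = FALSE)
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("input-format error: malformed FASTA (",
                                           conditionMessage(e), ")", call. = FALSE))
  if (length(raw) == 0L)
    stop("input-format error: FASTA file has no records: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(raw))
  chars <- as.character(raw)
  empty <- which(nchar(chars) == 0L | is.na(ids) | ids == "")
  if (length(empty))
    stop("input-format error: record ", empty[1L],
         " has no header token or no residues", call. = FALSE)
  chars <- normalizeResidues(unname(chars), ids)
  out <- Biostrings::RNAStringSet(chars)
  names(out) <- ids
  out
}

#' Write RNA sequences to a FASTA file
#'
#' @param seqs an \link[Biostrings]{RNAStringSet} (or named character vector).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeRnaFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::RNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Construct a SiteWindowSet
#'
#' @param seqs window sequences: character vector or
#'   \link[Biostrings]{RNAStringSet}; \code{T} is mapped to \code{U}.
#' @param transcriptId source transcript ids (recycled if length 1).
#' @param centerPos 1-based position of the central adenosine on the source
#'   transcript (defaults to the central window offset).
#' @param label \code{"m6A"}, \code{"non-m6A"} or \code{NA}, per window.
#' @param windowLen common odd window width; inferred from the sequences
#'   when missing.
#' @return a \linkS4class{SiteWindowSet}.
#' @examples
#' w <- SiteWindowSet(paste0(strrep("C", 25), "A", strrep("G", 25)),
#'                    transcriptId = "t1", label = "m6A")
#' windowLabels(w)
#' @export
SiteWindowSet <- function(seqs, transcriptId = NA_character_,
                          centerPos = NA_integer_, label = NA_character_,
                          windowLen = NULL) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  seqs <- normalizeResidues(unname(seqs))
  n <- length(seqs)
  if (is.null(windowLen)) {
    windowLen <- if (n) nchar(seqs[1L]) else 51L
  }
  windowLen <- as.integer(windowLen)
  if (is.na(centerPos[1L]) && length(centerPos) == 1L)
    centerPos <- rep((windowLen + 1L) %/% 2L, n)
  rss <- Biostrings::RNAStringSet(seqs)
  S4Vectors::mcols(rss) <- S4Vectors::DataFrame(
    transcriptId = rep_len(as.character(transcriptId), n),
    centerPos = rep_len(as.integer(centerPos), n),
    label = rep_len(as.character(label), n))
  new("SiteWindowSet", rss, windowLen = windowLen)
}

#' @rdname SiteWindowSet
#' @export
setMethod("transcriptId", "SiteWindowSet",
          function(x) S4Vectors::mcols(x)$transcriptId)

#' @rdname SiteWindowSet
#' @export
setMethod("centerPos", "SiteWindowSet",
          function(x) S4Vectors::mcols(x)$centerPos)

#' @rdname SiteWindowSet
#' @export
setMethod("windowLabels", "SiteWindowSet",
          function(x) S4Vectors::mcols(x)$label)

#' @rdname SiteWindowSet
#' @export
setReplaceMethod("windowLabels", "SiteWindowSet", function(x, value) {
  S4Vectors::mcols(x)$label <- rep_len(as.character(value), length(x))
  validObject(x)
  x
})

#' @rdname SiteWindowSet
#' @export
setMethod("windowLen", "SiteWindowSet", function(x) x@windowLen)

setMethod("show", "SiteWindowSet", function(object) {
  lab <- windowLabels(object)
  cat(sprintf("SiteWindowSet of %d window(s), width %d (central A at offset %d)\n",
              length(object), object@windowLen, (object@windowLen + 1L) %/% 2L))
  cat(sprintf("  labels: %d %s, %d %s, %d unlabeled\n",
              sum(lab %in% LABEL_POS), LABEL_POS,
              sum(lab %in% LABEL_NEG), LABEL_NEG, sum(is.na(lab))))
  if (length(object)) {
    k <- min(3L, length(object))
    for (i in seq_len(k))
      cat(sprintf("  [%d] %s @%d %s\n", i, transcriptId(object)[i],
                  centerPos(object)[i], as.character(object[[i]])))
    if (length(object) > k) cat("  ...\n")
  }
  invisible(NULL)
})

#' Extract candidate windows around every eligible adenosine
#'
#' Scans each transcript for adenosines with at least \code{(windowLen-1)/2}
#' residues on each side and returns one unlabeled window per eligible A,
#' ordered by transcript then center position (1-based, forward strand; m6A
#' is a single-stranded transcript mark, so no reverse-complement scanning
#' is performed).
#'
#' @param seqs an \link[Biostrings]{RNAStringSet} (e.g. from
#'   \code{\link{readRnaFasta}}), or a single character string.
#' @param windowLen odd window width (default 51).
#' @return a \linkS4class{SiteWindowSet}; empty when no adenosine is
#'   eligible.
#' @examples
#' s <- Biostrings::RNAStringSet(c(t1 = "CCCACCCCCCC"))
#' extractWindows(s, windowLen = 5)
#' @export
extractWindows <- function(seqs, windowLen = 51L) {
  windowLen <- as.integer(windowLen)
  if (windowLen < 1L || windowLen %% 2L == 0L)
    stop("config error: windowLen must be odd and positive", call. = FALSE)
  if (is.character(seqs)) seqs <- Biostrings::RNAStringSet(normalizeResidues(seqs))
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  flank <- (windowLen - 1L) %/% 2L
  outSeq <- character(0); outId <- character(0); outPos <- integer(0)
  for (i in seq_along(seqs)) {
    s <- as.character(seqs[[i]])
    L <- nchar(s)
    if (L < windowLen) next
    aPos <- which(strsplit(s, "", fixed = TRUE)[[1L]] == "A")
    aPos <- aPos[aPos > flank & aPos <= L - flank]
    if (!length(aPos)) next
    outSeq <- c(outSeq, substring(s, aPos - flank, aPos + flank))
    outId <- c(outId, rep(ids[i], length(aPos)))
    outPos <- c(outPos, aPos)
  }
  SiteWindowSet(outSeq, transcriptId = outId, centerPos = outPos,
                windowLen = windowLen)
}

#' Write / read a tab-delimited site report
#'
#' One row per scored window with the transcript id, center position,
#' final ensemble call, both voting scores and the three per-classifier
#' labels. \code{readSiteReport} parses the file back into the same
#' data.frame, so write-then-read is the identity.
#'
#' @param predictions a data.frame as returned by
#'   \code{\link{predictSites}} (columns \code{transcript_id},
#'   \code{center_pos}, \code{predicted}, \code{V_m6A}, \code{V_non_m6A},
#'   \code{psednc}, \code{motif}, \code{gkm}).
#' @param path output (input) path.
#' @return \code{writeSiteReport}: invisibly, \code{path};
#'   \code{readSiteReport}: the parsed data.frame.
#' @export
writeSiteReport <- function(predictions, path) {
  cols <- c("transcript_id", "center_pos", "predicted",
            "V_m6A", "V_non_m6A", "psednc", "motif", "gkm")
  if (is.null(predictions) || nrow(predictions) == 0L) {
    predictions <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  }
  missing <- setdiff(cols, colnames(predictions))
  if (length(missing))
    stop("site report is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  ok <- tryCatch({
    utils::write.table(predictions[, cols], path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write site report to ", path, call. = FALSE)
  invisible(path)
}

#' @rdname writeSiteReport
#' @export
readSiteReport <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(transcript_id = "character",
                                   center_pos = "integer",
                                   predicted = "character",
                                   V_m6A = "numeric", V_non_m6A = "numeric",
                                   psednc = "character", motif = "character",
                                   gkm = "character"))
}
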
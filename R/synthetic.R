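# Synthetic benchmark generator: balanced 51-nt A-centered windows with a
# plantable consensus motif, so every pipeline stage is testable without
# external data.

#' Generate a labeled synthetic window dataset
#'
#' Emulates the balanced benchmark design the method was built for:
#' \code{nPos} positive and \code{nNeg} negative windows of odd width
#' \code{windowLen}, every window carrying \code{A} at the central offset.
#' Background residues are drawn i.i.d. from \code{background}; each
#' positive additionally carries the consensus \code{motif} with
#' probability \code{plantProb}, shifted around the center by a jitter.
#'
#' The default motif \code{"GGACU"} is the canonical m6A methyltransferase
#' consensus context (its single A is the methylated adenosine); no
#' biological claim is attached to the default and it is fully overridable.
#' The shift is drawn uniformly from the shifts in \code{[-jitter, jitter]}
#' compatible with a central A — the motif's A sits on the center, or the
#' motif clears the center entirely — because a shifted consensus whose
#' non-A residue covered the center would break either the window invariant
#' or the planted motif.
#'
#' @param nPos,nNeg class sizes.
#' @param windowLen odd window width (default 51).
#' @param background nucleotide probabilities for A, C, G, U (default
#'   uniform; must sum to 1).
#' @param motif consensus string over A/C/G/U planted in positives; must
#'   contain an A (the first A is the center anchor).
#' @param plantProb probability that a positive carries the motif (default
#'   0.9).
#' @param jitter maximum shift of the motif around the center (default 3).
#' @param seed integer seed; identical seeds give byte-identical datasets.
#' @param strictNegatives resample any negative window that contains the
#'   motif by chance (default FALSE, mirroring real negative-sampling
#'   noise; set TRUE for separability tests).
#' @return a labeled \linkS4class{SiteWindowSet} (positives first), with
#'   transcript ids \code{pos1..} / \code{neg1..}.
#' @examples
#' ds <- syntheticWindows(5, 5, seed = 1)
#' table(windowLabels(ds))
#' @export
syntheticWindows <- function(nPos, nNeg, windowLen = 51L,
                             background = rep(0.25, 4), motif = "GGACU",
                             plantProb = 0.9, jitter = 3L, seed = 1L,
                             strictNegatives = FALSE) {
  windowLen <- as.integer(windowLen)
  if (windowLen < 1L || windowLen %% 2L == 0L)
    stop("config error: windowLen must be odd", call. = FALSE)
  if (abs(sum(background) - 1) > 1e-9 || any(background < 0))
    stop("config error: background probabilities must be >= 0 and sum to 1",
         call. = FALSE)
  motif <- normalizeResidues(motif)
  mLen <- nchar(motif)
  mChars <- strsplit(motif, "", fixed = TRUE)[[1L]]
  aOff <- which(mChars == "A")[1L]
  if (is.na(aOff))
    stop("config error: motif must contain an A to align to the center",
         call. = FALSE)
  ctr <- (windowLen + 1L) %/% 2L
  jitter <- as.integer(jitter)
  # admissible shifts: motif's A on the center, or motif clear of the center
  shifts <- (-jitter):jitter
  coversCenter <- shifts >= -(mLen - aOff) & shifts <= aOff - 1L
  aAtCenter <- coversCenter & mChars[pmin(pmax(aOff - shifts, 1L), mLen)] == "A"
  shifts <- shifts[aAtCenter | !coversCenter]
  starts <- ctr + shifts - (aOff - 1L)
  ok <- starts >= 1L & starts + mLen - 1L <= windowLen
  if (!all(ok))
    stop("config error: motif does not fit in the window at all allowed ",
         "offsets (windowLen ", windowLen, ", jitter ", jitter, ")",
         call. = FALSE)

  set.seed(seed)
  drawWindow <- function() {
    ch <- sample(RNA_BASES, windowLen, replace = TRUE, prob = background)
    ch[ctr] <- "A"
    ch
  }
  makePositive <- function() {
    ch <- drawWindow()
    if (stats::runif(1) < plantProb) {
      st <- starts[sample.int(length(starts), 1L)]
      ch[st:(st + mLen - 1L)] <- mChars
    }
    paste(ch, collapse = "")
  }
  makeNegative <- function() {
    repeat {
      s <- paste(drawWindow(), collapse = "")
      if (!strictNegatives || !grepl(motif, s, fixed = TRUE)) return(s)
    }
  }
  pos <- vapply(seq_len(nPos), function(i) makePositive(), character(1))
  neg <- vapply(seq_len(nNeg), function(i) makeNegative(), character(1))
  SiteWindowSet(c(pos, neg),
                transcriptId = c(paste0("pos", seq_len(nPos)),
                                 paste0("neg", seq_len(nNeg))),
                centerPos = ctr,
                label = c(rep(LABEL_POS, nPos), rep(LABEL_NEG, nNeg)),
                windowLen = windowLen)
}

#' Write a window set as paired FASTA files
#'
#' Emits the positives and negatives of a labeled window set to two FASTA
#' files (consumable by the command-line \code{train} and \code{evaluate}
#' subcommands), plus an optional sidecar text file echoing the generating
#' configuration for provenance.
#'
#' @param windows a labeled \linkS4class{SiteWindowSet}.
#' @param posPath,negPath output FASTA paths.
#' @param sidecar optional path for a \code{key = value} provenance file.
#' @param config named list echoed into the sidecar.
#' @return invisibly, \code{c(posPath, negPath)}.
#' @export
writePairedFasta <- function(windows, posPath, negPath, sidecar = NULL,
                             config = list()) {
  lab <- windowLabels(windows)
  if (anyNA(lab)) stop("all windows must be labeled", call. = FALSE)
  pos <- windows[lab == LABEL_POS]
  neg <- windows[lab == LABEL_NEG]
  outPos <- Biostrings::RNAStringSet(as.character(pos))
  names(outPos) <- transcriptId(pos)
  outNeg <- Biostrings::RNAStringSet(as.character(neg))
  names(outNeg) <- transcriptId(neg)
  Biostrings::writeXStringSet(outPos, posPath)
  Biostrings::writeXStringSet(outNeg, negPath)
  if (!is.null(sidecar))
    writeLines(paste(names(config), unlist(lapply(config, format)),
                     sep = " = "), sidecar)
  invisible(c(posPath, negPath))
}

#' Simulated base-classifier label streams
#'
#' For ensemble tests: stream k agrees with the truth independently with
#' probability \code{p[k]}.
#'
#' @param p numeric of length 3, accuracies strictly in (0.5, 1) (1.0 is
#'   additionally allowed here so perfectly faithful streams can be built).
#' @param truth character or factor of true labels.
#' @param seed integer seed.
#' @return character matrix, one column per classifier stream.
#' @export
stubVotes <- function(p, truth, seed = 1L) {
  p <- as.numeric(p)
  if (length(p) != 3L || any(p <= 0.5) || any(p > 1))
    stop("domain error: accuracies must lie in (0.5, 1]", call. = FALSE)
  truth <- as.character(asLabelFactor(truth))
  n <- length(truth)
  other <- ifelse(truth == LABEL_POS, LABEL_NEG, LABEL_POS)
  set.seed(seed)
  agree <- matrix(stats::runif(n * 3L), ncol = 3L) <
    matrix(p, nrow = n, ncol = 3L, byrow = TRUE)
  out <- matrix(rep(truth, 3L), ncol = 3L)
  out[!agree] <- rep(other, 3L)[!agree]
  colnames(out) <- paste0("classifier", 1:3)
  out
}
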
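# Independent brute-force oracles shared by the unit and acceptance tests.
# These deliberately avoid the package's own index structures: vocabulary
# mining is re-derived by full substring enumeration and the gkm kernel by
# the explicit count-vector inner product.

randomRnaSeq <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

randomRnaSeqs <- function(n, maxLen, minLen = 6) {
  vapply(seq_len(n), function(i) randomRnaSeq(sample(minLen:maxLen, 1)),
         character(1))
}

# all-substrings set difference with optional minimality filter, checking
# every proper substring against the retained set
oracleBruteVocabulary <- function(pos, neg, minLen, maxLen, minimalOnly) {
  allSubs <- function(seqs, len) {
    unique(unlist(lapply(seqs, function(s) {
      if (nchar(s) < len) return(character(0))
      vapply(seq_len(nchar(s) - len + 1L),
             function(i) substr(s, i, i + len - 1L), character(1))
    })))
  }
  entries <- data.frame(substring = character(0), side = character(0),
                        stringsAsFactors = FALSE)
  retained <- list(positive_only = character(0),
                   negative_only = character(0))
  for (len in minLen:maxLen) {
    ps <- allSubs(pos, len); ns <- allSubs(neg, len)
    for (side in c("positive_only", "negative_only")) {
      cand <- sort(if (side == "positive_only") setdiff(ps, ns)
                   else setdiff(ns, ps))
      if (minimalOnly && length(cand)) {
        keep <- vapply(cand, function(s) {
          for (sl in minLen:(len - 1L)) {
            if (sl >= len) next
            for (i in seq_len(len - sl + 1L)) {
              if (substr(s, i, i + sl - 1L) %in% retained[[side]])
                return(FALSE)
            }
          }
          TRUE
        }, logical(1))
        cand <- cand[keep]
      }
      if (length(cand))
        entries <- rbind(entries,
                         data.frame(substring = cand, side = side,
                                    stringsAsFactors = FALSE))
      retained[[side]] <- c(retained[[side]], cand)
    }
  }
  entries <- entries[order(nchar(entries$substring), entries$substring), ,
                     drop = FALSE]
  rownames(entries) <- NULL
  entries
}

# explicit gapped k-mer feature-space inner product
oracleCountInnerProduct <- function(a, b, params) {
  ca <- gappedKmerCounts(a, params)
  cb <- gappedKmerCounts(b, params)
  shared <- intersect(names(ca), names(cb))
  sum(as.numeric(ca[shared]) * as.numeric(cb[shared]))
}

# exhaustive 8-outcome enumeration of 3 independent voters
oracleVotingAccuracy <- function(p) {
  acc <- 0
  for (o1 in 0:1) for (o2 in 0:1) for (o3 in 0:1) {
    if (o1 + o2 + o3 >= 2) {
      acc <- acc + prod(ifelse(c(o1, o2, o3) == 1, p, 1 - p))
    }
  }
  acc
}
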
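# Shared constants and small helpers.

# Fixed lexicographic dinucleotide order (AA, AC, ..., UU); all feature
# vectors and property tables index dinucleotides in this order.
RNA_BASES <- c("A", "C", "G", "U")
DINUCLEOTIDES <- sort(as.vector(outer(RNA_BASES, RNA_BASES, paste0)))

# Canonical class labels: positive = m6A site, negative = non-m6A.
LABEL_POS <- "m6A"
LABEL_NEG <- "non-m6A"
LABEL_LEVELS <- c(LABEL_POS, LABEL_NEG)

asLabelFactor <- function(x) factor(as.character(x), levels = LABEL_LEVELS)

#' @noRd
normalizeResidues <- function(x, id = "<sequence>") {
  x <- chartr("acgut", "ACGUT", x)
  x <- chartr("T", "U", x)
  bad <- regexpr("[^ACGU]", x)
  off <- which(bad > 0L)
  if (length(off)) {
    stop(sprintf("alphabet error: sequence '%s' has a residue outside {A,C,G,U,T} at offset %d",
                 id[off[1L]], bad[off[1L]]), call. = FALSE)
  }
  x
}

# Deterministic sub-seed derivation: one master seed fans out to independent
# 31-bit sub-seeds for each randomized stage.
deriveSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% .Machine$integer.max)
}

# Stratified fold assignment: within each class, samples are shuffled under
# the seed and dealt round-robin into k folds.
stratifiedFolds <- function(labels, k, seed) {
  labels <- as.character(labels)
  n <- length(labels)
  if (k > n) stop("config error: k = ", k, " exceeds n = ", n, call. = FALSE)
  fold <- integer(n)
  set.seed(seed)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Fingerprint of a training set (sequences + labels), used to stamp models.
datasetFingerprint <- function(seqs, labels) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(seqs, as.character(labels), sep = "\t"), tf)
  unname(tools::md5sum(tf))
}
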
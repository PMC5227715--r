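# Gapped k-mer string kernel: each l-mer of a sequence contributes one
# count to each of its choose(l,k) gapped k-mers (k fixed letters, l-k
# wildcards at fixed positions); the kernel is the inner product of the two
# count vectors, computable in closed form from l-mer Hamming distances.

#' Gapped k-mer parameters
#'
#' @param l word length (default 10).
#' @param k number of informative, non-wildcard positions (default 6; the
#'   published defaults of the gkm-SVM family). Wildcards tolerate local
#'   mismatches, which is what lets the kernel see a shared consensus
#'   context through variable flanks.
#' @return a \linkS4class{GkmParams}.
#' @export
GkmParams <- function(l = 10L, k = 6L) {
  new("GkmParams", l = as.integer(l), k = as.integer(k))
}

# All choose(l,k) informative-position masks, as a k x C(l,k) matrix.
gkmMasks <- function(params) {
  utils::combn(params@l, params@k)
}

# Character matrix of all l-mers of a sequence: (L-l+1) x l.
lmerMatrix <- function(seq, l) {
  L <- nchar(seq)
  if (L < l)
    stop("too-short error: sequence length ", L, " < l = ", l, call. = FALSE)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- L - l + 1L
  matrix(ch[outer(seq_len(n), 0:(l - 1L), `+`)], nrow = n)
}

#' Gapped k-mer count vector
#'
#' Explicit feature map of the gkm kernel: every l-mer of the sequence
#' contributes one count to each of its \code{choose(l, k)} gapped k-mer
#' patterns, so the total count mass is \code{(L - l + 1) * choose(l, k)}.
#'
#' @param seq residues (length >= l).
#' @param params a \linkS4class{GkmParams}.
#' @return named integer vector of counts; names are the patterns with
#'   \code{"."} at wildcard positions (e.g. \code{"A."}).
#' @examples
#' gappedKmerCounts("AAAA", GkmParams(l = 2, k = 1))
#' @export
gappedKmerCounts <- function(seq, params = GkmParams()) {
  stopifnot(is(params, "GkmParams"))
  M <- lmerMatrix(seq, params@l)
  masks <- gkmMasks(params)
  pats <- character(0)
  for (m in seq_len(ncol(masks))) {
    P <- matrix(".", nrow = nrow(M), ncol = params@l)
    P[, masks[, m]] <- M[, masks[, m]]
    pats <- c(pats, apply(P, 1L, paste, collapse = ""))
  }
  tab <- table(pats)
  setNames(as.integer(tab), names(tab))
}

# Sparse count representation for a set of sequences: a list with the
# n x P pattern-count sparse matrix F, the pattern keys, and the per-sequence
# self kernels diag(F F^T). A pattern is keyed by (mask index, base-4 code
# of the k informative letters) packed into one number; only inner products
# ever use the keys, so no printable pattern strings are built here.
gkmCountMatrix <- function(seqs, params) {
  stopifnot(is(params, "GkmParams"))
  l <- params@l; k <- params@k
  short <- which(nchar(seqs) < l)
  if (length(short))
    stop("too-short error: sequence index ", short[1L], " has length ",
         nchar(seqs)[short[1L]], " < l = ", l, call. = FALSE)
  masks <- gkmMasks(params)
  nl <- nchar(seqs) - l + 1L
  seqIdx <- rep.int(seq_along(seqs), nl)
  Mall <- do.call(rbind, lapply(seqs, lmerMatrix, l = l))
  Mnum <- matrix(match(Mall, RNA_BASES) - 1L, nrow = nrow(Mall))
  pow <- 4^(0:(k - 1L))
  keys <- vector("list", ncol(masks))
  for (m in seq_len(ncol(masks))) {
    keys[[m]] <- as.vector(Mnum[, masks[, m], drop = FALSE] %*% pow) +
      (m - 1L) * 4^k
  }
  keys <- unlist(keys, use.names = FALSE)
  patterns <- sort(unique(keys))
  F <- Matrix::sparseMatrix(i = rep.int(seqIdx, ncol(masks)),
                            j = match(keys, patterns), x = 1,
                            dims = c(length(seqs), length(patterns)))
  list(F = F, patterns = patterns, self = Matrix::rowSums(F^2))
}

#' Gapped k-mer kernel between two sequences
#'
#' Closed form: summing over all l-mer pairs (u in a, v in b),
#' \code{choose(l - m(u, v), k)} where m is the pair's Hamming distance
#' (zero contribution when \code{m > l - k}). This equals the inner product
#' of the two explicit gapped k-mer count vectors exactly and is always a
#' non-negative integer.
#'
#' @param a,b residues (each of length >= l).
#' @param params a \linkS4class{GkmParams}.
#' @return a single non-negative number; symmetric in its arguments.
#' @examples
#' gkmKernel("AC", "AG", GkmParams(l = 2, k = 1))  # 1
#' @export
gkmKernel <- function(a, b, params = GkmParams()) {
  stopifnot(is(params, "GkmParams"))
  l <- params@l; k <- params@k
  A <- lmerMatrix(a, l); B <- lmerMatrix(b, l)
  mism <- matrix(0L, nrow(A), nrow(B))
  for (j in seq_len(l))
    mism <- mism + outer(A[, j], B[, j], `!=`)
  contrib <- choose(l - mism, k)
  contrib[mism > l - k] <- 0
  sum(contrib)
}

#' Gapped k-mer kernel matrix
#'
#' Gram matrix of \code{\link{gkmKernel}} over a set of sequences, computed
#' through the sparse count-vector representation. With
#' \code{normalize = TRUE} (default) entries become
#' \eqn{K'_{ij} = K_{ij} / \sqrt{K_{ii} K_{jj}}}, giving a unit diagonal and
#' entries in [0, 1].
#'
#' @param seqs character vector, \link[Biostrings]{RNAStringSet} or
#'   \linkS4class{SiteWindowSet}.
#' @param params a \linkS4class{GkmParams}.
#' @param normalize cosine-normalize the matrix (default TRUE).
#' @return symmetric positive semidefinite numeric matrix with sequence
#'   names as dimnames (when available).
#' @export
gkmKernelMatrix <- function(seqs, params = GkmParams(), normalize = TRUE) {
  nms <- names(seqs)
  if (is(seqs, "XStringSet")) { nms <- names(seqs); seqs <- as.character(seqs) }
  cm <- gkmCountMatrix(unname(seqs), params)
  K <- as.matrix(Matrix::tcrossprod(cm$F))
  if (normalize) K <- K / sqrt(outer(cm$self, cm$self))
  if (!is.null(nms)) dimnames(K) <- list(nms, nms)
  K
}

#' Cross kernel between two sequence sets
#'
#' Rectangular gkm kernel \code{K[i, j] = gkmKernel(a[i], b[j])}, optionally
#' normalized by the per-sequence self kernels — the matrix needed to score
#' new windows against a trained string classifier.
#'
#' @param a,b character vectors or string sets.
#' @param params a \linkS4class{GkmParams}.
#' @param normalize cosine-normalize (default TRUE).
#' @return length(a) x length(b) numeric matrix.
#' @export
gkmCrossKernelMatrix <- function(a, b, params = GkmParams(), normalize = TRUE) {
  if (is(a, "XStringSet")) a <- as.character(a)
  if (is(b, "XStringSet")) b <- as.character(b)
  ca <- gkmCountMatrix(unname(a), params)
  cb <- gkmCountMatrix(unname(b), params)
  crossFromCounts(ca, cb, normalize)
}

# Cross kernel from two precomputed count representations.
crossFromCounts <- function(ca, cb, normalize = TRUE) {
  shared <- intersect(ca$patterns, cb$patterns)
  if (length(shared)) {
    Fa <- ca$F[, match(shared, ca$patterns), drop = FALSE]
    Fb <- cb$F[, match(shared, cb$patterns), drop = FALSE]
    K <- as.matrix(Fa %*% Matrix::t(Fb))
  } else {
    K <- matrix(0, nrow(ca$F), nrow(cb$F))
  }
  if (normalize) K <- K / sqrt(outer(ca$self, cb$self))
  K
}

#' Export a kernel matrix as tab-delimited text
#'
#' Square matrix with sequence ids as both header and first column, for
#' inspection or precomputed-kernel training elsewhere.
#'
#' @param K square numeric matrix (dimnames used as ids when present).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeKernelMatrix <- function(K, path) {
  ids <- rownames(K)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(K)))
  df <- data.frame(id = ids, K, check.names = FALSE)
  colnames(df) <- c("id", ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
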
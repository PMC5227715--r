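#' PseDNC configuration constructor
#'
#' @param lambda number of correlation tiers (default 6, the value selected
#'   by 10-fold cross-validation in the method this package implements).
#' @param w weight factor in \code{[0, 1]} balancing composition against
#'   sequence-order correlation (default 0.9).
#' @param countingMode how dinucleotides are counted for the composition
#'   part: \code{"overlapping"} (all adjacent pairs, the established PseDNC
#'   convention; default) or \code{"nonoverlapping"} (disjoint pairs 1-2,
#'   3-4, ...; on odd-length sequences the final unpaired residue is
#'   ignored).
#' @return a \linkS4class{PseDncConfig}.
#' @export
PseDncConfig <- function(lambda = 6L, w = 0.9,
                         countingMode = c("overlapping", "nonoverlapping")) {
  new("PseDncConfig", lambda = as.integer(lambda), w = as.numeric(w),
      countingMode = match.arg(countingMode))
}

#' Built-in dinucleotide thermodynamic property table
#'
#' The raw enthalpy (kcal/mol), entropy (cal/(mol K)) and free-energy
#' (kcal/mol) values of the 16 RNA dinucleotides used to quantify
#' secondary-structure stability. Several rows coincide (GG and CC; AC and
#' GU), which forces their pairwise correlation Theta to zero.
#'
#' @return a raw (non-standardized) \linkS4class{PropertyTable}.
#' @examples
#' propertyValues(builtinPropertyTable())["GG", ]
#' @export
builtinPropertyTable <- function() {
  vals <- matrix(c(
    # enthalpy, entropy, free_energy
    -6.6,  -18.4, -0.93,   # AA
    -10.2, -26.2, -2.24,   # AC
    -7.6,  -19.2, -2.08,   # AG
    -5.7,  -15.5, -1.10,   # AU
    -10.5, -27.8, -2.11,   # CA
    -12.2, -29.7, -3.26,   # CC
    -8.0,  -19.4, -2.36,   # CG
    -7.6,  -19.2, -2.08,   # CU
    -13.3, -35.5, -2.35,   # GA
    -14.2, -34.9, -3.42,   # GC
    -12.2, -29.7, -3.26,   # GG
    -10.2, -26.2, -2.24,   # GU
    -8.1,  -22.6, -1.33,   # UA
    -10.2, -26.2, -2.35,   # UC
    -7.6,  -19.2, -2.11,   # UG
    -6.6,  -18.4, -0.93),  # UU
    nrow = 16L, byrow = TRUE,
    dimnames = list(DINUCLEOTIDES, c("enthalpy", "entropy", "free_energy")))
  new("PropertyTable", values = vals, standardized = FALSE)
}

#' @rdname builtinPropertyTable
#' @param table a \linkS4class{PropertyTable}.
#' @return \code{propertyValues}: the underlying 16 x v numeric matrix;
#'   \code{isStandardized}: logical.
#' @export
propertyValues <- function(table) table@values

#' @rdname builtinPropertyTable
#' @export
isStandardized <- function(table) table@standardized

setMethod("show", "PropertyTable", function(object) {
  cat(sprintf("PropertyTable: %d properties (%s), %s\n",
              ncol(object@values), paste(colnames(object@values), collapse = ", "),
              if (object@standardized) "standardized" else "raw"))
  print(utils::head(object@values, 4L))
  cat("  ...\n")
  invisible(NULL)
})

#' Read / write a property table as tab-delimited text
#'
#' Lets users substitute their own property set. The format is one row per
#' dinucleotide: \code{dinucleotide <tab> property1 <tab> ...} with a header
#' line.
#'
#' @param path file path.
#' @param table a \linkS4class{PropertyTable}.
#' @return \code{readPropertyTable}: a raw \linkS4class{PropertyTable};
#'   \code{writePropertyTable}: invisibly, \code{path}.
#' @export
readPropertyTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (colnames(df)[1L] != "dinucleotide")
    stop("input-format error: first column must be 'dinucleotide'", call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$dinucleotide
  if (!setequal(rownames(m), DINUCLEOTIDES))
    stop("input-format error: property table must cover all 16 dinucleotides",
         call. = FALSE)
  m <- m[DINUCLEOTIDES, , drop = FALSE]
  new("PropertyTable", values = m, standardized = FALSE)
}

#' @rdname readPropertyTable
#' @export
writePropertyTable <- function(table, path) {
  df <- data.frame(dinucleotide = rownames(table@values), table@values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Standardize a property table
#'
#' Each property column is independently centered by its mean over the 16
#' dinucleotides and scaled by its standard deviation, so different physical
#' units (kcal vs cal) become irrelevant for the correlation function.
#'
#' @param table a raw \linkS4class{PropertyTable}.
#' @return the standardized \linkS4class{PropertyTable}.
#' @export
standardizeProperties <- function(table) {
  stopifnot(is(table, "PropertyTable"))
  if (table@standardized) return(table)
  v <- table@values
  sdev <- apply(v, 2L, stats::sd)
  if (any(sdev == 0))
    stop("degenerate-property error: property '",
         colnames(v)[which(sdev == 0)[1L]], "' is constant", call. = FALSE)
  v <- scale(v, center = TRUE, scale = sdev)
  attr(v, "scaled:center") <- NULL
  attr(v, "scaled:scale") <- NULL
  new("PropertyTable", values = v[, , drop = FALSE], standardized = TRUE)
}

#' Correlation function between two dinucleotides
#'
#' The PseDNC correlation \eqn{\Theta(D_i, D_j) = \frac{1}{v}\sum_{u=1}^{v}
#' [P_u(D_i) - P_u(D_j)]^2} over the v standardized properties: a symmetric,
#' non-negative dissimilarity that vanishes exactly when the two property
#' rows coincide.
#'
#' @param d1,d2 dinucleotide strings, e.g. \code{"AC"}.
#' @param table a standardized \linkS4class{PropertyTable}.
#' @return a single non-negative number.
#' @examples
#' tab <- standardizeProperties(builtinPropertyTable())
#' thetaCorrelation("GG", "CC", tab)  # 0: identical property rows
#' @export
thetaCorrelation <- function(d1, d2, table) {
  stopifnot(is(table, "PropertyTable"), table@standardized)
  v <- table@values
  if (!d1 %in% rownames(v) || !d2 %in% rownames(v))
    stop("key error: unknown dinucleotide ",
         if (d1 %in% rownames(v)) d2 else d1, call. = FALSE)
  mean((v[d1, ] - v[d2, ])^2)
}

# Dinucleotides D_i = R_i R_{i+1} along a sequence, as a character vector.
overlappingDinucs <- function(seq) {
  L <- nchar(seq)
  substring(seq, seq_len(L - 1L), seq_len(L - 1L) + 1L)
}

#' Normalized dinucleotide frequencies
#'
#' @param seq residues (character scalar over A/C/G/U).
#' @param countingMode \code{"overlapping"} counts all L-1 adjacent pairs;
#'   \code{"nonoverlapping"} counts disjoint pairs 1-2, 3-4, ... (an odd
#'   final residue is ignored).
#' @return named numeric of length 16 (order AA..UU) summing to 1.
#' @export
dinucleotideFrequencies <- function(seq,
    countingMode = c("overlapping", "nonoverlapping")) {
  countingMode <- match.arg(countingMode)
  L <- nchar(seq)
  if (L < 2L) stop("too-short error: need L >= 2, got ", L, call. = FALSE)
  dn <- if (countingMode == "overlapping") {
    overlappingDinucs(seq)
  } else {
    starts <- seq.int(1L, L - 1L, by = 2L)
    substring(seq, starts, starts + 1L)
  }
  cnt <- table(factor(dn, levels = DINUCLEOTIDES))
  setNames(as.vector(cnt) / sum(cnt), DINUCLEOTIDES)
}

#' Tier correlation factors
#'
#' \eqn{\theta_j = \frac{1}{L-1-j} \sum_{i=1}^{L-1-j} \Theta(D_i, D_{i+j})}
#' for j = 1..lambda, where \eqn{D_i = R_i R_{i+1}} runs over all
#' overlapping dinucleotides (regardless of the composition counting mode):
#' the j-tier global sequence-order signal of PseDNC.
#'
#' @param seq residues.
#' @param lambda number of tiers; must satisfy \code{lambda <= L - 2}.
#' @param table a standardized \linkS4class{PropertyTable}.
#' @return numeric of length \code{lambda} (named theta1..), non-negative.
#' @export
tierCorrelationFactors <- function(seq, lambda, table) {
  stopifnot(is(table, "PropertyTable"), table@standardized)
  lambda <- as.integer(lambda)
  L <- nchar(seq)
  if (lambda > L - 2L)
    stop("insufficient-length error: lambda = ", lambda,
         " needs L >= lambda + 2, got L = ", L, call. = FALSE)
  if (lambda == 0L) return(setNames(numeric(0), character(0)))
  P <- table@values[overlappingDinucs(seq), , drop = FALSE]
  nd <- nrow(P)
  theta <- vapply(seq_len(lambda), function(j) {
    i <- seq_len(nd - j)
    mean(rowMeans((P[i, , drop = FALSE] - P[i + j, , drop = FALSE])^2))
  }, numeric(1))
  names(theta) <- paste0("theta", seq_len(lambda))
  theta
}

#' Pseudo dinucleotide composition vector
#'
#' Encodes a sequence as \eqn{d_k = f_k / (1 + w\sum_j \theta_j)} for the 16
#' dinucleotide components and \eqn{d_{16+j} = w\theta_j / (1 + w\sum_j
#' \theta_j)} for the lambda pseudo components, so the full vector is
#' non-negative and sums to 1. With \code{lambda = 0} or \code{w = 0} it
#' reduces to the plain (normalized) dinucleotide composition.
#'
#' @param seq residues (length >= lambda + 2).
#' @param config a \linkS4class{PseDncConfig}.
#' @param table a standardized \linkS4class{PropertyTable}; defaults to the
#'   standardized built-in thermodynamic table.
#' @return named numeric of length \code{16 + lambda} with attributes
#'   \code{f} (the 16 frequencies) and \code{theta} (the tier factors).
#' @examples
#' v <- psedncVector(strrep("A", 51), PseDncConfig())
#' sum(v)  # 1
#' @export
psedncVector <- function(seq, config = PseDncConfig(),
                         table = standardizeProperties(builtinPropertyTable())) {
  stopifnot(is(config, "PseDncConfig"))
  f <- dinucleotideFrequencies(seq, config@countingMode)
  theta <- tierCorrelationFactors(seq, config@lambda, table)
  denom <- 1 + config@w * sum(theta)
  d <- c(f, config@w * theta) / denom
  names(d) <- c(DINUCLEOTIDES,
                if (config@lambda) paste0("lambda", seq_len(config@lambda)))
  attr(d, "f") <- f
  attr(d, "theta") <- theta
  d
}

#' PseDNC feature matrix for a set of windows
#'
#' @param seqs a \linkS4class{SiteWindowSet}, \link[Biostrings]{RNAStringSet}
#'   or character vector.
#' @inheritParams psedncVector
#' @return numeric matrix, one row per sequence, \code{16 + lambda} columns.
#' @export
psedncMatrix <- function(seqs, config = PseDncConfig(),
                         table = standardizeProperties(builtinPropertyTable())) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  m <- t(vapply(unname(seqs),
                function(s) as.vector(psedncVector(s, config, table)),
                numeric(16L + config@lambda)))
  colnames(m) <- c(DINUCLEOTIDES,
                   if (config@lambda) paste0("lambda", seq_len(config@lambda)))
  m
}

#' Grid search for the PseDNC weight and tier count
#'
#' Mirrors the parameter optimization of the original method: for each
#' (w, lambda) pair the windows are PseDNC-encoded and a radial-kernel SVM
#' is scored by stratified 10-fold cross-validation; the pair with the
#' highest mean CV accuracy wins (ties go to the first pair in grid order:
#' lambda-major, then w).
#'
#' @param windows a labeled \linkS4class{SiteWindowSet}.
#' @param wGrid,lambdaGrid candidate values (defaults: w in 0.1..1 by 0.1,
#'   lambda in 1..10).
#' @param folds number of CV folds (default 10).
#' @param seed integer seed controlling fold assignment.
#' @param cost,gamma fixed SVM hyperparameters used during the search.
#' @return a list with \code{w}, \code{lambda}, \code{accuracy} and the full
#'   \code{grid} data.frame.
#' @export
psedncGridSearch <- function(windows, wGrid = seq(0.1, 1, by = 0.1),
                             lambdaGrid = 1:10, folds = 10L, seed = 1L,
                             cost = 1, gamma = 1 / 22) {
  labels <- asLabelFactor(windowLabels(windows))
  if (anyNA(labels)) stop("all windows must be labeled", call. = FALSE)
  fold <- stratifiedFolds(labels, folds, deriveSeed(seed, 17L))
  seqs <- as.character(windows)
  grid <- expand.grid(w = wGrid, lambda = lambdaGrid, KEEP.OUT.ATTRS = FALSE)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    cfg <- PseDncConfig(lambda = grid$lambda[g], w = grid$w[g])
    X <- psedncMatrix(seqs, cfg)
    mean(vapply(seq_len(folds), function(fd) {
      tr <- fold != fd
      fit <- e1071::svm(X[tr, , drop = FALSE], labels[tr], kernel = "radial",
                        cost = cost, gamma = gamma, scale = FALSE)
      mean(predict(fit, X[!tr, , drop = FALSE]) == labels[!tr])
    }, numeric(1)))
  }, numeric(1))
  grid$accuracy <- acc
  best <- which.max(acc)
  list(w = grid$w[best], lambda = grid$lambda[best], accuracy = acc[best],
       grid = grid)
}
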
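stdTab <- standardizeProperties(builtinPropertyTable())

test_that("built-in property table matches the published thermodynamics", {
  tab <- builtinPropertyTable()
  v <- propertyValues(tab)
  expect_identical(dim(v), c(16L, 3L))
  expect_identical(rownames(v), sort(rownames(v)))
  expect_false(isStandardized(tab))
  expect_equal(unname(v["GG", ]), c(-12.2, -29.7, -3.26))
  expect_equal(unname(v["AU", ]), c(-5.7, -15.5, -1.10))
  # duplicated rows that force zero correlations downstream
  expect_equal(unname(v["GG", ]), unname(v["CC", ]))
  expect_equal(unname(v["AC", ]), unname(v["GU", ]))
})

test_that("standardization centers and scales every property column", {
  v <- propertyValues(stdTab)
  expect_true(isStandardized(stdTab))
  expect_true(all(abs(colMeans(v)) < 1e-9))
  expect_true(all(abs(apply(v, 2, sd) - 1) < 1e-9))
  expect_equal(unname(v["GG", ]), unname(v["CC", ]))
  # constant column is degenerate
  broken <- propertyValues(builtinPropertyTable())
  broken[, "enthalpy"] <- 1
  brokenTab <- new("PropertyTable", values = broken, standardized = FALSE)
  expect_error(standardizeProperties(brokenTab), "degenerate-property")
})

test_that("property tables round-trip through tab-delimited text", {
  tf <- tempfile(fileext = ".tsv")
  writePropertyTable(builtinPropertyTable(), tf)
  back <- readPropertyTable(tf)
  expect_equal(propertyValues(back), propertyValues(builtinPropertyTable()))
})

test_that("theta correlation is a symmetric non-negative dissimilarity", {
  for (d in rownames(propertyValues(stdTab)))
    expect_identical(thetaCorrelation(d, d, stdTab), 0)
  # identical raw rows force zero
  expect_identical(thetaCorrelation("GG", "CC", stdTab), 0)
  expect_identical(thetaCorrelation("AC", "GU", stdTab), 0)
  set.seed(7)
  dn <- rownames(propertyValues(stdTab))
  for (i in 1:25) {
    a <- sample(dn, 1); b <- sample(dn, 1)
    expect_gte(thetaCorrelation(a, b, stdTab), 0)
    expect_equal(thetaCorrelation(a, b, stdTab),
                 thetaCorrelation(b, a, stdTab))
  }
  expect_error(thetaCorrelation("AT", "GG", stdTab), "key error")
})

test_that("dinucleotide frequencies under both counting modes", {
  f <- dinucleotideFrequencies(strrep("A", 51))
  expect_equal(unname(f["AA"]), 1)
  expect_equal(sum(f), 1)
  f2 <- dinucleotideFrequencies("ACGU", "overlapping")
  expect_equal(unname(f2[c("AC", "CG", "GU")]), rep(1 / 3, 3))
  f3 <- dinucleotideFrequencies("ACGU", "nonoverlapping")
  expect_equal(unname(f3[c("AC", "GU")]), rep(1 / 2, 2))
  expect_equal(unname(f3["CG"]), 0)
  expect_error(dinucleotideFrequencies("A"), "too-short")
})

# independent oracle: standardize with scale(), enumerate (i, i+j) pairs
oracleTheta <- function(seq, lambda) {
  raw <- propertyValues(builtinPropertyTable())
  std <- scale(raw)
  L <- nchar(seq)
  dn <- substring(seq, 1:(L - 1), 2:L)
  vapply(seq_len(lambda), function(j) {
    pairs <- vapply(seq_len(L - 1 - j), function(i) {
      mean((std[dn[i], ] - std[dn[i + j], ])^2)
    }, numeric(1))
    mean(pairs)
  }, numeric(1))
}

test_that("tier correlation factors match an independent enumeration", {
  expect_equal(unname(tierCorrelationFactors(strrep("A", 20), 3, stdTab)),
               rep(0, 3))
  expect_equal(unname(tierCorrelationFactors("GGGGGG", 2, stdTab)),
               rep(0, 2))
  # 'ACGUA', lambda = 2, including the Theta(AC,GU) = 0 cross-check
  got <- tierCorrelationFactors("ACGUA", 2, stdTab)
  expect_equal(unname(got), oracleTheta("ACGUA", 2))
  expect_equal(unname(got[2]),
               (thetaCorrelation("AC", "GU", stdTab) +
                thetaCorrelation("CG", "UA", stdTab)) / 2)
  expect_identical(thetaCorrelation("AC", "GU", stdTab), 0)
  set.seed(11)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "U"), sample(8:30, 1), TRUE),
               collapse = "")
    lam <- sample(1:6, 1)
    expect_equal(unname(tierCorrelationFactors(s, lam, stdTab)),
                 oracleTheta(s, lam))
  }
  expect_error(tierCorrelationFactors("ACGU", 3, stdTab),
               "insufficient-length")
})

test_that("PseDNC vectors follow the closed form and its reductions", {
  # poly-A: f_AA = 1, all theta 0, so d = (1, 0, ..., 0)
  v <- psedncVector(strrep("A", 51), PseDncConfig())
  expect_equal(unname(v["AA"]), 1)
  expect_equal(sum(v), 1)
  expect_length(v, 22L)

  # 'ACGUA', lambda 2, w 0.9: independent evaluation of the closed form
  theta <- oracleTheta("ACGUA", 2)
  f <- dinucleotideFrequencies("ACGUA")
  denom <- 1 + 0.9 * sum(theta)
  expected <- c(f / denom, 0.9 * theta / denom)
  got <- psedncVector("ACGUA", PseDncConfig(lambda = 2, w = 0.9))
  expect_equal(as.vector(got), as.vector(unname(expected)))

  # lambda = 0 reduces to plain dinucleotide composition
  expect_equal(as.vector(psedncVector("ACGUACG", PseDncConfig(lambda = 0))),
               as.vector(dinucleotideFrequencies("ACGUACG")))
  # w = 0: first 16 equal raw frequencies, pseudo components 0
  v0 <- psedncVector("ACGUACG", PseDncConfig(lambda = 3, w = 0))
  expect_equal(as.vector(v0[1:16]),
               as.vector(dinucleotideFrequencies("ACGUACG")))
  expect_equal(unname(v0[17:19]), rep(0, 3))
})

test_that("PseDNC vectors are non-negative and sum to 1 (fuzz)", {
  set.seed(13)
  for (i in 1:40) {
    s <- paste(sample(c("A", "C", "G", "U"), sample(10:51, 1), TRUE),
               collapse = "")
    cfg <- PseDncConfig(lambda = sample(0:6, 1), w = runif(1),
                        countingMode = sample(c("overlapping",
                                                "nonoverlapping"), 1))
    v <- psedncVector(s, cfg)
    expect_length(v, 16L + cfg@lambda)
    expect_true(all(v >= 0))
    expect_equal(sum(v), 1, tolerance = 1e-9)
  }
})

test_that("inflating the correlation factors shrinks every composition component", {
  v <- psedncVector("ACGUACGGAUCCA", PseDncConfig(lambda = 3))
  f <- attr(v, "f"); theta <- attr(v, "theta")
  expect_gt(sum(theta), 0)
  for (cc in c(1.5, 3, 10)) {
    inflated <- f / (1 + 0.9 * sum(cc * theta))
    expect_true(all(inflated[f > 0] < v[1:16][f > 0]))
  }
})

test_that("PseDNC matrix encodes one row per window", {
  ds <- syntheticWindows(4, 4, seed = 3)
  m <- psedncMatrix(ds)
  expect_identical(dim(m), c(8L, 22L))
  expect_equal(unname(rowSums(m)), rep(1, 8))
  expect_equal(unname(m[1, ]),
               as.vector(psedncVector(as.character(ds)[1], PseDncConfig())))
})

test_that("the (w, lambda) grid search returns the best CV pair", {
  ds <- syntheticWindows(12, 12, seed = 9)
  gs <- psedncGridSearch(ds, wGrid = c(0.5, 0.9), lambdaGrid = c(2, 6),
                         folds = 3, seed = 1)
  expect_true(gs$w %in% c(0.5, 0.9))
  expect_true(gs$lambda %in% c(2, 6))
  expect_identical(nrow(gs$grid), 4L)
  expect_equal(gs$accuracy, max(gs$grid$accuracy))
})
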
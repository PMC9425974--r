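test_that("the shipped BLOSUM62 model has the published scores and is symmetric", {
  S <- scoreMatrix(bl62)
  expect_equal(S["W", "W"], 11)
  expect_equal(S["A", "A"], 4)
  expect_equal(S["D", "K"], S["K", "D"])
  expect_equal(S, t(S))
  f <- backgroundFreqs(bl62)
  expect_length(f, 20)
  expect_true(all(f > 0))
  expect_equal(sum(f), 1, tolerance = 1e-12)
})

test_that("matrix reader rejects malformed input and renormalizes scaled frequencies", {
  path <- system.file("extdata", "BLOSUM62.txt", package = "varcog")
  lines <- readLines(path)
  truncated <- tempfile(fileext = ".txt")
  writeLines(lines[-grep("^W", lines)], truncated)  # drop the W row
  expect_error(readScoreMatrix(truncated), "missing amino acid")

  freqs <- tempfile(fileext = ".tsv")
  f <- backgroundFreqs(bl62) * 2   # scaled by 2 -> warn and renormalize
  write.table(data.frame(names(f), unname(f)), freqs, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  expect_warning(model <- readScoreMatrix(path, freqs), "renormalizing")
  expect_equal(sum(backgroundFreqs(model)), 1, tolerance = 1e-12)

  asym <- scoreMatrix(bl62)
  asym["A", "W"] <- asym["A", "W"] + 1
  expect_error(ScoreModel(asym), "symmetric")
})

test_that("column consensus maximizes Q over the alphabet with alphabetical ties", {
  # invariant column: the residue's self-score wins
  cc <- columnConsensus(rep("A", 6), bl62)
  expect_identical(cc$consensus, "A")
  expect_equal(cc$Qc, scoreMatrix(bl62)["A", "A"])

  # mixed column: agree with 20-way brute-force enumeration
  col <- c(rep("D", 4), rep("K", 4))
  S <- scoreMatrix(bl62)
  Q <- vapply(AA_LETTERS, function(x)
    mean(vapply(col, function(a) S[a, x], 1)), 1)
  expect_identical(columnConsensus(col, bl62)$consensus,
                   AA_LETTERS[which.max(Q)])

  # engineered exact tie resolves to the alphabetically first residue
  M <- matrix(0L, 20, 20, dimnames = list(AA_LETTERS, AA_LETTERS))
  diag(M) <- 2L
  tied <- ScoreModel(M)
  expect_identical(columnConsensus(c("I", "L"), tied)$consensus, "I")
})

test_that("column homogeneity matches the formula's fixed points and the brute-force oracle", {
  expect_identical(columnHomogeneity(rep("W", 8), bl62), 1)
  expect_identical(columnHomogeneity(rep("G", 3), bl62), 1)
  expect_equal(columnHomogeneity(c(rep("D", 4), rep("K", 4)), bl62),
               oracleColumnHomogeneity(c(rep("D", 4), rep("K", 4)), bl62),
               tolerance = 1e-12)
  # columns no better than random clamp at zero: use a hostile pairing
  S <- scoreMatrix(bl62)
  worst <- which(S == min(S), arr.ind = TRUE)[1L, ]
  col <- c(rep(rownames(S)[worst[1L]], 4), rep(colnames(S)[worst[2L]], 4))
  expect_gte(columnHomogeneity(col, bl62), 0)
  expect_error(columnHomogeneity(c("A", "-", "-"), bl62), "degenerate")
})

test_that("homogeneity obeys its invariants on fuzz columns", {
  set.seed(42)
  for (rep in 1:300) {
    n <- sample(3:30, 1)
    col <- randomColumn(n)
    if (sum(col != "-") < 2) next
    h <- columnHomogeneity(col, bl62)
    expect_gte(h, 0)
    expect_lte(h, 1)
    # row permutation invariance
    expect_equal(columnHomogeneity(sample(col), bl62), h, tolerance = 1e-12)
    # duplicating all rows leaves the weighted composition unchanged
    expect_equal(columnHomogeneity(c(col, col), bl62), h, tolerance = 1e-12)
    # oracle equivalence
    expect_equal(h, oracleColumnHomogeneity(col, bl62), tolerance = 1e-12)
  }
})

test_that("two-residue columns agree with the explicit-sum oracle at all mixture ratios", {
  for (m in 1:7) {
    col <- c(rep("E", m), rep("V", 8 - m))
    expect_equal(columnHomogeneity(col, bl62),
                 oracleColumnHomogeneity(col, bl62), tolerance = 1e-12)
  }
})

test_that("the inclusion filter counts non-identical sequences and informative columns", {
  # 8 copies of one sequence deduplicate to 1
  aln <- FamilyAlignment(rep("ACDEFGHIKL", 8), sprintf("g%d", 1:8))
  flt <- alignmentPassesFilter(aln)
  expect_equal(flt$nNonIdentical, 1)
  expect_false(flt$pass)

  # 7 distinct sequences fail regardless of length
  sim7 <- simulateFamilyAlignment(7, 100, theta = 0.3, seed = 11)
  expect_false(alignmentPassesFilter(sim7$alignment)$pass)

  # 10 distinct sequences x 100 informative columns pass
  sim10 <- simulateFamilyAlignment(10, 100, theta = 0.3, seed = 12)
  flt10 <- alignmentPassesFilter(sim10$alignment)
  expect_true(flt10$pass)
  expect_equal(flt10$nInformativeColumns, 100)

  # singular-insertion columns are not informative
  gappy <- FamilyAlignment(c("AW-", "A-C", "A-C"), c("g1", "g2", "g3"))
  expect_equal(alignmentPassesFilter(gappy)$nInformativeColumns, 2)
})

test_that("profiles mask singular and all-gap columns and score the rest", {
  aln <- FamilyAlignment(c("AW-K", "A--K", "A--K"), c("g1", "g2", "g3"))
  prof <- homogeneityProfile(aln, bl62, applyFilter = FALSE)
  expect_identical(columnMask(prof),
                   c("scored", "skipped-singular", "skipped-all-gap",
                     "scored"))
  expect_identical(homogeneityValues(prof), c(1, 1))
  expect_true(is.na(homogeneityValues(prof, scoredOnly = FALSE)[2]))

  # identical sequences (filter overridden): all h = 1
  aln8 <- FamilyAlignment(rep("ACDEFGHIKL", 8), sprintf("g%d", 1:8))
  prof8 <- homogeneityProfile(aln8, bl62, applyFilter = FALSE)
  expect_identical(unique(homogeneityValues(prof8)), 1)

  # the filter blocks under-sized alignments unless overridden
  expect_error(homogeneityProfile(aln8, bl62), "filter")
})

test_that("user-supplied sequence weights are honored", {
  aln <- FamilyAlignment(c("D", "D", "K", "K"), sprintf("g%d", 1:4))
  prof <- homogeneityProfile(aln, bl62, weights = c(0.4, 0.4, 0.1, 0.1),
                             applyFilter = FALSE)
  expect_equal(homogeneityValues(prof),
               oracleColumnHomogeneity(c("D", "D", "K", "K"), bl62,
                                       weights = c(0.4, 0.4, 0.1, 0.1)),
               tolerance = 1e-12)
  expect_error(homogeneityProfile(aln, bl62, weights = c(1, 1, 1, 1),
                                  applyFilter = FALSE), "sum to 1")
})
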
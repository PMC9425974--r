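# shared fixtures and independent oracles used across the suite

bl62 <- blosum62ScoreModel()

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# brute-force column homogeneity: explicit loops over sequences and the
# 20-letter alphabet, written independently of the package's matrix-based
# implementation
oracleColumnHomogeneity <- function(residues, model, weights = NULL) {
  S <- scoreMatrix(model)
  f <- backgroundFreqs(model)
  keep <- residues %in% AA_LETTERS
  res <- residues[keep]
  if (is.null(weights)) weights <- rep(1, length(residues))
  w <- weights[keep]
  w <- w / sum(w)
  Q <- sapply(AA_LETTERS, function(x) {
    total <- 0
    for (i in seq_along(res)) total <- total + w[i] * S[res[i], x]
    total
  })
  # first max = alphabetical tie-break (tolerance guards float roundoff
  # on exact rational ties)
  c <- AA_LETTERS[which(Q >= max(Q) - 1e-9)[1L]]
  Qc <- max(Q)
  QR <- 0
  for (b in AA_LETTERS) QR <- QR + f[[b]] * Q[[b]]
  max((Qc - QR) / (S[c, c] - QR), 0)
}

# random amino-acid column with optional gaps
randomColumn <- function(n, pGap = 0.15) {
  alphabet <- c(AA_LETTERS, "-")
  probs <- c(rep((1 - pGap) / 20, 20), pGap)
  sample(alphabet, n, replace = TRUE, prob = probs)
}

# direct double-loop Gaussian smoothing oracle over scored positions
oracleSmooth <- function(h, b) {
  pos <- which(!is.na(h))
  out <- numeric(length(pos))
  for (ii in seq_along(pos)) {
    num <- 0; den <- 0
    for (jj in seq_along(pos)) {
      kk <- exp(-((pos[jj] - pos[ii]) / b)^2)
      num <- num + h[pos[jj]] * kk
      den <- den + kk
    }
    out[ii] <- num / den
  }
  out
}

# exhaustive csCOG extraction oracle on a laminar-family representation:
# the clades of the pruned tree are the non-empty restrictions of the
# original clades to the remaining tips, so pruning needs no tree
# surgery. Tie-break (index desc, S_C desc, P_C asc, then smallest
# member id) mirrors the documented rule; it must, because extracting
# one of two tied clades can raise an ancestor's index and change the
# rest of the partition.
oracleExtract <- function(tree, genome) {
  nt <- ape::Ntip(tree)
  clades <- phangorn::Descendants(tree, seq_len(nt + tree$Nnode), "tips")
  clades <- lapply(clades, function(i) sort(tree$tip.label[i]))
  S <- length(unique(genome))
  remaining <- sort(tree$tip.label)
  groups <- list()
  repeat {
    cur <- unique(lapply(clades, function(cl) intersect(cl, remaining)))
    cur <- cur[lengths(cur) > 0]
    P <- lengths(cur)
    Sc <- vapply(cur, function(cl) length(unique(genome[cl])), 1L)
    idx <- Sc^2 / (P * S)
    minLeaf <- vapply(cur, min, "")
    ord <- order(-idx, -Sc, P, minLeaf)
    best <- cur[[ord[1L]]]
    groups[[length(groups) + 1L]] <- sort(best)
    if (length(best) == length(remaining)) break
    remaining <- setdiff(remaining, best)
  }
  groups
}

partitionAsSet <- function(groups) {
  canon <- lapply(groups, sort)
  canon[order(vapply(canon, paste, "", collapse = "\r"))]
}

# independent binomial upper tail by direct summation of the p.m.f.
oracleBinomTail <- function(t, p, n) {
  if (n <= 0) return(1)
  if (n > t) return(0)
  sum(vapply(n:t, function(i) choose(t, i) * p^i * (1 - p)^(t - i), 1))
}

# write a set of synthetic family alignments into a directory, return paths
writeFixtureFamilies <- function(dir, thetas, nSequences = 10L,
                                 nColumns = 80L, seedBase = 100L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vapply(seq_along(thetas), function(i) {
    sim <- simulateFamilyAlignment(nSequences = nSequences,
                                   nColumns = nColumns,
                                   theta = thetas[i],
                                   familyId = sprintf("fam%02d", i),
                                   seed = seedBase + i)
    writeFamilyAlignment(sim$alignment,
                         file.path(dir, sprintf("fam%02d.afa", i)))
  }, "")
}
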
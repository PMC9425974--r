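#' Construct a FamilyAlignment
#'
#' @param seqs an \linkS4class{AAStringSet} (or character vector) of
#'   equal-length gapped sequences.
#' @param genomeId character vector of genome identifiers, one per
#'   sequence.
#' @param familyId single character family identifier.
#' @return A \linkS4class{FamilyAlignment}.
#' @export
FamilyAlignment <- function(seqs, genomeId, familyId = "family") {
  if (is.character(seqs))
    seqs <- Biostrings::AAStringSet(seqs)
  new("FamilyAlignment", familyId = familyId, seqs = seqs,
      genomeId = as.character(genomeId))
}

#' @rdname FamilyAlignment-accessors
#' @param x a \linkS4class{FamilyAlignment} (or, where it applies, a
#'   \linkS4class{HomogeneityProfile}).
#' @export
setMethod("familyId", "FamilyAlignment", function(x) x@familyId)

#' @rdname FamilyAlignment-accessors
#' @export
setMethod("genomeIds", "FamilyAlignment", function(x) x@genomeId)

#' @rdname FamilyAlignment-accessors
#' @export
setMethod("nColumns", "FamilyAlignment",
          function(x) Biostrings::width(x@seqs)[1L])

#' @rdname FamilyAlignment-accessors
#' @export
setMethod("nSequences", "FamilyAlignment", function(x) length(x@seqs))

setMethod("show", "FamilyAlignment", function(object) {
  cat("FamilyAlignment", object@familyId, ":", length(object@seqs),
      "sequences x", nColumns(object), "columns,",
      length(unique(object@genomeId)), "genomes\n")
})

# Character matrix (sequences x columns) with ambiguous residues
# (B, Z, X, U, O, J) recoded as gaps: no score is guaranteed for them in
# every matrix file, so they are excluded from column sums like gaps.
alignmentCharMatrix <- function(aln) {
  m <- do.call(rbind, strsplit(as.character(aln@seqs), ""))
  m[!(m %in% AA20)] <- "-"
  m
}

# Per-column weight mass for each of the 20 residues: 20 x L matrix.
# weights is the per-sequence weight vector (summing to 1 over all rows);
# each column is then renormalized over its non-gap rows.
columnWeightMatrix <- function(charMat, weights) {
  W <- vapply(AA20, function(aa)
    colSums(weights * (charMat == aa)), numeric(ncol(charMat)))
  if (is.null(dim(W))) W <- matrix(W, nrow = 1L, dimnames = list(NULL, AA20))
  W <- t(W)                     # 20 x L
  tot <- colSums(W)
  keep <- tot > 0
  W[, keep] <- sweep(W[, keep, drop = FALSE], 2L, tot[keep], "/")
  W
}

homogeneityFromWeights <- function(W, model) {
  S <- scoreMatrix(model)
  f <- backgroundFreqs(model)
  Q <- S %*% W                      # Q[x, col] = sum_a W[a,col] * S[a,x]
  Qc <- apply(Q, 2L, max)
  # argmax with alphabetical tie-break: AA20 is alphabetical; ties are
  # exact in rational arithmetic (integer scores, rational weights), so a
  # small tolerance shields the tie-break from dot-product roundoff
  cons <- AA20[apply(Q, 2L, function(q) which(q >= max(q) - 1e-9)[1L])]
  QR <- as.numeric(f %*% Q)
  Scc <- diag(S)[cons]
  denom <- Scc - QR
  if (any(abs(denom) < 1e-12))
    stop("degenerate column: consensus self-score equals the random expectation")
  list(h = pmax((Qc - QR) / denom, 0), consensus = cons, Qc = Qc, QR = QR)
}

#' Consensus residue of an alignment column
#'
#' The effective consensus of a column is the amino acid x maximizing the
#' weighted column score Q_x = sum_i w_i S(a_i, x) over the 20 standard
#' residues; ties are broken alphabetically. Weights are renormalized over
#' the non-gap rows of the column.
#'
#' @param residues character vector of single residues (gaps allowed).
#' @param model a \linkS4class{ScoreModel}.
#' @param weights optional per-row weights (default equal); renormalized
#'   over non-gap rows.
#' @return list with \code{consensus} (single letter) and \code{Qc} (its
#'   weighted score).
#' @export
columnConsensus <- function(residues, model, weights = NULL) {
  prep <- prepareColumn(residues, weights)
  if (prep$nNonGap < 1L)
    stop("degenerate column: no non-gap residues")
  res <- homogeneityFromWeights(prep$W, model)
  list(consensus = res$consensus[1L], Qc = res$Qc[1L])
}

prepareColumn <- function(residues, weights) {
  residues <- toupper(as.character(residues))
  residues[!(residues %in% AA20)] <- "-"
  if (is.null(weights)) weights <- rep(1 / length(residues), length(residues))
  if (length(weights) != length(residues) || any(weights < 0))
    stop("weights must be non-negative, one per row")
  m <- matrix(residues, ncol = 1L)
  list(W = columnWeightMatrix(m, weights / sum(weights)),
       nNonGap = sum(residues != "-"))
}

#' Homogeneity of an alignment column
#'
#' h = max((Q_c - Q_R) / (S(c,c) - Q_R), 0), where Q_c is the weighted
#' score of the effective consensus c against the column and
#' Q_R = sum_b f_b Q_b is the expected score of the column against a
#' random assortment of residues drawn from the background frequencies.
#' An invariant column has h = 1; a column matching random expectation (or
#' worse) has h = 0.
#'
#' @inheritParams columnConsensus
#' @return homogeneity value in [0, 1].
#' @examples
#' model <- blosum62ScoreModel()
#' columnHomogeneity(rep("W", 8), model)      # 1
#' columnHomogeneity(c(rep("D", 4), rep("K", 4)), model)
#' @export
columnHomogeneity <- function(residues, model, weights = NULL) {
  prep <- prepareColumn(residues, weights)
  if (prep$nNonGap < 2L)
    stop("degenerate column: need at least 2 non-gap residues")
  unname(homogeneityFromWeights(prep$W, model)$h[1L])
}

#' Family-alignment inclusion filter
#'
#' A family alignment enters the variability analysis only if it has at
#' least \code{minSequences} non-identical protein sequences (exact
#' duplicates of the ungapped residue string removed) and at least
#' \code{minColumns} informative aligned columns, where singular
#' insertions (columns whose non-gap residues come from exactly one
#' sequence) and all-gap columns are not informative.
#'
#' @param aln a \linkS4class{FamilyAlignment}.
#' @param minSequences minimum non-identical sequences (default 8).
#' @param minColumns minimum informative columns (default 60).
#' @return list with \code{pass}, \code{nNonIdentical},
#'   \code{nInformativeColumns}.
#' @export
alignmentPassesFilter <- function(aln, minSequences = 8L, minColumns = 60L) {
  ungapped <- gsub("[-.]", "", as.character(aln@seqs))
  nNonIdentical <- length(unique(ungapped))
  m <- alignmentCharMatrix(aln)
  nonGapPerCol <- colSums(m != "-")
  nInformative <- sum(nonGapPerCol >= 2L)
  list(pass = nNonIdentical >= minSequences && nInformative >= minColumns,
       nNonIdentical = nNonIdentical,
       nInformativeColumns = nInformative)
}

#' Per-column homogeneity profile of a family alignment
#'
#' Computes h for every column with at least two non-gap residues;
#' singular-insertion columns (one non-gap residue) and all-gap columns
#' are masked. Sequences get equal weights 1/N unless a weight vector is
#' supplied.
#'
#' @param aln a \linkS4class{FamilyAlignment}.
#' @param model a \linkS4class{ScoreModel}.
#' @param weights optional per-sequence weights summing to 1.
#' @param applyFilter require the alignment to pass
#'   \code{\link{alignmentPassesFilter}} (default TRUE); set FALSE for
#'   exploratory use on small alignments.
#' @return A \linkS4class{HomogeneityProfile}.
#' @export
homogeneityProfile <- function(aln, model, weights = NULL,
                               applyFilter = TRUE) {
  if (nSequences(aln) < 1L || nColumns(aln) < 1L)
    stop("empty alignment")
  if (applyFilter) {
    flt <- alignmentPassesFilter(aln)
    if (!flt$pass)
      stop(sprintf(paste0("alignment %s fails the inclusion filter ",
                          "(%d non-identical sequences, %d informative ",
                          "columns); use applyFilter = FALSE to override"),
                   aln@familyId, flt$nNonIdentical,
                   flt$nInformativeColumns))
  }
  if (is.null(weights)) {
    weights <- rep(1 / nSequences(aln), nSequences(aln))
  } else {
    if (length(weights) != nSequences(aln) || any(weights < 0))
      stop("weights must be non-negative, one per sequence")
    if (abs(sum(weights) - 1) > 1e-9)
      stop("weights must sum to 1")
  }
  m <- alignmentCharMatrix(aln)
  nonGap <- colSums(m != "-")
  mask <- rep("scored", ncol(m))
  mask[nonGap == 1L] <- "skipped-singular"
  mask[nonGap == 0L] <- "skipped-all-gap"
  h <- rep(NA_real_, ncol(m))
  scored <- mask == "scored"
  if (any(scored)) {
    W <- columnWeightMatrix(m[, scored, drop = FALSE], weights)
    h[scored] <- pmin(homogeneityFromWeights(W, model)$h, 1)
  }
  new("HomogeneityProfile", familyId = aln@familyId, h = h, mask = mask,
      nSequences = nSequences(aln))
}

#' Accessors for HomogeneityProfile
#'
#' @param x a \linkS4class{HomogeneityProfile}.
#' @param scoredOnly return only scored columns (default) or the full
#'   per-column vector with NA at masked columns.
#' @name HomogeneityProfile-accessors
NULL

#' @rdname HomogeneityProfile-accessors
#' @export
setMethod("homogeneityValues", "HomogeneityProfile",
          function(x, scoredOnly = TRUE) {
  if (scoredOnly) x@h[x@mask == "scored"] else x@h
})

#' @rdname HomogeneityProfile-accessors
#' @export
setMethod("columnMask", "HomogeneityProfile", function(x) x@mask)

#' @rdname HomogeneityProfile-accessors
#' @export
setMethod("familyId", "HomogeneityProfile", function(x) x@familyId)

#' @rdname HomogeneityProfile-accessors
#' @export
setMethod("meanHomogeneity", "HomogeneityProfile",
          function(x) mean(x@h[x@mask == "scored"]))

setMethod("show", "HomogeneityProfile", function(object) {
  sc <- object@mask == "scored"
  cat("HomogeneityProfile", object@familyId, ":", length(object@h),
      "columns (", sum(sc), "scored ), mean h =",
      if (any(sc)) round(mean(object@h[sc]), 4) else NA, "\n")
})
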
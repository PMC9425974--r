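#' @import methods
#' @importFrom stats cmdscale dnorm pbinom sd cor setNames runif quantile
#' @importFrom utils read.table write.table head tail
#' @importClassesFrom Biostrings AAStringSet
#' @importClassesFrom IRanges IRanges
NULL

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHARS <- c("-", ".")

#' ScoreModel: substitution scores plus background amino-acid frequencies
#'
#' Couples an integer-valued symmetric substitution score matrix (BLOSUM62
#' by default, in the half-bit units it is distributed in) with a table of
#' background amino-acid frequencies. The pair calibrates column
#' homogeneity: the matrix scores the consensus against the column, the
#' background gives the random-assortment expectation.
#'
#' @slot scores numeric 20x20 symmetric matrix over the standard amino
#'   acids, dimnames in alphabetical order.
#' @slot background named numeric vector of 20 relative frequencies,
#'   strictly positive, summing to 1.
#' @slot metadata list recording provenance (matrix source, frequency
#'   table source).
#' @exportClass ScoreModel
setClass("ScoreModel",
  representation(scores = "matrix", background = "numeric",
                 metadata = "list"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@scores), c(20L, 20L)) ||
        !identical(rownames(object@scores), AA20) ||
        !identical(colnames(object@scores), AA20))
      msg <- c(msg, "scores must be a 20x20 matrix over the standard amino acids")
    else if (!isTRUE(all.equal(object@scores, t(object@scores))))
      msg <- c(msg, "score matrix must be symmetric")
    if (!identical(names(object@background), AA20))
      msg <- c(msg, "background must be named by the 20 standard amino acids")
    else {
      if (any(object@background <= 0))
        msg <- c(msg, "background frequencies must be strictly positive")
      if (abs(sum(object@background) - 1) > 1e-9)
        msg <- c(msg, "background frequencies must sum to 1")
    }
    if (length(msg)) msg else TRUE
  })

#' FamilyAlignment: a genome-labeled multiple protein alignment
#'
#' One protein family (csCOG): aligned amino-acid sequences with the genome
#' each sequence comes from. The unit on which column homogeneity is
#' computed.
#'
#' @slot familyId single character identifier.
#' @slot seqs \linkS4class{AAStringSet} of equal-width gapped sequences.
#' @slot genomeId character vector parallel to \code{seqs}.
#' @exportClass FamilyAlignment
setClass("FamilyAlignment",
  representation(familyId = "character", seqs = "AAStringSet",
                 genomeId = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@familyId) != 1L)
      msg <- c(msg, "familyId must be a single string")
    if (length(object@seqs) < 1L)
      msg <- c(msg, "alignment must contain at least one sequence")
    else if (length(unique(Biostrings::width(object@seqs))) != 1L)
      msg <- c(msg, "all aligned sequences must have identical length")
    if (length(object@genomeId) != length(object@seqs))
      msg <- c(msg, "genomeId must be parallel to the sequences")
    else if (any(is.na(object@genomeId) | object@genomeId == ""))
      msg <- c(msg, "every sequence needs a non-empty genome id")
    if (length(msg)) msg else TRUE
  })

#' HomogeneityProfile: per-column homogeneity of one family alignment
#'
#' Holds the column homogeneity values h in [0,1] for every alignment
#' column, with a mask distinguishing scored columns from skipped ones
#' (singular insertions, i.e. columns whose residues come from a single
#' sequence, and all-gap columns). Masked columns carry \code{NA} in
#' \code{h}.
#'
#' @slot familyId single character identifier.
#' @slot h numeric vector, one value per alignment column (NA if masked).
#' @slot mask character vector, one of \code{"scored"},
#'   \code{"skipped-singular"}, \code{"skipped-all-gap"}.
#' @slot nSequences number of sequences the profile was computed from.
#' @exportClass HomogeneityProfile
setClass("HomogeneityProfile",
  representation(familyId = "character", h = "numeric", mask = "character",
                 nSequences = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@h) != length(object@mask))
      msg <- c(msg, "h and mask must have one entry per column")
    if (!all(object@mask %in%
             c("scored", "skipped-singular", "skipped-all-gap")))
      msg <- c(msg, "unknown mask label")
    sc <- object@mask == "scored"
    if (any(is.na(object@h[sc])))
      msg <- c(msg, "scored columns must carry a homogeneity value")
    if (any(object@h[sc] < -1e-12 | object@h[sc] > 1 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "scored homogeneity values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' CladeContext: clade-wide mean homogeneity
#'
#' The normalization context for relative variability: the arithmetic mean
#' homogeneity h_T over all scored columns of all family alignments in a
#' clade, with the pooled counts.
#'
#' @slot cladeId single character identifier.
#' @slot hT mean homogeneity, strictly inside (0, 1).
#' @slot nFamilies number of profiles pooled.
#' @slot nColumnsTotal number of scored columns pooled.
#' @slot method \code{"pooled"} (column-weighted) or \code{"mean-of-means"}.
#' @exportClass CladeContext
setClass("CladeContext",
  representation(cladeId = "character", hT = "numeric",
                 nFamilies = "integer", nColumnsTotal = "integer",
                 method = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@hT) != 1L || is.na(object@hT) ||
        object@hT <= 0 || object@hT >= 1)
      msg <- c(msg, "hT must lie strictly inside (0, 1)")
    if (length(msg)) msg else TRUE
  })

#' HomogeneityDensity: a homogeneity p.d.f. on the fixed 101-point grid
#'
#' Probability mass of a family's smoothed homogeneity values on 101
#' equidistant grid points spanning [0, 1]; unit total mass. The common
#' grid is what makes Hellinger distances between families well defined.
#'
#' @slot familyId single character identifier.
#' @slot grid numeric, the 101 grid points.
#' @slot mass numeric, non-negative, summing to 1.
#' @slot metadata list (estimator, bandwidth, n).
#' @exportClass HomogeneityDensity
setClass("HomogeneityDensity",
  representation(familyId = "character", grid = "numeric", mass = "numeric",
                 metadata = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@grid) != length(object@mass))
      msg <- c(msg, "grid and mass must have equal length")
    if (any(object@mass < -1e-12))
      msg <- c(msg, "mass must be non-negative")
    if (abs(sum(object@mass) - 1) > 1e-9)
      msg <- c(msg, "mass must sum to 1")
    if (length(msg)) msg else TRUE
  })

#' CsCOGPartition: gene-tree leaves partitioned into csCOGs
#'
#' Result of iteratively carving clade-specific orthologous groups out of a
#' genome-labeled gene tree by the coverage-paralogy tradeoff index. The
#' groups are an exact partition of the input leaf set, in extraction
#' order (the final group is the residual tree).
#'
#' @slot groups list of data.frames with columns \code{sequenceId},
#'   \code{genomeId}.
#' @slot stats data.frame, one row per group: \code{cscogId}, \code{P_C},
#'   \code{S_C}, \code{paralogy}, \code{coverage}, \code{index},
#'   \code{round}.
#' @exportClass CsCOGPartition
setClass("CsCOGPartition",
  representation(groups = "list", stats = "data.frame"),
  validity = function(object) {
    msg <- character()
    ids <- unlist(lapply(object@groups, function(g) g$sequenceId))
    if (anyDuplicated(ids))
      msg <- c(msg, "groups must be disjoint")
    if (nrow(object@stats) != length(object@groups))
      msg <- c(msg, "stats must have one row per group")
    if (length(msg)) msg else TRUE
  })

#' MsrAnnotation: microsatellite-like regions on one nucleotide sequence
#'
#' Merged, disjoint intervals (0-based half-open) covered by statistically
#' non-random, closely spaced k-mer recurrences, plus the fraction of the
#' sequence they cover.
#'
#' @slot sequenceId single character identifier.
#' @slot intervals \linkS4class{IRanges} of merged intervals, stored
#'   1-based closed as is native to IRanges; exported writers emit 0-based
#'   half-open coordinates.
#' @slot seqLength sequence length in nucleotides.
#' @slot msrFraction covered length / sequence length.
#' @slot detail data.frame of per-k, per-motif significant intervals
#'   (columns k, motif, start, end; 0-based half-open).
#' @exportClass MsrAnnotation
setClass("MsrAnnotation",
  representation(sequenceId = "character", intervals = "IRanges",
                 seqLength = "integer", msrFraction = "numeric",
                 detail = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (object@msrFraction < 0 || object@msrFraction > 1)
      msg <- c(msg, "msrFraction must lie in [0, 1]")
    if (length(object@intervals) > 1L &&
        any(IRanges::start(object@intervals)[-1] <=
            IRanges::end(object@intervals)[-length(object@intervals)]))
      msg <- c(msg, "intervals must be disjoint and sorted")
    if (length(msg)) msg else TRUE
  })
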
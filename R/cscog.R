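setClass("GeneTree",
  representation(tree = "ANY", genome = "character"),
  validity = function(object) {
    msg <- character()
    if (!inherits(object@tree, "phylo"))
      msg <- c(msg, "tree must be an ape phylo object")
    else {
      tips <- object@tree$tip.label
      if (!identical(sort(names(object@genome)), sort(tips)))
        msg <- c(msg, "genome map must cover exactly the tip labels")
      if (any(is.na(object@genome) | object@genome == ""))
        msg <- c(msg, "every leaf needs a non-empty genome id")
    }
    if (length(msg)) msg else TRUE
  })

parseGenomeFromLabels <- function(labels, delim = "|") {
  parts <- strsplit(labels, delim, fixed = TRUE)
  genome <- vapply(parts, function(p) p[[length(p)]], "")
  bad <- genome == "" | is.na(genome)
  if (any(bad))
    stop("cannot parse a genome id from leaf label(s): ",
         paste(labels[bad], collapse = ", "))
  setNames(genome, labels)
}

#' Construct a genome-labeled gene tree
#'
#' Wraps an \pkg{ape} \code{phylo} gene tree together with the genome each
#' leaf comes from. Genome ids default to the token after the last
#' \code{delim} in each leaf label. Unrooted trees are midpoint-rooted
#' (with unit branch lengths substituted if the tree carries none).
#'
#' @param tree an \code{ape::phylo} object, or a path/string accepted by
#'   \code{ape::read.tree}.
#' @param genome optional named character vector mapping tip labels to
#'   genome ids; parsed from labels when absent.
#' @param delim delimiter for genome-id parsing (default \code{"|"}).
#' @return A \code{GeneTree} object.
#' @export
GeneTree <- function(tree, genome = NULL, delim = "|") {
  if (is.character(tree))
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("could not obtain a phylo tree")
  if (anyDuplicated(tree$tip.label)) {
    warning("duplicate leaf labels; uniquifying")
    tree$tip.label <- make.unique(tree$tip.label, sep = "#")
  }
  if (ape::Ntip(tree) > 2L && !ape::is.rooted(tree)) {
    if (is.null(tree$edge.length))
      tree$edge.length <- rep(1, nrow(tree$edge))
    message("unrooted gene tree: midpoint-rooting")
    tree <- phangorn::midpoint(tree)
  }
  if (is.null(genome))
    genome <- parseGenomeFromLabels(tree$tip.label, delim)
  new("GeneTree", tree = tree, genome = genome[tree$tip.label])
}

setMethod("show", "GeneTree", function(object) {
  cat("GeneTree:", ape::Ntip(object@tree), "leaves from",
      length(unique(object@genome)), "genomes\n")
})

# tip labels under every node (tips first, then internals), as a list
# indexed by ape node number
nodeTipSets <- function(tree) {
  nt <- ape::Ntip(tree)
  desc <- phangorn::Descendants(tree, seq_len(nt + tree$Nnode), "tips")
  lapply(desc, function(i) tree$tip.label[i])
}

# final tie-break key: the lexicographically smallest member sequence id
# of each clade. Well defined on the leaf set alone (unlike traversal
# orders, which depend on sibling rotations), and tied maxima are always
# disjoint clades, so the key is unambiguous.
minLeafLabels <- function(tree) {
  tipSets <- nodeTipSets(tree)
  vapply(tipSets, function(tl) min(tl), "")
}

#' Coverage-paralogy statistics of every clade in a gene tree
#'
#' For each node (leaves included) of a gene tree whose leaves come from S
#' distinct genomes, reports the leaf count P_C, the distinct genome count
#' S_C, the paralogy ratio P_C / S_C, the genome coverage S_C / S, and the
#' coverage-paralogy tradeoff index S_C^2 / (P_C * S) that drives csCOG
#' extraction.
#'
#' @param gt a \code{\link{GeneTree}}.
#' @param S total genome count used for coverage; defaults to the number
#'   of distinct genomes among the tree's leaves.
#' @return data.frame with one row per node: \code{node} (ape node
#'   number), \code{isRoot}, \code{isLeaf}, \code{P_C}, \code{S_C},
#'   \code{paralogy}, \code{coverage}, \code{index}.
#' @export
cladeStatistics <- function(gt, S = NULL) {
  tree <- gt@tree
  nt <- ape::Ntip(tree)
  if (nt < 1L) stop("empty tree")
  if (nt == 1L) {
    S <- if (is.null(S)) 1L else S
    return(data.frame(node = 1L, isRoot = TRUE, isLeaf = TRUE, P_C = 1L,
                      S_C = 1L, paralogy = 1, coverage = 1 / S,
                      index = 1 / S))
  }
  if (is.null(S)) S <- length(unique(gt@genome))
  tipSets <- nodeTipSets(tree)
  P <- lengths(tipSets)
  Sc <- vapply(tipSets, function(tl) length(unique(gt@genome[tl])), 1L)
  data.frame(node = seq_along(tipSets),
             isRoot = seq_along(tipSets) == nt + 1L,
             isLeaf = seq_along(tipSets) <= nt,
             P_C = as.integer(P), S_C = Sc, paralogy = P / Sc,
             coverage = Sc / S, index = Sc^2 / (P * S))
}

# pick the extraction candidate: maximal index, ties broken by larger
# S_C, then smaller P_C, then smallest member sequence id
selectBestClade <- function(stats, minLeaf) {
  ord <- order(-stats$index, -stats$S_C, stats$P_C, minLeaf[stats$node])
  stats[ord[1L], ]
}

#' Carve clade-specific orthologous groups out of a gene tree
#'
#' Iteratively finds the clade with the maximum coverage-paralogy tradeoff
#' index S_C^2 / (P_C * S). If that clade is the tree root, the whole
#' remaining tree becomes the final csCOG and extraction stops; otherwise
#' the clade is detached as a csCOG (unifurcations suppressed) and the
#' procedure repeats on the pruned tree. Leaves are eligible clades, so
#' orphan sequences can become singleton csCOGs. Ties are broken by larger
#' S_C, then smaller P_C, then the lexicographically smallest member
#' sequence id (a tie-break defined by the leaf set alone, independent of
#' how siblings happen to be rotated in the input file).
#'
#' @param gt a \code{\link{GeneTree}}.
#' @param freezeS keep S (the genome-coverage denominator) fixed at the
#'   original tree's genome count across extraction rounds (default TRUE);
#'   FALSE recomputes S from the pruned tree each round.
#' @return A \linkS4class{CsCOGPartition}; groups are in extraction order
#'   and exactly partition the input leaves.
#' @export
extractCsCOGs <- function(gt, freezeS = TRUE) {
  genome <- gt@genome
  S0 <- length(unique(genome))
  tree <- gt@tree
  groups <- list()
  rows <- list()
  round <- 0L
  takeGroup <- function(tips, st, round) {
    list(group = data.frame(sequenceId = tips,
                            genomeId = unname(genome[tips]),
                            stringsAsFactors = FALSE),
         row = data.frame(cscogId = sprintf("cscog%03d", round),
                          P_C = st$P_C, S_C = st$S_C,
                          paralogy = st$paralogy, coverage = st$coverage,
                          index = st$index, round = round))
  }
  repeat {
    round <- round + 1L
    nt <- ape::Ntip(tree)
    cur <- new("GeneTree", tree = tree,
               genome = genome[tree$tip.label])
    S <- if (freezeS) S0 else length(unique(genome[tree$tip.label]))
    stats <- cladeStatistics(cur, S = S)
    if (nt == 1L) {
      res <- takeGroup(tree$tip.label, stats[1L, ], round)
      groups[[round]] <- res$group; rows[[round]] <- res$row
      break
    }
    best <- selectBestClade(stats, minLeafLabels(tree))
    tips <- if (best$isLeaf) tree$tip.label[best$node]
            else nodeTipSets(tree)[[best$node]]
    res <- takeGroup(tips, best, round)
    groups[[round]] <- res$group; rows[[round]] <- res$row
    if (best$isRoot) break
    remaining <- setdiff(tree$tip.label, tips)
    if (length(remaining) == 0L) break
    if (length(remaining) == 1L) {
      round <- round + 1L
      lastGt <- new("GeneTree",
                    tree = structure(list(edge = matrix(c(2L, 1L), 1L),
                                          tip.label = remaining,
                                          Nnode = 1L),
                                     class = "phylo"),
                    genome = genome[remaining])
      st <- cladeStatistics(lastGt, S = if (freezeS) S0 else 1L)[1L, ]
      res <- takeGroup(remaining, st, round)
      groups[[round]] <- res$group; rows[[round]] <- res$row
      break
    }
    tree <- ape::drop.tip(tree, tips)
  }
  new("CsCOGPartition", groups = groups, stats = do.call(rbind, rows))
}

#' Accessors for CsCOGPartition
#'
#' @param x a \linkS4class{CsCOGPartition}.
#' @name CsCOGPartition-accessors
NULL

#' @rdname CsCOGPartition-accessors
#' @export
setMethod("cscogGroups", "CsCOGPartition", function(x) x@groups)

#' @rdname CsCOGPartition-accessors
#' @export
setMethod("cscogStats", "CsCOGPartition", function(x) x@stats)

setMethod("show", "CsCOGPartition", function(object) {
  cat("CsCOGPartition:", length(object@groups), "csCOGs over",
      sum(vapply(object@groups, nrow, 1L)), "sequences\n")
})
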
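# run expr under a fixed RNG seed without disturbing the caller's stream
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Simulate a protein family alignment at controlled divergence
#'
#' Star-tree substitution model: a consensus sequence is drawn from the
#' background amino-acid frequencies; each of the n sequences replaces
#' each site independently with probability \code{theta} by a residue
#' drawn from the background. theta = 0 yields identical sequences
#' (homogeneity 1 everywhere); theta = 1 yields near-random columns. The
#' background defaults to the table shipped with the default score model,
#' so the homogeneity calibration of simulated families is coherent.
#'
#' @param nSequences number of sequences (default 10).
#' @param nColumns alignment length (default 100).
#' @param theta per-site substitution probability in [0, 1].
#' @param genomes genome labels to cycle over the sequences (default one
#'   genome per sequence).
#' @param background amino-acid frequency table (default Robinson &
#'   Robinson).
#' @param familyId identifier for the family.
#' @param seed integer seed; the same seed reproduces the alignment
#'   exactly.
#' @return list with \code{alignment} (a
#'   \linkS4class{FamilyAlignment}), \code{consensus} (character string)
#'   and \code{theta}.
#' @export
simulateFamilyAlignment <- function(nSequences = 10L, nColumns = 100L,
                                    theta, genomes = NULL,
                                    background = ROBINSON_FREQS,
                                    familyId = "sim", seed = NULL) {
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  background <- normalizeFreqs(background)
  if (is.null(genomes))
    genomes <- sprintf("g%02d", seq_len(nSequences))
  genomes <- rep_len(genomes, nSequences)
  withSeed(seed, {
    consensus <- sample(AA20, nColumns, replace = TRUE, prob = background)
    seqs <- vapply(seq_len(nSequences), function(i) {
      res <- consensus
      hit <- runif(nColumns) < theta
      res[hit] <- sample(AA20, sum(hit), replace = TRUE, prob = background)
      paste(res, collapse = "")
    }, "")
    names(seqs) <- sprintf("%s_s%02d|%s", familyId, seq_len(nSequences),
                           genomes)
    list(alignment = FamilyAlignment(seqs, genomes, familyId = familyId),
         consensus = paste(consensus, collapse = ""), theta = theta)
  })
}

#' Simulate a nucleotide sequence with a planted tandem repeat
#'
#' An i.i.d. uniform A/C/G/T background sequence with a tandem array of
#' \code{copies} repeats of \code{motif} overwriting the positions from
#' \code{position} (0-based). The planted footprint is returned as the
#' ground-truth interval.
#'
#' @param length total sequence length.
#' @param motif repeat unit (e.g. \code{"AT"}).
#' @param copies number of tandem copies (0 plants nothing).
#' @param position 0-based start of the array.
#' @param seed integer seed.
#' @return list with \code{sequence} (character string) and \code{truth}
#'   (0-based half-open \code{c(start, end)}, or NULL when copies = 0).
#' @export
plantMsrSequence <- function(length, motif, copies, position = 0L,
                             seed = NULL) {
  insert <- strrep(motif, copies)
  if (position < 0 || position + nchar(insert) > length)
    stop("planted array does not fit inside the sequence")
  withSeed(seed, {
    s <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
               collapse = "")
    if (copies > 0)
      substr(s, position + 1L, position + nchar(insert)) <- insert
    list(sequence = s,
         truth = if (copies > 0) c(position, position + nchar(insert))
                 else NULL)
  })
}

# --- tiny recursive tree structure for the gene-tree generator ---------
# leaf: list(genome = <id>, tag = <copy tag>); internal: list(children =
# list(left, right)). Kept separate from ape so duplications are simple
# deep copies.

simLeaf <- function(genome, tag) list(genome = genome, tag = tag)
simIsLeaf <- function(node) !is.null(node$genome)

# random rooted topology by sequential random joins
simRandomTopology <- function(genomes, tag = "0") {
  nodes <- lapply(genomes, simLeaf, tag = tag)
  while (length(nodes) > 1L) {
    i <- sample.int(length(nodes), 2L)
    joined <- list(children = nodes[i])
    nodes <- c(nodes[-i], list(joined))
  }
  nodes[[1L]]
}

simRetag <- function(node, suffix) {
  if (simIsLeaf(node)) {
    node$tag <- paste0(node$tag, suffix)
    node
  } else {
    node$children <- lapply(node$children, simRetag, suffix = suffix)
    node
  }
}

simCountInternal <- function(node) {
  if (simIsLeaf(node)) 0L
  else 1L + sum(vapply(node$children, simCountInternal, 0L))
}

# duplicate the subtree rooted at the idx-th internal node (preorder);
# idx = 1 is the root
simDuplicateAt <- function(node, idx, suffixes = c("a", "b")) {
  counter <- 0L
  recurse <- function(nd) {
    if (simIsLeaf(nd)) return(nd)
    counter <<- counter + 1L
    if (counter == idx)
      return(list(children = list(simRetag(nd, suffixes[1L]),
                                  simRetag(nd, suffixes[2L]))))
    nd$children <- lapply(nd$children, recurse)
    nd
  }
  recurse(node)
}

simToNewick <- function(node) {
  if (simIsLeaf(node))
    sprintf("%s.%s|%s", node$genome, node$tag, node$genome)
  else
    sprintf("(%s)", paste(vapply(node$children, simToNewick, ""),
                          collapse = ","))
}

#' Simulate a genome-labeled gene tree with known ortholog partition
#'
#' Builds a random rooted species topology over the genomes, then applies
#' whole-tree duplications: each duplication replaces the current tree T
#' by (T, T'), tagging the leaf copies, so after d duplications every
#' genome appears 2^d times and the true ortholog groups are the 2^d
#' duplicate copies. With \code{at = "internal"} each duplication instead
#' doubles the subtree under a random internal node, which produces
#' partial-coverage paralogy (note that such duplicates are not generally
#' separable by coverage-maximizing extraction).
#'
#' @param genomes character vector of genome ids.
#' @param duplications number of duplication events (default 0).
#' @param seed integer seed.
#' @param at \code{"root"} (default) or \code{"internal"}.
#' @return list with \code{tree} (a \code{\link{GeneTree}}; leaf labels
#'   \code{<genome>.<copyTag>|<genome>}) and \code{truth} (list of
#'   character vectors of leaf labels, the true ortholog groups).
#' @export
simulateLabeledGeneTree <- function(genomes, duplications = 0L,
                                    seed = NULL, at = c("root", "internal")) {
  at <- match.arg(at)
  if (length(genomes) < 1L) stop("need at least one genome")
  withSeed(seed, {
    root <- simRandomTopology(genomes)
    for (d in seq_len(duplications)) {
      if (simIsLeaf(root)) {
        root <- list(children = list(simRetag(root, "a"),
                                     simRetag(root, "b")))
      } else {
        idx <- if (at == "root") 1L
               else sample.int(simCountInternal(root), 1L)
        root <- simDuplicateAt(root, idx)
      }
    }
    nwk <- paste0(simToNewick(root), ";")
    if (length(genomes) == 1L && duplications == 0L)
      nwk <- sprintf("(%s);", simToNewick(root))
    tree <- ape::read.tree(text = nwk)
    gt <- GeneTree(tree)
    tags <- sub("\\|.*$", "", tree$tip.label)
    tags <- sub("^[^.]*\\.", "", tags)
    truth <- split(tree$tip.label, tags)
    list(tree = gt, truth = unname(truth))
  })
}

#' Simulate a binary presence/absence history on a species tree
#'
#' Markov presence process: the root is present with probability
#' \code{rootPresent} (or deterministically when logical); along each
#' edge an absent gene is gained with probability \code{gainRate} and a
#' present gene lost with probability \code{lossRate}. Node states are
#' emitted as 0/1 posteriors, so discrete event inference on the emitted
#' posteriors reproduces the recorded event list exactly.
#'
#' @param tree rooted \code{ape::phylo} with labeled internal nodes (or a
#'   Newick string/path).
#' @param gainRate,lossRate per-edge transition probabilities.
#' @param rootPresent TRUE/FALSE, or a probability (default 0.5).
#' @param familyId identifier.
#' @param seed integer seed.
#' @return list with \code{posterior} (a
#'   \code{\link{PresencePosterior}} carrying the 0/1 states), and
#'   \code{events} (data.frame \code{parent}, \code{child},
#'   \code{event}; the root origination appears with parent NA).
#' @export
simulatePresenceHistory <- function(tree, gainRate, lossRate,
                                    rootPresent = 0.5, familyId = "sim",
                                    seed = NULL) {
  if (is.character(tree))
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  if (is.null(tree$node.label) || any(tree$node.label == ""))
    tree$node.label <- sprintf("n%d", seq_len(tree$Nnode))
  nt <- ape::Ntip(tree)
  root <- nt + 1L
  withSeed(seed, {
    state <- integer(nt + tree$Nnode)
    state[root] <- if (is.logical(rootPresent)) as.integer(rootPresent)
                   else as.integer(runif(1) < rootPresent)
    edges <- ape::reorder.phylo(tree, "cladewise")$edge
    ev <- list()
    if (state[root] == 1L)
      ev[[1L]] <- data.frame(parent = NA_integer_, child = root,
                             event = "gain")
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1L]; chd <- edges[e, 2L]
      s <- state[par]
      if (s == 0L && runif(1) < gainRate) {
        s <- 1L
        ev[[length(ev) + 1L]] <- data.frame(parent = par, child = chd,
                                            event = "gain")
      } else if (s == 1L && runif(1) < lossRate) {
        s <- 0L
        ev[[length(ev) + 1L]] <- data.frame(parent = par, child = chd,
                                            event = "loss")
      }
      state[chd] <- s
    }
    labels <- c(tree$tip.label, tree$node.label)
    pp <- PresencePosterior(tree, setNames(as.numeric(state), labels),
                            familyId = familyId)
    events <- if (length(ev)) do.call(rbind, ev)
              else data.frame(parent = integer(), child = integer(),
                              event = character())
    list(posterior = pp, events = events)
  })
}
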
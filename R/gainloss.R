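#' Attach ancestral-presence posteriors to a rooted species tree
#'
#' Pairs a rooted species tree (internal nodes labeled) with the posterior
#' probability that the gene family was present at every node, as produced
#' by phyletic-pattern reconstruction tools. All downstream gain/loss
#' inference reads parent-child differences of these probabilities.
#'
#' @param tree an \code{ape::phylo} with non-empty \code{node.label}s, or
#'   a path/Newick string.
#' @param prob named numeric vector of presence probabilities in [0, 1],
#'   names covering every tip and internal-node label.
#' @param familyId identifier of the family.
#' @return object of class \code{PresencePosterior} (list with
#'   \code{tree}, \code{prob} indexed by ape node number,
#'   \code{familyId}).
#' @export
PresencePosterior <- function(tree, prob, familyId = "family") {
  if (is.character(tree))
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  nt <- ape::Ntip(tree)
  labels <- c(tree$tip.label,
              if (is.null(tree$node.label)) character() else tree$node.label)
  if (length(labels) != nt + tree$Nnode || any(labels == ""))
    stop("species tree needs labels on every tip and internal node")
  missing <- setdiff(labels, names(prob))
  if (length(missing))
    stop("no posterior for node(s): ", paste(missing, collapse = ", "))
  p <- unname(prob[labels])
  if (any(is.na(p) | p < 0 | p > 1))
    stop("posterior probabilities must lie in [0, 1]")
  structure(list(tree = tree, prob = p, familyId = familyId),
            class = "PresencePosterior")
}

#' @export
print.PresencePosterior <- function(x, ...) {
  cat("PresencePosterior", x$familyId, ":", ape::Ntip(x$tree), "tips,",
      "root presence", round(x$prob[ape::Ntip(x$tree) + 1L], 3), "\n")
  invisible(x)
}

# per-edge table: parent, child, delta = child - parent, child depth
# (edges from root), terminal flag; optionally prepended virtual edge
# from absence (probability 0) into the root
edgeDeltas <- function(pp, virtualRoot = TRUE) {
  tree <- pp$tree
  nt <- ape::Ntip(tree)
  root <- nt + 1L
  unitTree <- tree
  unitTree$edge.length <- rep(1, nrow(tree$edge))
  depth <- ape::node.depth.edgelength(unitTree)
  df <- data.frame(parent = tree$edge[, 1L], child = tree$edge[, 2L])
  df$delta <- pp$prob[df$child] - pp$prob[df$parent]
  df$depth <- depth[df$child]
  df$terminal <- df$child <= nt
  if (virtualRoot)
    df <- rbind(data.frame(parent = NA_integer_, child = root,
                           delta = pp$prob[root], depth = 0,
                           terminal = nt == 1L), df)
  df
}

#' Discrete gain and loss events from presence posteriors
#'
#' A parent-to-child difference of presence posteriors of at least
#' \code{threshold} (default 0.5) is called a gain; of at most
#' \code{-threshold}, a loss. The root is given a virtual edge from
#' absence, so a root posterior >= threshold registers the origination of
#' the family as one gain at the root (disable with
#' \code{virtualRoot = FALSE}).
#'
#' @param pp a \code{\link{PresencePosterior}}.
#' @param threshold posterior-difference cutoff (default 0.5).
#' @param virtualRoot count origination at the root as a gain
#'   (default TRUE).
#' @return data.frame of events: \code{parent}, \code{child} (ape node
#'   numbers; parent NA for the root's virtual edge), \code{delta},
#'   \code{depth} (edges from root to child), \code{terminal},
#'   \code{event} ("gain" or "loss").
#' @export
inferDiscreteEvents <- function(pp, threshold = 0.5, virtualRoot = TRUE) {
  df <- edgeDeltas(pp, virtualRoot)
  df$event <- ifelse(df$delta >= threshold, "gain",
                     ifelse(df$delta <= -threshold, "loss", NA))
  df[!is.na(df$event), , drop = FALSE]
}

#' Summed gain and loss totals
#'
#' The expected total numbers of gains and losses over the family's
#' history: the sums of positive and of negative parent-to-child
#' posterior differences, respectively. Reported both with and without
#' the root origination term (the root posterior itself).
#'
#' @inheritParams inferDiscreteEvents
#' @return named numeric: \code{gainTotal}, \code{lossTotal} (with the
#'   root term), \code{gainTotalNoRoot}, \code{lossTotalNoRoot}.
#' @export
totalGainsLosses <- function(pp) {
  df <- edgeDeltas(pp, virtualRoot = FALSE)
  gains <- sum(pmax(df$delta, 0))
  losses <- sum(pmax(-df$delta, 0))
  rootP <- pp$prob[ape::Ntip(pp$tree) + 1L]
  c(gainTotal = gains + rootP, lossTotal = losses,
    gainTotalNoRoot = gains, lossTotalNoRoot = losses)
}

#' Ancestrality of a gene family in its clade
#'
#' A family with root presence posterior >= 0.5 is ancestral to the clade.
#' Otherwise the family was acquired later: on an internal branch
#' ("intermediate") or on a terminal branch ("terminal"), decided by the
#' deepest (closest to the root) gain event. Families with no gain event
#' at all are "unclassified".
#'
#' @param pp a \code{\link{PresencePosterior}}.
#' @param threshold posterior cutoff (default 0.5).
#' @return list with \code{ancestral} (logical), \code{class} (one of
#'   "ancestral", "intermediate", "terminal", "unclassified"), and
#'   \code{rootPosterior}.
#' @export
classifyAncestrality <- function(pp, threshold = 0.5) {
  rootP <- pp$prob[ape::Ntip(pp$tree) + 1L]
  if (rootP >= threshold)
    return(list(ancestral = TRUE, class = "ancestral",
                rootPosterior = rootP))
  ev <- inferDiscreteEvents(pp, threshold, virtualRoot = FALSE)
  gains <- ev[ev$event == "gain", , drop = FALSE]
  cls <- if (nrow(gains) == 0L) "unclassified"
         else if (gains$terminal[which.min(gains$depth)]) "terminal"
         else "intermediate"
  list(ancestral = FALSE, class = cls, rootPosterior = rootP)
}

#' Per-family gain/loss summary table
#'
#' @param pps list of \code{\link{PresencePosterior}} objects.
#' @return data.frame with one row per family: \code{familyId},
#'   \code{nGains}, \code{nLosses} (discrete events, root origination
#'   included), \code{gainTotal}, \code{lossTotal} (summed posterior
#'   differences, root term included), \code{ancestrality}.
#' @export
gainLossSummary <- function(pps) {
  if (inherits(pps, "PresencePosterior")) pps <- list(pps)
  do.call(rbind, lapply(pps, function(pp) {
    ev <- inferDiscreteEvents(pp)
    tot <- totalGainsLosses(pp)
    data.frame(familyId = pp$familyId,
               nGains = sum(ev$event == "gain"),
               nLosses = sum(ev$event == "loss"),
               gainTotal = unname(tot["gainTotal"]),
               lossTotal = unname(tot["lossTotal"]),
               ancestrality = classifyAncestrality(pp)$class,
               stringsAsFactors = FALSE)
  }))
}
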
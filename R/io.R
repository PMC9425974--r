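#' Read a genome-labeled aligned FASTA file
#'
#' Reads an aligned protein FASTA (equal-length gapped records) and parses
#' a genome id out of each record header: either a \code{genome=<id>}
#' token anywhere in the header (rule \code{"token"}, tried first by
#' default) or the token after the last \code{|} (rule \code{"pipe"}).
#'
#' @param path FASTA file path.
#' @param genomeRule \code{"auto"} (default: genome= token if present,
#'   else last pipe field), \code{"token"}, or \code{"pipe"}.
#' @param familyId identifier; defaults to the file name without
#'   extension.
#' @return A \linkS4class{FamilyAlignment}.
#' @export
readFamilyAlignment <- function(path, genomeRule = c("auto", "token",
                                                     "pipe"),
                                familyId = NULL) {
  genomeRule <- match.arg(genomeRule)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in ", path)
  if (length(unique(Biostrings::width(seqs))) != 1L) {
    widths <- Biostrings::width(seqs)
    bad <- names(seqs)[widths != widths[1L]][1L]
    stop("ragged alignment in ", path, ": record '", bad,
         "' has a different length")
  }
  headers <- names(seqs)
  genome <- rep(NA_character_, length(headers))
  if (genomeRule %in% c("auto", "token")) {
    m <- regmatches(headers, regexpr("genome=[^ |]+", headers))
    hit <- grepl("genome=", headers)
    genome[hit] <- sub("^genome=", "", m)
  }
  if (genomeRule %in% c("auto", "pipe")) {
    todo <- is.na(genome) & grepl("|", headers, fixed = TRUE)
    genome[todo] <- vapply(strsplit(headers[todo], "|", fixed = TRUE),
                           function(p) p[[length(p)]], "")
  }
  bad <- is.na(genome) | genome == ""
  if (any(bad))
    stop("cannot parse a genome id from record header(s): ",
         paste(headers[bad], collapse = ", "))
  if (is.null(familyId))
    familyId <- sub("\\.[^.]*$", "", basename(path))
  FamilyAlignment(seqs, genome, familyId = familyId)
}

#' Write a FamilyAlignment as aligned FASTA
#'
#' Headers carry a \code{genome=<id>} token so the file round-trips
#' through \code{\link{readFamilyAlignment}}.
#'
#' @param aln a \linkS4class{FamilyAlignment}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeFamilyAlignment <- function(aln, path) {
  seqs <- aln@seqs
  base <- if (is.null(names(seqs))) sprintf("%s_s%03d", aln@familyId,
                                            seq_along(seqs))
          else sub("\\s.*$", "", names(seqs))
  names(seqs) <- sprintf("%s genome=%s", base, aln@genomeId)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write / read per-column homogeneity profiles as TSV
#'
#' Columns: \code{family_id}, \code{column_index} (0-based), \code{h}
#' (empty for masked columns), \code{mask}.
#'
#' @param profiles a \linkS4class{HomogeneityProfile} or list thereof.
#' @param path TSV path.
#' @return \code{writeHomogeneityProfiles} returns the path invisibly;
#'   \code{readHomogeneityProfiles} returns a list of
#'   \linkS4class{HomogeneityProfile} objects.
#' @export
writeHomogeneityProfiles <- function(profiles, path) {
  if (inherits(profiles, "HomogeneityProfile")) profiles <- list(profiles)
  tab <- do.call(rbind, lapply(profiles, function(p)
    data.frame(family_id = familyId(p),
               column_index = seq_along(p@h) - 1L,
               h = p@h, mask = p@mask, stringsAsFactors = FALSE)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeHomogeneityProfiles
#' @export
readHomogeneityProfiles <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  lapply(split(tab, tab$family_id), function(d) {
    d <- d[order(d$column_index), ]
    new("HomogeneityProfile", familyId = d$family_id[1L], h = d$h,
        mask = d$mask, nSequences = NA_integer_)
  })
}

#' Write MSR annotations as a BED-like TSV
#'
#' Columns \code{sequence_id}, \code{start}, \code{end} with 0-based
#' half-open coordinates (BED convention).
#'
#' @param annotations a \linkS4class{MsrAnnotation} or list thereof.
#' @param path output path.
#' @export
writeMsrBed <- function(annotations, path) {
  if (inherits(annotations, "MsrAnnotation"))
    annotations <- list(annotations)
  tab <- do.call(rbind, lapply(annotations, msrIntervals))
  colnames(tab) <- c("sequence_id", "start", "end")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writeMsrBed
#' @export
readMsrBed <- function(path) {
  tab <- tryCatch(read.table(path, header = FALSE, sep = "\t",
                             col.names = c("sequence_id", "start", "end"),
                             stringsAsFactors = FALSE),
                  error = function(e)
                    data.frame(sequence_id = character(),
                               start = integer(), end = integer()))
  tab
}

#' Write csCOG membership as TSV
#'
#' Columns \code{cscog_id}, \code{sequence_id}, \code{genome_id}.
#'
#' @param partition a \linkS4class{CsCOGPartition}.
#' @param path output path.
#' @export
writeCsCOGMembers <- function(partition, path) {
  stats <- cscogStats(partition)
  tab <- do.call(rbind, lapply(seq_along(partition@groups), function(i)
    data.frame(cscog_id = stats$cscogId[i],
               sequence_id = partition@groups[[i]]$sequenceId,
               genome_id = partition@groups[[i]]$genomeId,
               stringsAsFactors = FALSE)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCsCOGMembers
#' @export
readCsCOGMembers <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read a per-node presence-posterior table
#'
#' TSV with columns \code{family_id}, \code{node_label},
#' \code{probability}, matched against a species tree with labeled
#' internal nodes.
#'
#' @param treePath Newick species tree path (internal nodes labeled).
#' @param tsvPath posterior table path.
#' @return list of \code{\link{PresencePosterior}} objects, one per
#'   family.
#' @export
readPresencePosteriors <- function(treePath, tsvPath) {
  tree <- ape::read.tree(treePath)
  tab <- read.table(tsvPath, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("family_id", "node_label", "probability")
  if (!all(need %in% colnames(tab)))
    stop("posterior table needs columns: ", paste(need, collapse = ", "))
  lapply(split(tab, tab$family_id), function(d)
    PresencePosterior(tree, setNames(d$probability, d$node_label),
                      familyId = d$family_id[1L]))
}
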
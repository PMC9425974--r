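#' Binomial tail probability of a k-mer recurrence
#'
#' Probability that a fixed k-mer over an alphabet of size A recurs at
#' least n times in a random sequence stretch of length L, modeling the
#' t = L - k + 1 start positions as independent Bernoulli trials with
#' per-trial probability p = A^-k. Computed with the numerically stable
#' survival function.
#'
#' @param L stretch length in characters (L >= k).
#' @param k motif length.
#' @param n recurrence count.
#' @param A alphabet size (default 4, nucleotides).
#' @return upper tail probability P(X >= n).
#' @examples
#' recurrenceTailProbability(1000, 6, 6)   # ~2.3e-7, below 1e-6
#' @export
recurrenceTailProbability <- function(L, k, n, A = 4L) {
  if (any(L < k)) stop("stretch length L must be at least the motif length k")
  if (any(n < 0)) stop("recurrence count must be non-negative")
  t <- L - k + 1
  p <- A^(-k)
  ifelse(n == 0, 1,
         ifelse(n > t, 0, pbinom(n - 1, t, p, lower.tail = FALSE)))
}

#' Minimal significant recurrence count in a window
#'
#' Smallest count n whose binomial tail probability within a window of
#' length L falls below \code{alpha}. For hexamers (k = 6) at
#' alpha = 1e-6 this reproduces the threshold ladder 6 / 5 / 4 / 3 for
#' windows of 1000 / 500 / 200 / 80 bp.
#'
#' @inheritParams recurrenceTailProbability
#' @param alpha significance threshold (default 1e-6).
#' @return smallest significant n (t + 1, i.e. unattainable, if no count
#'   up to the number of trials is significant).
#' @examples
#' minSignificantCount(1000, 6)   # 6
#' minSignificantCount(80, 6)     # 3
#' @export
minSignificantCount <- function(L, k, A = 4L, alpha = 1e-6) {
  if (L < k) stop("window length L must be at least the motif length k")
  t <- L - k + 1
  # tail is decreasing in n: binary search over 0..t+1
  lo <- 0L; hi <- as.integer(t) + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (recurrenceTailProbability(L, k, mid, A) < alpha) hi <- mid
    else lo <- mid + 1L
  }
  lo
}

# lookup vector n_min for L = k..maxL (index L - k + 1); cached per
# (k, A, alpha) since the scanner asks for the same table per segment
.minCountCache <- new.env(parent = emptyenv())

minCountTable <- function(k, maxL, A = 4L, alpha = 1e-6) {
  key <- paste(k, A, alpha, sep = "_")
  tab <- .minCountCache[[key]]
  if (is.null(tab) || length(tab) < maxL - k + 1L) {
    tab <- vapply(k:maxL, function(L) minSignificantCount(L, k, A, alpha),
                  0L)
    .minCountCache[[key]] <- tab
  }
  tab[seq_len(maxL - k + 1L)]
}

# start positions (1-based) of every valid occurrence of each k-mer in a
# segment of pure A/C/G/T
kmerOccurrences <- function(segment, k) {
  n <- nchar(segment)
  if (n < k) return(list())
  chars <- strsplit(segment, "")[[1]]
  starts <- seq_len(n - k + 1L)
  kmers <- substring(segment, starts, starts + k - 1L)
  split(starts, kmers)
}

# significant recurrence chains of one motif. Occurrences (sorted start
# positions) are chained while consecutive start-to-start intervals are
# I <= k (the tandem-recurrence rule); each chain of n >= 2 occurrences
# is tested binomially on its own span (n >= nminTab[span - k + 1]).
# Chains whose span exceeds the locality cap are always significant:
# an I <= k chain packs at least (cap - k)/k + 1 occurrences into any
# cap-length window, far above the window threshold for every k <= 6.
# Returns coverage intervals [first, last + k - 1], 1-based inclusive.
significantChains <- function(pos, k, nminTab, cap) {
  if (length(pos) < 2L) return(NULL)
  gap <- diff(pos)
  breaks <- which(gap > k)
  startIdx <- c(1L, breaks + 1L)
  endIdx <- c(breaks, length(pos))
  n <- endIdx - startIdx + 1L
  span <- pos[endIdx] + k - pos[startIdx]
  keep <- n >= 2L & (span > cap | n >= nminTab[pmin(span, cap) - k + 1L])
  if (!any(keep)) return(NULL)
  cbind(start = pos[startIdx[keep]], end = pos[endIdx[keep]] + k - 1L)
}

#' Scan a nucleotide sequence for microsatellite-like regions
#'
#' Detects statistically non-random local recurrences of k-mers for every
#' motif length k = 1..\code{kMax} (overlapping occurrences allowed).
#' Occurrences of a motif at start-to-start intervals I <= k form
#' recurrence chains (the tandem-repeat signature); a chain is non-random
#' when its occurrence count within its own span (capped at
#' \code{windowCap} characters) has a binomial tail probability
#' (p = A^-k per start position) below \code{alpha}. Microsatellite-like
#' regions (MSRs) are the footprints of the significant chains; per-k
#' regions closer than k are merged, and the per-k tracks are united into
#' one disjoint annotation. Characters outside A/C/G/T never occur inside
#' motifs and break occurrence chains.
#'
#' @param seq nucleotide sequence (character string, or a
#'   \code{Biostrings::DNAString}).
#' @param sequenceId identifier for the annotation.
#' @param kMax largest motif length scanned (default 6).
#' @param alpha per-stretch significance threshold (default 1e-6).
#' @param windowCap locality window in characters (default 1000).
#' @return A \linkS4class{MsrAnnotation}.
#' @export
scanSequence <- function(seq, sequenceId = "seq", kMax = 6L, alpha = 1e-6,
                         windowCap = 1000L) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  detail <- list()
  if (n > 0) {
    # split at ambiguity characters: motifs and runs never cross them
    segs <- gregexpr("[ACGT]+", seq)[[1]]
    if (segs[1L] != -1L) {
      offsets <- as.integer(segs)
      lens <- attr(segs, "match.length")
      for (si in seq_along(offsets)) {
        segment <- substr(seq, offsets[si], offsets[si] + lens[si] - 1L)
        for (k in seq_len(kMax)) {
          if (nchar(segment) < k + 1L) next
          nminTab <- minCountTable(k, min(nchar(segment), windowCap),
                                   alpha = alpha)
          occ <- kmerOccurrences(segment, k)
          for (motif in names(occ)) {
            pos <- occ[[motif]]
            if (length(pos) < 2L) next
            cov <- significantChains(pos, k, nminTab, windowCap)
            if (is.null(cov)) next
            detail[[length(detail) + 1L]] <-
              data.frame(k = k, motif = motif,
                         start = cov[, "start"] + offsets[si] - 2L,
                         end = cov[, "end"] + offsets[si] - 1L)
          }
        }
      }
    }
  }
  emptyDetail <- data.frame(k = integer(), motif = character(),
                            start = integer(), end = integer())
  if (length(detail)) {
    detail <- do.call(rbind, detail)           # 0-based half-open
    # per-k merge: regions of the same motif length closer than k fuse
    perK <- lapply(split(detail, detail$k), function(d) {
      k <- d$k[1L]
      IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end),
                      min.gapwidth = k)
    })
    merged <- IRanges::reduce(do.call(c, unname(perK)))
  } else {
    detail <- emptyDetail
    merged <- IRanges::IRanges()
  }
  covered <- sum(IRanges::width(merged))
  new("MsrAnnotation", sequenceId = sequenceId, intervals = merged,
      seqLength = as.integer(n),
      msrFraction = if (n > 0) covered / n else 0,
      detail = detail)
}

#' Accessors for MsrAnnotation
#'
#' @param x a \linkS4class{MsrAnnotation}.
#' @return \code{msrIntervals}: data.frame of merged intervals with
#'   0-based half-open \code{start}, \code{end}; \code{msrFraction}: the
#'   covered fraction of the sequence.
#' @name MsrAnnotation-accessors
NULL

#' @rdname MsrAnnotation-accessors
#' @export
setMethod("msrIntervals", "MsrAnnotation", function(x) {
  data.frame(sequenceId = rep(x@sequenceId, length(x@intervals)),
             start = IRanges::start(x@intervals) - 1L,
             end = IRanges::end(x@intervals), stringsAsFactors = FALSE)
})

#' @rdname MsrAnnotation-accessors
#' @export
setMethod("msrFraction", "MsrAnnotation", function(x) x@msrFraction)

setMethod("show", "MsrAnnotation", function(object) {
  cat("MsrAnnotation", object@sequenceId, ":", length(object@intervals),
      "region(s),", sprintf("%.1f%%", 100 * object@msrFraction),
      "of", object@seqLength, "nt\n")
})

#' Mean MSR fraction per family
#'
#' @param annotations list of \linkS4class{MsrAnnotation} objects.
#' @param family character vector assigning each annotation to a family
#'   (default: all one family).
#' @return data.frame with \code{familyId}, \code{nMembers},
#'   \code{meanMsrFraction}.
#' @export
msrFractionSummary <- function(annotations, family = NULL) {
  if (inherits(annotations, "MsrAnnotation")) annotations <- list(annotations)
  if (length(annotations) == 0L) stop("need at least one annotation")
  if (is.null(family)) family <- rep("family", length(annotations))
  frac <- vapply(annotations, msrFraction, 1)
  agg <- tapply(frac, family, mean)
  data.frame(familyId = names(agg),
             nMembers = as.integer(table(family)[names(agg)]),
             meanMsrFraction = as.numeric(agg), stringsAsFactors = FALSE,
             row.names = NULL)
}
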
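# Background amino-acid frequencies: Robinson & Robinson (1991) table as
# distributed with the NCBI toolkit, here normalized to sum exactly 1.
# The homogeneity calibration only requires strictly positive frequencies
# summing to 1; the table used is recorded in the ScoreModel metadata.
ROBINSON_FREQS <- c(
  A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295, F = 0.03856,
  G = 0.07377, H = 0.02199, I = 0.05142, K = 0.05744, L = 0.09019,
  M = 0.02243, N = 0.04487, P = 0.05203, Q = 0.04264, R = 0.05129,
  S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216)

normalizeFreqs <- function(freqs, warnTol = 1e-6) {
  freqs <- freqs[AA20]
  if (any(is.na(freqs)))
    stop("background frequency table must cover all 20 standard amino acids")
  if (any(freqs <= 0))
    stop("background frequencies must be strictly positive")
  s <- sum(freqs)
  if (abs(s - 1) > warnTol)
    warning(sprintf("background frequencies sum to %.6g; renormalizing to 1", s))
  freqs / s
}

#' Construct a ScoreModel
#'
#' @param scores symmetric numeric matrix whose dimnames cover the 20
#'   standard amino acids (extra rows/columns such as B, Z, X, * are
#'   dropped).
#' @param background named numeric vector of background frequencies over
#'   the 20 standard amino acids; renormalized to sum 1 (with a warning if
#'   it was off by more than 1e-6).
#' @param metadata list of provenance notes.
#' @return A \linkS4class{ScoreModel}.
#' @export
ScoreModel <- function(scores, background = ROBINSON_FREQS,
                       metadata = list()) {
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("score matrix must have amino-acid dimnames")
  missing <- setdiff(AA20, intersect(rownames(scores), colnames(scores)))
  if (length(missing))
    stop("score matrix is missing amino acid(s): ",
         paste(missing, collapse = ", "))
  scores <- scores[AA20, AA20, drop = FALSE]
  if (!isTRUE(all.equal(scores, t(scores), tolerance = 0)))
    stop("score matrix must be symmetric")
  storage.mode(scores) <- "double"
  new("ScoreModel", scores = scores, background = normalizeFreqs(background),
      metadata = metadata)
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-separated square matrix format in which BLOSUM
#' and PAM matrices are distributed (comment lines starting with
#' \code{#}, a header row of residue letters, one labeled row per
#' residue). Only the 20 standard amino acids are retained.
#'
#' @param path path to the matrix file.
#' @param freqsPath optional path to a two-column whitespace-separated
#'   table (amino acid, frequency). When absent the built-in Robinson &
#'   Robinson background table is used and recorded in the metadata.
#' @return A \linkS4class{ScoreModel}.
#' @examples
#' model <- blosum62ScoreModel()
#' scoreMatrix(model)["W", "W"]   # 11
#' @export
readScoreMatrix <- function(path, freqsPath = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("not a matrix file: ", path)
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  labels <- vapply(rows, `[[`, "", 1L)
  vals <- lapply(rows, function(r) suppressWarnings(as.numeric(r[-1])))
  if (any(vapply(vals, function(v) any(is.na(v)) ||
                 length(v) != length(header), TRUE)))
    stop("malformed matrix row(s) in ", path)
  M <- do.call(rbind, vals)
  dimnames(M) <- list(labels, header)
  missing <- setdiff(AA20, intersect(labels, header))
  if (length(missing))
    stop("matrix in ", path, " is missing amino acid(s): ",
         paste(missing, collapse = ", "))
  background <- ROBINSON_FREQS
  freqSource <- "built-in Robinson-Robinson (1991) table"
  if (!is.null(freqsPath)) {
    tab <- read.table(freqsPath, header = FALSE, col.names = c("aa", "freq"),
                      stringsAsFactors = FALSE)
    background <- setNames(tab$freq, tab$aa)
    freqSource <- freqsPath
  }
  ScoreModel(M, background,
             metadata = list(matrixSource = path,
                             frequencySource = freqSource))
}

#' @rdname readScoreMatrix
#' @export
blosum62ScoreModel <- function() {
  path <- system.file("extdata", "BLOSUM62.txt", package = "varcog",
                      mustWork = TRUE)
  model <- readScoreMatrix(path)
  model@metadata$matrixSource <- "built-in BLOSUM62 (half-bit units)"
  model
}

#' Accessors for ScoreModel
#'
#' @param x a \linkS4class{ScoreModel}.
#' @return \code{scoreMatrix}: the 20x20 numeric score matrix;
#'   \code{backgroundFreqs}: the named background frequency vector.
#' @name ScoreModel-accessors
NULL

#' @rdname ScoreModel-accessors
#' @export
setMethod("scoreMatrix", "ScoreModel", function(x) x@scores)

#' @rdname ScoreModel-accessors
#' @export
setMethod("backgroundFreqs", "ScoreModel", function(x) x@background)

setMethod("show", "ScoreModel", function(object) {
  cat("ScoreModel:", 20, "amino acids\n")
  if (!is.null(object@metadata$matrixSource))
    cat("  matrix:", object@metadata$matrixSource, "\n")
  if (!is.null(object@metadata$frequencySource))
    cat("  background:", object@metadata$frequencySource, "\n")
  cat("  score range: [", min(object@scores), ",", max(object@scores), "]\n")
})
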
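#' Clade-wide mean homogeneity
#'
#' Pools the scored columns of all family homogeneity profiles in a clade
#' and returns their arithmetic mean h_T, the normalization constant for
#' relative variability. By default every scored column counts equally
#' ("pooled"); \code{method = "mean-of-means"} averages the per-family
#' means instead.
#'
#' @param profiles list of \linkS4class{HomogeneityProfile} objects.
#' @param cladeId identifier for the clade.
#' @param method \code{"pooled"} (default) or \code{"mean-of-means"}.
#' @return A \linkS4class{CladeContext}.
#' @export
cladeMeanHomogeneity <- function(profiles, cladeId = "clade",
                                 method = c("pooled", "mean-of-means")) {
  method <- match.arg(method)
  if (inherits(profiles, "HomogeneityProfile")) profiles <- list(profiles)
  vals <- lapply(profiles, homogeneityValues)
  n <- vapply(vals, length, 1L)
  if (sum(n) == 0L)
    stop("no scored columns in any profile")
  hT <- if (method == "pooled") mean(unlist(vals))
        else mean(vapply(vals[n > 0], mean, 1))
  if (hT >= 1 || hT <= 0)
    stop(sprintf(paste0("degenerate clade mean homogeneity h_T = %g; ",
                        "relative variability requires 0 < h_T < 1"), hT))
  new("CladeContext", cladeId = cladeId, hT = hT,
      nFamilies = length(profiles), nColumnsTotal = sum(n),
      method = method)
}

setMethod("show", "CladeContext", function(object) {
  cat("CladeContext", object@cladeId, ": h_T =", round(object@hT, 5),
      "over", object@nColumnsTotal, "columns in", object@nFamilies,
      "families (", object@method, ")\n")
})

#' Relative variability
#'
#' v = (1 - h_C) h_T / ((1 - h_T) h_C): the family (or position) mean
#' homogeneity h_C rescaled by the clade-wide mean h_T so that a family of
#' exactly clade-average homogeneity has v = 1, an invariant family has
#' v = 0, and larger values mean higher variability.
#'
#' @param hC family or position homogeneity, in (0, 1]; 0 is allowed only
#'   when \code{zeroCap} is supplied and yields the capped sentinel.
#' @param hT clade mean homogeneity, strictly inside (0, 1) (scalar or a
#'   \linkS4class{CladeContext}).
#' @param zeroCap finite sentinel returned for h_C = 0 ("arbitrarily high
#'   variability"); \code{NULL} (default) makes h_C = 0 an error.
#' @return relative variability value(s), >= 0.
#' @examples
#' relativeVariability(0.7, 0.7)   # 1
#' relativeVariability(1.0, 0.8)   # 0
#' @export
relativeVariability <- function(hC, hT, zeroCap = NULL) {
  if (is(hT, "CladeContext")) hT <- hT@hT
  if (any(hT <= 0 | hT >= 1))
    stop("h_T must lie strictly inside (0, 1)")
  if (any(hC < 0 | hC > 1))
    stop("h_C must lie in [0, 1]")
  if (any(hC == 0) && is.null(zeroCap))
    stop("h_C = 0 has unbounded variability; supply zeroCap for a sentinel")
  v <- ifelse(hC == 0, if (is.null(zeroCap)) NA_real_ else zeroCap,
              (1 - hC) * hT / ((1 - hT) * hC))
  unname(v)
}

#' Variability class of a family or position
#'
#' Conserved below 0.5, variable above 2, intermediate in between
#' (boundary values 0.5 and 2 are intermediate: the outer classes are the
#' open intervals v < 0.5 and v > 2).
#'
#' @param v relative variability value(s), >= 0.
#' @return character vector over \code{c("conserved", "intermediate",
#'   "variable")}.
#' @export
classifyVariability <- function(v) {
  if (any(v < 0, na.rm = TRUE))
    stop("relative variability cannot be negative")
  ifelse(v < 0.5, "conserved", ifelse(v > 2, "variable", "intermediate"))
}

#' Position-level variability along one family profile
#'
#' Applies the relative-variability transform to every scored column's raw
#' (unsmoothed) homogeneity. Columns with h = 0 get a finite sentinel
#' (default 1e6, flagged), standing in for the arbitrarily high
#' variability of a column no better than random.
#'
#' @param profile a \linkS4class{HomogeneityProfile}.
#' @param ctx a \linkS4class{CladeContext} (or scalar h_T).
#' @param zeroCap sentinel for h = 0 columns (default 1e6).
#' @return data.frame with \code{column} (0-based index), \code{h},
#'   \code{v}, \code{varClass}, \code{sentinel} (logical).
#' @export
positionVariability <- function(profile, ctx, zeroCap = 1e6) {
  hT <- if (is(ctx, "CladeContext")) ctx@hT else ctx
  scored <- which(columnMask(profile) == "scored")
  h <- profile@h[scored]
  v <- relativeVariability(h, hT, zeroCap = zeroCap)
  data.frame(column = scored - 1L, h = h, v = v,
             varClass = classifyVariability(v), sentinel = h == 0,
             stringsAsFactors = FALSE)
}

#' Fractions of conserved / intermediate / variable positions
#'
#' @param varClass character vector of position classes (from
#'   \code{\link{positionVariability}}).
#' @return named numeric of length 3 summing to 1: \code{conserved},
#'   \code{intermediate}, \code{variable}.
#' @export
positionClassFractions <- function(varClass) {
  if (length(varClass) == 0L)
    stop("no scored positions")
  lv <- c("conserved", "intermediate", "variable")
  tab <- table(factor(varClass, levels = lv))
  setNames(as.numeric(tab) / length(varClass), lv)
}

#' Family-level variability record
#'
#' Bundles the family mean homogeneity h_C, its relative variability v_C,
#' the variability class, and the fractions of conserved / intermediate /
#' variable positions.
#'
#' @param profile a \linkS4class{HomogeneityProfile}.
#' @param ctx a \linkS4class{CladeContext}.
#' @param zeroCap sentinel for h = 0 (positions and, degenerately, h_C).
#' @return one-row data.frame: \code{familyId}, \code{nColumnsScored},
#'   \code{hC}, \code{vC}, \code{varClass}, \code{fConserved},
#'   \code{fIntermediate}, \code{fVariable}.
#' @export
familyVariability <- function(profile, ctx, zeroCap = 1e6) {
  hC <- meanHomogeneity(profile)
  vC <- relativeVariability(hC, ctx, zeroCap = zeroCap)
  pos <- positionVariability(profile, ctx, zeroCap = zeroCap)
  f <- positionClassFractions(pos$varClass)
  data.frame(familyId = familyId(profile), nColumnsScored = nrow(pos),
             hC = hC, vC = vC, varClass = classifyVariability(vC),
             fConserved = f[["conserved"]],
             fIntermediate = f[["intermediate"]],
             fVariable = f[["variable"]], stringsAsFactors = FALSE)
}

#' Bin genomic features of a csCOG
#'
#' Applies the feature discretization used for downstream association
#' analysis: paralogy (proteins per covered genome) into low [1, 1.25),
#' medium [1.25, 3), high [3, Inf); gain rate (summed gain total) into low
#' [0, 0.5), medium [0.5, 2), high [2, Inf); membrane / secreted flags set
#' when at least one third of the member proteins carry the predicted
#' feature.
#'
#' @param paralogy proteins-per-genome ratio (>= 1).
#' @param gainRate summed gain total (>= 0).
#' @param rootAncestral logical, family inferred present at the clade root.
#' @param fracTM fraction of members with predicted transmembrane segments.
#' @param fracSignal fraction of members with predicted signal peptides.
#' @return one-row data.frame: \code{paralogyBin}, \code{gainRateBin}
#'   (factors low/medium/high), \code{ancestral}, \code{membrane},
#'   \code{secreted}.
#' @export
binFeatures <- function(paralogy, gainRate, rootAncestral = NA,
                        fracTM = 0, fracSignal = 0) {
  if (any(paralogy < 1))
    stop("paralogy ratio cannot be below 1")
  if (any(gainRate < 0) || any(fracTM < 0 | fracTM > 1) ||
      any(fracSignal < 0 | fracSignal > 1))
    stop("gain rate must be >= 0 and fractions must lie in [0, 1]")
  lv <- c("low", "medium", "high")
  pBin <- cut(paralogy, c(1, 1.25, 3, Inf), labels = lv, right = FALSE,
              include.lowest = TRUE)
  gBin <- cut(gainRate, c(0, 0.5, 2, Inf), labels = lv, right = FALSE,
              include.lowest = TRUE)
  data.frame(paralogyBin = pBin, gainRateBin = gBin,
             ancestral = rootAncestral,
             membrane = fracTM >= 1 / 3, secreted = fracSignal >= 1 / 3)
}
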
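#' Gaussian-kernel smoothing of a homogeneity profile
#'
#' Smooths per-column homogeneity along the sequence with a Gaussian
#' kernel of bandwidth \code{b} (in alignment positions):
#' h'_i = sum_j h_j K_ij / sum_j K_ij with K_ij = exp(-((j - i) / b)^2).
#' The kernel is truncated at the profile ends; the normalization absorbs
#' the edge effect. Masked columns are excluded from the sums but keep
#' their place in the coordinate system, so smoothing respects true
#' column distances across masked stretches.
#'
#' @param h numeric homogeneity vector (NA for masked columns), or a
#'   \linkS4class{HomogeneityProfile}.
#' @param b kernel bandwidth in positions (default 20).
#' @return numeric vector of smoothed values at the scored positions (same
#'   length as the scored part of the input).
#' @export
smoothProfile <- function(h, b = 20) {
  if (is(h, "HomogeneityProfile")) h <- homogeneityValues(h, scoredOnly = FALSE)
  if (b <= 0) stop("bandwidth must be positive")
  pos <- which(!is.na(h))
  if (length(pos) == 0L) stop("empty profile")
  x <- h[pos]
  if (length(pos) == 1L) return(x)
  K <- exp(-((outer(pos, pos, "-")) / b)^2)
  as.numeric(K %*% x / rowSums(K))
}

#' Density of smoothed homogeneity values on the fixed 101-point grid
#'
#' Gaussian kernel density estimate of the smoothed column homogeneities,
#' evaluated at 101 equidistant points on [0, 1], with boundary reflection
#' at 0 and 1 (homogeneity cannot leave the unit interval) and
#' renormalized to unit mass on the grid. The KDE bandwidth follows
#' Silverman's rule of thumb; when all values coincide the density
#' degenerates to a unit spike at the nearest grid point.
#'
#' @param values numeric vector of (smoothed) homogeneity values in
#'   [0, 1], or a \linkS4class{HomogeneityProfile} (smoothed with the
#'   default bandwidth first).
#' @param familyId identifier attached to the result.
#' @param gridSize number of grid points (default 101).
#' @param bw kernel bandwidth; default \code{"silverman"}.
#' @return A \linkS4class{HomogeneityDensity}.
#' @export
estimateDensity <- function(values, familyId = "family", gridSize = 101L,
                            bw = "silverman") {
  if (is(values, "HomogeneityProfile")) {
    familyId <- familyId(values)
    values <- smoothProfile(values)
  }
  values <- values[!is.na(values)]
  if (length(values) < 1L) stop("no values to estimate a density from")
  grid <- seq(0, 1, length.out = gridSize)
  if (identical(bw, "silverman")) {
    n <- length(values)
    spread <- c(sd(values),
                diff(quantile(values, c(0.25, 0.75), names = FALSE)) / 1.34)
    spread <- spread[is.finite(spread) & spread > 0]
    bw <- if (length(spread)) 0.9 * min(spread) * n^(-1 / 5) else 0
  }
  if (!is.finite(bw) || bw <= 0 || sd(values) == 0) {
    # degenerate: all values (effectively) identical -> single-bin spike
    mass <- numeric(gridSize)
    mass[which.min(abs(grid - mean(values)))] <- 1
    meta <- list(estimator = "degenerate-spike", bw = 0, n = length(values))
  } else {
    dens <- vapply(grid, function(g) {
      sum(dnorm(g - values, sd = bw) +        # direct
          dnorm(g + values, sd = bw) +        # reflected at 0
          dnorm(g - (2 - values), sd = bw))   # reflected at 1
    }, numeric(1))
    mass <- dens / sum(dens)
    meta <- list(estimator = "gaussian-kde-reflected", bw = bw,
                 n = length(values))
  }
  new("HomogeneityDensity", familyId = familyId, grid = grid, mass = mass,
      metadata = meta)
}

setMethod("show", "HomogeneityDensity", function(object) {
  cat("HomogeneityDensity", object@familyId, ":", length(object@grid),
      "grid points, mode at h =",
      round(object@grid[which.max(object@mass)], 3), "\n")
})

#' Hellinger distance between two homogeneity densities
#'
#' Discrete Hellinger distance d = sqrt(1 - sum_i sqrt(p_i q_i)) on the
#' shared grid (the Bhattacharyya form on unit-mass grid vectors), bounded
#' in [0, 1]: 0 for identical distributions, 1 for disjoint supports.
#'
#' @param p,q \linkS4class{HomogeneityDensity} objects on identical grids,
#'   or bare unit-mass numeric vectors of equal length.
#' @return distance in [0, 1].
#' @export
hellingerDistance <- function(p, q) {
  if (is(p, "HomogeneityDensity") && is(q, "HomogeneityDensity")) {
    if (length(p@grid) != length(q@grid) ||
        max(abs(p@grid - q@grid)) > 1e-12)
      stop("densities must share the same grid")
    p <- p@mass; q <- q@mass
  }
  if (length(p) != length(q)) stop("densities must share the same grid")
  bc <- sum(sqrt(pmax(p, 0) * pmax(q, 0)))
  sqrt(max(1 - bc, 0))
}

#' All pairwise Hellinger distances
#'
#' @param densities list of \linkS4class{HomogeneityDensity} objects on a
#'   common grid.
#' @return symmetric numeric matrix with zero diagonal, dimnames from the
#'   family ids.
#' @export
hellingerDistanceMatrix <- function(densities) {
  n <- length(densities)
  ids <- vapply(densities, function(d) d@familyId, "")
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(D)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      D[i, j] <- D[j, i] <- hellingerDistance(densities[[i]],
                                              densities[[j]])
  D
}

#' Classical multidimensional scaling of a family distance matrix
#'
#' Torgerson scaling: double-centers the squared distances and embeds the
#' families on the leading positive eigenvectors (R's \code{cmdscale}).
#' Negative eigenvalues (non-Euclidean part of the distances) are
#' truncated and returned for inspection.
#'
#' @param D symmetric non-negative distance matrix with zero diagonal.
#' @param dims target dimensionality (default 2).
#' @return list with \code{coordinates} (n x dims matrix, column means
#'   zero; zero-padded if fewer positive eigenvalues than \code{dims})
#'   and \code{eigenvalues} (all n of them, decreasing).
#' @export
classicalMDS <- function(D, dims = 2L) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
    stop("distance matrix must be symmetric")
  if (any(diag(D) != 0) || any(D < 0))
    stop("distance matrix must be non-negative with zero diagonal")
  fit <- cmdscale(D, k = min(dims, nrow(D) - 1L), eig = TRUE)
  coords <- fit$points
  if (is.null(dim(coords)) || ncol(coords) < dims) {
    pad <- matrix(0, nrow(D), dims - NCOL(coords))
    coords <- cbind(coords, pad)
  }
  coords <- coords[, seq_len(dims), drop = FALSE]
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("dim", seq_len(dims))
  list(coordinates = coords, eigenvalues = fit$eig)
}
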
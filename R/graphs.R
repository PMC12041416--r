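#' Build the spatial proximity graph
#'
#' Connects every pair of distinct spots whose Euclidean distance is at most
#' \code{radius}, giving a binary symmetric adjacency. Typical radii are
#' platform presets: 560 for Visium DLPFC-style slides in full-resolution
#' pixel units, 15 for the other platforms, and ~1.5 on the simulator's
#' unit-spaced lattice (8-neighborhood).
#'
#' @param coords spot-by-2 coordinate matrix (or a
#'   \linkS4class{SpatialSlide}, whose coordinates are used).
#' @param radius neighborhood radius in the units of \code{coords}; must be
#'   positive.
#' @return a \linkS4class{SpotGraph}.
#' @examples
#' g <- buildSpatialGraph(cbind(rep(1:3, 3), rep(1:3, each = 3)), 1.0)
#' edgeCount(g)  # 12: rook adjacency of the 3 x 3 grid
#' @export
buildSpatialGraph <- function(coords, radius) {
  if (is(coords, "SpatialSlide")) coords <- spatialCoords(coords)
  coords <- as.matrix(coords)
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("radius must be a positive number")
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  A <- (D <= radius)
  diag(A) <- FALSE
  adj <- as(Matrix::Matrix(A * 1, sparse = TRUE), "CsparseMatrix")
  if (any(Matrix::rowSums(adj) == 0))
    warning(sprintf("%d spot(s) have no spatial neighbor at radius %g",
                    sum(Matrix::rowSums(adj) == 0), radius))
  SpotGraph(adj)
}

# cosine similarity matrix of rows of X; zero rows get similarity -1
cosineSimilarity <- function(X) {
  nrm <- sqrt(rowSums(X * X))
  zero <- nrm == 0
  if (any(zero)) warning(sprintf(
    "%d spot(s) have zero expression norm; cosine treated as -1", sum(zero)))
  Y <- X / ifelse(nrm > 0, nrm, 1)
  S <- tcrossprod(Y)
  S[zero, ] <- -1
  S[, zero] <- -1
  S
}

#' Build the expression-similarity (feature) graph
#'
#' Each spot is linked to its \code{k} nearest neighbors by cosine
#' similarity of expression profiles; the directed k-nearest-neighbor
#' relation is then symmetrized by union and stored with binary weights
#' (cosine ranks the neighbors, it does not weight the edges). Ties resolve
#' toward the lower spot index.
#'
#' @param X spot-by-gene expression matrix (normalized), or a
#'   \linkS4class{SpatialSlide} whose encoder input is used.
#' @param k neighbors per spot; \code{1 <= k < N}.
#' @return a \linkS4class{SpotGraph}.
#' @export
buildFeatureGraph <- function(X, k = 15) {
  if (is(X, "SpatialSlide")) X <- encoderInput(X)
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < N")
  S <- cosineSimilarity(X)
  diag(S) <- -Inf
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(n)) {
    nb <- order(-S[i, ], seq_len(n))[seq_len(k)]
    ii <- c(ii, rep.int(i, k)); jj <- c(jj, nb)
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  A <- ((A + Matrix::t(A)) > 0) * 1      # union symmetrization, binary
  SpotGraph(as(A, "CsparseMatrix"))
}

#' Initialize an adaptive adjacency on a base graph's pattern
#'
#' The learnable adjacency shares the base graph's sparsity pattern plus all
#' self-loops (so the diagonal of the self-loop-augmented propagation matrix
#' can also be rescaled). Weights start at 1, which makes the initial
#' adaptive propagation identical to the standard symmetric-normalized
#' propagation; training then updates them freely by gradient descent while
#' the pattern stays fixed.
#'
#' @param base a symmetric \linkS4class{SpotGraph}.
#' @return an \linkS4class{AdaptiveGraph} with all values 1.
#' @export
initAdaptiveGraph <- function(base) {
  stopifnot(is(base, "SpotGraph"))
  n <- nrow(base@adjacency)
  tr <- Matrix::summary(as(as(base@adjacency + Matrix::Diagonal(n),
                              "generalMatrix"), "CsparseMatrix"))
  new("AdaptiveGraph", n = as.integer(n), i = as.integer(tr$i),
      j = as.integer(tr$j), values = rep(1, nrow(tr)))
}

#' Symmetric-normalized propagation matrix
#'
#' Computes \eqn{\tilde D^{-1/2} \tilde A \tilde D^{-1/2}} with
#' \eqn{\tilde A = A + I} and \eqn{\tilde D} its diagonal degree matrix —
#' the constant propagation operator of the graph convolution layers.
#'
#' @param graph a \linkS4class{SpotGraph}.
#' @return sparse symmetric matrix with self-loops.
#' @export
normalizedAdjacency <- function(graph) {
  A <- graph@adjacency
  n <- nrow(A)
  At <- A + Matrix::Diagonal(n)
  d <- Matrix::rowSums(At)
  Dm <- Matrix::Diagonal(n, 1 / sqrt(d))
  as(Dm %*% At %*% Dm, "CsparseMatrix")
}

# normalization coefficient of each stored (i, j) index of an AdaptiveGraph
adaptiveNormCoefficients <- function(ag, base) {
  S <- normalizedAdjacency(base)
  as.vector(S[cbind(ag@i, ag@j)])
}
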
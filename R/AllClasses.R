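#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal rowSums colSums t crossprod
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SingleCellExperiment SingleCellExperiment reducedDim
#' @importFrom SummarizedExperiment assay assay<- assayNames colData colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' SpatialSlide: a spatial transcriptomics slide
#'
#' Extends \linkS4class{SingleCellExperiment} (genes in rows, spots in
#' columns) with planar spot coordinates. Optional columns of
#' \code{colData}: \code{in_tissue} (logical capture-area flag) and
#' \code{domain} (reference domain labels used for evaluation).
#'
#' @slot spatialCoords numeric matrix with one row per spot and two columns
#'   (platform units).
#'
#' @export
setClass("SpatialSlide",
         contains = "SingleCellExperiment",
         slots = c(spatialCoords = "matrix"))

setValidity("SpatialSlide", function(object) {
  msg <- NULL
  sc <- object@spatialCoords
  if (nrow(sc) != ncol(object))
    msg <- c(msg, "spatialCoords must have one row per spot")
  if (ncol(sc) != 2L)
    msg <- c(msg, "spatialCoords must have exactly 2 columns")
  if (nrow(sc) > 0 && !all(is.finite(sc)))
    msg <- c(msg, "spatialCoords must be finite")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate spot identifiers")
  if ("counts" %in% SummarizedExperiment::assayNames(object)) {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a SpatialSlide
#'
#' @param counts gene-by-spot count matrix (dense or \code{Matrix} sparse);
#'   non-negative integers.
#' @param coords spot-by-2 coordinate matrix, rows aligned with the columns
#'   of \code{counts}.
#' @param in_tissue optional logical vector flagging spots inside the
#'   capture area; defaults to all \code{TRUE}.
#' @param domain optional reference domain labels (factor/character/integer).
#' @param spot_ids,gene_ids optional identifiers; default to the dimnames of
#'   \code{counts} or generated names.
#'
#' @return A \linkS4class{SpatialSlide}.
#' @examples
#' cts <- matrix(rpois(50, 2), nrow = 10,
#'               dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
#' xy <- cbind(x = 1:5, y = rep(1, 5))
#' SpatialSlide(cts, xy)
#' @export
SpatialSlide <- function(counts, coords, in_tissue = NULL, domain = NULL,
                         spot_ids = NULL, gene_ids = NULL) {
  counts <- as(counts, "CsparseMatrix")
  if (is.null(spot_ids)) spot_ids <- colnames(counts)
  if (is.null(spot_ids)) spot_ids <- sprintf("spot%04d", seq_len(ncol(counts)))
  if (is.null(gene_ids)) gene_ids <- rownames(counts)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%04d", seq_len(nrow(counts)))
  dimnames(counts) <- list(gene_ids, spot_ids)
  coords <- as.matrix(coords)
  if (nrow(coords) != ncol(counts))
    stop("coords must have one row per spot (column of counts)")
  colnames(coords) <- c("x", "y")
  rownames(coords) <- spot_ids
  cd <- S4Vectors::DataFrame(row.names = spot_ids)
  cd$in_tissue <- if (is.null(in_tissue)) rep(TRUE, ncol(counts))
                  else as.logical(in_tissue)
  if (!is.null(domain)) cd$domain <- domain
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd)
  new("SpatialSlide", sce, spatialCoords = coords)
}

#' SpotGraph: sparse symmetric adjacency over spots
#'
#' Holds a binary (or weighted) symmetric adjacency with an empty diagonal;
#' self-loops are added only at propagation time through \eqn{\tilde A = A + I}.
#'
#' @slot adjacency symmetric \code{dgCMatrix}, zero diagonal.
#' @export
setClass("SpotGraph", slots = c(adjacency = "Matrix"))

setValidity("SpotGraph", function(object) {
  A <- object@adjacency
  msg <- NULL
  if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency must be square")
  if (any(Matrix::diag(A) != 0)) msg <- c(msg, "self-loops are not stored")
  if (!Matrix::isSymmetric(A)) msg <- c(msg, "adjacency must be symmetric")
  if (is.null(msg)) TRUE else msg
})

SpotGraph <- function(adjacency) {
  # store in general (dgC) form: symmetric-storage classes expose only one
  # triangle to triplet extraction, which would halve every edge pattern
  adjacency <- as(as(as(adjacency, "CsparseMatrix"), "generalMatrix"),
                  "CsparseMatrix")
  dimnames(adjacency) <- NULL
  new("SpotGraph", adjacency = Matrix::drop0(adjacency))
}

#' AdaptiveGraph: learnable per-edge weights on a fixed sparsity pattern
#'
#' The pattern is the edge set of a base \linkS4class{SpotGraph} plus all
#' self-loops; the values are free parameters updated during training (all
#' 1 at initialization, so the initial propagation equals the standard
#' normalized propagation).
#'
#' @slot n number of spots.
#' @slot i,j 1-based indices of the stored (directed) entries.
#' @slot values numeric weights, one per stored index.
#' @export
setClass("AdaptiveGraph",
         slots = c(n = "integer", i = "integer", j = "integer",
                   values = "numeric"))

setValidity("AdaptiveGraph", function(object) {
  msg <- NULL
  if (length(object@i) != length(object@j) ||
      length(object@i) != length(object@values))
    msg <- c(msg, "i, j and values must have equal length")
  if (length(object@i) &&
      (min(object@i, object@j) < 1L || max(object@i, object@j) > object@n))
    msg <- c(msg, "indices out of range")
  if (is.null(msg)) TRUE else msg
})

#' SGFModel: a trained multi-view graph fusion model
#'
#' @slot params named list of trained parameter matrices (encoder weights,
#'   adaptive edge values, fusion head, decoder heads).
#' @slot config the training configuration used (see \code{\link{sgfConfig}}).
#' @slot embedding final fused spot embedding (spots x d).
#' @slot viewEmbeddings list with the five view embeddings Hs, Hf, Hsj,
#'   Hfj, Hj.
#' @slot attention per-spot attention coefficients over the joint, spatial
#'   and feature views (spots x 3, rows on the simplex).
#' @slot lossTrace data.frame of per-epoch component and total losses.
#' @slot graphs list with the spatial and feature \linkS4class{SpotGraph}s
#'   and the trained \linkS4class{AdaptiveGraph}s.
#' @slot zinb list with the decoder output matrices mu, theta, pi
#'   (spots x genes).
#' @export
setClass("SGFModel",
         slots = c(params = "list", config = "list", embedding = "matrix",
                   viewEmbeddings = "list", attention = "matrix",
                   lossTrace = "data.frame", graphs = "list", zinb = "list"))
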
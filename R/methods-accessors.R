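#' @describeIn spatialCoords coordinates of a slide
#' @export
setMethod("spatialCoords", "SpatialSlide", function(x) x@spatialCoords)

#' @rdname spatialCoords
#' @export
setReplaceMethod("spatialCoords", "SpatialSlide", function(x, value) {
  x@spatialCoords <- as.matrix(value)
  validObject(x)
  x
})

#' @describeIn inTissue flags of a slide
#' @export
setMethod("inTissue", "SpatialSlide", function(x) {
  it <- SummarizedExperiment::colData(x)$in_tissue
  if (is.null(it)) rep(TRUE, ncol(x)) else it
})

#' @describeIn domainLabels labels of a slide
#' @export
setMethod("domainLabels", "SpatialSlide", function(x)
  SummarizedExperiment::colData(x)$domain)

#' @rdname domainLabels
#' @export
setReplaceMethod("domainLabels", "SpatialSlide", function(x, value) {
  SummarizedExperiment::colData(x)$domain <- value
  x
})

#' @describeIn adjacencyMatrix of a SpotGraph
#' @export
setMethod("adjacencyMatrix", "SpotGraph", function(x) x@adjacency)

#' @describeIn adjacencyMatrix of an AdaptiveGraph (weights on the stored
#'   pattern, self-loops included)
#' @export
setMethod("adjacencyMatrix", "AdaptiveGraph", function(x)
  Matrix::sparseMatrix(i = x@i, j = x@j, x = x@values, dims = c(x@n, x@n)))

#' @describeIn edgeCount undirected edge count
#' @export
setMethod("edgeCount", "SpotGraph", function(x)
  as.integer(Matrix::nnzero(x@adjacency) / 2))

#' @describeIn adaptiveValues weights of an AdaptiveGraph
#' @export
setMethod("adaptiveValues", "AdaptiveGraph", function(x) x@values)

#' @describeIn embedding embedding of an SGFModel
#' @export
setMethod("embedding", "SGFModel", function(x) x@embedding)

#' @describeIn lossTrace trace of an SGFModel
#' @export
setMethod("lossTrace", "SGFModel", function(x) x@lossTrace)

#' @describeIn attentionCoefficients coefficients of an SGFModel
#' @export
setMethod("attentionCoefficients", "SGFModel", function(x) x@attention)

#' @describeIn SpatialSlide subsetting keeps coordinates aligned with spots
#' @param x,i,j,...,drop standard matrix-style subsetting arguments.
#' @export
setMethod("[", "SpatialSlide", function(x, i, j, ..., drop = TRUE) {
  out <- callNextMethod()
  if (!missing(j))
    out@spatialCoords <- x@spatialCoords[j, , drop = FALSE]
  out
})

setMethod("show", "SpatialSlide", function(object) {
  cat(sprintf("SpatialSlide: %d genes x %d spots (%d in tissue)\n",
              nrow(object), ncol(object), sum(inTissue(object))))
  lab <- domainLabels(object)
  if (!is.null(lab))
    cat(sprintf("  reference domains: %d\n", length(unique(lab))))
  callNextMethod()
})

setMethod("show", "SpotGraph", function(object) {
  n <- nrow(object@adjacency)
  m <- edgeCount(object)
  cat(sprintf("SpotGraph: %d spots, %d undirected edges (mean degree %.2f)\n",
              n, m, if (n > 0) 2 * m / n else 0))
})

setMethod("show", "AdaptiveGraph", function(object) {
  cat(sprintf(
    "AdaptiveGraph: %d spots, %d stored indices, value range [%.3g, %.3g]\n",
    object@n, length(object@values),
    if (length(object@values)) min(object@values) else NA,
    if (length(object@values)) max(object@values) else NA))
})

setMethod("show", "SGFModel", function(object) {
  cat(sprintf("SGFModel: %d spots, embedding dimension %d\n",
              nrow(object@embedding), ncol(object@embedding)))
  lt <- object@lossTrace
  if (nrow(lt) > 0)
    cat(sprintf("  trained %d epochs; total loss %.4f -> %.4f\n",
                nrow(lt), lt$total[1], lt$total[nrow(lt)]))
})
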
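#' Spot coordinates of a slide
#'
#' @param x a \linkS4class{SpatialSlide}.
#' @return numeric matrix (spots x 2).
#' @export
setGeneric("spatialCoords", function(x) standardGeneric("spatialCoords"))

#' @rdname spatialCoords
#' @param value replacement coordinate matrix.
#' @export
setGeneric("spatialCoords<-",
           function(x, value) standardGeneric("spatialCoords<-"))

#' In-tissue flags of a slide
#' @param x a \linkS4class{SpatialSlide}.
#' @return logical vector, one element per spot.
#' @export
setGeneric("inTissue", function(x) standardGeneric("inTissue"))

#' Reference domain labels attached to a slide
#' @param x a \linkS4class{SpatialSlide}.
#' @return label vector or \code{NULL} when no labels are attached.
#' @export
setGeneric("domainLabels", function(x) standardGeneric("domainLabels"))

#' @rdname domainLabels
#' @param value replacement labels.
#' @export
setGeneric("domainLabels<-",
           function(x, value) standardGeneric("domainLabels<-"))

#' Adjacency matrix of a spot graph
#' @param x a \linkS4class{SpotGraph} or \linkS4class{AdaptiveGraph}.
#' @return a sparse symmetric matrix.
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' Number of undirected edges of a spot graph
#' @param x a \linkS4class{SpotGraph}.
#' @return integer edge count (each undirected edge counted once).
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' Adaptive edge weights
#' @param x an \linkS4class{AdaptiveGraph}.
#' @return numeric vector of per-index weights.
#' @export
setGeneric("adaptiveValues", function(x) standardGeneric("adaptiveValues"))

#' Final fused embedding of a trained model
#' @param x an \linkS4class{SGFModel}.
#' @return numeric matrix (spots x d).
#' @export
setGeneric("embedding", function(x) standardGeneric("embedding"))

#' Per-epoch loss trace of a trained model
#' @param x an \linkS4class{SGFModel}.
#' @return data.frame with columns epoch, zinb, consistency, spatial, total.
#' @export
setGeneric("lossTrace", function(x) standardGeneric("lossTrace"))

#' Attention coefficients of a trained model
#' @param x an \linkS4class{SGFModel}.
#' @return matrix (spots x 3) with columns joint, spatial, feature.
#' @export
setGeneric("attentionCoefficients",
           function(x) standardGeneric("attentionCoefficients"))
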
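#' Drop spots outside the capture area
#'
#' Spots flagged \code{in_tissue = FALSE} (off-tissue background positions)
#' are removed; counts, coordinates and identifiers are subset consistently
#' and spot order is preserved. Slides without the flag are returned
#' unchanged (all spots treated as in tissue).
#'
#' @param slide a \linkS4class{SpatialSlide}.
#' @return the filtered \linkS4class{SpatialSlide}.
#' @export
filterSpots <- function(slide) {
  stopifnot(is(slide, "SpatialSlide"))
  keep <- inTissue(slide)
  if (!any(keep)) stop("all spots are outside the tissue area")
  slide[, keep]
}

#' Rank genes by mean-binned normalized dispersion
#'
#' Expression is first depth-normalized per spot (counts scaled to a common
#' total), then each gene's dispersion (variance/mean) is z-scored within 20
#' bins of genes of similar mean expression, so that highly variable genes
#' are those unusually dispersed for their expression level. Ties and
#' degenerate bins resolve toward the lower gene index, making the ranking
#' deterministic.
#'
#' @param slide a \linkS4class{SpatialSlide}.
#' @param n_top number of genes to keep (all genes kept when fewer exist).
#' @param n_bins number of mean-expression bins for dispersion
#'   normalization.
#' @return the slide restricted to the selected genes, original gene order
#'   preserved.
#' @export
selectHVG <- function(slide, n_top = 3000, n_bins = 20) {
  stopifnot(is(slide, "SpatialSlide"), n_top >= 1)
  cts <- SummarizedExperiment::assay(slide, "counts")
  M <- nrow(cts)
  if (M <= n_top) return(slide)
  tot <- Matrix::colSums(cts)
  sf <- ifelse(tot > 0, 1e4 / tot, 0)
  Xn <- t(t(cts) * sf)                      # depth-normalized, genes x spots
  mu <- Matrix::rowMeans(Xn)
  v <- Matrix::rowMeans(Xn^2) - mu^2
  v <- v * ncol(Xn) / max(1, ncol(Xn) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  if (all(v == 0)) {
    warning("all genes have zero variance; ranking by total count")
    score <- Matrix::rowSums(cts)
  } else {
    n_bins <- max(1L, min(as.integer(n_bins), M %/% 5L))  # >=5 genes/bin
    bins <- cut(rank(mu, ties.method = "first"),
                breaks = n_bins, labels = FALSE)
    bm <- tapply(disp, bins, mean)
    bs <- tapply(disp, bins, stats::sd)
    bs[is.na(bs) | bs == 0] <- 1
    score <- (disp - bm[bins]) / bs[bins]
  }
  ord <- order(-score, seq_len(M))          # tie-break: lower gene index
  keep <- sort(ord[seq_len(n_top)])
  slide[keep, ]
}

#' Depth-normalize expression to a fixed per-spot total
#'
#' Each spot's counts are scaled so they sum to \code{scale_factor}
#' (10000 by default), the standard library-size normalization
#' \eqn{x_{ij} = 10^4 \, c_{ij} / \sum_j c_{ij}}. Spots with zero total
#' count are dropped with a warning. When \code{log1p = TRUE} a
#' \code{log(1+x)} transform is applied on top and stored as the
#' \code{"logexpr"} assay; the untransformed matrix is always stored as
#' \code{"normexpr"}. Raw counts are retained for the reconstruction
#' likelihood.
#'
#' @param slide a \linkS4class{SpatialSlide}.
#' @param scale_factor target per-spot total after scaling.
#' @param log1p whether to add the log-transformed assay.
#' @return the slide with added assays.
#' @export
normalizeCounts <- function(slide, scale_factor = 1e4, log1p = TRUE) {
  stopifnot(is(slide, "SpatialSlide"))
  cts <- SummarizedExperiment::assay(slide, "counts")
  tot <- Matrix::colSums(cts)
  if (any(tot == 0)) {
    warning(sprintf("dropping %d spot(s) with zero total count",
                    sum(tot == 0)))
    slide <- slide[, tot > 0]
    cts <- SummarizedExperiment::assay(slide, "counts")
    tot <- tot[tot > 0]
  }
  Xn <- t(t(cts) * (scale_factor / tot))
  SummarizedExperiment::assay(slide, "normexpr") <- Xn
  if (log1p)
    SummarizedExperiment::assay(slide, "logexpr") <- log1p(Xn)
  slide
}

#' Full preprocessing pipeline
#'
#' Off-tissue filtering, highly-variable-gene selection and depth
#' normalization in sequence. The result carries the raw HVG counts (for
#' the count-model decoder) alongside the normalized/log expression that
#' feeds the graph encoder.
#'
#' @inheritParams selectHVG
#' @inheritParams normalizeCounts
#' @return the processed \linkS4class{SpatialSlide}.
#' @examples
#' sl <- simulateSlide(sgfSimConfig(grid_side = 5, n_genes = 30))
#' sl <- preprocessSlide(sl, n_top = 20)
#' SummarizedExperiment::assayNames(sl)
#' @export
preprocessSlide <- function(slide, n_top = 3000, scale_factor = 1e4,
                            log1p = TRUE) {
  slide <- filterSpots(slide)
  slide <- selectHVG(slide, n_top = n_top)
  normalizeCounts(slide, scale_factor = scale_factor, log1p = log1p)
}

# spots x genes dense matrix of the encoder input
encoderInput <- function(slide) {
  an <- SummarizedExperiment::assayNames(slide)
  nm <- if ("logexpr" %in% an) "logexpr" else
        if ("normexpr" %in% an) "normexpr" else "counts"
  as.matrix(t(SummarizedExperiment::assay(slide, nm)))
}

# spots x genes dense matrix of raw counts (ZINB target)
rawCounts <- function(slide)
  as.matrix(t(SummarizedExperiment::assay(slide, "counts")))
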
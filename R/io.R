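## Readers and writers for the interchange formats: 10x-style matrix
## directories, CSV fallbacks, edge lists, label tables and metric reports.

findFile <- function(dir, names) {
  for (nm in names) {
    for (sub in c("", "spatial", "filtered_feature_bc_matrix")) {
      p <- file.path(dir, sub, nm)
      if (file.exists(p)) return(p)
    }
  }
  NULL
}

readTable <- function(path, ...) {
  if (endsWith(path, ".gz"))
    utils::read.table(gzfile(path), ...)
  else utils::read.table(path, ...)
}

#' Read a Visium-style matrix directory
#'
#' Expects \code{matrix.mtx[.gz]}, \code{features.tsv[.gz]} (or
#' \code{genes.tsv}), \code{barcodes.tsv[.gz]} and a tissue-positions CSV
#' (\code{tissue_positions.csv} with header, or
#' \code{tissue_positions_list.csv} without), searched in the directory
#' itself and the usual \code{spatial/} subdirectory. Pixel coordinates
#' become the spot coordinates (x = column, y = row); the
#' \code{in_tissue} column is carried over. A \code{labels.csv}
#' (spot_id,label), if present, is attached as reference domains.
#'
#' @param dir path to the directory.
#' @return a \linkS4class{SpatialSlide}.
#' @export
readVisium <- function(dir) {
  if (!dir.exists(dir)) stop("input directory does not exist: ", dir)
  mtx <- findFile(dir, c("matrix.mtx", "matrix.mtx.gz"))
  feat <- findFile(dir, c("features.tsv", "features.tsv.gz",
                          "genes.tsv", "genes.tsv.gz"))
  bc <- findFile(dir, c("barcodes.tsv", "barcodes.tsv.gz"))
  pos <- findFile(dir, c("tissue_positions.csv", "tissue_positions.csv.gz",
                         "tissue_positions_list.csv",
                         "tissue_positions_list.csv.gz"))
  if (is.null(mtx) || is.null(feat) || is.null(bc))
    stop("matrix.mtx / features.tsv / barcodes.tsv not found under ", dir)
  if (is.null(pos)) stop("tissue positions file not found under ", dir)
  counts <- as(Matrix::readMM(mtx), "CsparseMatrix")
  features <- readTable(feat, sep = "\t", header = FALSE,
                        stringsAsFactors = FALSE)
  barcodes <- readTable(bc, sep = "\t", header = FALSE,
                        stringsAsFactors = FALSE)[, 1]
  gene_ids <- make.unique(as.character(
    features[, min(2, ncol(features))]))
  has_header <- grepl("tissue_positions.csv", pos, fixed = TRUE)
  tp <- readTable(pos, sep = ",", header = has_header,
                  stringsAsFactors = FALSE)
  colnames(tp) <- c("barcode", "in_tissue", "array_row", "array_col",
                    "pxl_row", "pxl_col")[seq_len(ncol(tp))]
  tp <- tp[match(barcodes, tp$barcode), ]
  if (anyNA(tp$barcode))
    stop("tissue positions are missing some matrix barcodes")
  slide <- SpatialSlide(counts,
                        coords = cbind(x = tp$pxl_col, y = tp$pxl_row),
                        in_tissue = tp$in_tissue == 1,
                        spot_ids = barcodes, gene_ids = gene_ids)
  lab <- findFile(dir, c("labels.csv"))
  if (!is.null(lab)) {
    lt <- utils::read.csv(lab, stringsAsFactors = FALSE)
    domainLabels(slide) <- lt[match(barcodes, lt[, 1]), 2]
  }
  slide
}

#' Write a slide as a Visium-style directory
#'
#' Emits \code{matrix.mtx}, \code{features.tsv}, \code{barcodes.tsv},
#' \code{tissue_positions.csv} and, when labels are attached,
#' \code{labels.csv} — the same layout \code{\link{readVisium}} accepts,
#' so simulated slides round-trip through the standard reader.
#'
#' @param slide a \linkS4class{SpatialSlide}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeVisium <- function(slide, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cts <- SummarizedExperiment::assay(slide, "counts")
  Matrix::writeMM(as(cts, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(id = rownames(cts), name = rownames(cts),
               type = "Gene Expression"),
    file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  writeLines(colnames(cts), file.path(dir, "barcodes.tsv"))
  sc <- spatialCoords(slide)
  utils::write.csv(
    data.frame(barcode = colnames(cts),
               in_tissue = as.integer(inTissue(slide)),
               array_row = sc[, "y"], array_col = sc[, "x"],
               pxl_row = sc[, "y"], pxl_col = sc[, "x"]),
    file.path(dir, "tissue_positions.csv"), row.names = FALSE,
    quote = FALSE)
  lab <- domainLabels(slide)
  if (!is.null(lab))
    utils::write.csv(data.frame(spot_id = colnames(cts), label = lab),
                     file.path(dir, "labels.csv"), row.names = FALSE,
                     quote = FALSE)
  invisible(dir)
}

#' Read a slide from plain CSV files
#'
#' @param counts_csv spots x genes count table; first column spot ids,
#'   header gene ids.
#' @param coords_csv table with columns spot_id, x, y.
#' @param labels_csv optional table with columns spot_id, label.
#' @return a \linkS4class{SpatialSlide}.
#' @export
readSlideCSV <- function(counts_csv, coords_csv, labels_csv = NULL) {
  if (!file.exists(counts_csv)) stop("counts file not found: ", counts_csv)
  if (!file.exists(coords_csv)) stop("coords file not found: ", coords_csv)
  cts <- utils::read.csv(counts_csv, row.names = 1, check.names = FALSE)
  xy <- utils::read.csv(coords_csv, stringsAsFactors = FALSE)
  xy <- xy[match(rownames(cts), xy[, 1]), ]
  if (anyNA(xy[, 1])) stop("coords are missing some spots")
  slide <- SpatialSlide(Matrix::t(Matrix::Matrix(as.matrix(cts),
                                                 sparse = TRUE)),
                        coords = as.matrix(xy[, 2:3]),
                        spot_ids = rownames(cts))
  if (!is.null(labels_csv)) {
    lt <- utils::read.csv(labels_csv, stringsAsFactors = FALSE)
    domainLabels(slide) <- lt[match(rownames(cts), lt[, 1]), 2]
  }
  slide
}

#' Export / import a graph as a 0-based edge-list text file
#'
#' Three whitespace-separated columns: i, j, weight, with 0-based indices
#' and every stored (directed) entry written once.
#'
#' @param graph a \linkS4class{SpotGraph}.
#' @param path output file.
#' @export
writeEdgeList <- function(graph, path) {
  tr <- Matrix::summary(graph@adjacency)
  utils::write.table(data.frame(i = tr$i - 1L, j = tr$j - 1L, w = tr$x),
                     path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeEdgeList
#' @param n number of spots of the graph being read.
#' @export
readEdgeList <- function(path, n) {
  e <- utils::read.table(path, col.names = c("i", "j", "w"))
  SpotGraph(Matrix::sparseMatrix(i = e$i + 1L, j = e$j + 1L, x = e$w,
                                 dims = c(n, n)))
}

#' Write spot labels as a 2-column CSV (spot_id, label)
#' @param labels named label vector.
#' @param path output file.
#' @export
writeLabels <- function(labels, path) {
  ids <- names(labels)
  if (is.null(ids)) ids <- sprintf("spot%04d", seq_along(labels))
  utils::write.csv(data.frame(spot_id = ids, label = unname(labels)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeLabels
#' @export
readLabels <- function(path) {
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(lt[, 2], lt[, 1])
}

#' Write an embedding with spot ids as CSV
#' @param H embedding matrix with row names.
#' @param path output file.
#' @export
writeEmbeddingCSV <- function(H, path) {
  df <- data.frame(spot_id = rownames(H), as.data.frame(unname(H)))
  colnames(df)[-1] <- sprintf("dim%02d", seq_len(ncol(H)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeEmbeddingCSV
#' @export
readEmbeddingCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  H <- as.matrix(df[, -1, drop = FALSE])
  rownames(H) <- df[, 1]
  H
}

#' Attach a trained embedding to a slide's reduced dimensions
#' @param slide a \linkS4class{SpatialSlide}.
#' @param model a trained \linkS4class{SGFModel}.
#' @return the slide with \code{reducedDim(slide, "SGF")} set.
#' @export
addEmbedding <- function(slide, model) {
  SingleCellExperiment::reducedDim(slide, "SGF") <- embedding(model)
  slide
}
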
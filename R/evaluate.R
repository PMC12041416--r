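#' Cluster an embedding into spatial domains
#'
#' Fits a Gaussian mixture (equal-shape covariances, the convention for
#' spatial-transcriptomics embeddings) or k-means with \code{k} components
#' and returns hard labels. By default the rows are first projected onto
#' their top \code{whiten} principal components scaled to unit variance;
#' learned embeddings (and expression matrices) often carry one dominant
#' nuisance direction — per-spot depth, global scale — and whitening stops
#' it from drowning the domain signal in the distance computations. The
#' RNG is seeded locally, so a fixed seed yields identical labels across
#' runs.
#'
#' @param H embedding matrix (spots x d) or an \linkS4class{SGFModel}.
#' @param k number of domains, \code{1 <= k <= N}.
#' @param method \code{"gmm"} or \code{"kmeans"}.
#' @param seed integer seed.
#' @param whiten number of whitened principal components to cluster on
#'   (capped at the input rank); 0 disables the projection.
#' @return integer vector of labels in \code{1..k}, named by the embedding
#'   row names.
#' @export
clusterEmbedding <- function(H, k, method = c("gmm", "kmeans"), seed = 0,
                             whiten = 20) {
  if (is(H, "SGFModel")) H <- embedding(H)
  method <- match.arg(method)
  H <- as.matrix(H)
  n <- nrow(H)
  stopifnot(k >= 1, k <= n)
  if (k > nrow(unique(H)))
    stop("k exceeds the number of distinct embedding rows")
  if (k == 1L)
    return(stats::setNames(rep(1L, n), rownames(H)))
  if (whiten > 0) {
    q <- min(whiten, ncol(H), n - 1L)
    Hc <- scale(H, scale = FALSE)
    s <- svd(Hc, nu = q, nv = 0)
    keep <- s$d[seq_len(q)] > max(s$d) * 1e-8
    if (any(keep)) {
      U <- s$u[, keep, drop = FALSE]
      rownames(U) <- rownames(H)
      H <- U
    }
  }
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  lab <- if (method == "gmm") {
    fit <- mclust::Mclust(H, G = k, modelNames = "EEE", verbose = FALSE)
    if (is.null(fit)) {
      warning("Gaussian mixture fit failed; falling back to k-means")
      stats::kmeans(H, centers = k, nstart = 10, iter.max = 100)$cluster
    } else fit$classification
  } else {
    stats::kmeans(H, centers = k, nstart = 10, iter.max = 100)$cluster
  }
  stats::setNames(as.integer(lab), rownames(H))
}

#' Clustering agreement metrics
#'
#' Adjusted Rand index, normalized mutual information, homogeneity,
#' completeness and V-measure from the contingency table of predicted
#' against reference labels. All five are invariant to relabeling either
#' argument; V-measure is the harmonic mean of homogeneity and
#' completeness, and NMI uses the arithmetic-mean normalization.
#'
#' @param pred predicted labels.
#' @param truth reference labels, same length and order.
#' @return named numeric vector \code{c(ARI, NMI, HS, CS, V)}.
#' @examples
#' scoreClustering(c(1, 1, 2, 2), c(2, 2, 1, 1))  # all ones
#' @export
scoreClustering <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  n <- length(pred)
  ct <- table(pred, truth)
  # ARI (pair-counting, adjusted for chance)
  sij <- sum(choose(ct, 2))
  ai <- sum(choose(rowSums(ct), 2))
  bj <- sum(choose(colSums(ct), 2))
  expd <- ai * bj / choose(n, 2)
  mx <- (ai + bj) / 2
  ARI <- if (mx == expd) 1 else (sij - expd) / (mx - expd)
  # entropies and mutual information (natural log)
  p <- ct / n
  pr <- rowSums(p); pc <- colSums(p)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  Hp <- ent(pr); Ht <- ent(pc)
  nzero <- p > 0
  MI <- sum(p[nzero] * log(p[nzero] / outer(pr, pc)[nzero]))
  NMI <- if ((Hp + Ht) == 0) 1 else 2 * MI / (Hp + Ht)
  # homogeneity: 1 - H(truth | pred) / H(truth); completeness symmetric
  HS <- if (Ht == 0) 1 else MI / Ht
  CS <- if (Hp == 0) 1 else MI / Hp
  V <- if (HS + CS == 0) 0 else 2 * HS * CS / (HS + CS)
  c(ARI = ARI, NMI = NMI, HS = HS, CS = CS, V = V)
}

#' Reconstructed ("denoised") expression
#'
#' The decoder's mean matrix \eqn{\mu}, usable as denoised expression for
#' marker-gene visualization: strictly positive, spots x genes, aligned
#' with the highly-variable-gene counts the model was trained on.
#'
#' @param model a trained \linkS4class{SGFModel}.
#' @return numeric matrix, spots x genes.
#' @export
reconstructExpression <- function(model) {
  stopifnot(is(model, "SGFModel"))
  model@zinb$mu
}
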
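#' Spatial contrastive regularization loss
#'
#' Pushes embeddings of spatially adjacent spots together and those of
#' sampled non-adjacent pairs apart. With \eqn{S_{ij}} the cosine
#' similarity of the embedding rows and \eqn{\sigma} the logistic
#' function,
#' \deqn{L = -\tfrac12\Big(\overline{\log\sigma(S_{ij})}_{(i,j)\in G_{nei}}
#'  + \overline{\log(1-\sigma(S_{ij}))}_{(i,j)\in G_{neg}}\Big),}
#' both terms being means over their pair sets. Because
#' \eqn{S_{ij}\in[-1,1]}, the loss is bounded below by
#' \eqn{-\log\sigma(1)\approx 0.3133}.
#'
#' @param H embedding matrix, spots x d.
#' @param pos_pairs 2-column index matrix of adjacent spot pairs.
#' @param neg_pairs 2-column index matrix of non-adjacent pairs, disjoint
#'   from \code{pos_pairs}.
#' @return scalar loss.
#' @export
spatialRegLoss <- function(H, pos_pairs, neg_pairs) {
  pos_pairs <- as.matrix(pos_pairs); neg_pairs <- as.matrix(neg_pairs)
  if (nrow(pos_pairs) == 0L || nrow(neg_pairs) == 0L)
    stop("both positive and negative pair sets must be non-empty")
  Y <- rowNormalize(H)
  sp <- rowSums(Y[pos_pairs[, 1], , drop = FALSE] *
                Y[pos_pairs[, 2], , drop = FALSE])
  sn <- rowSums(Y[neg_pairs[, 1], , drop = FALSE] *
                Y[neg_pairs[, 2], , drop = FALSE])
  # -log sigma(s) = softplus(-s); -log(1 - sigma(s)) = softplus(s)
  0.5 * (mean(softplus(-sp)) + mean(softplus(sn)))
}

#' Sample non-adjacent spot pairs
#'
#' Uniform rejection sampling of ordered pairs \eqn{(i, j)}, \eqn{i \ne j},
#' excluding pairs connected in \code{graph}; pairs are distinct within a
#' draw and the draw is reproducible given \code{seed} (the caller's RNG
#' state is left untouched when a seed is supplied).
#'
#' @param graph a \linkS4class{SpotGraph} defining adjacency.
#' @param n_samples number of pairs to draw.
#' @param seed optional integer seed.
#' @return 2-column integer matrix of pairs.
#' @export
sampleNegativePairs <- function(graph, n_samples, seed = NULL) {
  stopifnot(n_samples >= 1)
  A <- graph@adjacency
  n <- nrow(A)
  n_free <- n * (n - 1) - Matrix::nnzero(A)
  if (n_free < n_samples)
    stop("graph too dense: not enough non-adjacent pairs to sample")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  got <- matrix(integer(0), 0, 2)
  seen <- character(0)
  while (nrow(got) < n_samples) {
    m <- 2L * (n_samples - nrow(got)) + 8L
    i <- sample.int(n, m, replace = TRUE)
    j <- sample.int(n, m, replace = TRUE)
    ok <- i != j & A[cbind(i, j)] == 0
    key <- paste(i, j)
    ok <- ok & !duplicated(key) & !(key %in% seen)
    got <- rbind(got, cbind(i[ok], j[ok]))
    seen <- c(seen, key[ok])
  }
  got[seq_len(n_samples), , drop = FALSE]
}

#' Weighted total training objective
#'
#' \eqn{L = \alpha L_{ZINB} + \beta L_{con} + \gamma L_{reg}} with the
#' configured weights (defaults 1, 10, 0.1).
#'
#' @param l_zinb,l_con,l_reg finite component losses.
#' @param cfg an \code{\link{sgfConfig}} (only alpha, beta, gamma used).
#' @return scalar.
#' @export
totalLoss <- function(l_zinb, l_con, l_reg, cfg = sgfConfig()) {
  stopifnot(is.finite(l_zinb), is.finite(l_con), is.finite(l_reg))
  cfg$alpha * l_zinb + cfg$beta * l_con + cfg$gamma * l_reg
}

# positive pairs of a graph as a 2-column matrix (each undirected edge once)
positivePairs <- function(graph) {
  tr <- Matrix::summary(as(as(graph@adjacency, "generalMatrix"),
                           "CsparseMatrix"))
  m <- cbind(tr$i, tr$j)
  m[m[, 1] < m[, 2], , drop = FALSE]
}
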
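## Numeric (tape-free) implementations of the model's building blocks.
## These are the reference surface of each operation — usable standalone and
## compared in the tests against the autodiff forward used for training.

# adaptive reweighting of the normalized propagation matrix
adaptivePropagationMatrix <- function(graph, adaptive,
                                      mode = c("hadamard", "matmul"),
                                      nonneg = FALSE) {
  mode <- match.arg(mode)
  S <- normalizedAdjacency(graph)
  vals <- adaptive@values
  if (nonneg) vals <- pmax(vals, 0)
  if (mode == "hadamard") {
    nrm <- as.vector(S[cbind(adaptive@i, adaptive@j)])
    Matrix::sparseMatrix(i = adaptive@i, j = adaptive@j, x = vals * nrm,
                         dims = c(adaptive@n, adaptive@n))
  } else {
    Aad <- Matrix::sparseMatrix(i = adaptive@i, j = adaptive@j, x = vals,
                                dims = c(adaptive@n, adaptive@n))
    Aad %*% S
  }
}

#' One adaptive graph convolution layer
#'
#' Propagation rule
#' \eqn{H^{(l+1)} = \mathrm{ReLU}(A^{adapt} \odot
#' \tilde D^{-1/2}\tilde A\tilde D^{-1/2}\, H^{(l)} W^{(l)})}: the
#' symmetric-normalized self-loop-augmented adjacency, reweighted entrywise
#' by the learnable adaptive values on its own sparsity pattern, applied to
#' the linearly transformed features. With all adaptive values at 1 this is
#' exactly the standard normalized graph convolution.
#'
#' @param H input features, spots x d_in.
#' @param graph base \linkS4class{SpotGraph}.
#' @param adaptive \linkS4class{AdaptiveGraph} on the graph's pattern, or
#'   \code{NULL} for the plain normalized propagation.
#' @param W weight matrix d_in x d_out.
#' @param activation \code{"relu"} or \code{"linear"}.
#' @param mode see \code{\link{sgfConfig}} \code{adaptive_mode}.
#' @return propagated features, spots x d_out.
#' @export
gcnPropagate <- function(H, graph, adaptive = NULL, W,
                         activation = c("relu", "linear"),
                         mode = c("hadamard", "matmul")) {
  activation <- match.arg(activation)
  P <- if (is.null(adaptive)) normalizedAdjacency(graph)
       else adaptivePropagationMatrix(graph, adaptive, mode = match.arg(mode))
  Z <- as.matrix(P %*% (H %*% W))
  if (activation == "relu") pmax(Z, 0) else Z
}

#' Parameter-shared joint convolution layer
#'
#' The plain normalized propagation (no adaptive reweighting); the caller
#' applies the SAME weight stack once with the spatial graph and once with
#' the feature graph to obtain the two joint embeddings.
#'
#' @inheritParams gcnPropagate
#' @export
jointPropagate <- function(H, graph, W, activation = c("relu", "linear"))
  gcnPropagate(H, graph, adaptive = NULL, W = W,
               activation = match.arg(activation))

#' Joint embedding: elementwise mean of the two joint-branch outputs
#' @param Hsj,Hfj equally shaped matrices.
#' @export
jointEmbed <- function(Hsj, Hfj) {
  stopifnot(all(dim(Hsj) == dim(Hfj)))
  (Hsj + Hfj) / 2
}

# row-L2 normalization; all-zero rows stay zero (with optional warning)
rowNormalize <- function(H, warn = FALSE) {
  r <- sqrt(rowSums(H * H))
  if (warn && any(r == 0))
    warning(sprintf("%d all-zero row(s) left unnormalized", sum(r == 0)))
  H / ifelse(r > 0, r, 1)
}

#' Cross-view consistency loss
#'
#' Squared Frobenius distance between the spot-similarity Gram matrices of
#' the two row-normalized joint embeddings,
#' \eqn{\|\tilde H_{sj}\tilde H_{sj}^T - \tilde H_{fj}\tilde H_{fj}^T\|_2^2}.
#' Zero exactly when the normalized Gram matrices coincide.
#'
#' @param Hsj,Hfj equally shaped embedding matrices.
#' @param reduction \code{"sum"} (the squared norm itself) or \code{"mean"}
#'   (divided by \eqn{N^2}).
#' @return non-negative scalar.
#' @export
consistencyLoss <- function(Hsj, Hfj, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  stopifnot(all(dim(Hsj) == dim(Hfj)))
  D <- tcrossprod(rowNormalize(Hsj, warn = TRUE)) -
       tcrossprod(rowNormalize(Hfj, warn = TRUE))
  v <- sum(D * D)
  if (reduction == "mean") v / nrow(Hsj)^2 else v
}

glorot <- function(nin, nout)
  matrix(stats::runif(nin * nout, -sqrt(6 / (nin + nout)),
                      sqrt(6 / (nin + nout))), nin, nout)

#' Create an attention head for three-view fusion
#'
#' Scores each view embedding per spot as
#' \eqn{e_{iv} = q^\top \tanh(W h_{iv} + b)} with projection and query
#' shared across the three views, softmaxes the scores across views, and
#' maps the weighted sum through a single linear layer \eqn{F}.
#'
#' @param d embedding dimension.
#' @param attention_dim projection width.
#' @return list of head parameters (projection \code{W}, bias \code{b},
#'   query \code{q}, output layer \code{F_W}, \code{F_b}).
#' @export
newAttentionHead <- function(d, attention_dim = 32)
  list(W = glorot(d, attention_dim),
       b = matrix(0, 1, attention_dim),
       q = glorot(attention_dim, 1),
       F_W = glorot(d, d),
       F_b = matrix(0, 1, d))

#' Attention-based fusion of the three view embeddings
#'
#' @param Hj,Hs,Hf joint, spatial and feature embeddings (spots x d).
#' @param head an attention head from \code{\link{newAttentionHead}}.
#' @param granularity \code{"spot"} (a coefficient triple per spot) or
#'   \code{"global"} (one shared triple, the spot scores averaged).
#' @return list with \code{H} (fused, spots x d) and \code{coefficients}
#'   (spots x 3, each row non-negative and summing to 1; columns joint,
#'   spatial, feature).
#' @export
attentionFuse <- function(Hj, Hs, Hf, head,
                          granularity = c("spot", "global")) {
  granularity <- match.arg(granularity)
  stopifnot(all(dim(Hj) == dim(Hs)), all(dim(Hj) == dim(Hf)))
  score <- function(H)
    tanh(sweep(H %*% head$W, 2L, as.vector(head$b), "+")) %*% head$q
  E <- cbind(score(Hj), score(Hs), score(Hf))
  if (granularity == "global")
    E <- matrix(colMeans(E), nrow(E), 3, byrow = TRUE)
  E <- E - apply(E, 1L, max)
  A <- exp(E) / rowSums(exp(E))
  Hsum <- Hj * A[, 1] + Hs * A[, 2] + Hf * A[, 3]
  H <- sweep(Hsum %*% head$F_W, 2L, as.vector(head$F_b), "+")
  colnames(A) <- c("joint", "spatial", "feature")
  list(H = H, coefficients = A)
}

#' Bounded learnable-weight fusion
#'
#' \eqn{H = \tanh(c_j) H_j + \tanh(c_s) H_s + \tanh(c_f) H_f}: a weighted
#' sum whose scalar weights are squashed into \eqn{(-1, 1)}.
#'
#' @inheritParams attentionFuse
#' @param weights numeric vector \code{c(cj, cs, cf)} of unconstrained
#'   scalars.
#' @export
learnableFuse <- function(Hj, Hs, Hf, weights = c(0.5, 0.5, 0.5)) {
  stopifnot(length(weights) == 3)
  tanh(weights[1]) * Hj + tanh(weights[2]) * Hs + tanh(weights[3]) * Hf
}

#' Final embedding: mean of the two fusion strategies
#' @param Hattention,Hlearnable equally shaped matrices.
#' @export
finalEmbed <- function(Hattention, Hlearnable) {
  stopifnot(all(dim(Hattention) == dim(Hlearnable)))
  (Hattention + Hlearnable) / 2
}

#' Decode ZINB parameters from an embedding
#'
#' A shared ReLU hidden layer followed by three parallel linear heads with
#' range-enforcing transforms: \eqn{\mu = \exp(\cdot)} (positive),
#' \eqn{\theta = \mathrm{softplus}(\cdot)} floored at \eqn{10^{-4}} and
#' capped at \eqn{10^4}, \eqn{\pi = \mathrm{logistic}(\cdot)} in (0, 1).
#'
#' @param H embedding, spots x d.
#' @param dec decoder weights from \code{\link{newDecoder}}.
#' @param dispersion \code{"entry"} or \code{"gene"} (one theta per gene).
#' @return list of matrices \code{mu}, \code{theta}, \code{pi}
#'   (spots x genes).
#' @export
decodeZINB <- function(H, dec, dispersion = c("entry", "gene")) {
  dispersion <- match.arg(dispersion)
  Hd <- pmax(sweep(H %*% dec$W1, 2L, as.vector(dec$b1), "+"), 0)
  lin <- function(W, b) sweep(Hd %*% W, 2L, as.vector(b), "+")
  mu <- exp(pmin(pmax(lin(dec$Wmu, dec$bmu), -15), 15))
  theta <- if (dispersion == "gene")
    matrix(pmin(softplus(as.vector(dec$theta_gene)), 1e4) + 1e-4,
           nrow(H), length(dec$theta_gene), byrow = TRUE)
  else pmin(softplus(lin(dec$Wth, dec$bth)), 1e4) + 1e-4
  pi <- plogis(pmin(pmax(lin(dec$Wpi, dec$bpi), -10), 10))
  list(mu = mu, theta = theta, pi = pi)
}

#' Create decoder weights
#' @param d embedding dimension.
#' @param n_genes output genes.
#' @param hidden shared hidden width.
#' @export
newDecoder <- function(d, n_genes, hidden = 128)
  list(W1 = glorot(d, hidden), b1 = matrix(0, 1, hidden),
       Wmu = glorot(hidden, n_genes), bmu = matrix(0, 1, n_genes),
       Wth = glorot(hidden, n_genes), bth = matrix(0, 1, n_genes),
       Wpi = glorot(hidden, n_genes), bpi = matrix(0, 1, n_genes),
       theta_gene = matrix(0, 1, n_genes))

# all trainable parameters of the full model
initModelParams <- function(M, cfg, adaptiveSpatial, adaptiveFeature) {
  h <- cfg$hidden_dim; d <- cfg$embed_dim
  p <- list(
    Ws1 = glorot(M, h), Ws2 = glorot(h, d),
    Wf1 = glorot(M, h), Wf2 = glorot(h, d),
    Wj1 = glorot(M, h), Wj2 = glorot(h, d),
    vals_s = adaptiveSpatial@values,
    vals_f = adaptiveFeature@values,
    cj = matrix(0.5), cs = matrix(0.5), cf = matrix(0.5))
  p <- c(p, newAttentionHead(d, cfg$attention_dim))
  names(p)[match(c("W", "b", "q"), names(p))] <- c("Wa", "ba", "qa")
  c(p, newDecoder(d, M, cfg$decoder_hidden))
}
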
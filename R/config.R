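#' Training and architecture configuration
#'
#' Collects every tunable of the pipeline with its default. Loss weights
#' \code{alpha} (reconstruction), \code{beta} (cross-view consistency) and
#' \code{gamma} (spatial contrastive) default to 1, 10 and 0.1. The graph
#' radius is a platform preset: 560 (full-resolution pixels) suits
#' DLPFC-style Visium slides, 15 the other platforms, and 1.5 the
#' simulator's unit lattice.
#'
#' @param n_top_genes highly-variable genes retained.
#' @param log1p log-transform the normalized encoder input.
#' @param scale_factor per-spot total after depth normalization.
#' @param radius spatial-graph neighborhood radius (coordinate units).
#' @param k neighbors of the expression-similarity graph.
#' @param hidden_dim,embed_dim encoder layer widths (input -> hidden ->
#'   embedding, two layers per branch).
#' @param attention_dim width of the attention projection.
#' @param decoder_hidden width of the decoder's shared hidden layer.
#' @param adaptive_mode \code{"hadamard"}: adaptive weights rescale the
#'   normalized adjacency entrywise on its own pattern; \code{"matmul"}:
#'   the adaptive sparse matrix left-multiplies the normalized propagation.
#' @param adaptive_nonneg clamp adaptive edge weights at 0 from below.
#' @param last_activation \code{"linear"} (default) or \code{"relu"} on the
#'   final encoder layer.
#' @param attention_granularity \code{"spot"}: one coefficient triple per
#'   spot; \code{"global"}: a single shared triple.
#' @param dispersion \code{"entry"}: one theta per spot x gene;
#'   \code{"gene"}: one per gene.
#' @param lambda_pi weight of the zero-inflation ridge penalty.
#' @param loss_reduction aggregation of the reconstruction likelihood.
#' @param consistency_reduction \code{"sum"}: squared Frobenius norm of the
#'   Gram difference; \code{"mean"}: the same divided by \eqn{N^2}.
#' @param alpha,beta,gamma loss weights.
#' @param epochs,learning_rate,weight_decay Adam settings (full batch).
#' @param n_negative negative pairs per epoch for the spatial contrastive
#'   term; defaults to the number of positive (adjacent) pairs.
#' @param seed integer seed controlling initialization and sampling.
#' @param cluster_method \code{"gmm"} (Gaussian mixture, default) or
#'   \code{"kmeans"}.
#' @param ... overrides are rejected if not matching a known field.
#' @return a named list of class \code{sgf_config}.
#' @export
sgfConfig <- function(n_top_genes = 3000, log1p = TRUE, scale_factor = 1e4,
                      radius = 15, k = 15,
                      hidden_dim = 128, embed_dim = 64, attention_dim = 32,
                      decoder_hidden = 128,
                      adaptive_mode = c("hadamard", "matmul"),
                      adaptive_nonneg = FALSE,
                      last_activation = c("linear", "relu"),
                      attention_granularity = c("spot", "global"),
                      dispersion = c("entry", "gene"),
                      lambda_pi = 1, loss_reduction = c("mean", "sum"),
                      consistency_reduction = c("sum", "mean"),
                      alpha = 1, beta = 10, gamma = 0.1,
                      epochs = 300, learning_rate = 1e-3,
                      weight_decay = 1e-4, n_negative = NULL, seed = 0,
                      cluster_method = c("gmm", "kmeans"), ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration field(s): ",
         paste(names(extra), collapse = ", "))
  cfg <- list(
    n_top_genes = n_top_genes, log1p = log1p, scale_factor = scale_factor,
    radius = radius, k = k,
    hidden_dim = hidden_dim, embed_dim = embed_dim,
    attention_dim = attention_dim, decoder_hidden = decoder_hidden,
    adaptive_mode = match.arg(adaptive_mode),
    adaptive_nonneg = adaptive_nonneg,
    last_activation = match.arg(last_activation),
    attention_granularity = match.arg(attention_granularity),
    dispersion = match.arg(dispersion),
    lambda_pi = lambda_pi, loss_reduction = match.arg(loss_reduction),
    consistency_reduction = match.arg(consistency_reduction),
    alpha = alpha, beta = beta, gamma = gamma,
    epochs = as.integer(epochs), learning_rate = learning_rate,
    weight_decay = weight_decay, n_negative = n_negative,
    seed = as.integer(seed),
    cluster_method = match.arg(cluster_method))
  stopifnot(cfg$alpha >= 0, cfg$beta >= 0, cfg$gamma >= 0,
            cfg$epochs >= 1, cfg$lambda_pi >= 0)
  class(cfg) <- "sgf_config"
  cfg
}

#' Read a configuration from a YAML file
#'
#' Unknown fields raise an error; omitted fields keep their defaults.
#'
#' @param path YAML file whose top-level keys are \code{\link{sgfConfig}}
#'   arguments.
#' @return an \code{sgf_config} list.
#' @export
readConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(sgfConfig, vals)
}
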
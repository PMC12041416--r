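## Full-batch training: the complete forward pass is laid on the autodiff
## tape each epoch, backpropagated, and the parameters updated with Adam.

# Build the whole model forward on a fresh tape. `consts` carries the fixed
# inputs (X, counts, normalized adjacencies, adaptive patterns, pair sets);
# returns the tape, one leaf id per parameter and the ids of every quantity
# the caller may want to read off.
forwardTape <- function(params, consts, cfg) {
  tp <- tapeNew()
  L <- lapply(params, function(p) tgLeaf(tp, p))
  X <- tgLeaf(tp, consts$X)
  n <- nrow(consts$X)

  branch <- function(W1, W2, valsId, pat) {
    vals <- if (cfg$adaptive_nonneg) tgClamp(tp, valsId, 0, Inf) else valsId
    prop <- function(h) {
      if (cfg$adaptive_mode == "hadamard")
        tgAdaptiveSpmm(tp, vals, h, pat$i, pat$j, pat$nrm, n)
      else
        tgAdaptiveSpmm(tp, vals, tgSpmm(tp, pat$S, h), pat$i, pat$j,
                       rep(1, length(pat$i)), n)
    }
    h1 <- tgRelu(tp, prop(tgMatmul(tp, X, W1)))
    out <- prop(tgMatmul(tp, h1, W2))
    if (cfg$last_activation == "relu") tgRelu(tp, out) else out
  }
  jointBranch <- function(S) {
    h1 <- tgRelu(tp, tgSpmm(tp, S, tgMatmul(tp, X, L$Wj1)))
    out <- tgSpmm(tp, S, tgMatmul(tp, h1, L$Wj2))
    if (cfg$last_activation == "relu") tgRelu(tp, out) else out
  }

  Hs <- branch(L$Ws1, L$Ws2, L$vals_s, consts$spat)
  Hf <- branch(L$Wf1, L$Wf2, L$vals_f, consts$feat)
  Hsj <- jointBranch(consts$spat$S)
  Hfj <- jointBranch(consts$feat$S)
  Hj <- tgScale(tp, tgAdd(tp, Hsj, Hfj), 0.5)

  # cross-view consistency on the normalized Gram matrices
  lcon <- tgGramDiff2(tp, tgRowNormalize(tp, Hsj),
                      tgRowNormalize(tp, Hfj))
  if (cfg$consistency_reduction == "mean") lcon <- tgScale(tp, lcon, 1 / n^2)

  # attention fusion
  score <- function(H) tgMatmul(tp, tgTanh(tp, tgAddBias(
    tp, tgMatmul(tp, H, L$Wa), L$ba)), L$qa)
  E <- tgCbind(tp, c(score(Hj), score(Hs), score(Hf)))
  if (cfg$attention_granularity == "global") {
    ones <- tgLeaf(tp, matrix(1, n, 1))
    E <- tgMatmul(tp, ones, tgMatmul(tp, tgLeaf(tp, matrix(1 / n, 1, n)), E))
  }
  A <- tgSoftmaxRows(tp, E)
  Hsum <- tgAdd(tp, tgAdd(tp,
            tgRowScale(tp, tgColumn(tp, A, 1L), Hj),
            tgRowScale(tp, tgColumn(tp, A, 2L), Hs)),
            tgRowScale(tp, tgColumn(tp, A, 3L), Hf))
  Hatt <- tgAddBias(tp, tgMatmul(tp, Hsum, L$F_W), L$F_b)

  # bounded learnable-weight fusion and the final embedding
  Hlearn <- tgAdd(tp, tgAdd(tp,
              tgScaleByScalar(tp, tgTanh(tp, L$cj), Hj),
              tgScaleByScalar(tp, tgTanh(tp, L$cs), Hs)),
              tgScaleByScalar(tp, tgTanh(tp, L$cf), Hf))
  H <- tgScale(tp, tgAdd(tp, Hatt, Hlearn), 0.5)

  # ZINB decoder
  Hd <- tgRelu(tp, tgAddBias(tp, tgMatmul(tp, H, L$W1), L$b1))
  lin <- function(W, b) tgAddBias(tp, tgMatmul(tp, Hd, W), b)
  mu <- tgExp(tp, tgClamp(tp, lin(L$Wmu, L$bmu), -15, 15))
  theta <- if (cfg$dispersion == "gene")
    tgRowBroadcast(tp, tgAddConst(tp, tgClamp(tp, tgSoftplus(
      tp, L$theta_gene), -Inf, 1e4), 1e-4), n)
  else
    tgAddConst(tp, tgClamp(tp, tgSoftplus(tp, lin(L$Wth, L$bth)),
                           -Inf, 1e4), 1e-4)
  pimat <- tgSigmoid(tp, tgClamp(tp, lin(L$Wpi, L$bpi), -10, 10))
  nll <- tgZinbNll(tp, mu, theta, pimat, consts$counts)
  ridge <- tgMean(tp, tgMul(tp, pimat, pimat))
  if (cfg$loss_reduction == "sum") {
    ne <- length(consts$counts)
    nll <- tgScale(tp, nll, ne)
    ridge <- tgScale(tp, ridge, ne)
  }
  lzinb <- tgAdd(tp, nll, tgScale(tp, ridge, cfg$lambda_pi))

  # spatial contrastive regularizer on the final embedding
  Y <- tgRowNormalize(tp, H)
  sp <- tgPairDot(tp, Y, consts$pos[, 1], consts$pos[, 2])
  sn <- tgPairDot(tp, Y, consts$neg[, 1], consts$neg[, 2])
  lreg <- tgScale(tp, tgAdd(tp,
            tgMean(tp, tgSoftplus(tp, tgScale(tp, sp, -1))),
            tgMean(tp, tgSoftplus(tp, sn))), 0.5)

  total <- tgAdd(tp, tgAdd(tp, tgScale(tp, lzinb, cfg$alpha),
                           tgScale(tp, lcon, cfg$beta)),
                 tgScale(tp, lreg, cfg$gamma))
  list(tp = tp, leaves = L,
       ids = list(Hs = Hs, Hf = Hf, Hsj = Hsj, Hfj = Hfj, Hj = Hj,
                  H = H, attention = A, mu = mu, theta = theta, pi = pimat,
                  lzinb = lzinb, lcon = lcon, lreg = lreg, total = total))
}

adamInit <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adamStep <- function(params, grads, st, lr, wd,
                     b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) g <- params[[nm]] * 0
    g <- g + wd * params[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    mhat <- st$m[[nm]] / (1 - b1^st$t)
    vhat <- st$v[[nm]] / (1 - b2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

# fixed constants of the training problem, precomputed once
trainingConstants <- function(X, counts, spatialGraph, featureGraph,
                              ags, agf) {
  pack <- function(graph, ag) {
    S <- normalizedAdjacency(graph)
    list(S = S, i = ag@i, j = ag@j,
         nrm = as.vector(S[cbind(ag@i, ag@j)]))
  }
  list(X = X, counts = counts,
       spat = pack(spatialGraph, ags), feat = pack(featureGraph, agf),
       pos = positivePairs(spatialGraph))
}

#' Train the multi-view graph fusion model
#'
#' Full-batch joint optimization of the three-branch graph convolutional
#' encoder (with its two adaptive adjacencies), the two-strategy fusion
#' head and the ZINB decoder against the weighted sum of reconstruction,
#' consistency and spatial-contrastive losses. Negative pairs for the
#' contrastive term are re-sampled every epoch; all randomness flows from
#' \code{config$seed}, so a repeated run reproduces the loss trace and
#' embedding exactly.
#'
#' @param slide a preprocessed \linkS4class{SpatialSlide} (see
#'   \code{\link{preprocessSlide}}).
#' @param spatialGraph,featureGraph optional prebuilt
#'   \linkS4class{SpotGraph}s; built from the slide with the configured
#'   radius / k when omitted.
#' @param config an \code{\link{sgfConfig}}.
#' @param verbose print the loss every 50 epochs.
#' @return a trained \linkS4class{SGFModel}.
#' @examples
#' sl <- preprocessSlide(simulateSlide(sgfSimConfig(grid_side = 5,
#'   n_genes = 20)), n_top = 20)
#' fit <- trainModel(sl, config = sgfConfig(radius = 1.5, k = 3,
#'   hidden_dim = 8, embed_dim = 4, epochs = 2))
#' lossTrace(fit)
#' @export
trainModel <- function(slide, spatialGraph = NULL, featureGraph = NULL,
                       config = sgfConfig(), verbose = FALSE) {
  stopifnot(is(slide, "SpatialSlide"))
  cfg <- config
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$seed)

  X <- encoderInput(slide)
  counts <- rawCounts(slide)
  if (is.null(spatialGraph))
    spatialGraph <- buildSpatialGraph(spatialCoords(slide), cfg$radius)
  if (is.null(featureGraph))
    featureGraph <- buildFeatureGraph(X, cfg$k)
  ags <- initAdaptiveGraph(spatialGraph)
  agf <- initAdaptiveGraph(featureGraph)
  params <- initModelParams(ncol(X), cfg, ags, agf)
  consts <- trainingConstants(X, counts, spatialGraph, featureGraph,
                              ags, agf)
  n_neg <- if (is.null(cfg$n_negative)) nrow(consts$pos) else cfg$n_negative

  st <- adamInit(params)
  trace <- matrix(NA_real_, cfg$epochs, 4)
  fw <- NULL
  for (ep in seq_len(cfg$epochs)) {
    consts$neg <- sampleNegativePairs(spatialGraph, n_neg)
    fw <- forwardTape(params, consts, cfg)
    comp <- c(zinb = tgValue(fw$tp, fw$ids$lzinb),
              consistency = tgValue(fw$tp, fw$ids$lcon),
              spatial = tgValue(fw$tp, fw$ids$lreg),
              total = tgValue(fw$tp, fw$ids$total))
    if (!all(is.finite(comp)))
      stop(sprintf(
        "non-finite loss at epoch %d (zinb=%g, consistency=%g, spatial=%g)",
        ep, comp[1], comp[2], comp[3]))
    trace[ep, ] <- comp
    grads <- tgBackward(fw$tp, fw$ids$total)
    g <- lapply(fw$leaves, function(id) grads[[id]])
    up <- adamStep(params, g, st, cfg$learning_rate, cfg$weight_decay)
    params <- up$params; st <- up$state
    if (verbose && (ep %% 50 == 0 || ep == 1))
      message(sprintf("epoch %4d  total %.4f  (zinb %.4f  con %.5f  reg %.4f)",
                      ep, comp[4], comp[1], comp[2], comp[3]))
  }

  # one evaluation pass with the final parameters
  fw <- forwardTape(params, consts, cfg)
  val <- function(nm) tgValue(fw$tp, fw$ids[[nm]])
  ags@values <- params$vals_s
  agf@values <- params$vals_f
  emb <- val("H")
  rownames(emb) <- colnames(slide)
  att <- val("attention")
  dimnames(att) <- list(colnames(slide), c("joint", "spatial", "feature"))
  zb <- lapply(list(mu = "mu", theta = "theta", pi = "pi"), function(nm) {
    m <- val(nm)
    dimnames(m) <- list(colnames(slide), rownames(slide))
    m
  })
  new("SGFModel",
      params = params, config = unclass(cfg), embedding = emb,
      viewEmbeddings = list(Hs = val("Hs"), Hf = val("Hf"),
                            Hsj = val("Hsj"), Hfj = val("Hfj"),
                            Hj = val("Hj")),
      attention = att,
      lossTrace = data.frame(epoch = seq_len(cfg$epochs),
                             zinb = trace[, 1], consistency = trace[, 2],
                             spatial = trace[, 3], total = trace[, 4]),
      graphs = list(spatial = spatialGraph, feature = featureGraph,
                    adaptiveSpatial = ags, adaptiveFeature = agf),
      zinb = zb)
}
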
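# The autodiff tape is the machinery behind training; its gradients are
# validated against central finite differences of the complete objective,
# and its forward pass against the standalone numeric operations.

test_that("tape gradients of the full objective match finite differences", {
  sgf <- asNamespace("SpaGraphFusion")
  set.seed(42)
  sl <- preprocessSlide(simulateSlide(sgfSimConfig(
    grid_side = 4, n_domains = 2, n_genes = 12, n_marker_per_domain = 3,
    seed = 9)), n_top = 10)
  cfg <- sgfConfig(radius = 1.5, k = 3, hidden_dim = 6, embed_dim = 4,
                   attention_dim = 3, decoder_hidden = 5, seed = 5)
  X <- sgf$encoderInput(sl)
  gs <- buildSpatialGraph(spatialCoords(sl), 1.5)
  gf <- buildFeatureGraph(X, 3)
  ags <- initAdaptiveGraph(gs); agf <- initAdaptiveGraph(gf)
  set.seed(5)
  p <- sgf$initModelParams(ncol(X), cfg, ags, agf)
  consts <- sgf$trainingConstants(X, sgf$rawCounts(sl), gs, gf, ags, agf)
  consts$neg <- sampleNegativePairs(gs, nrow(consts$pos), seed = 2)
  lossAt <- function(q) {
    fw <- sgf$forwardTape(q, consts, cfg)
    sgf$tgValue(fw$tp, fw$ids$total)
  }
  fw <- sgf$forwardTape(p, consts, cfg)
  gr <- sgf$tgBackward(fw$tp, fw$ids$total)
  for (nm in names(p)) {
    ag <- gr[[fw$leaves[[nm]]]]
    if (is.null(ag)) ag <- p[[nm]] * 0
    for (ii in sample(length(p[[nm]]), min(3, length(p[[nm]])))) {
      eps <- 1e-5
      up <- p; up[[nm]][ii] <- up[[nm]][ii] + eps
      dn <- p; dn[[nm]][ii] <- dn[[nm]][ii] - eps
      num <- (lossAt(up) - lossAt(dn)) / (2 * eps)
      # relative error with an absolute floor: tiny gradients are dominated
      # by finite-difference noise
      rel <- abs(ag[ii] - num) / max(1e-6, abs(num), abs(ag[ii]))
      expect_lt(rel, 1e-3,
                label = sprintf("gradient error of %s[%d]", nm, ii))
    }
  }
})

test_that("tape forward agrees with the numeric operations end to end", {
  sgf <- asNamespace("SpaGraphFusion")
  set.seed(27)
  sl <- preprocessSlide(simulateSlide(sgfSimConfig(
    grid_side = 5, n_domains = 2, n_genes = 16, n_marker_per_domain = 4,
    seed = 13)), n_top = 14)
  cfg <- sgfConfig(radius = 1.5, k = 4, hidden_dim = 8, embed_dim = 5,
                   attention_dim = 4, decoder_hidden = 6, seed = 8)
  X <- sgf$encoderInput(sl)
  gs <- buildSpatialGraph(spatialCoords(sl), 1.5)
  gf <- buildFeatureGraph(X, 4)
  ags <- initAdaptiveGraph(gs); agf <- initAdaptiveGraph(gf)
  set.seed(8)
  p <- sgf$initModelParams(ncol(X), cfg, ags, agf)
  consts <- sgf$trainingConstants(X, sgf$rawCounts(sl), gs, gf, ags, agf)
  consts$neg <- sampleNegativePairs(gs, nrow(consts$pos), seed = 3)
  fw <- sgf$forwardTape(p, consts, cfg)
  v <- function(nm) sgf$tgValue(fw$tp, fw$ids[[nm]])

  # encoder branches via the exported layer functions
  ags@values <- p$vals_s; agf@values <- p$vals_f
  h1s <- gcnPropagate(X, gs, ags, p$Ws1)
  Hs <- gcnPropagate(h1s, gs, ags, p$Ws2, activation = "linear")
  expect_equal(v("Hs"), Hs, tolerance = 1e-12)
  Hsj <- jointPropagate(jointPropagate(X, gs, p$Wj1), gs, p$Wj2,
                        activation = "linear")
  Hfj <- jointPropagate(jointPropagate(X, gf, p$Wj1), gf, p$Wj2,
                        activation = "linear")
  expect_equal(v("Hsj"), Hsj, tolerance = 1e-12)
  expect_equal(v("Hj"), jointEmbed(Hsj, Hfj), tolerance = 1e-12)

  # fused consistency equals the Gram-matrix definition
  expect_equal(v("lcon"), consistencyLoss(Hsj, Hfj), tolerance = 1e-8)

  # fusion heads
  head <- list(W = p$Wa, b = p$ba, q = p$qa, F_W = p$F_W, F_b = p$F_b)
  Hf_ <- v("Hf"); Hj_ <- v("Hj")
  att <- attentionFuse(Hj_, v("Hs"), Hf_, head)
  expect_equal(unname(v("attention")), unname(att$coefficients),
               tolerance = 1e-12)
  Hl <- learnableFuse(Hj_, v("Hs"), Hf_,
                      c(p$cj[1], p$cs[1], p$cf[1]))
  expect_equal(v("H"), finalEmbed(att$H, Hl), tolerance = 1e-12)

  # decoder heads and losses
  dec <- p[c("W1", "b1", "Wmu", "bmu", "Wth", "bth", "Wpi", "bpi",
             "theta_gene")]
  zo <- decodeZINB(v("H"), dec)
  expect_equal(v("mu"), zo$mu, tolerance = 1e-10)
  expect_equal(v("theta"), zo$theta, tolerance = 1e-10)
  expect_equal(v("pi"), zo$pi, tolerance = 1e-10)
  expect_equal(v("lzinb"),
               zinbLoss(consts$counts, zo$mu, zo$theta, zo$pi,
                        lambda_pi = cfg$lambda_pi), tolerance = 1e-8)
  expect_equal(v("lreg"),
               spatialRegLoss(v("H"), consts$pos, consts$neg),
               tolerance = 1e-10)
  expect_equal(v("total"),
               totalLoss(v("lzinb"), v("lcon"), v("lreg"), cfg),
               tolerance = 1e-8)
})

test_that("matmul-mode adaptive propagation multiplies the normalized operator", {
  set.seed(44)
  A <- randomAdjacency(10, 0.3)
  g <- SpotGraph(Matrix::Matrix(A, sparse = TRUE))
  ag <- initAdaptiveGraph(g)
  ag@values <- runif(length(ag@values), 0.5, 1.5)
  H <- matrix(rnorm(10 * 4), 10)
  W <- matrix(rnorm(4 * 3), 4)
  S <- as.matrix(normalizedAdjacency(g))
  Aad <- matrix(0, 10, 10); Aad[cbind(ag@i, ag@j)] <- ag@values
  expect_equal(gcnPropagate(H, g, ag, W, mode = "matmul"),
               pmax(Aad %*% S %*% H %*% W, 0), tolerance = 1e-10)
})
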
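# Shared fixtures and independent oracles used across the suite.

# tiny slide with explicit counts/coords for deterministic unit tests
toySlide <- function(n_spots = 5, n_genes = 8, seed = 11,
                     in_tissue = NULL) {
  set.seed(seed)
  cts <- matrix(rpois(n_genes * n_spots, 3), n_genes, n_spots,
                dimnames = list(paste0("g", seq_len(n_genes)),
                                paste0("s", seq_len(n_spots))))
  coords <- cbind(x = seq_len(n_spots), y = rep(1, n_spots))
  SpatialSlide(cts, coords, in_tissue = in_tissue)
}

# dense independent oracle of the symmetric-normalized GCN layer
denseGcnOracle <- function(A, H, W, adapt = NULL, relu = TRUE) {
  n <- nrow(A)
  At <- A + diag(n)
  d <- rowSums(At)
  S <- diag(1 / sqrt(d)) %*% At %*% diag(1 / sqrt(d))
  P <- if (is.null(adapt)) S else adapt * S
  Z <- P %*% H %*% W
  if (relu) pmax(Z, 0) else Z
}

# random symmetric binary adjacency without self-loops
randomAdjacency <- function(n, p = 0.2) {
  A <- matrix(runif(n * n) < p, n, n)
  A <- A | t(A)
  diag(A) <- FALSE
  A * 1
}

# O(N^2) pair-counting adjusted Rand index
ariPairOracle <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  tot <- choose(n, 2)
  exp_ri <- (s11 + s10) * (s11 + s01) / tot
  max_ri <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_ri == exp_ri) 1 else (s11 - exp_ri) / (max_ri - exp_ri)
}

# entropy-based oracle for homogeneity / completeness / V
hcvOracle <- function(pred, truth) {
  ct <- table(pred, truth)
  n <- sum(ct)
  ent <- function(x) { p <- x[x > 0] / sum(x); -sum(p * log(p)) }
  Ht <- ent(colSums(ct)); Hp <- ent(rowSums(ct))
  Hct_given_p <- sum(apply(ct, 1, function(r)
    if (sum(r) > 0) sum(r) / n * ent(r) else 0))
  Hp_given_t <- sum(apply(ct, 2, function(r)
    if (sum(r) > 0) sum(r) / n * ent(r) else 0))
  h <- if (Ht == 0) 1 else 1 - Hct_given_p / Ht
  c <- if (Hp == 0) 1 else 1 - Hp_given_t / Hp
  v <- if (h + c == 0) 0 else 2 * h * c / (h + c)
  c(HS = h, CS = c, V = v)
}

# direct pairwise evaluation of the spatial contrastive loss
spatialRegOracle <- function(S, pos, neg) {
  lp <- mean(log(plogis(S[pos])))
  ln <- mean(log(1 - plogis(S[neg])))
  -0.5 * (lp + ln)
}
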
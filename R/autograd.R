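# Reverse-mode automatic differentiation over matrices.
#
# The training objective mixes sparse graph propagation, attention softmax,
# Gram-matrix penalties and a ZINB likelihood; a small tape keeps all the
# backward passes in one audited place instead of hand-chaining them through
# the training loop. Nodes are integer ids into tape$nodes; each node stores
# its value, parent ids and a backward closure mapping the incoming gradient
# to one gradient per parent. Values are base-R dense matrices (or length-n
# numeric vectors for per-edge weights); sparse adjacencies enter only as
# constants inside propagation ops.

tapeNew <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp$n <- 0L
  tp
}

tgNode <- function(tp, val, parents = integer(0), bw = NULL) {
  # force args before touching tape state: evaluating a lazily passed
  # sub-expression may itself append nodes
  force(val); force(parents); force(bw)
  tp$n <- tp$n + 1L
  tp$nodes[[tp$n]] <- list(val = val, parents = parents, bw = bw)
  tp$n
}

tgValue <- function(tp, id) {
  force(id)               # may append nodes; must run before reading tape
  tp$nodes[[id]]$val
}

# leaf: a parameter or constant; gradients accumulate here
tgLeaf <- function(tp, val) tgNode(tp, val)

#' @noRd
tgBackward <- function(tp, loss) {
  grads <- vector("list", tp$n)
  lv <- tp$nodes[[loss]]$val
  stopifnot(length(lv) == 1L)
  grads[[loss]] <- 1
  for (id in seq(tp$n, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    nd <- tp$nodes[[id]]
    if (length(nd$parents) == 0L) next
    pg <- nd$bw(g)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[k]
      if (is.null(pg[[k]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  grads
}

## ---- elementwise / linear-algebra ops ----

tgMatmul <- function(tp, a, b) {
  A <- tgValue(tp, a); B <- tgValue(tp, b)
  tgNode(tp, A %*% B, c(a, b),
         function(g) list(tcrossprod(g, B), crossprod(A, g)))
}

tgAdd <- function(tp, a, b) {
  tgNode(tp, tgValue(tp, a) + tgValue(tp, b), c(a, b), function(g) list(g, g))
}

tgSub <- function(tp, a, b) {
  tgNode(tp, tgValue(tp, a) - tgValue(tp, b), c(a, b), function(g) list(g, -g))
}

tgMul <- function(tp, a, b) {
  A <- tgValue(tp, a); B <- tgValue(tp, b)
  tgNode(tp, A * B, c(a, b), function(g) list(g * B, g * A))
}

# multiply by a fixed scalar constant
tgScale <- function(tp, a, s) {
  tgNode(tp, tgValue(tp, a) * s, a, function(g) list(g * s))
}

# add a 1 x k bias row to every row of an N x k matrix
tgAddBias <- function(tp, a, b) {
  A <- tgValue(tp, a); bias <- tgValue(tp, b)
  tgNode(tp, sweep(A, 2L, as.vector(bias), "+"), c(a, b),
         function(g) list(g, matrix(colSums(g), nrow = 1L)))
}

tgRelu <- function(tp, a) {
  A <- tgValue(tp, a)
  tgNode(tp, pmax(A, 0), a, function(g) list(g * (A > 0)))
}

tgTanh <- function(tp, a) {
  V <- tanh(tgValue(tp, a))
  tgNode(tp, V, a, function(g) list(g * (1 - V * V)))
}

tgSigmoid <- function(tp, a) {
  V <- plogis(tgValue(tp, a))
  tgNode(tp, V, a, function(g) list(g * V * (1 - V)))
}

tgExp <- function(tp, a) {
  V <- exp(tgValue(tp, a))
  tgNode(tp, V, a, function(g) list(g * V))
}

# numerically stable log(1 + exp(x)) = max(x, 0) + log1p(exp(-|x|))
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

tgSoftplus <- function(tp, a) {
  A <- tgValue(tp, a)
  tgNode(tp, softplus(A), a, function(g) list(g * plogis(A)))
}

# add a fixed scalar constant
tgAddConst <- function(tp, a, cst) {
  tgNode(tp, tgValue(tp, a) + cst, a, function(g) list(g))
}

# multiply a matrix by a learnable 1 x 1 scalar node
tgScaleByScalar <- function(tp, s, h) {
  sv <- as.vector(tgValue(tp, s))[1]
  H <- tgValue(tp, h)
  tgNode(tp, H * sv, c(s, h), function(g)
    list(matrix(sum(g * H)), g * sv))
}

# repeat a 1 x k row vector into an n x k matrix
tgRowBroadcast <- function(tp, a, n) {
  b <- tgValue(tp, a)
  tgNode(tp, matrix(as.vector(b), n, length(b), byrow = TRUE), a,
         function(g) list(matrix(colSums(g), nrow = 1L)))
}

# clamp with pass-through gradient inside the interval
tgClamp <- function(tp, a, lo, hi) {
  A <- tgValue(tp, a)
  tgNode(tp, pmin(pmax(A, lo), hi), a,
         function(g) list(g * (A >= lo & A <= hi)))
}

tgSum <- function(tp, a) {
  A <- tgValue(tp, a)
  tgNode(tp, sum(A), a, function(g) list(A * 0 + g))
}

tgMean <- function(tp, a) {
  A <- tgValue(tp, a)
  n <- length(A)
  tgNode(tp, sum(A) / n, a, function(g) list(A * 0 + g / n))
}

## ---- row normalization and Gram products ----

# L2-normalize rows; all-zero rows stay zero
tgRowNormalize <- function(tp, a) {
  A <- tgValue(tp, a)
  r <- sqrt(rowSums(A * A))
  rs <- ifelse(r > 0, r, 1)
  V <- A / rs
  tgNode(tp, V, a, function(g) {
    dot <- rowSums(g * V)
    list((g - V * dot) / rs)
  })
}

# G = Y %*% t(Y)
tgGram <- function(tp, a) {
  Y <- tgValue(tp, a)
  tgNode(tp, tcrossprod(Y), a, function(g) list((g + t(g)) %*% Y))
}

# squared Frobenius distance of the Gram matrices of Y1 and Y2, computed
# through d x d cross-products so no N x N matrix is ever formed:
# ||Y1 Y1' - Y2 Y2'||_F^2 = ||Y1'Y1||^2 - 2 ||Y1'Y2||^2 + ||Y2'Y2||^2
tgGramDiff2 <- function(tp, a, b) {
  Y1 <- tgValue(tp, a); Y2 <- tgValue(tp, b)
  C11 <- crossprod(Y1); C22 <- crossprod(Y2); C12 <- crossprod(Y1, Y2)
  val <- sum(C11 * C11) - 2 * sum(C12 * C12) + sum(C22 * C22)
  tgNode(tp, val, c(a, b), function(g) list(
    4 * g * (Y1 %*% C11 - Y2 %*% t(C12)),
    4 * g * (Y2 %*% C22 - Y1 %*% C12)))
}

# dot products of selected row pairs: out[e] = sum(Y[i[e],] * Y[j[e],]), n_e x 1
tgPairDot <- function(tp, a, i, j) {
  Y <- tgValue(tp, a)
  V <- matrix(rowSums(Y[i, , drop = FALSE] * Y[j, , drop = FALSE]), ncol = 1L)
  tgNode(tp, V, a, function(g) {
    gv <- as.vector(g)
    dY <- matrix(0, nrow(Y), ncol(Y))
    ai <- rowsum(gv * Y[j, , drop = FALSE], group = i)
    dY[as.integer(rownames(ai)), ] <- dY[as.integer(rownames(ai)), ] + ai
    aj <- rowsum(gv * Y[i, , drop = FALSE], group = j)
    dY[as.integer(rownames(aj)), ] <- dY[as.integer(rownames(aj)), ] + aj
    list(dY)
  })
}

## ---- sparse graph propagation ----

# out = S %*% H for a constant sparse matrix S
tgSpmm <- function(tp, S, h) {
  H <- tgValue(tp, h)
  tgNode(tp, as.matrix(S %*% H), h,
         function(g) list(as.matrix(Matrix::crossprod(S, g))))
}

# Adaptive propagation: out = A %*% H where A = sparse(i, j, vals * nrm).
# `vals` is the learnable per-edge weight vector (a leaf), `nrm` the fixed
# symmetric-normalization coefficient at the same index, so the product is
# the Hadamard reweighting of the normalized adjacency on its own pattern.
tgAdaptiveSpmm <- function(tp, valsId, h, i, j, nrm, n) {
  vals <- tgValue(tp, valsId)
  H <- tgValue(tp, h)
  A <- Matrix::sparseMatrix(i = i, j = j, x = as.vector(vals) * nrm,
                            dims = c(n, n))
  tgNode(tp, as.matrix(A %*% H), c(valsId, h), function(g) {
    dvals <- nrm * rowSums(g[i, , drop = FALSE] * H[j, , drop = FALSE])
    list(dvals, as.matrix(Matrix::crossprod(A, g)))
  })
}

## ---- attention plumbing ----

# scale rows of H by a per-row coefficient column a (N x 1)
tgRowScale <- function(tp, a, h) {
  av <- as.vector(tgValue(tp, a))
  H <- tgValue(tp, h)
  tgNode(tp, H * av, c(a, h), function(g)
    list(matrix(rowSums(g * H), ncol = 1L), g * av))
}

tgCbind <- function(tp, ids) {
  vals <- lapply(ids, function(id) tgValue(tp, id))
  dims <- vapply(vals, ncol, 1L)
  ends <- cumsum(dims)
  starts <- ends - dims + 1L
  tgNode(tp, do.call(cbind, vals), as.integer(ids), function(g)
    lapply(seq_along(ids), function(k) g[, starts[k]:ends[k], drop = FALSE]))
}

tgColumn <- function(tp, a, k) {
  A <- tgValue(tp, a)
  tgNode(tp, A[, k, drop = FALSE], a, function(g) {
    dA <- A * 0
    dA[, k] <- g
    list(dA)
  })
}

# softmax across the columns of each row
tgSoftmaxRows <- function(tp, a) {
  A <- tgValue(tp, a)
  m <- apply(A, 1L, max)
  E <- exp(A - m)
  P <- E / rowSums(E)
  tgNode(tp, P, a, function(g) list(P * (g - rowSums(g * P))))
}

## ---- fused ZINB negative log-likelihood ----

# Mean negative ZINB log-likelihood of counts x under (mu, theta, pi) with
# analytic gradients; the x = 0 branch mixes the zero mass with NB(0)
# through a stable direct evaluation (both terms are probabilities < 1).
tgZinbNll <- function(tp, muId, thetaId, piId, x) {
  mu <- tgValue(tp, muId); th <- tgValue(tp, thetaId); pp <- tgValue(tp, piId)
  n <- length(x)
  z <- x == 0
  logp0 <- th * (log(th) - log(th + mu))      # log NB(0 | mu, theta)
  p0 <- exp(logp0)
  ll <- numeric(n); dim(ll) <- dim(mu)
  L0 <- pp + (1 - pp) * p0
  ll[z] <- log(L0[z])
  lnb <- lgamma(x + th) - lgamma(th) - lgamma(x + 1) +
    th * (log(th) - log(th + mu)) + x * (log(mu) - log(th + mu))
  ll[!z] <- log1p(-pp[!z]) + lnb[!z]
  val <- -sum(ll) / n
  tgNode(tp, val, c(muId, thetaId, piId), function(g) {
    dmu <- numeric(n); dth <- numeric(n); dpi <- numeric(n)
    dim(dmu) <- dim(dth) <- dim(dpi) <- dim(mu)
    # x = 0: d/d. of log(pi + (1-pi) p0)
    w <- (1 - pp[z]) * p0[z] / L0[z]
    dpi[z] <- (1 - p0[z]) / L0[z]
    dmu[z] <- w * (-th[z] / (th[z] + mu[z]))
    dth[z] <- w * (log(th[z]) + 1 - log(th[z] + mu[z]) -
                     th[z] / (th[z] + mu[z]))
    # x > 0: d/d. of log(1-pi) + log NB
    nz <- !z
    dpi[nz] <- -1 / (1 - pp[nz])
    dmu[nz] <- x[nz] / mu[nz] - (x[nz] + th[nz]) / (th[nz] + mu[nz])
    dth[nz] <- digamma(x[nz] + th[nz]) - digamma(th[nz]) +
      log(th[nz]) + 1 - log(th[nz] + mu[nz]) -
      (x[nz] + th[nz]) / (th[nz] + mu[nz])
    s <- -g / n
    list(s * dmu, s * dth, s * dpi)
  })
}
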
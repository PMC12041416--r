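test_that("NB log-pmf matches geometric closed forms and dnbinom", {
  expect_equal(exp(nbLogPMF(0, mu = 1, theta = 1)), 0.5)
  expect_equal(exp(nbLogPMF(1, mu = 1, theta = 1)), 0.25)
  # independent implementation: stats::dnbinom in mean/size form
  set.seed(19)
  for (i in 1:50) {
    x <- rpois(1, 5); mu <- rexp(1) + 0.1; th <- rexp(1) + 0.1
    expect_equal(nbLogPMF(x, mu, th),
                 dnbinom(x, size = th, mu = mu, log = TRUE),
                 tolerance = 1e-10)
  }
})

test_that("NB approaches Poisson as dispersion grows", {
  x <- 0:10
  expect_equal(exp(nbLogPMF(x, mu = 2, theta = 1e6)),
               dpois(x, 2), tolerance = 1e-4)
})

test_that("ZINB log-pmf honors its mixture structure", {
  # pure zero mass
  expect_equal(exp(zinbLogPMF(0, pi = 1, mu = 3, theta = 2)), 1)
  # pi = 0 reduces exactly to the NB
  x <- c(0, 1, 4, 9)
  expect_identical(zinbLogPMF(x, 0, 2.5, 0.7), nbLogPMF(x, 2.5, 0.7))
  # hand-computed mixture at x = 0
  expect_equal(exp(zinbLogPMF(0, 0.5, 1, 1)), 0.75)
  # zero mass increases monotonically in pi
  p <- exp(zinbLogPMF(rep(0, 5), seq(0.1, 0.9, 0.2), 2, 1))
  expect_true(all(diff(p) > 0))
})

test_that("ZINB pmf sums to one over the count support", {
  for (par in list(c(0.3, 2, 1), c(0.05, 10, 0.5), c(0.7, 1, 5))) {
    tot <- sum(exp(zinbLogPMF(0:5000, par[1], par[2], par[3])))
    expect_equal(tot, 1, tolerance = 1e-4)
  }
})

test_that("zinbLoss agrees with direct pmf evaluation on random tuples", {
  set.seed(23)
  n <- 100
  x <- rpois(n, 3)
  pi <- runif(n, 0.01, 0.9)
  mu <- rexp(n, 0.3) + 0.05
  th <- rexp(n, 0.5) + 0.05
  # independent oracle: direct density of the mixture via dnbinom
  oracle <- log(pi * (x == 0) + (1 - pi) * dnbinom(x, size = th, mu = mu))
  expect_equal(zinbLogPMF(x, pi, mu, th), oracle, tolerance = 1e-6)
  lam <- 0.7
  expect_equal(zinbLoss(x, mu, th, pi, lambda_pi = lam),
               -mean(oracle) + lam * mean(pi^2), tolerance = 1e-6)
})

test_that("zinbLoss reduces to NB likelihood at pi = 0 and to the ridge at the perfect-zero fit", {
  set.seed(4)
  x <- matrix(rpois(20, 2), 4)
  mu <- matrix(rexp(20) + 0.1, 4); th <- matrix(rexp(20) + 0.1, 4)
  expect_equal(zinbLoss(x, mu, th, pi = x * 0, lambda_pi = 0),
               -mean(dnbinom(x, size = th, mu = mu, log = TRUE)),
               tolerance = 1e-8)
  # all-zero counts with pi -> 1: NLL term vanishes, ridge -> lambda
  z <- x * 0
  pi1 <- z + (1 - 1e-9)
  expect_equal(zinbLoss(z, mu, th, pi1, lambda_pi = 2), 2,
               tolerance = 1e-6)
  # sum reduction scales by the entry count
  p <- matrix(runif(20, 0.1, 0.5), 4)
  expect_equal(zinbLoss(x, mu, th, p, 1, reduction = "sum"),
               20 * zinbLoss(x, mu, th, p, 1), tolerance = 1e-10)
})

test_that("decoder outputs respect parameter ranges and shapes", {
  set.seed(12)
  n <- 7; d <- 5; M <- 9
  dec <- newDecoder(d, M, hidden = 6)
  H <- matrix(rnorm(n * d), n)
  out <- decodeZINB(H, dec)
  expect_equal(dim(out$mu), c(n, M))
  expect_equal(dim(out$theta), c(n, M))
  expect_equal(dim(out$pi), c(n, M))
  expect_true(all(out$mu > 0))
  expect_true(all(out$theta > 0))
  expect_true(all(out$pi > 0 & out$pi < 1))
  # zero weights, zero embedding: mu = exp(0) = 1, pi = logistic(0) = 0.5
  dec0 <- lapply(dec, function(m) m * 0)
  out0 <- decodeZINB(matrix(0, 2, d), dec0)
  expect_equal(out0$mu, matrix(1, 2, M))
  expect_equal(out0$pi, matrix(0.5, 2, M))
  # gene-level dispersion broadcasts one theta per gene
  outg <- decodeZINB(H, dec, dispersion = "gene")
  expect_equal(outg$theta, matrix(outg$theta[1, ], n, M, byrow = TRUE))
})

test_that("fused ZINB loss op has finite, correct gradients at extreme counts", {
  sgf <- asNamespace("SpaGraphFusion")
  set.seed(33)
  x <- matrix(c(0, 1, 5, 1e4), 2)
  mu <- matrix(rexp(4) + 0.5, 2); th <- matrix(rexp(4) + 0.5, 2)
  pi <- matrix(runif(4, 0.1, 0.9), 2)
  tp <- sgf$tapeNew()
  ids <- c(mu = sgf$tgLeaf(tp, mu), th = sgf$tgLeaf(tp, th),
           pi = sgf$tgLeaf(tp, pi))
  loss <- sgf$tgZinbNll(tp, ids["mu"], ids["th"], ids["pi"], x)
  expect_equal(sgf$tgValue(tp, loss),
               -mean(zinbLogPMF(x, pi, mu, th)), tolerance = 1e-10)
  gr <- sgf$tgBackward(tp, loss)
  for (nm in names(ids)) {
    g <- gr[[ids[nm]]]
    expect_true(all(is.finite(g)))
    # finite-difference check on every entry
    ref <- list(mu = mu, th = th, pi = pi)[[nm]]
    for (ii in seq_along(ref)) {
      eps <- 1e-6 * max(1, abs(ref[ii]))
      up <- list(mu = mu, th = th, pi = pi); up[[nm]][ii] <- ref[ii] + eps
      dn <- list(mu = mu, th = th, pi = pi); dn[[nm]][ii] <- ref[ii] - eps
      num <- (-mean(zinbLogPMF(x, up$pi, up$mu, up$th)) +
               mean(zinbLogPMF(x, dn$pi, dn$mu, dn$th))) / (2 * eps)
      expect_equal(g[ii], num, tolerance = 1e-4)
    }
  }
})
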
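test_that("simulated slides honor geometry, determinism and error contracts", {
  cfg <- sgfSimConfig(grid_side = 6, n_domains = 3, n_genes = 30,
                      n_marker_per_domain = 5, seed = 77)
  sl <- simulateSlide(cfg)
  expect_equal(ncol(sl), 36L)
  expect_equal(nrow(sl), 30L)
  expect_equal(sort(unique(domainLabels(sl))), 1:3)
  # bands: domain is a function of the y coordinate alone
  expect_true(all(tapply(domainLabels(sl), spatialCoords(sl)[, "y"],
                         function(v) length(unique(v))) == 1))
  # same seed, same counts
  sl2 <- simulateSlide(cfg)
  expect_identical(as.matrix(SummarizedExperiment::assay(sl, "counts")),
                   as.matrix(SummarizedExperiment::assay(sl2, "counts")))
  expect_error(simulateSlide(sgfSimConfig(grid_side = 3, n_domains = 4,
                                          n_genes = 10,
                                          n_marker_per_domain = 2)),
               "n_domains exceeds")
  expect_error(sgfSimConfig(fold_change = 1), "fold_change")
  expect_error(sgfSimConfig(pi_sim = 1), "pi_sim")
})

test_that("sample means approach planted means in the Poisson limit", {
  cfg <- sgfSimConfig(grid_side = 30, n_domains = 3, n_genes = 60,
                      n_marker_per_domain = 6, base_mean = 2,
                      fold_change = 3, theta_sim = 1e6, pi_sim = 0,
                      seed = 55)
  sl <- simulateSlide(cfg)
  cts <- as.matrix(SummarizedExperiment::assay(sl, "counts"))
  dom <- domainLabels(sl)
  marker_of <- S4Vectors::metadata(sl)$marker_of
  for (d in 1:3) {
    own <- which(marker_of == d)
    inside <- mean(cts[own, dom == d])
    outside <- mean(cts[own, dom != d])
    expect_equal(inside, 6, tolerance = 0.05)
    expect_equal(outside, 2, tolerance = 0.05)
  }
  bg <- which(is.na(marker_of))
  expect_equal(mean(cts[bg, ]), 2, tolerance = 0.05)
})

test_that("dropout floors the zero fraction and NB counts are overdispersed", {
  cfg <- sgfSimConfig(grid_side = 12, n_domains = 2, n_genes = 50,
                      n_marker_per_domain = 5, pi_sim = 0.9, seed = 31)
  cts <- as.matrix(SummarizedExperiment::assay(simulateSlide(cfg), "counts"))
  expect_gte(mean(cts == 0), 0.9)

  cfg2 <- sgfSimConfig(grid_side = 15, n_domains = 2, n_genes = 40,
                       n_marker_per_domain = 4, base_mean = 5,
                       theta_sim = 0.3, pi_sim = 0, seed = 32)
  cts2 <- as.matrix(SummarizedExperiment::assay(simulateSlide(cfg2),
                                                "counts"))
  gv <- apply(cts2, 1, var); gm <- rowMeans(cts2)
  expect_true(mean(gv > gm) > 0.95)
})

test_that("planted labels are more spatially coherent than permuted ones", {
  sl <- simulateSlide(sgfSimConfig(grid_side = 10, n_domains = 3,
                                   n_genes = 20, n_marker_per_domain = 3,
                                   seed = 6))
  g <- buildSpatialGraph(spatialCoords(sl), 1.0)
  pairs <- SpaGraphFusion:::positivePairs(g)
  lab <- domainLabels(sl)
  agree <- function(l) mean(l[pairs[, 1]] == l[pairs[, 2]])
  a0 <- agree(lab)
  set.seed(3)
  for (i in 1:20) expect_gt(a0, agree(sample(lab)))
})

test_that("fixture suite pins sizes and balanced bands", {
  fx <- makeFixtureSuite()
  expect_equal(ncol(fx$tiny), 25L)
  expect_equal(nrow(fx$tiny), 20L)
  expect_equal(length(unique(domainLabels(fx$tiny))), 2L)
  expect_equal(ncol(fx$small), 900L)
  expect_equal(unname(table(domainLabels(fx$small))), rep(300L, 3),
               ignore_attr = TRUE)
  # pinned seed: counts reproduce exactly
  fx2 <- makeFixtureSuite()
  expect_identical(
    as.matrix(SummarizedExperiment::assay(fx$small, "counts")),
    as.matrix(SummarizedExperiment::assay(fx2$small, "counts")))
})

test_that("voronoi geometry yields K connected-ish irregular domains", {
  sl <- simulateSlide(sgfSimConfig(grid_side = 8, n_domains = 3,
                                   n_genes = 20, n_marker_per_domain = 3,
                                   geometry = "voronoi", seed = 12))
  expect_equal(sort(unique(domainLabels(sl))), 1:3)
  # each spot belongs to the nearest of the (reproducible) centers, so
  # domains partition all 64 spots
  expect_equal(length(domainLabels(sl)), 64L)
})
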
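test_that("Slatkin linearization follows D = Fst/(1 - Fst)", {
  expect_equal(slatkin_linearize(0), 0)
  expect_equal(slatkin_linearize(0.5), 1)
  expect_equal(slatkin_linearize(-0.01), -0.0099009900990099,
               tolerance = 1e-12)
  expect_error(slatkin_linearize(1), "infinite")
})

test_that("BH adjustment matches the step-up oracle and its properties", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(44)
  for (r in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("permutation p for a fixed pair is seeded and hits the floor", {
  sim <- simulate_divergence_populations(
    sim_config(2, 12, 300, 12, 0, seed = 21))
  p <- fst_permutation_p(sim$dataset, c("P01", "P02"), n_perm = 999, seed = 2)
  expect_equal(p, 1 / 1000)  # minimum attainable, never exactly 0
  p2 <- fst_permutation_p(sim$dataset, c("P01", "P02"), n_perm = 999, seed = 2)
  expect_identical(p, p2)
})

test_that("fst_analysis produces coherent symmetric results", {
  sim <- simulate_divergence_populations(
    sim_config(3, 6, 150, 5, 1, groups = list(1, 2, 3), seed = 61))
  fr <- fst_analysis(sim$dataset, n_perm = 99, seed = 3)
  expect_true(isSymmetric(fr$fst))
  expect_true(all(diag(fr$fst) == 0))
  low <- lower.tri(fr$fst)
  expect_true(all(fr$adjusted_pvalues[low] >= fr$pvalues[low]))
  expect_true(all(fr$pvalues[low] > 0 & fr$pvalues[low] <= 1))
  expect_equal(fr$linearized[low],
               fr$fst[low] / (1 - fr$fst[low]), tolerance = 1e-12)
})

test_that("the Fst matrix ignores within-population sample order", {
  sim <- simulate_divergence_populations(
    sim_config(3, 5, 100, 4, 2, seed = 13))
  ds <- sim$dataset
  m1 <- pairwise_phist(ds)
  set.seed(2)
  perm <- order(ds$samples$population, runif(nrow(ds$samples)))
  ds2 <- mt_dataset(ds$samples[perm, ], ds$region, ds$metadata)
  expect_equal(m1, pairwise_phist(ds2), tolerance = 1e-12)
})

test_that("small populations are rejected with their name", {
  sim <- simulate_divergence_populations(sim_config(2, c(1, 4), 80, 3, 1,
                                                    seed = 2))
  expect_error(pairwise_phist(sim$dataset), "P01")
})

test_that("classical MDS respects symmetric configurations", {
  D <- matrix(1, 3, 3); diag(D) <- 0
  emb <- mds_embed(D, dims = 2, mode = "classical")
  pd <- as.matrix(dist(emb$points))
  off <- pd[upper.tri(pd)]
  expect_true(max(off) - min(off) < 1e-9)
})

test_that("nonmetric MDS recovers embeddable configurations", {
  set.seed(10)
  pts <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(dist(pts))
  emb <- mds_embed(D, dims = 2, mode = "nonmetric", seed = 1)
  expect_lt(emb$stress, 1e-6)
})

test_that("nonmetric stress never exceeds the classical-seeded stress", {
  set.seed(20)
  for (r in 1:20) {
    D <- matrix(runif(64), 8, 8); D <- D + t(D); diag(D) <- 0
    cls <- mds_embed(D, mode = "classical")
    nm <- mds_embed(D, mode = "nonmetric", seed = r)
    expect_lte(nm$stress, cls$stress + 1e-9)
  }
})

test_that("negative dissimilarities are clamped before embedding", {
  D <- matrix(c(0, -0.01, 0.3, -0.01, 0, 0.2, 0.3, 0.2, 0), 3, 3)
  emb <- suppressWarnings(mds_embed(D, mode = "classical"))
  expect_true(all(is.finite(emb$points)))
  expect_error(mds_embed(D, dims = 3), "dims")
})
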
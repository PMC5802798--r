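sim_two_group <- function(seed, n_pop = 4, n = 5, L = 60, d = 6, theta = 2) {
  sizes <- if (length(n) == 1) rep(n, n_pop) else n
  simulate_divergence_populations(
    sim_config(n_pop, sizes, L, d, theta,
               groups = list(seq_len(n_pop %/% 2),
                             (n_pop %/% 2 + 1):n_pop), seed = seed))
}

test_that("variance components match the definitional double-loop oracle", {
  for (s in 1:10) {
    set.seed(s)
    sizes <- sample(3:8, 4, replace = TRUE)
    sim <- sim_two_group(800 + s, n = sizes)
    ds <- sim$dataset
    g <- mt_grouping(list(A = c("P01", "P02"), B = c("P03", "P04")))
    a <- variance_components(ds, g)
    o <- oracle_amova(ds$samples$sequence, ds$samples$population, c(1, 1, 2, 2))
    expect_equal(a$sigma_a, o$sigma_a, tolerance = 1e-10)
    expect_equal(a$sigma_b, o$sigma_b, tolerance = 1e-10)
    expect_equal(a$sigma_c, o$sigma_c, tolerance = 1e-10)
    expect_equal(unname(a$ssd), unname(o$ssd), tolerance = 1e-10)
  }
})

test_that("sums of squares decompose additively", {
  sim <- sim_two_group(31)
  a <- variance_components(sim$dataset,
                           mt_grouping(list(A = c("P01", "P02"),
                                            B = c("P03", "P04"))))
  expect_equal(unname(a$ssd["total"]),
               unname(a$ssd["ag"] + a$ssd["apwg"] + a$ssd["wp"]),
               tolerance = 1e-9)
})

test_that("complete fixation with one population per group gives Phi_CT = 1", {
  sim <- simulate_divergence_populations(sim_config(2, 5, 100, 8, 0, seed = 4))
  a <- variance_components(sim$dataset,
                           mt_grouping(list(A = "P01", B = "P02")))
  expect_equal(a$phi_ct, 1)
  expect_equal(a$sigma_c, 0)
})

test_that("one-group AMOVA equals pairwise Phi_ST and the two-level model", {
  sim <- sim_two_group(55)
  ds <- sim$dataset
  pp <- pairwise_phist(ds)
  for (pair in list(c("P01", "P02"), c("P01", "P03"), c("P02", "P04"))) {
    a <- variance_components(ds, mt_grouping(list(A = pair)))
    expect_identical(unname(pp[pair[1], pair[2]]), a$phi_st)
    expect_true(is.na(a$sigma_a))
  }
  # collapsing all groups into one reduces three-level Phi_ST to two-level
  all_one <- variance_components(ds, mt_grouping(list(A = ds$populations)))
  # definitional two-level oracle, explicit loops
  seqs <- ds$samples$sequence; pop <- ds$samples$population
  n <- length(seqs)
  d2 <- matrix(0, n, n)
  ch <- lapply(seqs, seq_chars)
  for (i in 1:n) for (j in 1:n) d2[i, j] <- sum(ch[[i]] != ch[[j]])
  pops <- unique(pop); P <- length(pops)
  n_p <- sapply(pops, function(p) sum(pop == p))
  sstot <- sum(d2) / (2 * n)
  sswp <- sum(sapply(pops, function(p) {
    idx <- which(pop == p); sum(d2[idx, idx]) / (2 * length(idx))
  }))
  sc <- sswp / (n - P)
  nc <- (n - sum(n_p^2) / n) / (P - 1)
  sb <- ((sstot - sswp) / (P - 1) - sc) / nc
  expect_equal(all_one$phi_st, sb / (sb + sc), tolerance = 1e-10)
})

test_that("AMOVA is invariant to individual and population ordering", {
  sim <- sim_two_group(91)
  ds <- sim$dataset
  g <- mt_grouping(list(A = c("P01", "P02"), B = c("P03", "P04")))
  a <- variance_components(ds, g)
  set.seed(1)
  perm <- sample(nrow(ds$samples))
  ds2 <- mt_dataset(ds$samples[perm, ], ds$region, ds$metadata)
  g2 <- mt_grouping(list(B = c("P04", "P03"), A = c("P02", "P01")))
  a2 <- variance_components(ds2, g2)
  expect_equal(a$sigma_a, a2$sigma_a, tolerance = 1e-12)
  expect_equal(a$phi_ct, a2$phi_ct, tolerance = 1e-12)
  expect_equal(a$phi_st, a2$phi_st, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected informatively", {
  sim <- simulate_divergence_populations(sim_config(2, 3, 50, 0, 0, seed = 1))
  expect_error(variance_components(sim$dataset,
                                   mt_grouping(list(A = c("P01", "P02")))),
               "zero total variance")
  sim2 <- sim_two_group(7)
  expect_error(variance_components(sim2$dataset,
                                   mt_grouping(list(A = c("P01", "NOPE")))),
               "NOPE")
})

test_that("permutation p-values are seeded and detect planted structure", {
  sim <- sim_two_group(12, n = 6, d = 8, theta = 1)
  g <- mt_grouping(list(A = c("P01", "P02"), B = c("P03", "P04")))
  p1 <- suppressWarnings(amova_permutation(sim$dataset, g, n_perm = 99,
                                           seed = 5))
  p2 <- suppressWarnings(amova_permutation(sim$dataset, g, n_perm = 99,
                                           seed = 5))
  expect_identical(c(p1$p_ct, p1$p_sc, p1$p_st), c(p2$p_ct, p2$p_sc, p2$p_st))
  expect_lt(p1$p_st, 0.05)
  # few distinct population-level permutations -> warns about replacement
  expect_warning(amova_permutation(sim$dataset, g, n_perm = 99, seed = 1),
                 "replacement")
})

test_that("grouping enumeration counts set partitions correctly", {
  pops <- c("F1", "F2", "A", "B", "C")
  g2 <- enumerate_groupings(pops, fixed_block = c("F1", "F2"), n_groups = 2)
  expect_length(g2, 1)  # all free populations together
  g3 <- enumerate_groupings(pops, fixed_block = c("F1", "F2"), n_groups = 3)
  expect_length(g3, 4)  # 1 + S(3,2) = 4
  gall <- enumerate_groupings(c("A", "B"), fixed_block = c("A", "B"),
                              n_groups = 2)
  expect_length(gall, 1)
  expect_error(enumerate_groupings(pops, n_groups = 1), ">= 2")
  # canonical deterministic ordering
  g3b <- enumerate_groupings(pops, fixed_block = c("F1", "F2"), n_groups = 3)
  expect_identical(lapply(g3, `[[`, "groups"), lapply(g3b, `[[`, "groups"))
})

test_that("grouping search ranks by Phi_CT and resolves ties by Phi_SC", {
  sim <- simulate_divergence_populations(
    sim_config(6, 8, 200, 8, 1, groups = list(1:2, 3:4, 5:6), seed = 303))
  pops <- sim$dataset$populations
  truth <- sim$truth$partition
  wrong <- mt_grouping(list(A = pops[c(1, 3)], B = pops[c(2, 5)],
                            C = pops[c(4, 6)]), "wrong")
  gs <- grouping_search(sim$dataset, list(wrong, truth))
  expect_equal(canon_partition(gs$optimum$groups),
               canon_partition(truth$groups))
  expect_equal(gs$table$name[1], "generating")
  single <- grouping_search(sim$dataset, list(wrong))
  expect_equal(single$optimum$name, "wrong")
  expect_error(grouping_search(sim$dataset, list()), "empty")
})
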
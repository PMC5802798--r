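dataset_from_seqs <- function(seqs, ids = sprintf("s%02d", seq_along(seqs))) {
  mt_dataset(data.frame(sample_id = ids, population = "P", epoch = "IA",
                        sequence = seqs), mt_region(1, nchar(seqs[1])))
}

test_that("identical sequences collapse into haplotype nodes", {
  ds <- dataset_from_seqs(c("AAAA", "AAAA", "AAAA", "CCCC"))
  col <- collapse_haplotypes(ds)
  expect_equal(nrow(col$nodes), 2)
  expect_setequal(col$nodes$size, c(3, 1))
  expect_equal(sum(lengths(col$members)), 4)
  expect_equal(col$nodes$node[1], "s01")  # lexicographically first member
  all_diff <- collapse_haplotypes(dataset_from_seqs(c("AAAA", "CCCC", "GGGG")))
  expect_equal(nrow(all_diff$nodes), 3)
})

test_that("the MSN keeps all tied minimum spanning edges", {
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  g <- build_msn(c("A", "B", "C"), D)
  expect_setequal(edge_key(g$edges), c("A~B", "B~C"))
  Deq <- matrix(1, 3, 3); diag(Deq) <- 0
  expect_equal(nrow(build_msn(c("A", "B", "C"), Deq)$edges), 3)
})

test_that("the MSN equals the exhaustive union of minimum spanning trees", {
  set.seed(101)
  for (r in 1:25) {
    n <- sample(3:6, 1)
    D <- matrix(0, n, n)
    D[upper.tri(D)] <- sample(1:4, n * (n - 1) / 2, replace = TRUE)
    D <- D + t(D)
    labels <- LETTERS[1:n]
    g <- build_msn(labels, D)
    oe <- oracle_msn(D)
    expect_setequal(edge_key(g$edges),
                    paste(labels[oe[, 1]], labels[oe[, 2]], sep = "~"))
  }
})

test_that("the MSN is invariant to node order and epsilon relaxes it", {
  set.seed(55)
  n <- 6
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- sample(1:5, 15, replace = TRUE)
  D <- D + t(D)
  labels <- letters[1:n]
  g1 <- build_msn(labels, D)
  perm <- sample(n)
  g2 <- build_msn(labels[perm], D[perm, perm])
  expect_setequal(edge_key(g1$edges), edge_key(g2$edges))
  g_eps <- build_msn(labels, D, epsilon = 2)
  expect_true(all(edge_key(g1$edges) %in% edge_key(g_eps$edges)))
  expect_gte(nrow(g_eps$edges), nrow(g1$edges))
})

test_that("distance-d pairs are found exactly and disjointly", {
  sim <- simulate_divergence_populations(
    sim_config(2, 6, 150, 6, 1, seed = 71,
               n_identical_pairs = 1, n_one_diff_pairs = 1))
  ds <- sim$dataset
  p0 <- find_pairs_at_distance(ds, 0)
  p1 <- find_pairs_at_distance(ds, 1)
  planted <- sim$truth$planted_pairs
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_true(key(planted$sample1[1], planted$sample2[1]) %in%
                key(p0$sample1, p0$sample2))
  expect_true(key(planted$sample1[2], planted$sample2[2]) %in%
                key(p1$sample1, p1$sample2))
  expect_length(intersect(key(p0$sample1, p0$sample2),
                          key(p1$sample1, p1$sample2)), 0)
})

test_that("deduplication keeps one member per identical-sequence component", {
  ds <- dataset_from_seqs(c("AAAA", "AAAA", "AAAA", "CCCC", "GGGG"),
                          ids = c("z", "a", "m", "b", "c"))
  dd <- deduplicate(ds)
  expect_equal(nrow(dd$removed), 2)  # component rule on the triple
  expect_equal(unique(dd$removed$kept_as), "a")
  expect_setequal(dd$dataset$samples$sample_id, c("a", "b", "c"))
  clean <- deduplicate(dataset_from_seqs(c("AAAA", "CCCC")))
  expect_equal(nrow(clean$removed), 0)
  expect_equal(nrow(clean$dataset$samples), 2)
})

test_that("msn() on a dataset spans every haplotype connectedly", {
  sim <- simulate_divergence_populations(sim_config(1, 12, 120, 0, 2,
                                                    seed = 14))
  g <- msn(sim$dataset)
  # connectivity: walk the edge list
  reach <- g$nodes[1]
  repeat {
    grow <- unique(c(reach, g$edges$to[g$edges$from %in% reach],
                     g$edges$from[g$edges$to %in% reach]))
    if (length(grow) == length(reach)) break
    reach <- grow
  }
  expect_setequal(reach, g$nodes)
  expect_true(all(g$edges$weight >= 1))
  expect_equal(sum(lengths(g$members)), 12)
})
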
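test_that("bin assignment follows longest-prefix specificity", {
  cept <- bin_scheme("CEPT23")
  expect_equal(assign_bin("U5a1d1", cept), "U5a")
  expect_equal(assign_bin("H5a1", cept), "H5")
  expect_equal(assign_bin("H1f1a", cept), "H")
  expect_equal(assign_bin("HV18", cept), "HV")
  expect_equal(assign_bin("HV0a", cept), "HV0")
  expect_equal(assign_bin("V3", cept), "V")
  expect_equal(assign_bin("N1a1", cept), "N1a")
  expect_equal(assign_bin("T2b16", cept), "T2")
  expect_equal(assign_bin("L3e", cept), "others")
  ept <- bin_scheme("EPT25")
  expect_equal(assign_bin("C4a", ept), "Asian")
  expect_equal(assign_bin("V3", ept), "V/HV0")
  world <- bin_scheme("WORLD23")
  expect_equal(assign_bin("L3e", world), "African")
  expect_equal(assign_bin("I1a", world), "I1")
  expect_equal(assign_bin("I4a", world), "I")
})

test_that("bin assignment is total and idempotent", {
  cept <- bin_scheme("CEPT23")
  labels <- c("H5a1", "U5b1d1", "garbage", "", NA, "X2c1", "K2a")
  b1 <- assign_bin(labels, cept)
  expect_true(all(b1 %in% cept$bins))
  expect_equal(assign_bin(b1, cept), b1)
})

test_that("frequency matrices conserve counts and normalize rows", {
  a <- data.frame(population = "X",
                  haplogroup = c("H1a", "H5a1", "U5b1d"))
  fm <- build_frequency_matrix(a, bin_scheme("CEPT23"))
  expect_equal(unname(fm$counts[1, c("H", "H5", "U5b")]), c(1, 1, 1))
  expect_equal(sum(fm$counts), 3)
  expect_equal(unname(rowSums(fm$freq)), 1)
  # row order of the input does not matter
  b <- a[c(3, 1, 2), ]
  expect_equal(build_frequency_matrix(b, bin_scheme("CEPT23"))$counts,
               fm$counts)
})

test_that("the published assignments give a conserved 40-sample row", {
  kept <- filter_assignments(kowalewko_assignments(), 0, 0,
                             c("PCA0018", "PCA0063"))$kept
  kept$population <- "Kow-OVIA"
  fm <- build_frequency_matrix(kept, bin_scheme("CEPT23"))
  expect_equal(sum(fm$counts), 40)
  expect_equal(unname(rowSums(fm$freq)), 1, tolerance = 1e-9)
})

test_that("Ward clustering merges closest profiles first, deterministically", {
  m <- rbind(a = c(0.5, 0.5), b = c(0.5, 0.5), c = c(0.9, 0.1))
  hc <- ward_cluster(m)
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))  # identical pair first
  expect_equal(hc$height[1], 0)
  m2 <- cbind(x = c(p0 = 0, p1 = 1, p10 = 10))
  hc2 <- ward_cluster(m2)
  expect_setequal(clade_labels(hc2)[[1]], c("p0", "p1"))
  # row order invariance of the clade sets
  m3 <- m2[c(3, 1, 2), , drop = FALSE]
  expect_setequal(sapply(clade_labels(ward_cluster(m3)), paste, collapse = "+"),
                  sapply(clade_labels(hc2), paste, collapse = "+"))
  expect_error(ward_cluster(m[1, , drop = FALSE]), ">= 2")
})

test_that("bootstrap support is seeded, bounded, and finds planted splits", {
  # two well-separated blocks with duplicated column structure
  counts <- rbind(A1 = c(40, 38, 41, 2, 1, 2), A2 = c(39, 41, 40, 1, 2, 1),
                  B1 = c(2, 1, 1, 40, 39, 41), B2 = c(1, 2, 2, 38, 42, 40))
  colnames(counts) <- c("h1", "h2", "h3", "u1", "u2", "u3")
  fm <- freq_matrix(counts)
  bs <- bootstrap_support(fm, n_boot = 200, seed = 9)
  expect_true(all(bs$support >= 0 & bs$support <= 100))
  sets <- clade_labels(bs$hclust)
  planted <- which(sapply(sets, function(s)
    setequal(s, c("A1", "A2")) || setequal(s, c("B1", "B2"))))
  expect_true(all(bs$support[planted] > 95))
  bs2 <- bootstrap_support(fm, n_boot = 200, seed = 9)
  expect_identical(bs$support, bs2$support)
  expect_error(bootstrap_support(fm, n_boot = 0), "n_boot")
})

test_that("frequency PCA matches an independent eigen solver up to sign", {
  set.seed(23)
  for (r in 1:5) {
    m <- matrix(runif(10 * 25), 10, 25)
    m <- m / rowSums(m)
    pc <- pca_frequencies(m)
    expect_equal(sum(pc$explained), 1, tolerance = 1e-9)
    cm <- scale(m, center = TRUE, scale = FALSE)
    ev <- eigen(crossprod(cm) / (nrow(m) - 1), symmetric = TRUE)
    k <- min(nrow(m) - 1, 5)
    sco <- cm %*% ev$vectors[, seq_len(k)]
    for (j in seq_len(k))
      expect_lt(min(max(abs(pc$scores[, j] - sco[, j])),
                    max(abs(pc$scores[, j] + sco[, j]))), 1e-8)
  }
  two <- pca_frequencies(rbind(c(0.2, 0.8), c(0.7, 0.3)))
  expect_equal(two$explained[1], 1, tolerance = 1e-9)
  expect_error(pca_frequencies(matrix(1, 1, 3)), ">= 2")
})

test_that("metapopulation resampling is uniform without replacement", {
  pool <- data.frame(sample_id = sprintf("i%04d", 1:2000),
                     country = rep(c("PL", "CZ", "DE", "AT"),
                                   times = c(800, 400, 500, 300)))
  all_in <- build_metapopulation(pool, n = 2000, seed = 1)
  expect_setequal(all_in$sample$sample_id, pool$sample_id)
  m1 <- build_metapopulation(pool, n = 500, seed = 1)
  m2 <- build_metapopulation(pool, n = 500, seed = 2)
  expect_equal(nrow(m1$sample), 500)
  expect_false(setequal(m1$sample$sample_id, m2$sample$sample_id))
  expect_false(anyDuplicated(m1$sample$sample_id) > 0)
  # country proportions track the pool over repeated draws
  tot <- Reduce(`+`, lapply(1:200, function(s)
    table(factor(build_metapopulation(pool, 500, seed = s)$sample$country,
                 levels = c("PL", "CZ", "DE", "AT")))))
  expected <- c(PL = 800, CZ = 400, DE = 500, AT = 300) / 2000 * sum(tot)
  chi <- sum((as.numeric(tot) - expected)^2 / expected)
  expect_gt(stats::pchisq(chi, df = 3, lower.tail = FALSE), 0.01)
  expect_error(build_metapopulation(pool, n = 3000), "smaller")
})

test_that("Fisher tests follow the hypergeometric and Monte-Carlo rules", {
  ex <- fisher_rxc(matrix(c(2, 0, 0, 2), 2, 2))
  expect_equal(ex$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(ex$method, "exact")
  same <- fisher_rxc(matrix(c(3, 3, 2, 2), 2, 2))
  expect_equal(same$p_value, 1)
  # Monte-Carlo agrees with the exact network algorithm on a small 2x3
  tab <- matrix(c(6, 1, 2, 5, 1, 4), 2, 3)
  mc <- fisher_rxc(tab, n_sim = 1e5, seed = 7)
  exact <- stats::fisher.test(tab)$p.value
  se <- sqrt(exact * (1 - exact) / 1e5)
  expect_lt(abs(mc$p_value - exact), 3 * se + 2e-5)
  expect_equal(mc$method, "monte-carlo")
  mc2 <- fisher_rxc(tab, n_sim = 1e4, seed = 5)
  expect_identical(mc2$p_value, fisher_rxc(tab, n_sim = 1e4, seed = 5)$p_value)
  expect_error(fisher_rxc(matrix(c(1, 0, 2, 0), 2, 2)), "all-zero")
  expect_error(fisher_rxc(matrix(1.5, 2, 2)), "integer")
})
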
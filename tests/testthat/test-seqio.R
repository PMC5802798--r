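test_that("regions use 1-based inclusive coordinates and compose", {
  expect_equal(region_length(mt_region(16064, 16400)), 337)
  expect_equal(region_length(mt_region(16033, 16365)), 333)
  joint <- mt_region(c(73, 16033), c(340, 16365), "HVS-II+HVS-I")
  expect_equal(region_length(joint), 268 + 333)
  expect_error(mt_region(0, 5), "1-based")
  expect_error(mt_region(10, 5), ">= start")
  expect_error(mt_region(c(1, 5), c(6, 9)), "overlap")
})

test_that("FASTA reading normalizes case, parses populations, slices rCRS", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1|KOW", "acgt", ">s2|BEC", "ttnn"), f)
  ds <- read_fasta(f, mt_region(1, 4))
  expect_equal(ds$samples$sequence, c("ACGT", "TTNN"))
  expect_equal(ds$samples$population, c("KOW", "BEC"))
  # full-length record sliced to an HVS fragment
  full <- paste(rep("A", 16569), collapse = "")
  writeLines(c(">w|X", full), f)
  ds2 <- read_fasta(f, mt_region(16064, 16400))
  expect_equal(nchar(ds2$samples$sequence), 337)
  # length mismatch names the offending record
  writeLines(c(">good|X", "ACGTA", ">bad|X", "ACG"), f)
  expect_error(read_fasta(f, mt_region(1, 5)), "bad")
  writeLines(character(0), f)
  expect_equal(nrow(read_fasta(f, mt_region(1, 5))$samples), 0)
})

test_that("FASTA round trip preserves the dataset", {
  sim <- simulate_divergence_populations(sim_config(2, 5, 40, 3, 1, seed = 11))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(sim$dataset, f)
  back <- read_fasta(f, sim$dataset$region)
  expect_equal(back$samples[c("sample_id", "population", "sequence")],
               sim$dataset$samples[c("sample_id", "population", "sequence")])
})

test_that("region slicing is associative and supports joint haplotypes", {
  sim <- simulate_divergence_populations(sim_config(1, 3, 100, 0, 2, seed = 2))
  ds <- sim$dataset
  twice <- slice_region(slice_region(ds, mt_region(11, 80)), mt_region(21, 50))
  once <- slice_region(ds, mt_region(21, 50))
  expect_equal(twice$samples$sequence, once$samples$sequence)
  single <- slice_region(ds, mt_region(5, 5))
  expect_equal(nchar(single$samples$sequence[1]), 1)
  joint <- slice_region(ds, mt_region(c(1, 51), c(20, 60)))
  expect_equal(nchar(joint$samples$sequence[1]), 30)
  expect_equal(joint$samples$sequence[1],
               paste0(substr(ds$samples$sequence[1], 1, 20),
                      substr(ds$samples$sequence[1], 51, 60)))
  expect_error(slice_region(once, mt_region(1, 99)), "not contained")
})

test_that("sex tokens parse and resolve with genetic precedence", {
  tok <- parse_sex_token(c("(M)/M", "(F)/-", "(F)/M", "(-)/-"))
  expect_equal(tok$anthropological_sex, c("M", "F", "F", "unknown"))
  expect_equal(tok$genetic_sex, c("M", "unknown", "M", "unknown"))
  rs <- resolve_sex(tok$anthropological_sex, tok$genetic_sex)
  expect_equal(rs$sex, c("M", "F", "M", "unknown"))
  expect_equal(rs$conflict, c(FALSE, FALSE, TRUE, FALSE))
  expect_error(resolve_sex("X", "F"), "F, M, unknown")
})

test_that("assignment filtering applies thresholds and exclusions", {
  m <- data.frame(sample_id = c("a", "b", "c", "d"),
                  anthropological_sex = "unknown", genetic_sex = "unknown",
                  haplogroup = c("H", "U5a", NA, "K"),
                  haplogroup_score = c(0.79, 0.8, 1, NA),
                  mean_coverage = c(10, 10, 10, 10))
  out <- filter_assignments(m, 0.8, 3)
  expect_equal(out$kept$sample_id, "b")  # >= keeps exactly 0.8
  expect_equal(nrow(out$kept) + nrow(out$dropped), nrow(m))
  out0 <- filter_assignments(m, 0, 0)
  expect_setequal(out0$kept$sample_id, c("a", "b", "d"))
  outx <- filter_assignments(m, 0, 0, exclusion_list = "a")
  expect_setequal(outx$kept$sample_id, c("b", "d"))
  expect_true(all(nzchar(out$dropped$reason)))
})

test_that("the published assignment table yields 40 analyzable individuals", {
  meta <- kowalewko_assignments()
  expect_equal(nrow(meta), 60)
  kept <- filter_assignments(meta, 0, 0,
                             exclusion_list = c("PCA0018", "PCA0063"))$kept
  expect_equal(nrow(kept), 40)
})

test_that("sample tables round trip", {
  meta <- kowalewko_assignments()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sample_table(meta, f)
  expect_equal(read_sample_table(f), meta)
})
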
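# Synthetic-data generator: a founder-divergence model producing datasets
# with controllable within-population diversity and between-group
# divergence, plus ground-truth records for recovery tests. Not a
# coalescent: the analyses under test need controllable within/between
# variance, not genealogical realism.

DEFAULT_HAPLOGROUP_PROFILE <- c(H = 0.25, H5 = 0.05, J = 0.08, K = 0.10,
                                T2 = 0.10, U3 = 0.07, U5a = 0.10,
                                U5b = 0.10, W = 0.05, I = 0.04, X = 0.03,
                                N1a = 0.03)

#' Simulation configuration
#'
#' Defaults describe the regime the package's validation runs use: three
#' populations of 20 individuals over a 400-nt region (the scale of an
#' HVS-I fragment), founder divergence of 8 expected fixed differences
#' between groups and one expected private mutation per individual.
#'
#' @param n_populations Number of populations.
#' @param n_per_population Individuals per population (scalar or vector).
#' @param region_length Sequence length (nt).
#' @param founder_divergence Expected fixed differences between founders
#'   of populations in different truth groups (`d`).
#' @param within_theta Expected private mutations per individual
#'   (`theta_w`).
#' @param groups Truth partition: list of population-index vectors
#'   (default: every population its own group).
#' @param epoch_labels Epoch per population (recycled).
#' @param haplogroup_profile Probability vector over haplogroup labels, or
#'   a list of one vector per population.
#' @param sex_ratio Fraction female.
#' @param n_identical_pairs,n_one_diff_pairs Planted duplicate /
#'   near-duplicate pairs appended to the dataset.
#' @param seed Integer seed.
#' @return List of class `mt_simconfig`.
#' @export
sim_config <- function(n_populations = 3, n_per_population = 20,
                       region_length = 400, founder_divergence = 8,
                       within_theta = 1, groups = NULL,
                       epoch_labels = "IA",
                       haplogroup_profile = DEFAULT_HAPLOGROUP_PROFILE,
                       sex_ratio = 0.5, n_identical_pairs = 0,
                       n_one_diff_pairs = 0, seed = 1) {
  stopifnot(n_populations >= 1, region_length >= 1, founder_divergence >= 0,
            within_theta >= 0, sex_ratio >= 0, sex_ratio <= 1)
  n_per_population <- rep_len(n_per_population, n_populations)
  if (any(n_per_population < 1)) stopf("all population sizes must be positive")
  if (is.null(groups)) groups <- as.list(seq_len(n_populations))
  if (!setequal(unlist(groups), seq_len(n_populations)))
    stopf("groups must partition 1..n_populations")
  prof <- if (is.list(haplogroup_profile)) haplogroup_profile else
    rep(list(haplogroup_profile), n_populations)
  for (p in prof)
    if (abs(sum(p) - 1) > 1e-9) stopf("haplogroup profile must sum to 1")
  structure(list(n_populations = n_populations,
                 n_per_population = n_per_population,
                 region_length = region_length,
                 founder_divergence = founder_divergence,
                 within_theta = within_theta, groups = groups,
                 epoch_labels = rep_len(epoch_labels, n_populations),
                 haplogroup_profile = prof, sex_ratio = sex_ratio,
                 n_identical_pairs = n_identical_pairs,
                 n_one_diff_pairs = n_one_diff_pairs, seed = seed),
            class = "mt_simconfig")
}

#' Mutate a sequence at k distinct positions
#'
#' Exactly `k` substitutions at `k` distinct uniformly chosen positions,
#' each to a uniformly chosen different base; deterministic given `seed`.
#'
#' @param founder Sequence string.
#' @param k Number of substitutions (`k <= nchar(founder)`).
#' @param seed Integer seed (NULL: use the current RNG stream).
#' @return The mutated sequence string.
#' @export
mutate_sequence <- function(founder, k, seed = NULL) {
  L <- nchar(founder)
  if (k > L) stopf("k (%d) exceeds sequence length (%d)", k, L)
  if (k == 0L) return(founder)
  with_seed(seed, {
    ch <- seq_chars(founder)
    pos <- sample.int(L, k)
    for (i in pos)
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    paste(ch, collapse = "")
  })
}

random_sequence <- function(L) paste(sample(c("A", "C", "G", "T"), L,
                                            replace = TRUE), collapse = "")

#' Simulate diverged populations with ground truth
#'
#' One founder per truth group: each group founder receives
#' `Poisson(d/2)` private substitutions from a common root at positions
#' disjoint across groups, so two founders of different groups differ at
#' `Poisson(d)` expected fixed sites. Populations of the same group share
#' their founder. Each individual is its population founder plus
#' `Poisson(theta_w)` private mutations. Haplogroup labels are drawn from
#' the per-population profile, sex is Bernoulli(`sex_ratio`), and planted
#' identical / one-difference pairs are appended as extra samples.
#'
#' @param config An [sim_config()].
#' @return List with `dataset` (`mt_dataset`) and `truth` (generating
#'   partition as an [mt_grouping()], per-pair differentiation regime,
#'   planted pairs).
#' @export
simulate_divergence_populations <- function(config) {
  stopifnot(inherits(config, "mt_simconfig"))
  cf <- config
  with_seed(cf$seed, {
    L <- cf$region_length
    root <- random_sequence(L)
    G <- length(cf$groups)
    k_g <- stats::rpois(G, cf$founder_divergence / 2)
    k_g <- pmin(k_g, L)  # degenerate short-region guard
    if (sum(k_g) > L) k_g <- floor(k_g * L / sum(k_g))
    pos_all <- sample.int(L, sum(k_g))
    founders_g <- character(G)
    off <- 0L
    for (g in seq_len(G)) {
      ch <- seq_chars(root)
      if (k_g[g] > 0) for (i in pos_all[(off + 1L):(off + k_g[g])])
        ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
      off <- off + k_g[g]
      founders_g[g] <- paste(ch, collapse = "")
    }
    group_of_pop <- integer(cf$n_populations)
    for (g in seq_len(G)) group_of_pop[cf$groups[[g]]] <- g
    pop_names <- sprintf("P%02d", seq_len(cf$n_populations))
    rows <- list()
    for (p in seq_len(cf$n_populations)) {
      founder <- founders_g[group_of_pop[p]]
      n <- cf$n_per_population[p]
      hg <- sample(names(cf$haplogroup_profile[[p]]), n, replace = TRUE,
                   prob = cf$haplogroup_profile[[p]])
      sex <- ifelse(stats::runif(n) < cf$sex_ratio, "F", "M")
      seqs <- character(n)
      for (i in seq_len(n)) {
        # each individual descends from the founder or a random earlier
        # member of its population, so polymorphisms are shared within
        # populations (a genealogy-like copying chain, not an iid star)
        template <- if (i == 1L) founder else {
          pick <- sample.int(i, 1L)  # i = founder slot
          if (pick == i) founder else seqs[pick]
        }
        k <- min(stats::rpois(1L, cf$within_theta), L)
        seqs[i] <- mutate_sequence(template, k)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_I%03d", pop_names[p], i),
          population = pop_names[p], epoch = cf$epoch_labels[p],
          sequence = seqs[i],
          haplogroup = hg[i], sex = sex[i], stringsAsFactors = FALSE)
      }
    }
    s <- do.call(rbind, rows)
    planted <- data.frame(sample1 = character(), sample2 = character(),
                          distance = integer(), stringsAsFactors = FALSE)
    plant <- function(dist_nt, tag, n_pairs) {
      for (q in seq_len(n_pairs)) {
        src <- s[sample.int(nrow(s), 1L), , drop = FALSE]
        dup <- src
        dup$sample_id <- sprintf("%s_%s%d", src$sample_id, tag, q)
        if (dist_nt > 0) dup$sequence <- mutate_sequence(src$sequence, dist_nt)
        s <<- rbind(s, dup)
        planted <<- rbind(planted, data.frame(
          sample1 = src$sample_id, sample2 = dup$sample_id,
          distance = dist_nt, stringsAsFactors = FALSE))
      }
    }
    plant(0L, "DUP", cf$n_identical_pairs)
    plant(1L, "NEAR", cf$n_one_diff_pairs)
    meta <- empty_metadata(s$sample_id)
    meta$genetic_sex <- s$sex
    meta$haplogroup <- s$haplogroup
    meta$haplogroup_score <- 1
    meta$mean_coverage <- 100
    ds <- mt_dataset(s[c("sample_id", "population", "epoch", "sequence")],
                     mt_region(1L, L, "simulated"), meta)
    truth_groups <- lapply(cf$groups, function(ix) pop_names[ix])
    names(truth_groups) <- paste0("G", seq_along(truth_groups))
    regime <- outer(group_of_pop, group_of_pop, function(a, b)
      ifelse(a == b, "none",
             if (cf$founder_divergence >= 4) "strong" else "weak"))
    dimnames(regime) <- list(pop_names, pop_names)
    diag(regime) <- "none"
    list(dataset = ds,
         truth = list(partition = mt_grouping(truth_groups, "generating"),
                      pair_regime = regime, planted_pairs = planted,
                      founders = founders_g, seed = cf$seed))
  })
}

#' Draw per-population haplogroup-bin frequency profiles
#'
#' Each population's bin frequencies are drawn from the Dirichlet
#' distribution of its epoch's concentration vector; rows sum to 1.
#'
#' @param alpha_by_epoch Named list: epoch label -> positive concentration
#'   vector over a common set of bins.
#' @param n_populations Number of populations to draw.
#' @param epochs Epoch label per population (recycled over
#'   `names(alpha_by_epoch)` by default).
#' @param seed Integer seed.
#' @return An `mt_freq` with the drawn frequencies (counts unset).
#' @export
generate_frequency_profiles <- function(alpha_by_epoch, n_populations,
                                        epochs = NULL, seed = NULL) {
  if (!is.list(alpha_by_epoch) || is.null(names(alpha_by_epoch)))
    stopf("alpha_by_epoch must be a named list of concentration vectors")
  bins <- names(alpha_by_epoch[[1L]])
  for (a in alpha_by_epoch) {
    if (any(a <= 0)) stopf("Dirichlet concentrations must be positive")
    if (!identical(names(a), bins)) stopf("all alphas must share bin names")
  }
  if (is.null(epochs))
    epochs <- rep_len(names(alpha_by_epoch), n_populations)
  stopifnot(length(epochs) == n_populations,
            all(epochs %in% names(alpha_by_epoch)))
  m <- with_seed(seed, t(vapply(seq_len(n_populations), function(p) {
    a <- alpha_by_epoch[[epochs[p]]]
    g <- stats::rgamma(length(a), shape = a)
    g / sum(g)
  }, numeric(length(bins)))))
  dimnames(m) <- list(sprintf("%s_%02d", epochs, seq_len(n_populations)),
                      bins)
  structure(list(counts = NULL, freq = m, populations = rownames(m),
                 bins = bins, scheme = "simulated", epochs = epochs),
            class = "mt_freq")
}

#' Simulate a target population with epoch-labelled reference panels
#'
#' Builds a set of distinct target haplotypes and reference populations
#' across epochs such that each target haplotype has a known (planted)
#' earliest epoch of occurrence, or is novel. Used to validate ancestral
#' lineage assignment.
#'
#' @param n_target Number of distinct target haplotypes.
#' @param epochs Ordered epoch labels to plant references in (subset of
#'   [mt_epochs()], earliest first).
#' @param region_length Haplotype length.
#' @param p_novel Probability a target haplotype occurs in no reference.
#' @param seed Integer seed.
#' @return List with `target`, `references` (named list, one population
#'   per epoch), `epochs` (named vector), `truth` (planted earliest epoch
#'   per haplotype).
#' @export
simulate_shared_panel <- function(n_target = 20,
                                  epochs = c("EN", "MN", "LN/EBA"),
                                  region_length = 60, p_novel = 0.3,
                                  seed = 1) {
  stopifnot(all(epochs %in% mt_epochs()), n_target >= 1)
  with_seed(seed, {
    target <- unique(vapply(seq_len(n_target), function(i)
      random_sequence(region_length), character(1)))
    while (length(target) < n_target)
      target <- unique(c(target, random_sequence(region_length)))
    n_target <- length(target)
    truth <- character(n_target)
    refs <- stats::setNames(lapply(epochs, function(e) character()),
                            paste0("REF_", gsub("/", "_", epochs)))
    ep_of_ref <- stats::setNames(epochs, names(refs))
    rank <- match(epochs, mt_epochs())
    for (i in seq_len(n_target)) {
      if (stats::runif(1) < p_novel) {
        truth[i] <- "novel"
      } else {
        first <- sample(seq_along(epochs), 1L)
        truth[i] <- epochs[first]
        # present at the first epoch, possibly also later ones
        present <- unique(c(first, which(seq_along(epochs) > first &
                                           stats::runif(length(epochs)) < 0.5)))
        for (k in present)
          refs[[k]] <- c(refs[[k]], target[i])
      }
    }
    # pad references with decoy haplotypes absent from the target
    for (k in seq_along(refs))
      refs[[k]] <- c(refs[[k]],
                     paste0(vapply(seq_len(5), function(z)
                       random_sequence(region_length - 1), character(1)), "A"))
    list(target = target, references = refs, epochs = ep_of_ref,
         truth = stats::setNames(truth, target))
  })
}
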
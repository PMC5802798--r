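# Analysis of molecular variance (AMOVA) on pairwise squared sequence
# distances, with the method-of-moments variance components for unequal
# sample sizes, Phi statistics, permutation tests, and the grouping search
# over candidate population partitions.

#' Define a population grouping
#'
#' @param groups Named list of character vectors partitioning the analyzed
#'   population ids into disjoint non-empty groups.
#' @param name Grouping name.
#' @return An object of class `mt_grouping`.
#' @export
mt_grouping <- function(groups, name = "grouping") {
  if (!is.list(groups) || !length(groups)) stopf("groups must be a non-empty list")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("G", seq_along(groups))
  groups <- lapply(groups, as.character)
  if (any(lengths(groups) == 0L)) stopf("empty group in grouping '%s'", name)
  all_pops <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_pops))
    stopf("population assigned to more than one group in '%s'", name)
  structure(list(name = name, groups = groups), class = "mt_grouping")
}

#' @export
print.mt_grouping <- function(x, ...) {
  cat(sprintf("<mt_grouping> %s\n", x$name))
  for (g in names(x$groups))
    cat(sprintf("  %s: %s\n", g, paste(x$groups[[g]], collapse = ", ")))
  invisible(x)
}

# Squared-distance convention: with the "differences" model the squared
# Euclidean-like distance IS the difference count; other models are squared.
squared_distances <- function(dataset, model = "differences", gamma = NULL) {
  D <- dist_matrix(dataset, model, gamma)
  if (model == "differences") D else D^2
}

# Per-population pair sums of squared distances.
# Returns S[P x P] with S[p,q] = sum_{i in p, j in q} d2[i,j], sizes n_p.
pop_sums <- function(d2, pop, levels = unique(pop)) {
  z <- factor(pop, levels = levels)
  key <- as.character(levels)
  B <- rowsum(d2, z)
  S <- rowsum(t(B), z)[key, key, drop = FALSE]
  list(S = S, n = as.numeric(table(z)), levels = levels)
}

# Variance components from population pair-sums and a group map.
# g_of_p: integer group index per population (all 1s -> two-level model).
amova_from_sums <- function(S, n_p, g_of_p) {
  N <- sum(n_p); P <- length(n_p); G <- length(unique(g_of_p))
  tot <- sum(S)
  ssd_total <- tot / (2 * N)
  ssd_wp <- sum(diag(S) / (2 * n_p))
  if (G == 1L) {
    # two-level: among populations / within populations
    ssd_ap <- ssd_total - ssd_wp
    df_ap <- P - 1L; df_wp <- N - P
    sigma_c <- ssd_wp / df_wp
    n_c <- (N - sum(n_p^2) / N) / df_ap
    sigma_b <- (ssd_ap / df_ap - sigma_c) / n_c
    phi_st <- sigma_b / (sigma_b + sigma_c)
    return(list(sigma_a = NA_real_, sigma_b = sigma_b, sigma_c = sigma_c,
                phi_ct = NA_real_, phi_sc = NA_real_, phi_st = phi_st,
                df = c(ag = NA, apwg = df_ap, wp = df_wp),
                ssd = c(total = ssd_total, ag = NA, apwg = ssd_ap,
                        wp = ssd_wp)))
  }
  zg <- factor(g_of_p, levels = sort(unique(g_of_p)))
  N_g <- as.numeric(rowsum(n_p, zg, reorder = FALSE))
  Gm <- rowsum(S, zg, reorder = FALSE)
  Gs <- rowsum(t(Gm), zg, reorder = FALSE)
  ssd_wg <- sum(diag(Gs) / (2 * N_g))
  ssd_ag <- ssd_total - ssd_wg
  ssd_apwg <- ssd_wg - ssd_wp
  df_ag <- G - 1L; df_apwg <- P - G; df_wp <- N - P
  sigma_c <- ssd_wp / df_wp
  Sg <- as.numeric(rowsum(n_p^2, zg, reorder = FALSE))  # sum n_p^2 per group
  if (df_apwg > 0L) {
    n1 <- (N - sum(Sg / N_g)) / df_apwg
    sigma_b <- (ssd_apwg / df_apwg - sigma_c) / n1
  } else {
    sigma_b <- NA_real_
  }
  n2 <- (sum(Sg / N_g) - sum(n_p^2) / N) / df_ag
  n3 <- (N - sum(N_g^2) / N) / df_ag
  sb <- if (is.na(sigma_b)) 0 else sigma_b
  sigma_a <- (ssd_ag / df_ag - sigma_c - n2 * sb) / n3
  tot_var <- sigma_a + sb + sigma_c
  list(sigma_a = sigma_a, sigma_b = sigma_b, sigma_c = sigma_c,
       phi_ct = sigma_a / tot_var,
       phi_sc = if (is.na(sigma_b)) NA_real_ else sigma_b / (sigma_b + sigma_c),
       phi_st = (sigma_a + sb) / tot_var,
       df = c(ag = df_ag, apwg = df_apwg, wp = df_wp),
       ssd = c(total = ssd_total, ag = ssd_ag, apwg = ssd_apwg, wp = ssd_wp))
}

grouping_index <- function(grouping, levels) {
  g_of_p <- rep(NA_integer_, length(levels))
  for (k in seq_along(grouping$groups))
    g_of_p[match(grouping$groups[[k]], levels)] <- k
  if (anyNA(g_of_p))
    stopf("grouping '%s' does not cover populations: %s", grouping$name,
          paste(levels[is.na(g_of_p)], collapse = ", "))
  g_of_p
}

#' AMOVA variance components and Phi statistics
#'
#' Decomposes the total molecular variance of pairwise squared sequence
#' distances into among-group (`sigma_a`), among-populations-within-groups
#' (`sigma_b`), and within-population (`sigma_c`) components using the
#' Excoffier-Smouse-Quattro sums of squares with the standard
#' unequal-size coefficients, and reports `phi_ct = sigma_a / total`,
#' `phi_sc = sigma_b / (sigma_b + sigma_c)` and
#' `phi_st = (sigma_a + sigma_b) / total`. A one-group grouping yields the
#' two-level decomposition (`sigma_a` undefined, `phi_st` only). Negative
#' components are reported as computed (see `truncate_negative`).
#'
#' @param dataset An `mt_dataset` covering the grouping's populations.
#' @param grouping An [mt_grouping()]. Populations of the dataset not
#'   mentioned by the grouping are excluded from the analysis.
#' @param model,gamma Distance model (see [seq_distance()]). With
#'   `"differences"` the squared distance entering AMOVA is the difference
#'   count itself; other models are squared.
#' @param d2 Optional precomputed squared-distance matrix (sample order of
#'   the dataset); overrides `model`.
#' @param truncate_negative Truncate negative variance components to 0.
#' @return An object of class `mt_amova`.
#' @export
variance_components <- function(dataset, grouping, model = "differences",
                                gamma = NULL, d2 = NULL,
                                truncate_negative = FALSE) {
  stopifnot(inherits(dataset, "mt_dataset"), inherits(grouping, "mt_grouping"))
  pops <- unlist(grouping$groups, use.names = FALSE)
  absent <- setdiff(pops, dataset$populations)
  if (length(absent))
    stopf("grouping '%s' names population(s) absent from the dataset: %s",
          grouping$name, paste(absent, collapse = ", "))
  keep <- dataset$samples$population %in% pops
  if (is.null(d2)) {
    ds <- subset_dataset(dataset, keep)
    d2 <- squared_distances(ds, model, gamma)
    pop <- ds$samples$population
  } else {
    stopifnot(nrow(d2) == nrow(dataset$samples))
    d2 <- d2[keep, keep, drop = FALSE]
    pop <- dataset$samples$population[keep]
  }
  if (all(d2 == 0)) stopf("zero total variance: all sequences identical")
  ps <- pop_sums(d2, pop, levels = pops)
  g_of_p <- grouping_index(grouping, ps$levels)
  res <- amova_from_sums(ps$S, ps$n, g_of_p)
  if (truncate_negative) {
    for (f in c("sigma_a", "sigma_b", "sigma_c"))
      if (!is.na(res[[f]]) && res[[f]] < 0) res[[f]] <- 0
    tot <- sum(c(res$sigma_a, res$sigma_b, res$sigma_c), na.rm = TRUE)
    if (tot > 0) {
      if (!is.na(res$sigma_a)) res$phi_ct <- res$sigma_a / tot
      if (!is.na(res$sigma_b))
        res$phi_sc <- res$sigma_b / (res$sigma_b + res$sigma_c)
      res$phi_st <- sum(c(res$sigma_a, res$sigma_b), na.rm = TRUE) / tot
    }
  }
  res$negative_components <- any(c(res$sigma_a, res$sigma_b, res$sigma_c) < 0,
                                 na.rm = TRUE)
  res$grouping <- grouping
  res$n_individuals <- nrow(d2)
  res$model <- model
  class(res) <- "mt_amova"
  res
}

#' @export
print.mt_amova <- function(x, ...) {
  cat(sprintf("<mt_amova> grouping '%s' (%d groups, %d populations, %d individuals)\n",
              x$grouping$name, length(x$grouping$groups),
              length(unlist(x$grouping$groups)), x$n_individuals))
  cat(sprintf("  sigma_a=%s sigma_b=%s sigma_c=%s\n",
              format(x$sigma_a, digits = 5), format(x$sigma_b, digits = 5),
              format(x$sigma_c, digits = 5)))
  cat(sprintf("  Phi_CT=%s Phi_SC=%s Phi_ST=%s\n",
              format(x$phi_ct, digits = 5), format(x$phi_sc, digits = 5),
              format(x$phi_st, digits = 5)))
  if (!is.null(x$p_ct))
    cat(sprintf("  p_CT=%s p_SC=%s p_ST=%s (%d permutations)\n",
                format(x$p_ct, digits = 4), format(x$p_sc, digits = 4),
                format(x$p_st, digits = 4), x$n_permutations))
  if (isTRUE(x$negative_components))
    cat("  note: negative variance component(s) reported as computed\n")
  invisible(x)
}

subset_dataset <- function(dataset, keep) {
  mt_dataset(dataset$samples[keep, , drop = FALSE], dataset$region,
             dataset$metadata)
}

perm_pvalue <- function(perm_stats, observed) {
  (1 + sum(perm_stats >= observed - 1e-12)) / (length(perm_stats) + 1)
}

#' Permutation p-values for the AMOVA Phi statistics
#'
#' `p_ct` permutes whole populations among groups (holding the number of
#' populations per group fixed); `p_sc` permutes individuals among
#' populations within their group; `p_st` permutes individuals among all
#' populations ignoring groups. Each p-value is
#' `(1 + #{permuted >= observed}) / (n_perm + 1)`. Permutations are sampled
#' with replacement; when fewer distinct population-level permutations than
#' `n_perm` exist a warning is emitted.
#'
#' @inheritParams variance_components
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed; the caller's RNG stream is left untouched.
#' @return The `mt_amova` of the observed grouping augmented with
#'   `p_ct`, `p_sc`, `p_st`, `n_permutations`, `seed`.
#' @export
amova_permutation <- function(dataset, grouping, n_perm = 999, seed = NULL,
                              model = "differences", gamma = NULL, d2 = NULL) {
  stopifnot(n_perm >= 1)
  pops <- unlist(grouping$groups, use.names = FALSE)
  keep <- dataset$samples$population %in% pops
  if (is.null(d2)) {
    ds <- subset_dataset(dataset, keep)
    d2 <- squared_distances(ds, model, gamma)
    pop <- ds$samples$population
  } else {
    d2 <- d2[keep, keep, drop = FALSE]
    pop <- dataset$samples$population[keep]
  }
  obs <- variance_components(dataset, grouping, model = model, gamma = gamma,
                             d2 = NULL)
  # recompute observed on the local d2 to share the code path with perms
  ps <- pop_sums(d2, pop, levels = pops)
  g_of_p <- grouping_index(grouping, ps$levels)
  obs_stats <- amova_from_sums(ps$S, ps$n, g_of_p)
  G <- length(grouping$groups)
  m_g <- lengths(grouping$groups)
  if (G > 1L) {
    n_distinct <- exp(lgamma(length(pops) + 1) - sum(lgamma(m_g + 1)))
    if (n_distinct < n_perm)
      warning(sprintf(paste0("only ~%d distinct population-level ",
                             "permutations; sampling with replacement"),
                      round(n_distinct)), call. = FALSE)
  }
  group_sizes_ind <- vapply(grouping$groups, function(g)
    sum(pop %in% g), numeric(1))
  res <- with_seed(seed, {
    st <- matrix(NA_real_, n_perm, 3L,
                 dimnames = list(NULL, c("ct", "sc", "st")))
    for (b in seq_len(n_perm)) {
      if (G > 1L) {
        perm_g <- sample(g_of_p)
        st[b, "ct"] <- amova_from_sums(ps$S, ps$n, perm_g)$phi_ct
        # individuals among populations within groups
        pop_sc <- pop
        for (k in seq_len(G)) {
          in_g <- pop %in% grouping$groups[[k]]
          pop_sc[in_g] <- sample(pop[in_g])
        }
        ps_sc <- pop_sums(d2, pop_sc, levels = pops)
        st[b, "sc"] <- amova_from_sums(ps_sc$S, ps_sc$n, g_of_p)$phi_sc
      }
      pop_st <- sample(pop)
      ps_st <- pop_sums(d2, pop_st, levels = pops)
      st[b, "st"] <- amova_from_sums(ps_st$S, ps_st$n, g_of_p)$phi_st
    }
    st
  })
  obs$p_st <- perm_pvalue(res[, "st"], obs_stats$phi_st)
  obs$p_ct <- if (G > 1L) perm_pvalue(res[, "ct"], obs_stats$phi_ct) else NA_real_
  obs$p_sc <- if (G > 1L && !is.na(obs_stats$phi_sc))
    perm_pvalue(res[, "sc"], obs_stats$phi_sc) else NA_real_
  obs$n_permutations <- n_perm
  obs$seed <- seed
  obs
}

# --- grouping enumeration ---------------------------------------------------

# All set partitions of `items` into at most `max_blocks` non-empty blocks,
# enumerated in restricted-growth-string order (deterministic canonical
# ordering).
set_partitions <- function(items, max_blocks = length(items)) {
  n <- length(items)
  out <- list()
  rec <- function(i, assign, k) {
    if (i > n) {
      blocks <- split(items, assign[seq_len(n)])
      out[[length(out) + 1L]] <<- unname(blocks)
      return(invisible())
    }
    for (b in seq_len(min(k + 1L, max_blocks))) {
      assign[i] <- b
      rec(i + 1L, assign, max(k, b))
    }
  }
  if (n == 0L) return(list(list()))
  rec(1L, integer(n), 0L)
  out
}

#' Enumerate candidate groupings with a fixed block
#'
#' Generates all partitions of the non-fixed populations into at most
#' `n_groups - 1` groups (or `n_groups` when `fixed_block` is empty), each
#' combined with the fixed block as its own group, in a deterministic
#' canonical order.
#'
#' @param populations Character vector of population ids.
#' @param fixed_block Populations always kept together as one group.
#' @param n_groups Maximum total number of groups (>= 2).
#' @return List of [mt_grouping()] objects.
#' @export
enumerate_groupings <- function(populations, fixed_block = character(),
                                n_groups = 2) {
  if (n_groups < 2) stopf("n_groups must be >= 2")
  if (!all(fixed_block %in% populations))
    stopf("fixed_block must be a subset of populations")
  free <- setdiff(populations, fixed_block)
  has_fixed <- length(fixed_block) > 0L
  if (!length(free)) {
    return(list(mt_grouping(list(fixed = fixed_block), name = "fixed-only")))
  }
  max_free <- if (has_fixed) n_groups - 1L else n_groups
  parts <- set_partitions(free, max_blocks = max_free)
  lapply(seq_along(parts), function(i) {
    gr <- parts[[i]]
    names(gr) <- paste0("G", seq_along(gr) + has_fixed)
    if (has_fixed) gr <- c(list(G1 = fixed_block), gr)
    mt_grouping(gr, name = sprintf("grouping_%03d", i))
  })
}

#' Search candidate groupings for the optimal hierarchical structure
#'
#' Evaluates [variance_components()] for every candidate and ranks them by
#' `phi_ct` (descending). The optimum is the candidate minimizing `phi_sc`
#' among those within `1e-9` of the maximal `phi_ct`; the full table is
#' returned so other rankings can be applied. A candidate is flagged
#' `pareto` when no other candidate has both higher `phi_ct` and lower
#' `phi_sc`.
#'
#' @inheritParams variance_components
#' @param candidates List of [mt_grouping()] objects over the same
#'   population set.
#' @param n_perm If > 0, permutation p-values are computed per candidate.
#' @param seed Seed for the permutation tests.
#' @return List with `table` (data.frame), `optimum` (an `mt_grouping`),
#'   and `results` (per-candidate `mt_amova` objects).
#' @export
grouping_search <- function(dataset, candidates, model = "differences",
                            gamma = NULL, d2 = NULL, n_perm = 0, seed = NULL) {
  if (!length(candidates)) stopf("empty candidate list")
  pops0 <- sort(unlist(candidates[[1L]]$groups, use.names = FALSE))
  for (cand in candidates)
    if (!identical(sort(unlist(cand$groups, use.names = FALSE)), pops0))
      stopf("all candidates must partition the same population set")
  if (is.null(d2)) d2 <- squared_distances(
    subset_dataset(dataset, dataset$samples$population %in% pops0),
    model, gamma)
  ds <- subset_dataset(dataset, dataset$samples$population %in% pops0)
  results <- lapply(candidates, function(cand) {
    if (n_perm > 0)
      amova_permutation(ds, cand, n_perm = n_perm, seed = seed,
                        model = model, gamma = gamma, d2 = d2)
    else variance_components(ds, cand, model = model, gamma = gamma, d2 = d2)
  })
  tab <- data.frame(
    name = vapply(candidates, function(g) g$name, character(1)),
    n_groups = vapply(candidates, function(g) length(g$groups), numeric(1)),
    phi_ct = vapply(results, function(r) r$phi_ct, numeric(1)),
    phi_sc = vapply(results, function(r) r$phi_sc, numeric(1)),
    phi_st = vapply(results, function(r) r$phi_st, numeric(1)),
    stringsAsFactors = FALSE)
  if (n_perm > 0) {
    tab$p_ct <- vapply(results, function(r) r$p_ct, numeric(1))
    tab$p_sc <- vapply(results, function(r) r$p_sc, numeric(1))
    tab$p_st <- vapply(results, function(r) r$p_st, numeric(1))
  }
  # Pareto flag on candidates with defined two-criterion coordinates
  ok <- !is.na(tab$phi_ct) & !is.na(tab$phi_sc)
  pareto <- rep(NA, nrow(tab))
  idx <- which(ok)
  for (i in idx) {
    dominated <- any(tab$phi_ct[idx] >= tab$phi_ct[i] &
                     tab$phi_sc[idx] <= tab$phi_sc[i] &
                     (tab$phi_ct[idx] > tab$phi_ct[i] |
                      tab$phi_sc[idx] < tab$phi_sc[i]))
    pareto[i] <- !dominated
  }
  tab$pareto <- pareto
  o <- order(-tab$phi_ct, tab$phi_sc, na.last = TRUE)
  tab <- tab[o, , drop = FALSE]
  results <- results[o]
  candidates <- candidates[o]
  best_ct <- max(tab$phi_ct, na.rm = TRUE)
  near <- which(!is.na(tab$phi_ct) & tab$phi_ct >= best_ct - 1e-9)
  opt <- near[which.min(tab$phi_sc[near])]
  list(table = tab, optimum = candidates[[opt]],
       optimum_result = results[[opt]], results = results)
}
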
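# Population-level genetic distances: pairwise Phi_ST, Slatkin
# linearization, permutation p-values with Benjamini-Hochberg correction,
# and MDS embedding of the resulting dissimilarities.

#' Pairwise population Phi_ST matrix
#'
#' For every population pair, the two-level AMOVA (one group holding the
#' two populations) on squared sequence distances gives the AMOVA-based
#' fixation index Phi_ST. Negative values are retained: they are the
#' method-of-moments signature of no differentiation.
#'
#' @param dataset An `mt_dataset` with >= 2 populations, each with >= 2
#'   individuals.
#' @param region Optional [mt_region()] to slice before computing (e.g.
#'   HVS-I 16064-16400).
#' @param model,gamma Distance model (see [seq_distance()]).
#' @return Symmetric matrix (zero diagonal) with population dimnames.
#' @export
pairwise_phist <- function(dataset, region = NULL, model = "differences",
                           gamma = NULL) {
  if (!is.null(region)) dataset <- slice_region(dataset, region)
  pops <- dataset$populations
  if (length(pops) < 2L) stopf("need >= 2 populations")
  sizes <- table(dataset$samples$population)
  small <- names(sizes)[sizes < 2L]
  if (length(small))
    stopf("population(s) with fewer than 2 members: %s",
          paste(small, collapse = ", "))
  d2 <- squared_distances(dataset, model, gamma)
  pop <- dataset$samples$population
  M <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-1L]) for (j in seq_len(i - 1L)) {
    keep <- pop %in% pops[c(i, j)]
    ps <- pop_sums(d2[keep, keep, drop = FALSE], pop[keep],
                   levels = pops[c(i, j)])
    M[i, j] <- M[j, i] <- amova_from_sums(ps$S, ps$n, c(1L, 1L))$phi_st
  }
  M
}

#' Slatkin's linearized genetic distance
#'
#' `D = Fst / (1 - Fst)`; negative Fst maps to negative D.
#'
#' @param fst Numeric vector or matrix of Fst values, all `< 1`.
#' @return Same shape as the input.
#' @export
slatkin_linearize <- function(fst) {
  if (any(fst >= 1, na.rm = TRUE))
    stopf("Fst = 1 has infinite linearized distance")
  fst / (1 - fst)
}

#' Permutation p-value for one population pair
#'
#' Individuals are permuted among the two populations holding the sample
#' sizes fixed; `p = (1 + #{permuted Phi_ST >= observed}) / (n_perm + 1)`,
#' so the minimum attainable p is `1/(n_perm+1)` and p is never 0.
#'
#' @param dataset An `mt_dataset`.
#' @param pair Character vector of two population ids.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @param region,model,gamma As in [pairwise_phist()].
#' @return A single p-value in `(0, 1]`.
#' @export
fst_permutation_p <- function(dataset, pair, n_perm = 999, seed = NULL,
                              region = NULL, model = "differences",
                              gamma = NULL) {
  stopifnot(length(pair) == 2L, n_perm >= 1)
  if (!is.null(region)) dataset <- slice_region(dataset, region)
  keep <- dataset$samples$population %in% pair
  ds <- subset_dataset(dataset, keep)
  d2 <- squared_distances(ds, model, gamma)
  pop <- ds$samples$population
  phi <- function(lab) {
    ps <- pop_sums(d2, lab, levels = pair)
    amova_from_sums(ps$S, ps$n, c(1L, 1L))$phi_st
  }
  obs <- phi(pop)
  perm <- with_seed(seed, vapply(seq_len(n_perm),
                                 function(b) phi(sample(pop)), numeric(1)))
  perm_pvalue(perm, obs)
}

#' Benjamini-Hochberg adjustment
#'
#' The standard step-up FDR adjustment (sorted cumulative minimum of
#' `m * p / rank`, capped at 1); order-preserving and entrywise `>=` the
#' raw p-values.
#'
#' @param pvalues Numeric vector with all values in `(0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stopf("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Population Fst analysis with permutation inference
#'
#' Computes the pairwise Phi_ST matrix, Slatkin linearization, per-pair
#' permutation p-values, and Benjamini-Hochberg adjusted p-values over the
#' strict lower triangle (each unordered pair once).
#'
#' @inheritParams pairwise_phist
#' @param n_perm Permutations per pair.
#' @param seed Integer seed (one stream drives all pairs).
#' @return An object of class `mt_fst` with elements `fst`, `linearized`,
#'   `pvalues`, `adjusted_pvalues`, `n_permutations`, `seed`.
#' @export
fst_analysis <- function(dataset, region = NULL, model = "differences",
                         gamma = NULL, n_perm = 999, seed = NULL) {
  if (!is.null(region)) dataset <- slice_region(dataset, region)
  fst <- pairwise_phist(dataset, model = model, gamma = gamma)
  pops <- rownames(fst)
  P <- length(pops)
  pv <- matrix(NA_real_, P, P, dimnames = dimnames(fst))
  k <- 0L
  for (i in seq_len(P)[-1L]) for (j in seq_len(i - 1L)) {
    k <- k + 1L
    pv[i, j] <- pv[j, i] <- fst_permutation_p(
      dataset, c(pops[i], pops[j]), n_perm = n_perm,
      seed = if (is.null(seed)) NULL else seed + k,
      model = model, gamma = gamma)
  }
  lower <- lower.tri(pv)
  adj <- matrix(NA_real_, P, P, dimnames = dimnames(fst))
  adj[lower] <- bh_adjust(pv[lower])
  adj[upper.tri(adj)] <- t(adj)[upper.tri(adj)]
  lin <- fst
  lin[] <- slatkin_linearize(pmin(fst, 1 - 1e-12))
  diag(lin) <- 0
  structure(list(fst = fst, linearized = lin, pvalues = pv,
                 adjusted_pvalues = adj, n_permutations = n_perm,
                 seed = seed, model = model),
            class = "mt_fst")
}

#' @export
print.mt_fst <- function(x, ...) {
  cat(sprintf("<mt_fst> %d populations, model '%s', %d permutations/pair\n",
              nrow(x$fst), x$model, x$n_permutations))
  cat("Phi_ST (lower) / BH-adjusted p (upper):\n")
  M <- x$fst
  M[upper.tri(M)] <- x$adjusted_pvalues[upper.tri(M)]
  print(round(M, 4))
  invisible(x)
}

#' Multidimensional scaling of a dissimilarity matrix
#'
#' Classical mode is principal-coordinates analysis (double-centered
#' squared dissimilarities); nonmetric mode minimizes Kruskal stress-1 by
#' isotonic regression with seeded random restarts plus a
#' classical-solution start, keeping the best configuration. Negative
#' entries (possible for Fst matrices) are clamped to 0 and the diagonal
#' forced to 0 before embedding.
#'
#' @param dissimilarity Symmetric numeric matrix.
#' @param dims Embedding dimension (default 2; must be `< n`).
#' @param mode `"classical"` or `"nonmetric"`.
#' @param n_starts Random restarts for nonmetric mode.
#' @param seed Integer seed for the restarts.
#' @return List with `points` (n x dims), `stress` (stress-1 of the
#'   returned configuration), and `mode`.
#' @export
mds_embed <- function(dissimilarity, dims = 2,
                      mode = c("classical", "nonmetric"),
                      n_starts = 4, seed = NULL) {
  mode <- match.arg(mode)
  d <- as.matrix(dissimilarity)
  n <- nrow(d)
  if (dims > n - 1L) stopf("dims must be <= n - 1")
  d[d < 0] <- 0
  diag(d) <- 0
  d <- (d + t(d)) / 2
  dd <- stats::as.dist(d)
  cl <- stats::cmdscale(dd, k = dims)
  stress_of <- function(cfg)
    vegan::monoMDS(dd, y = cfg, k = dims, maxit = 0)$stress
  if (mode == "classical") {
    return(list(points = cl, stress = stress_of(cl), mode = mode))
  }
  best <- vegan::monoMDS(dd, y = cl, k = dims)
  with_seed(seed, {
    for (s in seq_len(n_starts)) {
      cfg0 <- matrix(stats::rnorm(n * dims), n, dims)
      fit <- vegan::monoMDS(dd, y = cfg0, k = dims)
      if (fit$stress < best$stress) best <- fit
    }
  })
  list(points = best$points, stress = best$stress, mode = mode)
}
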
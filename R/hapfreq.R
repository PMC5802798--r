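# Haplogroup binning, population frequency matrices, Ward clustering with
# bootstrap clade support, PCA with loadings, metapopulation resampling,
# and R x C count-table testing.

MACRO_SETS <- list(Asian = c("A", "C", "D", "F", "G", "Z"),
                   African = "L")

scheme_cept23 <- function() {
  bins <- c("H", "H5", "HV", "HV0", "V", "I", "J", "K", "N", "N1a", "R",
            "T1", "T2", "U", "U2", "U3", "U4", "U5a", "U5b", "U8", "W", "X",
            "others")
  list(name = "CEPT23", bins = bins,
       rules = data.frame(prefix = setdiff(bins, "others"),
                          bin = setdiff(bins, "others"),
                          macro = FALSE, stringsAsFactors = FALSE))
}

scheme_ept25 <- function() {
  # 24 distinct bins for populations of the ancient European transect
  pre <- c("N", "N1a", "I", "J", "W", "X", "R", "HV", "H", "H5", "T", "T1",
           "T2", "U", "U2", "U3", "U4", "U5a", "U5b", "U8", "K")
  rules <- data.frame(prefix = c(pre, "V", "HV0"),
                      bin = c(pre, "V/HV0", "V/HV0"),
                      macro = FALSE, stringsAsFactors = FALSE)
  rules <- rbind(rules, data.frame(prefix = "Asian", bin = "Asian",
                                   macro = TRUE, stringsAsFactors = FALSE))
  list(name = "EPT25",
       bins = c("Asian", pre[1:8], "V/HV0", pre[9:21], "others"),
       rules = rules)
}

scheme_world23 <- function() {
  pre <- c("N1a", "I", "I1", "W", "X", "HV", "H", "H5", "T1", "T2", "J",
           "U", "U2", "U3", "U4", "U5a", "U5b", "U8", "K")
  rules <- data.frame(prefix = c(pre, "V", "HV0"),
                      bin = c(pre, "V/HV0", "V/HV0"),
                      macro = FALSE, stringsAsFactors = FALSE)
  rules <- rbind(rules,
                 data.frame(prefix = c("Asian", "African"),
                            bin = c("Asian", "African"), macro = TRUE,
                            stringsAsFactors = FALSE))
  list(name = "WORLD23",
       bins = c("Asian", "African", pre[1:6], "V/HV0", pre[7:19], "others"),
       rules = rules)
}

#' Haplogroup bin schemes
#'
#' The three binning schemes used for frequency-based comparisons:
#' `CEPT23` (23 bins for the Central European transect), `EPT25` (the
#' ancient pan-European transect; its published bin list names one
#' haplogroup twice, so 24 distinct bins are defined), and `WORLD23`
#' (worldwide comparison, with Asian `A,C,D,F,G,Z` and African `L`
#' macro-bins). A custom scheme takes explicit `bins` and prefix
#' `rules`.
#'
#' @param name One of `"CEPT23"`, `"EPT25"`, `"WORLD23"`, `"custom"`.
#' @param bins,rules For `"custom"`: bin labels (must include `"others"`)
#'   and a data.frame with columns `prefix`, `bin`, `macro`.
#' @return An object of class `mt_binscheme`.
#' @export
bin_scheme <- function(name = c("CEPT23", "EPT25", "WORLD23", "custom"),
                       bins = NULL, rules = NULL) {
  name <- match.arg(name)
  sc <- switch(name,
               CEPT23 = scheme_cept23(),
               EPT25 = scheme_ept25(),
               WORLD23 = scheme_world23(),
               custom = {
                 stopifnot(!is.null(bins), !is.null(rules))
                 if (!"others" %in% bins) bins <- c(bins, "others")
                 if (!all(rules$bin %in% bins))
                   stopf("rule maps to undeclared bin")
                 list(name = "custom", bins = bins, rules = rules)
               })
  # most-specific-first: longer prefixes match before shorter ones
  o <- order(-nchar(sc$rules$prefix) + 1000 * sc$rules$macro)
  sc$rules <- sc$rules[o, , drop = FALSE]
  structure(sc, class = "mt_binscheme")
}

#' @export
print.mt_binscheme <- function(x, ...) {
  cat(sprintf("<mt_binscheme> %s: %d bins\n  %s\n", x$name, length(x$bins),
              paste(x$bins, collapse = ", ")))
  invisible(x)
}

#' Assign haplogroup labels to scheme bins
#'
#' Longest-matching-prefix rule (`"H5a1"` hits `H5`, not `H`; `"HV0a"`
#' hits `HV0`/`V` before `HV`); macro-bins match on the first letter of
#' the label; anything unmatched falls to `"others"`. Total and
#' idempotent: bin labels map to themselves.
#'
#' @param haplogroup_label Character vector of Phylotree-style labels.
#' @param scheme An [bin_scheme()].
#' @return Character vector of bin labels.
#' @export
assign_bin <- function(haplogroup_label, scheme) {
  stopifnot(inherits(scheme, "mt_binscheme"))
  r <- scheme$rules
  vapply(as.character(haplogroup_label), function(lab) {
    if (is.na(lab) || !nzchar(lab)) return("others")
    for (k in seq_len(nrow(r))) {
      if (r$macro[k]) {
        if (substr(lab, 1L, 1L) %in% MACRO_SETS[[r$bin[k]]]) return(r$bin[k])
      } else if (startsWith(lab, r$prefix[k])) return(r$bin[k])
    }
    "others"
  }, character(1), USE.NAMES = FALSE)
}

#' Population x bin frequency matrix
#'
#' Tabulates haplogroup assignments per population into scheme bins.
#' Zero-count bins are retained; populations without any assignment are
#' dropped with a warning.
#'
#' @param assignments data.frame with columns `population` and
#'   `haplogroup` (one row per individual).
#' @param scheme A [bin_scheme()].
#' @return Object of class `mt_freq` with `counts`, `freq` (rows
#'   normalized to 1), `populations`, `bins`, `scheme`.
#' @export
build_frequency_matrix <- function(assignments, scheme) {
  a <- as.data.frame(assignments)
  stopifnot(all(c("population", "haplogroup") %in% names(a)))
  a <- a[!is.na(a$haplogroup), , drop = FALSE]
  if (!nrow(a)) stopf("no haplogroup assignments")
  bins <- assign_bin(a$haplogroup, scheme)
  pops <- unique(as.character(a$population))
  counts <- table(factor(a$population, levels = pops),
                  factor(bins, levels = scheme$bins))
  counts <- unclass(as.matrix(counts))
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    warning(sprintf("dropping population(s) with no assignments: %s",
                    paste(rownames(counts)[empty], collapse = ", ")),
            call. = FALSE)
    counts <- counts[!empty, , drop = FALSE]
  }
  freq_matrix(counts, scheme)
}

#' Wrap a counts table as a frequency matrix
#'
#' For externally tabulated population haplogroup-count tables (rows =
#' populations, columns = bins of `scheme`).
#'
#' @param counts Non-negative integer matrix with dimnames.
#' @param scheme A [bin_scheme()] (or NULL for ad-hoc bins).
#' @return An `mt_freq`.
#' @export
freq_matrix <- function(counts, scheme = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("negative counts")
  freq <- counts / rowSums(counts)
  structure(list(counts = counts, freq = freq,
                 populations = rownames(counts), bins = colnames(counts),
                 scheme = if (is.null(scheme)) "custom" else scheme$name),
            class = "mt_freq")
}

#' @export
print.mt_freq <- function(x, ...) {
  cat(sprintf("<mt_freq> %d populations x %d bins (scheme %s), %d samples\n",
              nrow(x$counts), ncol(x$counts), x$scheme, sum(x$counts)))
  invisible(x)
}

#' Ward clustering of population haplogroup profiles
#'
#' Agglomerative clustering of the frequency rows with Euclidean distance
#' and the squared-distance Ward update (`hclust` method `ward.D2`).
#' Ties merge the lowest-index pair first (the `hclust` convention), so
#' the tree is deterministic.
#'
#' @param freq An `mt_freq` (or plain frequency matrix) with >= 2 rows.
#' @return An `hclust` object.
#' @export
ward_cluster <- function(freq) {
  m <- if (inherits(freq, "mt_freq")) freq$freq else as.matrix(freq)
  if (nrow(m) < 2L) stopf("need >= 2 populations to cluster")
  stats::hclust(stats::dist(m, method = "euclidean"), method = "ward.D2")
}

#' Leaf-label sets of every internal node of a dendrogram
#'
#' @param hc An `hclust` object.
#' @return List of sorted leaf-label vectors, one per internal node, in
#'   `hc$merge` row order (the order bootstrap supports are reported in).
#' @export
clade_labels <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[k, ]
    get1 <- function(v) if (v < 0) hc$labels[-v] else sets[[v]]
    sets[[k]] <- sort(c(get1(kids[1L]), get1(kids[2L])))
  }
  sets
}

#' Bootstrap support for Ward clusters
#'
#' Resamples the bin columns of the count matrix with replacement (same
#' number of columns), renormalizes, rebuilds the Ward tree, and reports
#' for every internal node of the observed tree the percentage of
#' replicates that contain a cluster with the identical leaf set (the
#' plain bootstrap proportion). `resample = "populations"` resamples rows
#' instead; a replicate then scores the nodes whose leaf set is fully
#' contained in the replicate.
#'
#' @param freq An `mt_freq`.
#' @param n_boot Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param resample `"bins"` (default) or `"populations"`.
#' @return List with `hclust` (observed tree), `support` (percentage per
#'   internal node, in `hclust$merge` order), `n_boot`, `seed`.
#' @export
bootstrap_support <- function(freq, n_boot = 1000, seed = NULL,
                              resample = c("bins", "populations")) {
  resample <- match.arg(resample)
  stopifnot(inherits(freq, "mt_freq"))
  if (n_boot < 1) stopf("n_boot must be >= 1")
  hc <- ward_cluster(freq)
  obs_sets <- clade_labels(hc)
  hits <- numeric(length(obs_sets))
  denom <- numeric(length(obs_sets))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      if (resample == "bins") {
        # redraw on the (rare) replicates that zero out a population's row
        for (try in 1:100) {
          cols <- sample(ncol(freq$counts), replace = TRUE)
          cb <- freq$counts[, cols, drop = FALSE]
          if (all(rowSums(cb) > 0)) break
        }
        if (any(rowSums(cb) == 0)) next
        fb <- freq_matrix(cb)
        rep_sets <- clade_labels(ward_cluster(fb))
        key <- vapply(rep_sets, paste, character(1), collapse = "\r")
        for (k in seq_along(obs_sets)) {
          denom[k] <- denom[k] + 1
          if (paste(obs_sets[[k]], collapse = "\r") %in% key)
            hits[k] <- hits[k] + 1
        }
      } else {
        rows <- unique(sample(nrow(freq$counts), replace = TRUE))
        if (length(rows) < 2L) next
        fb <- freq_matrix(freq$counts[rows, , drop = FALSE])
        rep_sets <- clade_labels(ward_cluster(fb))
        key <- vapply(rep_sets, paste, character(1), collapse = "\r")
        present <- rownames(freq$counts)[rows]
        for (k in seq_along(obs_sets)) {
          if (!all(obs_sets[[k]] %in% present)) next
          denom[k] <- denom[k] + 1
          if (paste(obs_sets[[k]], collapse = "\r") %in% key)
            hits[k] <- hits[k] + 1
        }
      }
    }
  })
  support <- ifelse(denom > 0, 100 * hits / denom, NA_real_)
  list(hclust = hc, support = support, n_boot = n_boot, seed = seed,
       resample = resample)
}

#' PCA of haplogroup frequency profiles
#'
#' Column-centered (unscaled) principal component analysis of the
#' frequency rows: an eigen-decomposition of the covariance between
#' populations. Bins share a scale by construction, so no correlation
#' scaling is applied.
#'
#' @param freq An `mt_freq` (or plain frequency matrix) with >= 2 rows.
#' @return List with `scores` (populations x components), `loadings`
#'   (bins x components), `explained` (variance fractions summing to 1),
#'   `sdev`.
#' @export
pca_frequencies <- function(freq) {
  m <- if (inherits(freq, "mt_freq")) freq$freq else as.matrix(freq)
  if (nrow(m) < 2L) stopf("need >= 2 populations for PCA")
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  list(scores = p$x, loadings = p$rotation,
       explained = p$sdev^2 / sum(p$sdev^2), sdev = p$sdev)
}

#' Resample a metapopulation from pooled individuals
#'
#' Uniform sampling without replacement of `n` individuals from a pooled
#' table of individuals with country labels (the construction of a
#' present-day metapopulation from several national datasets).
#'
#' @param pool data.frame with columns `sample_id`, `country`, and
#'   optionally `haplogroup`.
#' @param n Number of individuals to draw (`n <= nrow(pool)`).
#' @param seed Integer seed.
#' @return List with `sample` (the drawn rows) and `tally` (per-country
#'   counts).
#' @export
build_metapopulation <- function(pool, n = 500, seed = NULL) {
  pool <- as.data.frame(pool)
  if (nrow(pool) < n) stopf("pool (%d) smaller than requested n (%d)",
                            nrow(pool), n)
  idx <- with_seed(seed, sample(nrow(pool), n))
  drawn <- pool[idx, , drop = FALSE]
  list(sample = drawn, tally = table(drawn$country), n = n, seed = seed)
}

# log-probability of a contingency table under the fixed-margins null
log_table_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

#' Fisher's test for an R x C count table
#'
#' 2 x 2 tables use the exact two-sided hypergeometric test (the sum of
#' probabilities of tables no more probable than the observed one). Larger
#' tables use a Monte-Carlo estimate: tables are sampled from the
#' fixed-margins null and `p = (1 + #{prob <= observed}) / (n_sim + 1)`.
#'
#' @param counts Non-negative integer matrix, >= 2 rows and columns, with
#'   no all-zero row or column.
#' @param n_sim Monte-Carlo sample size for tables larger than 2 x 2.
#' @param seed Integer seed.
#' @return List with `p_value`, `method` (`"exact"` or `"monte-carlo"`),
#'   `n_sim`.
#' @export
fisher_rxc <- function(counts, n_sim = 1e5, seed = NULL) {
  tab <- as.matrix(counts)
  if (any(tab < 0) || any(tab != floor(tab)))
    stopf("counts must be non-negative integers")
  if (nrow(tab) < 2L || ncol(tab) < 2L) stopf("table must be >= 2 x 2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("all-zero row or column")
  if (nrow(tab) == 2L && ncol(tab) == 2L) {
    return(list(p_value = stats::fisher.test(tab)$p.value,
                method = "exact", n_sim = NA_integer_))
  }
  obs <- log_table_prob(tab)
  sims <- with_seed(seed, stats::r2dtable(n_sim, rowSums(tab), colSums(tab)))
  cnt <- sum(vapply(sims, log_table_prob, numeric(1)) <= obs + 1e-7)
  list(p_value = (1 + cnt) / (n_sim + 1), method = "monte-carlo",
       n_sim = n_sim)
}
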
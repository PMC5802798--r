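# Within-population diversity: haplotype diversity (HD) and nucleotide
# diversity (pi) with the classical sampling-variance estimators.

#' Haplotype diversity
#'
#' `HD = n (1 - sum p_i^2) / (n - 1)` over haplotype class frequencies,
#' i.e. the small-sample-corrected probability that two randomly drawn
#' haplotypes differ. Haplotypes are compared by exact string equality
#' after uppercasing; `N` is not treated as a wildcard, so partially
#' called strings are distinct haplotypes. The standard deviation comes
#' from Nei's sampling-variance estimator
#' `V = (2/(n(n-1))) (2(n-2)(sum p^3 - (sum p^2)^2) + sum p^2 - (sum p^2)^2)`.
#'
#' @param haplotypes Character vector of haplotype strings (one per
#'   individual; `n >= 2`).
#' @return List with `estimate`, `sd`, `n`, and `n_haplotypes`.
#' @examples
#' haplotype_diversity(c("A", "A", "B", "B"))$estimate  # 2/3
#' @export
haplotype_diversity <- function(haplotypes) {
  h <- toupper(as.character(haplotypes))
  n <- length(h)
  if (n < 2L) stopf("haplotype diversity needs n >= 2")
  p <- as.numeric(table(h)) / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  hd <- n * (1 - s2) / (n - 1)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(estimate = hd, sd = sqrt(max(v, 0)), n = n,
       n_haplotypes = length(unique(h)))
}

#' Nucleotide diversity
#'
#' The mean per-site proportion of differing positions over all sequence
#' pairs, with pairwise deletion: for each pair only the jointly called
#' sites count, and the pair contributes `d_ij / L_ij`. With
#' `complete_deletion = TRUE` sites missing in any sequence are removed
#' once for all pairs instead. The standard deviation is Tajima's total
#' (sampling + stochastic) variance estimator
#' `V = ((n+1)/(3(n-1))) pi/L + (2(n^2+n+3)/(9n(n-1))) pi^2`.
#'
#' @param sequences Character vector of equal-length aligned sequences
#'   (`n >= 2`).
#' @param complete_deletion Drop sites that are uncalled in any sequence
#'   before comparing (default `FALSE`, i.e. pairwise deletion).
#' @return List with `estimate`, `sd`, `n`, and `L` (mean number of sites
#'   compared per pair).
#' @export
nucleotide_diversity <- function(sequences, complete_deletion = FALSE) {
  s <- toupper(as.character(sequences))
  n <- length(s)
  if (n < 2L) stopf("nucleotide diversity needs n >= 2")
  if (length(unique(nchar(s))) != 1L) stopf("sequences differ in length")
  ch <- lapply(s, seq_chars)
  called <- lapply(ch, called_mask)
  if (complete_deletion) {
    keep <- Reduce(`&`, called)
    if (!any(keep)) stopf("no site is called in every sequence")
    ch <- lapply(ch, `[`, keep)
    called <- lapply(ch, called_mask)
  }
  pairs <- utils::combn(n, 2L)
  per_pair <- apply(pairs, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    ok <- called[[i]] & called[[j]]
    L <- sum(ok)
    if (L == 0L) stopf("sequences %d and %d share zero jointly called sites",
                       i, j)
    c(d = sum(ch[[i]][ok] != ch[[j]][ok]) / L, L = L)
  })
  pi_hat <- mean(per_pair["d", ])
  L_bar <- mean(per_pair["L", ])
  v <- (n + 1) / (3 * (n - 1)) * pi_hat / L_bar +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi_hat^2
  list(estimate = pi_hat, sd = sqrt(max(v, 0)), n = n, L = L_bar)
}

#' Haplotype strings of a dataset over given regions
#'
#' Convenience wrapper slicing (and concatenating, for multi-interval
#' regions) the analysis region and returning one haplotype string per
#' sample, named by sample id.
#'
#' @param dataset An `mt_dataset`.
#' @param region An [mt_region()]; default: the dataset's full region.
#' @export
haplotype_strings <- function(dataset, region = NULL) {
  if (!is.null(region)) dataset <- slice_region(dataset, region)
  stats::setNames(dataset$samples$sequence, dataset$samples$sample_id)
}
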
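# Minimum spanning network over haplotype nodes, duplicate detection and
# deduplication.

# simple union-find
dsu_new <- function(n) seq_len(n)
dsu_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Collapse identical sequences into haplotype nodes
#'
#' Groups samples by exact sequence identity; each node is labelled by the
#' lexicographically first member id.
#'
#' @param dataset An `mt_dataset`.
#' @return List with `nodes` (data.frame `node`, `haplotype`, `size`) and
#'   `members` (list of sample-id vectors, parallel to `nodes`).
#' @export
collapse_haplotypes <- function(dataset) {
  stopifnot(inherits(dataset, "mt_dataset"))
  s <- dataset$samples
  grp <- split(s$sample_id, s$sequence)
  members <- lapply(grp, sort)
  labels <- vapply(members, `[`, character(1), 1L)
  o <- order(labels)
  members <- members[o]
  nodes <- data.frame(node = labels[o], haplotype = names(grp)[o],
                      size = lengths(members), stringsAsFactors = FALSE,
                      row.names = NULL)
  list(nodes = nodes, members = unname(members))
}

#' Build a minimum spanning network
#'
#' The epsilon = 0 network is the union of all minimum spanning trees:
#' Kruskal's algorithm processed in equal-weight batches, keeping within a
#' batch every edge that joins two components of the pre-batch partition.
#' With epsilon > 0, any edge whose weight is at most the weight at which
#' its endpoints' components merged plus `epsilon` is also admitted.
#'
#' @param labels Node labels.
#' @param D Symmetric matrix of nucleotide differences between nodes.
#' @param epsilon Relaxation parameter (default 0).
#' @return Object of class `mt_msn` with `nodes`, `edges` (data.frame
#'   `from`, `to`, `weight`), `epsilon`.
#' @export
build_msn <- function(labels, D, epsilon = 0) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(length(labels) == n, epsilon >= 0)
  if (n == 1L)
    return(structure(list(nodes = labels,
                          edges = data.frame(from = character(),
                                             to = character(),
                                             weight = numeric()),
                          epsilon = epsilon), class = "mt_msn"))
  # join_w[i,j]: the batch weight at which i's and j's components merged
  parent <- dsu_new(n)
  join_w <- matrix(NA_real_, n, n)
  edges <- which(upper.tri(D), arr.ind = TRUE)
  ew <- D[edges]
  keep <- logical(nrow(edges))
  for (w in sort(unique(ew))) {
    batch <- which(ew == w)
    roots <- vapply(seq_len(n), function(i) dsu_find(parent, i), integer(1))
    # keep every batch edge joining two distinct pre-batch components
    cross <- batch[roots[edges[batch, 1L]] != roots[edges[batch, 2L]]]
    keep[cross] <- TRUE
    # then merge and record join weights between all newly connected pairs
    for (e in cross) {
      r1 <- dsu_find(parent, edges[e, 1L])
      r2 <- dsu_find(parent, edges[e, 2L])
      if (r1 != r2) {
        m1 <- which(vapply(seq_len(n), function(i)
          dsu_find(parent, i), integer(1)) == r1)
        m2 <- which(vapply(seq_len(n), function(i)
          dsu_find(parent, i), integer(1)) == r2)
        join_w[m1, m2] <- w
        join_w[m2, m1] <- w
        parent[r2] <- r1
      }
    }
  }
  if (epsilon > 0) {
    relax <- ew <= join_w[edges] + epsilon
    keep <- keep | relax
  }
  ed <- data.frame(from = labels[edges[keep, 1L]],
                   to = labels[edges[keep, 2L]],
                   weight = ew[keep], stringsAsFactors = FALSE)
  ed <- ed[order(ed$weight, ed$from, ed$to), , drop = FALSE]
  rownames(ed) <- NULL
  structure(list(nodes = labels, edges = ed, epsilon = epsilon),
            class = "mt_msn")
}

#' @export
print.mt_msn <- function(x, ...) {
  cat(sprintf("<mt_msn> %d nodes, %d edges (epsilon = %g)\n",
              length(x$nodes), nrow(x$edges), x$epsilon))
  invisible(x)
}

#' Minimum spanning network of a dataset
#'
#' Collapses identical sequences into haplotype nodes and connects them by
#' the union of all minimum spanning trees on the pairwise
#' nucleotide-difference counts (pairwise deletion of uncalled sites).
#'
#' @param dataset An `mt_dataset`.
#' @param epsilon Relaxation parameter for [build_msn()].
#' @return An `mt_msn` with `members` attached.
#' @export
msn <- function(dataset, epsilon = 0) {
  col <- collapse_haplotypes(dataset)
  seqs <- stats::setNames(col$nodes$haplotype, col$nodes$node)
  D <- if (length(seqs) > 1L) dist_matrix_seqs(seqs, "differences")
       else matrix(0, 1, 1)
  g <- build_msn(col$nodes$node, D, epsilon)
  g$members <- col$members
  g$node_table <- col$nodes
  g
}

#' Sample pairs at an exact sequence distance
#'
#' All unordered sample pairs whose sequences differ at exactly `d`
#' jointly called positions.
#'
#' @param dataset An `mt_dataset`.
#' @param d Non-negative integer distance.
#' @return data.frame with columns `sample1`, `sample2`, `distance`.
#' @export
find_pairs_at_distance <- function(dataset, d) {
  stopifnot(d >= 0)
  if (nrow(dataset$samples) < 2L)
    return(data.frame(sample1 = character(), sample2 = character(),
                      distance = numeric()))
  D <- dist_matrix(dataset, "differences")
  idx <- which(upper.tri(D) & D == d, arr.ind = TRUE)
  out <- data.frame(sample1 = rownames(D)[idx[, 1L]],
                    sample2 = colnames(D)[idx[, 2L]],
                    distance = d, stringsAsFactors = FALSE)
  out[order(out$sample1, out$sample2), , drop = FALSE]
}

#' Remove duplicate haplotypes
#'
#' From each connected component of the graph of identical-sequence pairs
#' (distance 0), keeps the lexicographically first sample id and removes
#' the rest — so a triple of identical sequences loses two members.
#'
#' @param dataset An `mt_dataset`.
#' @return List with `dataset` (deduplicated) and `removed` (data.frame
#'   `sample_id`, `kept_as`, `reason`).
#' @export
deduplicate <- function(dataset) {
  col <- collapse_haplotypes(dataset)
  removed <- data.frame(sample_id = character(), kept_as = character(),
                        reason = character(), stringsAsFactors = FALSE)
  for (m in col$members) {
    if (length(m) > 1L) {
      removed <- rbind(removed, data.frame(
        sample_id = m[-1L], kept_as = m[1L],
        reason = sprintf("identical mtDNA sequence to %s", m[1L]),
        stringsAsFactors = FALSE))
    }
  }
  keep <- !(dataset$samples$sample_id %in% removed$sample_id)
  list(dataset = subset_dataset(dataset, keep), removed = removed)
}
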
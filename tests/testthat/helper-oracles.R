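# Independent definitional oracles: explicit loops and exhaustive
# enumeration, sharing no code with the package implementation.

# Brute-force AMOVA: character-by-character distance counting and explicit
# double loops over individuals for every sum of squares.
oracle_amova <- function(seqs, pop, group_of_pop_by_level) {
  n <- length(seqs)
  ch <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  d2 <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- ch[[i]] %in% c("A", "C", "G", "T") &
      ch[[j]] %in% c("A", "C", "G", "T")
    d2[i, j] <- sum(ch[[i]][ok] != ch[[j]][ok])
  }
  pops <- unique(pop)
  g_ind <- group_of_pop_by_level[match(pop, pops)]
  N <- n; P <- length(pops); G <- length(unique(group_of_pop_by_level))
  ss_within <- function(idx) sum(d2[idx, idx]) / (2 * length(idx))
  sstot <- sum(d2) / (2 * N)
  sswp <- sum(sapply(pops, function(p) ss_within(which(pop == p))))
  sswg <- sum(sapply(unique(g_ind), function(g) ss_within(which(g_ind == g))))
  ssag <- sstot - sswg
  ssap <- sswg - sswp
  n_p <- sapply(pops, function(p) sum(pop == p))
  gl <- unique(group_of_pop_by_level)
  N_g <- sapply(gl, function(g) sum(g_ind == g))
  Sg <- sapply(gl, function(g) sum(n_p[group_of_pop_by_level == g]^2))
  dfag <- G - 1; dfap <- P - G; dfwp <- N - P
  sc <- sswp / dfwp
  n1 <- (N - sum(Sg / N_g)) / dfap
  sb <- (ssap / dfap - sc) / n1
  n2 <- (sum(Sg / N_g) - sum(n_p^2) / N) / dfag
  n3 <- (N - sum(N_g^2) / N) / dfag
  sa <- (ssag / dfag - sc - n2 * sb) / n3
  list(sigma_a = sa, sigma_b = sb, sigma_c = sc,
       phi_ct = sa / (sa + sb + sc), phi_sc = sb / (sb + sc),
       phi_st = (sa + sb) / (sa + sb + sc),
       ssd = c(total = sstot, ag = ssag, apwg = ssap, wp = sswp))
}

# Step-up BH by its textbook definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- Inf
  for (k in m:1) {
    val <- min(prev, m * p[o[k]] / k)
    adj[o[k]] <- min(val, 1)
    prev <- val
  }
  adj
}

# Exhaustive union of all minimum spanning trees for a small complete graph.
oracle_msn <- function(D) {
  n <- nrow(D)
  if (n == 1L) return(matrix(numeric(0), 0, 2))
  pairs <- t(utils::combn(n, 2L))
  w <- D[pairs]
  spanning <- function(sel) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (e in sel) {
      a <- find(pairs[e, 1L]); b <- find(pairs[e, 2L])
      if (a != b) parent[a] <- b
    }
    length(unique(sapply(seq_len(n), find))) == 1L
  }
  trees <- utils::combn(nrow(pairs), n - 1L, simplify = FALSE)
  ok <- Filter(spanning, trees)
  weights <- sapply(ok, function(sel) sum(w[sel]))
  keep <- ok[weights <= min(weights) + 1e-9]
  edges <- unique(do.call(rbind, lapply(keep, function(sel)
    pairs[sel, , drop = FALSE])))
  edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
}

# Double-loop haplotype diversity (probability two draws differ).
oracle_hd <- function(h) {
  n <- length(h)
  same <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    same <- same + (h[i] == h[j])
  n / (n - 1) * (1 - same / n^2)
}

# Double-loop nucleotide diversity with pairwise deletion.
oracle_pi <- function(seqs) {
  n <- length(seqs)
  ch <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  acc <- 0; m <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- ch[[i]] %in% c("A", "C", "G", "T") &
      ch[[j]] %in% c("A", "C", "G", "T")
    acc <- acc + sum(ch[[i]][ok] != ch[[j]][ok]) / sum(ok)
    m <- m + 1
  }
  acc / m
}

# canonical string for an unordered partition (list of character vectors)
canon_partition <- function(groups) {
  paste(sort(vapply(groups, function(g) paste(sort(g), collapse = "+"),
                    character(1))), collapse = "|")
}

edge_key <- function(edges_df) {
  if (!nrow(edges_df)) return(character(0))
  sort(paste(pmin(edges_df$from, edges_df$to),
             pmax(edges_df$from, edges_df$to), sep = "~"))
}

seq_chars <- function(s) strsplit(s, "")[[1]]

random_seqs <- function(n, L, mut = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                collapse = "")
  vapply(seq_len(n), function(i)
    mutate_sequence(base, stats::rpois(1, mut)), character(1))
}
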
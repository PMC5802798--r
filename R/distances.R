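# Sequence-level distances. Sites with N or - in either member of a pair
# are excluded for that pair (pairwise deletion); evolutionary models are
# computed on the jointly called sites via ape.

as_dnabin <- function(seqs, ids = names(seqs)) {
  m <- do.call(rbind, lapply(tolower(seqs), seq_chars))
  rownames(m) <- ids %||% paste0("s", seq_along(seqs))
  ape::as.DNAbin(m)
}

dist_model_name <- function(model) {
  switch(model,
         differences = "N",
         p = "raw",
         TN93 = "TN93",
         `TN93+G` = "TN93",
         stopf("unknown distance model '%s'", model))
}

#' Pairwise distance between two aligned sequences
#'
#' @param a,b Aligned sequences (equal-length strings over `A,C,G,T,N,-`).
#' @param model `"differences"` (count of differing jointly called sites),
#'   `"p"` (that count divided by the jointly called sites), `"TN93"`, or
#'   `"TN93+G"` (Tamura-Nei with gamma rate heterogeneity; requires
#'   `gamma`).
#' @param gamma Gamma shape parameter for `"TN93+G"`.
#' @return A single non-negative number.
#' @export
seq_distance <- function(a, b, model = c("differences", "p", "TN93", "TN93+G"),
                         gamma = NULL) {
  model <- match.arg(model)
  if (nchar(a) != nchar(b)) stopf("sequences differ in length")
  D <- dist_matrix_seqs(c(a = a, b = b), model, gamma)
  D[1L, 2L]
}

# Full symmetric distance matrix for a named character vector of sequences.
dist_matrix_seqs <- function(seqs, model = "differences", gamma = NULL) {
  if (model == "TN93+G" && is.null(gamma))
    stopf("model TN93+G requires a gamma shape parameter")
  ca <- lapply(seqs, seq_chars)
  joint <- outer(seq_along(ca), seq_along(ca), Vectorize(function(i, j)
    sum(called_mask(ca[[i]]) & called_mask(ca[[j]]))))
  if (any(joint[upper.tri(joint)] == 0))
    stopf("a sequence pair shares zero jointly called sites")
  bin <- as_dnabin(seqs)
  D <- ape::dist.dna(bin, model = dist_model_name(model),
                     gamma = if (model == "TN93+G") gamma else FALSE,
                     pairwise.deletion = TRUE, as.matrix = TRUE)
  if (model == "p") {
    Dn <- ape::dist.dna(bin, model = "N", pairwise.deletion = TRUE,
                        as.matrix = TRUE)
    D <- Dn / joint
    diag(D) <- 0
  }
  if (any(!is.finite(D))) {
    bad <- which(!is.finite(D), arr.ind = TRUE)[1L, ]
    stopf("distance undefined (saturated pair?) between '%s' and '%s'",
          rownames(D)[bad[1L]], rownames(D)[bad[2L]])
  }
  D
}

#' Pairwise sequence-distance matrix for a dataset
#'
#' @param dataset An `mt_dataset`.
#' @param model,gamma See [seq_distance()].
#' @return Symmetric numeric matrix with sample ids as dimnames.
#' @export
dist_matrix <- function(dataset, model = "differences", gamma = NULL) {
  stopifnot(inherits(dataset, "mt_dataset"))
  seqs <- dataset$samples$sequence
  names(seqs) <- dataset$samples$sample_id
  dist_matrix_seqs(seqs, model, gamma)
}
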
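# Shared-haplotype analysis: classical shared fractions against reference
# populations and epoch-ordered ancestral lineage assignment.

# Distinct fully-called target haplotypes; partially called ones are
# excluded and reported, because wildcard matching would inflate sharing.
target_haplotypes <- function(target) {
  t_up <- toupper(as.character(target))
  if (!length(t_up)) stopf("empty target population")
  callable <- !grepl("[N-]", t_up)
  list(haps = unique(t_up[callable]), all = t_up[callable],
       excluded = unique(t_up[!callable]))
}

#' Classical shared-haplotype fraction
#'
#' Percentage of the target population's haplotypes found identically
#' (exact string match after uppercasing) in at least one reference
#' population, with a per-reference breakdown. By default the denominator
#' counts distinct haplotypes; `weight = "individuals"` counts carriers
#' instead.
#'
#' @param target Character vector of target haplotypes (one per
#'   individual).
#' @param references Named list of character vectors of reference
#'   haplotypes.
#' @param weight `"haplotypes"` (default) or `"individuals"`.
#' @return List with `percent`, `per_reference` (named percentages),
#'   `shared` (the matched haplotypes), `excluded` (target haplotypes
#'   with uncalled positions, not analyzed).
#' @export
shared_fraction <- function(target, references,
                            weight = c("haplotypes", "individuals")) {
  weight <- match.arg(weight)
  th <- target_haplotypes(target)
  refs <- lapply(references, function(r) unique(toupper(as.character(r))))
  in_any <- th$haps[th$haps %in% unique(unlist(refs))]
  denom_units <- if (weight == "haplotypes") th$haps else th$all
  num <- if (weight == "haplotypes") length(in_any) else
    sum(th$all %in% in_any)
  per_ref <- vapply(refs, function(r) {
    hit <- th$haps[th$haps %in% r]
    100 * (if (weight == "haplotypes") length(hit) else
             sum(th$all %in% hit)) / length(denom_units)
  }, numeric(1))
  list(percent = 100 * num / length(denom_units), per_reference = per_ref,
       shared = in_any, excluded = th$excluded, weight = weight,
       n_haplotypes = length(th$haps), n_individuals = length(th$all))
}

#' Ancestral lineage assignment by earliest epoch
#'
#' Assigns every distinct target haplotype to the earliest epoch whose
#' reference populations contain an identical haplotype; haplotypes absent
#' from every reference are `"novel"`. Incidences are percentages over the
#' distinct target haplotypes (or carriers with `weight =
#' "individuals"`) and sum to 100 together with the novel percentage.
#'
#' @param target Character vector of target haplotypes.
#' @param references Named list of reference haplotype vectors.
#' @param epochs Named character vector: epoch label per reference
#'   population; every label must appear in `epoch_levels`.
#' @param epoch_levels Epoch ordering (default [mt_epochs()]).
#' @param weight `"haplotypes"` or `"individuals"`.
#' @return Object of class `mt_lineage`: `assignments` (data.frame
#'   `haplotype`, `epoch`, `populations`), `incidence` (named percentages
#'   per epoch plus `"novel"`), `excluded`.
#' @export
ancestral_assign <- function(target, references, epochs,
                             epoch_levels = mt_epochs(),
                             weight = c("haplotypes", "individuals")) {
  weight <- match.arg(weight)
  if (is.null(names(references)) || !all(names(references) %in% names(epochs)))
    stopf("every reference population needs an epoch label")
  ep <- epochs[names(references)]
  if (!all(ep %in% epoch_levels))
    stopf("unordered epoch label(s): %s",
          paste(setdiff(ep, epoch_levels), collapse = ", "))
  th <- target_haplotypes(target)
  refs <- lapply(references, function(r) unique(toupper(as.character(r))))
  rank <- match(ep, epoch_levels)
  assign1 <- function(h) {
    hit <- vapply(refs, function(r) h %in% r, logical(1))
    if (!any(hit)) return(list(epoch = "novel", pops = ""))
    first <- min(rank[hit])
    sel <- hit & rank == first
    list(epoch = epoch_levels[first],
         pops = paste(names(refs)[sel], collapse = ","))
  }
  res <- lapply(th$haps, assign1)
  assignments <- data.frame(
    haplotype = th$haps,
    epoch = vapply(res, `[[`, character(1), "epoch"),
    populations = vapply(res, `[[`, character(1), "pops"),
    stringsAsFactors = FALSE)
  lev <- c(epoch_levels, "novel")
  w <- if (weight == "haplotypes") rep(1, length(th$haps)) else
    vapply(th$haps, function(h) sum(th$all == h), numeric(1))
  inc <- vapply(lev, function(e)
    100 * sum(w[assignments$epoch == e]) / sum(w), numeric(1))
  structure(list(assignments = assignments, incidence = inc,
                 excluded = th$excluded, weight = weight),
            class = "mt_lineage")
}

#' @export
print.mt_lineage <- function(x, ...) {
  cat(sprintf("<mt_lineage> %d target haplotypes (%s-weighted)\n",
              nrow(x$assignments), x$weight))
  inc <- x$incidence[x$incidence > 0]
  cat("  incidence:", paste(sprintf("%s %.2f%%", names(inc), inc),
                            collapse = ", "), "\n")
  invisible(x)
}
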
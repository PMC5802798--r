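# Sex-stratified re-analysis: split the target population into female and
# male subgroups and re-run the sequence- and frequency-based analyses.

#' Sex-stratified re-analysis of a target population
#'
#' Resolves consensus sex from the metadata (genetic assignment takes
#' precedence), splits the target population into F and M subgroups
#' (individuals of unknown sex belong to neither but stay in the pooled
#' analysis), and re-runs the diversity, haplogroup-frequency, and
#' genetic-distance stages with the target replaced by each subgroup.
#' The F-vs-M bin-count table (zero-total bins dropped) is tested with
#' [fisher_rxc()].
#'
#' @param dataset An `mt_dataset`; populations other than `target` serve
#'   as references for the Fst tables.
#' @param target Population id to stratify.
#' @param scheme A [bin_scheme()] for the frequency analyses.
#' @param hd_region,pi_region Optional [mt_region()]s for haplotype /
#'   nucleotide diversity (default: full dataset region).
#' @param fst_region Optional region for the Fst-to-reference tables.
#' @param n_sim Monte-Carlo sample size for the Fisher test.
#' @param seed Integer seed.
#' @return Object of class `mt_stratified`: subgroup memberships,
#'   per-subgroup diversity and frequency rows, Fst-to-reference tables
#'   (when references exist), and the between-subgroup Fisher p-value.
#' @export
stratify_and_run <- function(dataset, target, scheme = bin_scheme("CEPT23"),
                             hd_region = NULL, pi_region = NULL,
                             fst_region = NULL, n_sim = 1e5, seed = NULL) {
  stopifnot(inherits(dataset, "mt_dataset"))
  if (!target %in% dataset$populations)
    stopf("population '%s' not in dataset", target)
  meta <- dataset$metadata
  sex <- resolve_sex(meta$anthropological_sex, meta$genetic_sex)$sex
  names(sex) <- meta$sample_id
  in_target <- dataset$samples$population == target
  ids <- dataset$samples$sample_id
  members <- list(F = ids[in_target & sex[ids] == "F"],
                  M = ids[in_target & sex[ids] == "M"],
                  unassigned = ids[in_target & sex[ids] == "unknown"])
  refs <- setdiff(dataset$populations, target)
  run_subgroup <- function(sub_ids, label) {
    if (length(sub_ids) < 2L) {
      warning(sprintf("subgroup %s has < 2 members; sequence analyses skipped",
                      label), call. = FALSE)
      return(list(n = length(sub_ids)))
    }
    keep <- !in_target | ids %in% sub_ids
    ds <- subset_dataset(dataset, keep)
    # relabel the subgroup so it stands in for the target population
    ds$samples$population[ds$samples$population == target] <-
      paste0(target, "-", label)
    ds$populations <- unique(ds$samples$population)
    sub <- subset_dataset(dataset, ids %in% sub_ids)
    out <- list(n = length(sub_ids))
    out$hd <- haplotype_diversity(haplotype_strings(sub, hd_region))
    out$pi <- nucleotide_diversity(haplotype_strings(sub, pi_region))
    hg <- meta$haplogroup[match(sub_ids, meta$sample_id)]
    out$bin_counts <- table(factor(assign_bin(hg[!is.na(hg)], scheme),
                                   levels = scheme$bins))
    if (length(refs) && all(table(ds$samples$population) >= 2)) {
      dsr <- if (is.null(fst_region)) ds else slice_region(ds, fst_region)
      out$fst_to_references <- pairwise_phist(dsr)[paste0(target, "-", label),
                                                   refs, drop = TRUE]
    }
    out
  }
  res_f <- run_subgroup(members$F, "F")
  res_m <- run_subgroup(members$M, "M")
  fisher <- NULL
  if (!is.null(res_f$bin_counts) && !is.null(res_m$bin_counts)) {
    tab <- rbind(F = as.numeric(res_f$bin_counts),
                 M = as.numeric(res_m$bin_counts))
    colnames(tab) <- scheme$bins
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    fisher <- fisher_rxc(tab, n_sim = n_sim, seed = seed)
    fisher$table <- tab
  }
  structure(list(target = target, members = members, F = res_f, M = res_m,
                 fisher = fisher, scheme = scheme$name),
            class = "mt_stratified")
}

#' @export
print.mt_stratified <- function(x, ...) {
  cat(sprintf("<mt_stratified> %s: %d F / %d M / %d unassigned\n",
              x$target, length(x$members$F), length(x$members$M),
              length(x$members$unassigned)))
  for (g in c("F", "M")) {
    r <- x[[g]]
    if (!is.null(r$pi))
      cat(sprintf("  %s: HD %.4f +/- %.4f, pi %.6f +/- %.6f (n = %d)\n", g,
                  r$hd$estimate, r$hd$sd, r$pi$estimate, r$pi$sd, r$n))
  }
  if (!is.null(x$fisher))
    cat(sprintf("  F vs M haplogroup frequencies: Fisher p = %.4g (%s)\n",
                x$fisher$p_value, x$fisher$method))
  invisible(x)
}
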
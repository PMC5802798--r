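# Orchestration: run the full analysis workflow from one configuration
# with deterministic per-stage seeding and an optional on-disk report
# bundle (TSV/JSON with a manifest).

#' Run the full analysis workflow
#'
#' Executes the study stages in order: read/filter, deduplication,
#' diversity, minimum spanning network, haplogroup frequencies
#' (clustering + PCA), pairwise Fst with MDS, AMOVA grouping search (when
#' candidate groupings are supplied; otherwise the stage is skipped and
#' logged), shared haplotypes (when references are supplied), and the
#' sex-stratified re-analysis. Per-stage seeds are derived from the master
#' seed by a fixed counter so stages can be re-run in isolation; the same
#' config and seed always give identical results.
#'
#' @param dataset An `mt_dataset` (e.g. from [read_fasta()] or
#'   [simulate_divergence_populations()]).
#' @param target Target population id for diversity / network / shared /
#'   sex stages (default: first population).
#' @param scheme A [bin_scheme()].
#' @param hd_region,pi_region,fst_region Optional analysis regions.
#' @param groupings Optional list of [mt_grouping()] candidates for the
#'   structure search.
#' @param references Optional named list of reference haplotype vectors
#'   with an `epochs` attribute (named epoch per reference) for the
#'   lineage stage.
#' @param n_perm Permutations for Fst/AMOVA p-values.
#' @param n_boot Bootstrap replicates for cluster support.
#' @param seed Master seed.
#' @param out_dir Optional directory to write the report bundle to.
#' @param deduplicate_target Remove identical-sequence duplicates from the
#'   target population before diversity analyses (default TRUE).
#' @return Object of class `mt_run`: a list of per-stage results plus a
#'   `log` data.frame and `manifest`.
#' @export
run_study <- function(dataset, target = NULL, scheme = bin_scheme("CEPT23"),
                      hd_region = NULL, pi_region = NULL, fst_region = NULL,
                      groupings = NULL, references = NULL,
                      n_perm = 999, n_boot = 1000, seed = 1,
                      out_dir = NULL, deduplicate_target = TRUE) {
  stopifnot(inherits(dataset, "mt_dataset"))
  target <- target %||% dataset$populations[1L]
  stage_seed <- function(k) seed + k
  log <- data.frame(stage = character(), status = character(),
                    detail = character(), stringsAsFactors = FALSE)
  note <- function(stage, status, detail = "") {
    log <<- rbind(log, data.frame(stage = stage, status = status,
                                  detail = detail, stringsAsFactors = FALSE))
    message(sprintf("[%s] %s %s", stage, status, detail))
  }
  res <- list(seed = seed, target = target)

  note("io", "ok", sprintf("%d samples, %d populations",
                           nrow(dataset$samples),
                           length(dataset$populations)))

  dd <- deduplicate(subset_dataset(dataset,
                                   dataset$samples$population == target))
  res$duplicates <- dd$removed
  target_ds <- if (deduplicate_target) dd$dataset else
    subset_dataset(dataset, dataset$samples$population == target)
  note("dedup", "ok", sprintf("%d duplicate(s) removed", nrow(dd$removed)))

  res$hd <- haplotype_diversity(haplotype_strings(target_ds, hd_region))
  res$pi <- nucleotide_diversity(haplotype_strings(target_ds, pi_region))
  note("diversity", "ok",
       sprintf("HD=%.4f pi=%.6f", res$hd$estimate, res$pi$estimate))

  res$msn <- msn(subset_dataset(dataset,
                                dataset$samples$population == target))
  note("msn", "ok", sprintf("%d haplotype nodes", length(res$msn$nodes)))

  hg <- dataset$metadata
  hg <- hg[!is.na(hg$haplogroup), c("sample_id", "haplogroup")]
  hg$population <- dataset$samples$population[
    match(hg$sample_id, dataset$samples$sample_id)]
  res$freq <- build_frequency_matrix(hg, scheme)
  if (nrow(res$freq$freq) >= 2L) {
    res$clustering <- bootstrap_support(res$freq, n_boot = n_boot,
                                        seed = stage_seed(1L))
    res$pca <- pca_frequencies(res$freq)
    note("hapfreq", "ok", sprintf("%d populations x %d bins",
                                  nrow(res$freq$freq), ncol(res$freq$freq)))
  } else note("hapfreq", "skipped", "fewer than 2 populations with counts")

  if (length(dataset$populations) >= 2L &&
      all(table(dataset$samples$population) >= 2)) {
    res$fst <- fst_analysis(dataset, region = fst_region,
                            n_perm = n_perm, seed = stage_seed(2L))
    res$mds <- mds_embed(res$fst$linearized, mode = "nonmetric",
                         seed = stage_seed(3L))
    note("fst", "ok", sprintf("%d pairs", sum(lower.tri(res$fst$fst))))
  } else note("fst", "skipped", "need >= 2 populations of >= 2")

  if (!is.null(groupings)) {
    res$structure <- grouping_search(dataset, groupings,
                                     n_perm = n_perm, seed = stage_seed(4L))
    note("amova", "ok",
         sprintf("optimum: %s", res$structure$optimum$name))
  } else note("amova", "skipped", "no candidate groupings supplied")

  if (!is.null(references)) {
    res$shared <- shared_fraction(haplotype_strings(target_ds), references)
    ep <- attr(references, "epochs")
    if (!is.null(ep))
      res$lineage <- ancestral_assign(haplotype_strings(target_ds),
                                      references, ep)
    note("shared", "ok", sprintf("%.1f%% shared", res$shared$percent))
  } else note("shared", "skipped", "no reference haplotypes supplied")

  res$sexdiff <- tryCatch(
    stratify_and_run(dataset, target, scheme = scheme,
                     hd_region = hd_region, pi_region = pi_region,
                     fst_region = fst_region, seed = stage_seed(5L)),
    warning = function(w) {
      note("sexdiff", "partial", conditionMessage(w))
      suppressWarnings(stratify_and_run(dataset, target, scheme = scheme,
                                        hd_region = hd_region,
                                        pi_region = pi_region,
                                        fst_region = fst_region,
                                        seed = stage_seed(5L)))
    })
  if (!any(log$stage == "sexdiff")) note("sexdiff", "ok", "")

  res$log <- log
  res$manifest <- list(package_version = as.character(
    utils::packageVersion("mtstruct")),
    seed = seed, n_perm = n_perm, n_boot = n_boot,
    scheme = scheme$name, target = target,
    n_samples = nrow(dataset$samples),
    region = paste(sprintf("%d-%d", dataset$region$start,
                           dataset$region$end), collapse = ","))
  class(res) <- "mt_run"
  if (!is.null(out_dir)) write_run_bundle(res, dataset, out_dir)
  res
}

#' @export
print.mt_run <- function(x, ...) {
  cat(sprintf("<mt_run> target %s (seed %d)\n", x$target, x$seed))
  print(x$log, row.names = FALSE)
  invisible(x)
}

# On-disk report bundle: TSVs for the matrices, JSON for the manifest.
write_run_bundle <- function(res, dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(obj, f) utils::write.table(
    obj, file.path(out_dir, f), sep = "\t", quote = FALSE, col.names = NA)
  fa <- file.path(out_dir, "dataset.fa")
  write_fasta(dataset, fa)
  if (!is.null(res$freq)) w(res$freq$counts, "haplogroup_counts.tsv")
  if (!is.null(res$fst)) {
    w(round(res$fst$fst, 6), "fst.tsv")
    w(round(res$fst$pvalues, 6), "fst_pvalues.tsv")
    w(round(res$fst$adjusted_pvalues, 6), "fst_pvalues_bh.tsv")
  }
  if (!is.null(res$msn))
    utils::write.table(res$msn$edges, file.path(out_dir, "msn_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$structure))
    utils::write.table(res$structure$table,
                       file.path(out_dir, "grouping_search.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- res$manifest
  manifest$input_checksum <- unname(tools::md5sum(fa))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
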
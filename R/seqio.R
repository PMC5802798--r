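# Input/output and sample-level filtering: FASTA in rCRS coordinates,
# tab-separated sample metadata, sex resolution.

RCRS_LENGTH <- 16569L

#' Assemble a sequence dataset
#'
#' The universal container for downstream analyses: aligned haplotype
#' sequences over a common rCRS region plus per-sample metadata.
#'
#' @param samples data.frame with columns `sample_id`, `population`,
#'   `epoch`, `sequence`. Sequences must be uppercase strings over
#'   `A,C,G,T,N,-`, all of length `region_length(region)`.
#' @param region The [mt_region()] the sequences are aligned to.
#' @param metadata Optional data.frame keyed by `sample_id` with columns
#'   `anthropological_sex`, `genetic_sex`, `haplogroup`, `haplogroup_score`,
#'   `mean_coverage`. Missing samples are filled with unknowns.
#' @return An object of class `mt_dataset`.
#' @export
mt_dataset <- function(samples, region, metadata = NULL) {
  stopifnot(is.data.frame(samples), inherits(region, "mt_region"))
  need <- c("sample_id", "population", "epoch", "sequence")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stopf("samples is missing columns: %s",
                          paste(miss, collapse = ", "))
  samples <- as.data.frame(samples)[need]
  samples$sample_id <- as.character(samples$sample_id)
  samples$population <- as.character(samples$population)
  samples$epoch <- as.character(samples$epoch)
  samples$sequence <- toupper(as.character(samples$sequence))
  if (anyDuplicated(samples$sample_id))
    stopf("duplicate sample ids: %s",
          paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
                collapse = ", "))
  L <- region_length(region)
  bad <- nchar(samples$sequence) != L
  if (any(bad))
    stopf("sequence length mismatch for %s (expected %d)",
          paste(samples$sample_id[bad], collapse = ", "), L)
  if (any(grepl("[^ACGTN-]", samples$sequence)))
    stopf("sequences may only contain A,C,G,T,N,-")
  meta <- empty_metadata(samples$sample_id)
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    metadata$sample_id <- as.character(metadata$sample_id)
    i <- match(meta$sample_id, metadata$sample_id)
    for (col in setdiff(names(meta), "sample_id")) {
      if (col %in% names(metadata)) {
        v <- metadata[[col]][i]
        meta[[col]][!is.na(i)] <- v[!is.na(i)]
      }
    }
  }
  structure(list(samples = samples, region = region, metadata = meta,
                 populations = unique(samples$population)),
            class = "mt_dataset")
}

empty_metadata <- function(ids) {
  n <- length(ids)
  data.frame(sample_id = ids,
             anthropological_sex = rep("unknown", n),
             genetic_sex = rep("unknown", n),
             haplogroup = rep(NA_character_, n),
             haplogroup_score = rep(NA_real_, n),
             mean_coverage = rep(NA_real_, n),
             stringsAsFactors = FALSE)
}

#' @export
print.mt_dataset <- function(x, ...) {
  cat(sprintf("<mt_dataset> %d samples, %d populations, region %s (%d nt)\n",
              nrow(x$samples), length(x$populations),
              if (nzchar(x$region$label)) x$region$label else
                paste(x$region$start, x$region$end, sep = "-"),
              region_length(x$region)))
  tab <- table(x$samples$population)
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples in a dataset
#' @param x An `mt_dataset`.
#' @export
n_samples <- function(x) nrow(x$samples)

#' Restrict a dataset to one or more populations
#'
#' @param dataset An `mt_dataset`.
#' @param populations Population id(s) to keep.
#' @return An `mt_dataset` with only those populations' samples.
#' @export
subset_population <- function(dataset, populations) {
  stopifnot(inherits(dataset, "mt_dataset"))
  miss <- setdiff(populations, dataset$populations)
  if (length(miss)) stopf("unknown population(s): %s",
                          paste(miss, collapse = ", "))
  subset_dataset(dataset, dataset$samples$population %in% populations)
}

#' Read aligned mtDNA sequences from FASTA
#'
#' Headers may follow the `sampleid|population` convention; otherwise the
#' population is taken from `metadata` (matched on sample id) or set to
#' `"unknown"`. Full-length rCRS records (16,569 nt) are sliced to `region`;
#' any other length must equal the region length exactly.
#'
#' @param path FASTA file.
#' @param region Target [mt_region()].
#' @param metadata Optional metadata data.frame (see [mt_dataset()]); may
#'   also carry `population` and `epoch` columns.
#' @param epoch Default epoch label for samples without one.
#' @return An `mt_dataset`. An empty file yields a zero-row dataset.
#' @export
read_fasta <- function(path, region, metadata = NULL, epoch = "IA") {
  stopifnot(inherits(region, "mt_region"))
  txt <- readLines(path, warn = FALSE)
  txt <- txt[nzchar(txt)]
  if (!length(txt)) {
    return(mt_dataset(data.frame(sample_id = character(),
                                 population = character(),
                                 epoch = character(),
                                 sequence = character()),
                      region, metadata))
  }
  hdr <- grep("^>", txt)
  if (!length(hdr)) stopf("%s does not look like FASTA", path)
  ends <- c(hdr[-1L] - 1L, length(txt))
  ids <- sub("^>", "", txt[hdr])
  seqs <- vapply(seq_along(hdr), function(i) {
    if (hdr[i] + 1L > ends[i]) "" else
      paste(txt[(hdr[i] + 1L):ends[i]], collapse = "")
  }, character(1))
  seqs <- toupper(gsub("[[:space:]]", "", seqs))
  has_pop <- grepl("|", ids, fixed = TRUE)
  sid <- ifelse(has_pop, sub("\\|.*$", "", ids), ids)
  pop <- ifelse(has_pop, sub("^[^|]*\\|", "", ids), NA_character_)
  L <- region_length(region)
  full <- nchar(seqs) == RCRS_LENGTH & L != RCRS_LENGTH
  if (any(full)) {
    idx <- region_positions(region)
    seqs[full] <- vapply(seqs[full], function(s)
      paste(seq_chars(s)[idx], collapse = ""), character(1))
  }
  bad <- nchar(seqs) != L
  if (any(bad))
    stopf("FASTA record '%s' has length %d; expected %d (region) or %d (rCRS)",
          ids[which(bad)[1L]], nchar(seqs[which(bad)[1L]]), L, RCRS_LENGTH)
  ep <- rep(epoch, length(sid))
  if (!is.null(metadata)) {
    m <- as.data.frame(metadata)
    i <- match(sid, as.character(m$sample_id))
    if ("population" %in% names(m)) {
      v <- as.character(m$population)[i]
      pop[is.na(pop) & !is.na(v)] <- v[is.na(pop) & !is.na(v)]
    }
    if ("epoch" %in% names(m)) {
      v <- as.character(m$epoch)[i]
      ep[!is.na(v)] <- v[!is.na(v)]
    }
  }
  pop[is.na(pop)] <- "unknown"
  mt_dataset(data.frame(sample_id = sid, population = pop, epoch = ep,
                        sequence = seqs, stringsAsFactors = FALSE),
             region, metadata)
}

#' Write a dataset to FASTA
#'
#' Headers use the `sampleid|population` convention so that
#' [read_fasta()] round-trips the dataset.
#'
#' @param dataset An `mt_dataset`.
#' @param path Output file.
#' @export
write_fasta <- function(dataset, path) {
  stopifnot(inherits(dataset, "mt_dataset"))
  s <- dataset$samples
  writeLines(as.vector(rbind(paste0(">", s$sample_id, "|", s$population),
                             s$sequence)), path)
  invisible(path)
}

#' Extract a sub-region of a dataset
#'
#' Slices every sequence to `region`, which must lie within the dataset's
#' current region. Multi-interval regions yield the concatenated haplotype
#' in ascending coordinate order (the joint HVS-I + HVS-II convention).
#'
#' @param dataset An `mt_dataset`.
#' @param region Target [mt_region()].
#' @return An `mt_dataset` over the new region.
#' @export
slice_region <- function(dataset, region) {
  stopifnot(inherits(dataset, "mt_dataset"), inherits(region, "mt_region"))
  cur <- region_positions(dataset$region)
  req <- region_positions(region)
  if (!all(req %in% cur))
    stopf("requested region (%s) is not contained in the dataset region",
          paste(sprintf("%d-%d", region$start, region$end), collapse = ","))
  idx <- match(req, cur)
  s <- dataset$samples
  s$sequence <- vapply(s$sequence, function(x)
    paste(seq_chars(x)[idx], collapse = ""), character(1), USE.NAMES = FALSE)
  mt_dataset(s, region, dataset$metadata)
}

#' Parse a Table-1 style sex token
#'
#' Tokens have the form `"(A)/G"` where `A` is the anthropological and `G`
#' the genetic assignment, each one of `F`, `M`, or `-` (unknown).
#'
#' @param token Character vector of tokens.
#' @return data.frame with columns `anthropological_sex`, `genetic_sex`
#'   coded `F`/`M`/`unknown`.
#' @export
parse_sex_token <- function(token) {
  token <- gsub("[[:space:]]", "", as.character(token))
  m <- regmatches(token, regexec("^\\(([FM-])\\)/([FM-])$", token))
  dec <- function(x) if (length(x) == 0L) c("unknown", "unknown") else
    ifelse(x[2:3] == "-", "unknown", x[2:3])
  out <- t(vapply(m, dec, character(2)))
  data.frame(anthropological_sex = out[, 1L], genetic_sex = out[, 2L],
             stringsAsFactors = FALSE)
}

#' Read a sample assignment table
#'
#' Tab-separated with header columns `sample_id`, `haplogroup_confidence`,
#' `haplogroup`, `sex_assignment` (Table-1 dialect, e.g. `"(F)/M"`), and
#' optionally `mean_coverage`. `-` denotes a missing value.
#'
#' @param path TSV file.
#' @return Metadata data.frame as used by [mt_dataset()] and
#'   [filter_assignments()].
#' @export
read_sample_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("sample_id", "haplogroup_confidence", "haplogroup",
            "sex_assignment")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("sample table missing columns: %s",
                          paste(miss, collapse = ", "))
  sex <- parse_sex_token(d$sex_assignment)
  hg <- trimws(d$haplogroup)
  hg[hg %in% c("-", "")] <- NA_character_
  sc <- suppressWarnings(as.numeric(sub(",", ".", d$haplogroup_confidence)))
  cov <- if ("mean_coverage" %in% names(d))
    suppressWarnings(as.numeric(d$mean_coverage)) else NA_real_
  data.frame(sample_id = d$sample_id,
             anthropological_sex = sex$anthropological_sex,
             genetic_sex = sex$genetic_sex,
             haplogroup = hg,
             haplogroup_score = sc,
             mean_coverage = cov,
             stringsAsFactors = FALSE)
}

#' Write a sample assignment table
#'
#' Inverse of [read_sample_table()] (round-trips the parsed fields).
#'
#' @param metadata Metadata data.frame.
#' @param path Output TSV file.
#' @export
write_sample_table <- function(metadata, path) {
  enc <- function(x) ifelse(x == "unknown" | is.na(x), "-", x)
  d <- data.frame(
    sample_id = metadata$sample_id,
    haplogroup_confidence = ifelse(is.na(metadata$haplogroup_score), "-",
                                   format(metadata$haplogroup_score)),
    haplogroup = ifelse(is.na(metadata$haplogroup), "-", metadata$haplogroup),
    sex_assignment = sprintf("(%s)/%s",
                             enc(metadata$anthropological_sex),
                             enc(metadata$genetic_sex)),
    stringsAsFactors = FALSE)
  if (!is.null(metadata$mean_coverage))
    d$mean_coverage <- ifelse(is.na(metadata$mean_coverage), "-",
                              format(metadata$mean_coverage))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply sample-level quality filters
#'
#' Keeps samples that carry a haplogroup label, meet the score and coverage
#' thresholds, and are not on the exclusion list. A missing score or
#' coverage passes only when the corresponding threshold is 0 (the value
#' was then never required).
#'
#' @param metadata Metadata data.frame (see [read_sample_table()]).
#' @param min_score Minimum haplogroup assignment score (default 0.8).
#' @param min_coverage Minimum mean coverage (default 3).
#' @param exclusion_list Character vector of sample ids to drop regardless.
#' @return List with data.frames `kept` and `dropped`; `dropped` carries a
#'   `reason` column. `nrow(kept) + nrow(dropped) == nrow(metadata)`.
#' @export
filter_assignments <- function(metadata, min_score = 0.8, min_coverage = 3,
                               exclusion_list = character()) {
  stopifnot(min_score >= 0, min_coverage >= 0)
  m <- as.data.frame(metadata)
  reason <- rep(NA_character_, nrow(m))
  fail <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- why
  }
  fail(m$sample_id %in% exclusion_list, "on exclusion list")
  fail(is.na(m$haplogroup), "no haplogroup assignment")
  if (min_score > 0) {
    fail(is.na(m$haplogroup_score), "haplogroup score missing")
    fail(m$haplogroup_score < min_score,
         sprintf("haplogroup score below %g", min_score))
  }
  if (min_coverage > 0) {
    fail(is.na(m$mean_coverage), "mean coverage missing")
    fail(m$mean_coverage < min_coverage,
         sprintf("mean coverage below %g", min_coverage))
  }
  keep <- is.na(reason)
  dropped <- m[!keep, , drop = FALSE]
  dropped$reason <- reason[!keep]
  list(kept = m[keep, , drop = FALSE], dropped = dropped)
}

#' Consensus sex from anthropological and genetic assignments
#'
#' Genetic sex takes precedence when present; the anthropological
#' assignment is used otherwise. Disagreement between two non-missing
#' assignments sets the conflict flag (the genetic call wins).
#'
#' @param anthropological_sex,genetic_sex Character vectors over
#'   `F`/`M`/`unknown`.
#' @return data.frame with columns `sex` and `conflict` (logical).
#' @export
resolve_sex <- function(anthropological_sex, genetic_sex) {
  a <- as.character(anthropological_sex)
  g <- as.character(genetic_sex)
  ok <- c("F", "M", "unknown")
  if (!all(a %in% ok) || !all(g %in% ok))
    stopf("sex values must be one of F, M, unknown")
  sex <- ifelse(g != "unknown", g, a)
  conflict <- a != "unknown" & g != "unknown" & a != g
  data.frame(sex = sex, conflict = conflict, stringsAsFactors = FALSE)
}

#' Kowalewko haplogroup assignment table
#'
#' The published haplogroup-assignment table for the Kow-OVIA group (60
#' Iron Age individuals from the Kowalewko cemetery): per-sample haplogroup
#' label with assignment confidence and anthropological/genetic sex,
#' shipped as a plain-text TSV and parsed with [read_sample_table()].
#'
#' @return Metadata data.frame (one row per individual).
#' @examples
#' m <- kowalewko_assignments()
#' nrow(filter_assignments(m, 0, 0, c("PCA0018", "PCA0063"))$kept)  # 40
#' @export
kowalewko_assignments <- function() {
  read_sample_table(system.file("extdata", "kowalewko_haplogroups.tsv",
                                package = "mtstruct", mustWork = TRUE))
}
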
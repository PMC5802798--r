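# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Ordered epoch levels
#'
#' The chronological ordering used for epoch labels throughout the package:
#' hunter-gatherer (HG), Early Neolithic (EN), Middle Neolithic (MN), Late
#' Neolithic / Early Bronze Age (LN/EBA), Iron Age (IA), and present-day.
#'
#' @return Character vector of epoch levels in chronological order.
#' @export
mt_epochs <- function() c("HG", "EN", "MN", "LN/EBA", "IA", "present")

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL evaluates in the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == floor(x) && x >= 0

# Called (non-missing) positions of an aligned sequence: anything but N or -.
called_mask <- function(chars) chars != "N" & chars != "-"

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
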
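#' Define an rCRS region
#'
#' A region is one or more intervals of 1-based inclusive rCRS nucleotide
#' positions. Multi-interval regions (e.g. a joint HVS-II + HVS-I haplotype)
#' are stored in ascending coordinate order and behave as the concatenation
#' of their intervals.
#'
#' @param start,end Integer vectors of equal length; 1-based inclusive
#'   coordinates with `start >= 1` and `end >= start` per interval.
#' @param label Free-text label for the region.
#' @return An object of class `mt_region`.
#' @examples
#' mt_region(16064, 16400, "HVS-I")
#' mt_region(c(73, 16033), c(340, 16365), "HVS-II+HVS-I")
#' @export
mt_region <- function(start, end, label = "") {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != length(end) || length(start) == 0L)
    stopf("start and end must be non-empty vectors of equal length")
  if (any(is.na(start)) || any(is.na(end)))
    stopf("region coordinates must be non-missing")
  if (any(start < 1L)) stopf("region start must be >= 1 (1-based rCRS)")
  if (any(end < start)) stopf("region end must be >= start")
  o <- order(start)
  start <- start[o]; end <- end[o]
  if (length(start) > 1L && any(start[-1L] <= end[-length(end)]))
    stopf("region intervals must not overlap")
  structure(list(start = start, end = end, label = as.character(label)[1L]),
            class = "mt_region")
}

#' @export
print.mt_region <- function(x, ...) {
  iv <- paste(sprintf("%d-%d", x$start, x$end), collapse = ", ")
  cat(sprintf("<mt_region> %s [%s] length %d\n",
              if (nzchar(x$label)) x$label else "(unnamed)",
              iv, region_length(x)))
  invisible(x)
}

#' Total length of a region
#'
#' @param region An [mt_region()].
#' @return Integer: the summed interval lengths (`end - start + 1`).
#' @export
region_length <- function(region) {
  stopifnot(inherits(region, "mt_region"))
  sum(region$end - region$start + 1L)
}

# rCRS positions covered by a region, in ascending order.
region_positions <- function(region) {
  unlist(Map(seq.int, region$start, region$end), use.names = FALSE)
}

# TRUE if all positions of `inner` are covered by `outer`.
region_within <- function(inner, outer) {
  all(region_positions(inner) %in% region_positions(outer))
}
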
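#' Consensus site set across samples
#'
#' Merges the per-sample peak interval sets (union of overlapping intervals)
#' and keeps each merged interval only when it is overlapped by intervals from
#' strictly more than `min_fraction` of the samples -- the "found in over 50%
#' of samples" consensus rule. Merging joins intervals that overlap by at
#' least one base.
#'
#' @param site_sets list of per-sample interval sets; each element is either a
#'   `GRanges` or a data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param min_fraction support threshold in (0, 1]; retention requires support
#'   from `> min_fraction` of samples (strictly greater).
#' @return data.frame of merged consensus intervals (`chrom`, `start`, `end`,
#'   `site_id`, `n_support`), sorted by (chrom, start). Empty input yields an
#'   empty result with a warning.
#' @examples
#' sets <- rep(list(data.frame(chrom = "chr1", start = 100, end = 200)), 6)
#' consensus_sites(sets, min_fraction = 0.5)
#' @export
consensus_sites <- function(site_sets, min_fraction = 0.5) {
  stopifnot(is.list(site_sets), min_fraction > 0, min_fraction <= 1)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), site_id = character(),
                      n_support = integer(), stringsAsFactors = FALSE)
  grs <- lapply(site_sets, function(s) {
    if (inherits(s, "GRanges")) s else sites_to_granges(s)
  })
  grs <- grs[vapply(grs, length, 1L) > 0]
  if (length(grs) == 0) {
    warning("no intervals supplied; returning empty consensus set")
    return(empty)
  }
  n <- length(site_sets)
  pooled <- suppressWarnings(do.call(c, unname(grs)))
  merged <- GenomicRanges::reduce(pooled)
  support <- Reduce(`+`, lapply(grs, function(g) {
    as.integer(GenomicRanges::countOverlaps(merged, g) > 0)
  }))
  keep <- support > min_fraction * n
  if (!any(keep)) {
    warning("no interval passed the consensus threshold")
    return(empty)
  }
  out <- granges_to_sites(merged[keep])
  out$role <- NULL
  out$n_support <- support[keep]
  out <- out[order(out$chrom, out$start), ]
  out$site_id <- sprintf("consensus_%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "site_id", "n_support")]
}
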
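#' Operational trajectory classification of binding sites
#'
#' Assigns each signal site to one of the trajectory classes using explicit,
#' deterministic thresholds on the response FDR, the response amplitude and
#' the pre-stimulation baseline (the low-dimensional embedding is kept for
#' visualization only and never feeds classification):
#' \itemize{
#'   \item responsive (`fdr < alpha` and `amplitude > 0`): class `"A"` when
#'     the amplitude reaches the split quantile of responsive-site amplitudes
#'     (default upper quartile), `"C"` otherwise;
#'   \item non-responsive with baseline at least `baseline_floor`: `"B"`
#'     (ligand-independent constitutive binding);
#'   \item everything else: `"unassigned"`.
#' }
#' Amplitude is the replicate-averaged post-activation mean
#' (`t >= min_time`) minus the 0 min mean; baseline is the 0 min mean.
#'
#' @param x a `pftc_binding` (or `pftc_counts`).
#' @param fdr_table response table from [response_fdr_table()]; computed from
#'   `x` (0 vs `min_time` contrast) when `NULL`. Sites missing from the table
#'   are flagged `unassigned` with a warning.
#' @param alpha response FDR threshold (default 0.05).
#' @param amplitude_quantile quantile of responsive-site amplitudes splitting
#'   strong (`A`) from weak (`C`) responders (default 0.75).
#' @param baseline_floor minimum 0 min occupancy for class `B`, in
#'   normalized-read-count units (default 20).
#' @param min_time first post-activation time point (default 10 min).
#' @return data.frame of class `site_classification`: `site_id`, `class`,
#'   `response_fdr`, `amplitude`, `baseline`, `time_of_max`; attribute
#'   `amplitude_split` records the realized split value.
#' @export
classify_sites <- function(x, fdr_table = NULL, alpha = 0.05,
                           amplitude_quantile = 0.75, baseline_floor = 20,
                           min_time = 10) {
  if (is.null(fdr_table)) {
    fdr_table <- response_fdr_table(x, time_a = 0, time_b = min_time)
  }
  prof <- collapse_replicates(x)[x$sites$role == "signal", , drop = FALSE]
  tps <- as.numeric(colnames(prof))
  post <- tps >= min_time
  baseline <- prof[, which(tps == 0)]
  amplitude <- rowMeans(prof[, post, drop = FALSE]) - baseline
  time_of_max <- tps[apply(prof, 1, which.max)]
  fdr <- fdr_table$fdr[match(rownames(prof), fdr_table$site_id)]
  if (anyNA(fdr)) {
    warning(sum(is.na(fdr)), " site(s) missing from the FDR table; ",
            "left unassigned")
  }
  responsive <- !is.na(fdr) & fdr < alpha & amplitude > 0
  q <- stats::quantile(amplitude[responsive], probs = amplitude_quantile,
                       names = FALSE)
  cls <- rep("unassigned", nrow(prof))
  cls[responsive] <- ifelse(amplitude[responsive] >= q, "A", "C")
  cls[!responsive & !is.na(fdr) & baseline >= baseline_floor] <- "B"
  out <- data.frame(site_id = rownames(prof), class = cls,
                    response_fdr = fdr, amplitude = amplitude,
                    baseline = baseline, time_of_max = time_of_max,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "amplitude_split") <- q
  class(out) <- c("site_classification", class(out))
  out
}

#' Heatmap row ordering by time of maximal binding
#'
#' Groups sites into blocks by the time point of maximal replicate-averaged
#' occupancy (blocks in time order), ordered within blocks by descending mean
#' occupancy. The same ordering serves both views the two normalization
#' strategies produce: `"row-max"` (each profile scaled to peak at 1) and
#' `"absolute"` (internal-control-normalized occupancy).
#'
#' @param x a `pftc_binding` (or `pftc_counts`).
#' @param mode `"row-max"` or `"absolute"`.
#' @return list with `order` (site ids), `view` (the reordered sites x time
#'   matrix for the requested mode), `time_of_max` (named by site), `mode`.
#' @export
order_for_heatmap <- function(x, mode = c("row-max", "absolute")) {
  mode <- match.arg(mode)
  prof <- collapse_replicates(x)
  keep <- apply(prof, 1, max) > 0
  prof <- prof[keep, , drop = FALSE]
  tps <- as.numeric(colnames(prof))
  tom <- tps[apply(prof, 1, which.max)]
  ord <- order(match(tom, tps), -rowMeans(prof))
  ids <- rownames(prof)[ord]
  view <- if (mode == "row-max") {
    v <- normalize_rows_to_max(x)
    v[ids, , drop = FALSE]
  } else {
    prof[ids, , drop = FALSE]
  }
  list(order = ids, view = view,
       time_of_max = stats::setNames(tom, rownames(prof))[ids],
       mode = mode)
}

#' @export
print.site_classification <- function(x, ...) {
  tab <- table(factor(x$class, levels = c("A", "B", "C", "unassigned")))
  cat(sprintf(
    "<site_classification> %d sites: %s (amplitude split %.3g)\n",
    nrow(x), paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
    attr(x, "amplitude_split")))
  invisible(x)
}
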
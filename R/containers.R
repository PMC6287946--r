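#' Raw count container for a binding time course
#'
#' Bundles a sites-by-samples integer count matrix with its site table
#' (genomic intervals, 0-based half-open, each tagged `signal` or `control`)
#' and sample manifest, in the style of an edgeR `DGEList`.
#'
#' @param counts integer matrix, sites x samples; dimnames are set from
#'   `sites$site_id` and `manifest$sample_id`.
#' @param sites data.frame with columns `chrom`, `start`, `end`, `site_id`,
#'   `role` (`"signal"` or `"control"`); `end > start`, `site_id` unique.
#' @param manifest data.frame as from [sample_manifest()].
#' @return an object of class `pftc_counts`.
#' @export
count_matrix <- function(counts, sites, manifest) {
  counts <- as.matrix(counts)
  validate_sites(sites)
  validate_manifest(manifest)
  if (nrow(counts) != nrow(sites) || ncol(counts) != nrow(manifest)) {
    stop("counts dimensions (", nrow(counts), " x ", ncol(counts),
         ") do not match sites (", nrow(sites), ") and manifest (",
         nrow(manifest), ")")
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative")
  }
  dimnames(counts) <- list(sites$site_id, manifest$sample_id)
  structure(list(counts = counts, sites = sites, manifest = manifest),
            class = "pftc_counts")
}

validate_sites <- function(sites) {
  req <- c("chrom", "start", "end", "site_id", "role")
  if (!all(req %in% names(sites))) {
    stop("sites must have columns ", paste(req, collapse = ", "))
  }
  if (any(sites$end <= sites$start)) stop("site intervals require end > start")
  if (anyDuplicated(sites$site_id)) stop("site_id values must be unique")
  if (!all(sites$role %in% c("signal", "control"))) {
    stop("site role must be 'signal' or 'control'")
  }
  invisible(sites)
}

#' Normalized occupancy container
#'
#' Same shape as [count_matrix()] but holding normalized occupancy values
#' (non-negative reals on the normalized-read-count scale). Produced by
#' [apply_factors()].
#'
#' @param values numeric matrix, sites x samples.
#' @param sites,manifest as in [count_matrix()].
#' @param factors optional [derive_factors()] result recorded as provenance.
#' @return an object of class `pftc_binding`.
#' @export
binding_matrix <- function(values, sites, manifest, factors = NULL) {
  values <- as.matrix(values)
  validate_sites(sites)
  validate_manifest(manifest)
  if (nrow(values) != nrow(sites) || ncol(values) != nrow(manifest)) {
    stop("values dimensions do not match sites/manifest")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("normalized occupancy must be finite and non-negative")
  }
  dimnames(values) <- list(sites$site_id, manifest$sample_id)
  structure(list(values = values, sites = sites, manifest = manifest,
                 factors = factors),
            class = "pftc_binding")
}

#' Restrict a count container to control or signal sites
#'
#' @param x a `pftc_counts` or `pftc_binding`.
#' @param role `"control"` or `"signal"`.
#' @return object of the same class containing only the requested sites.
#' @export
subset_sites <- function(x, role = c("control", "signal")) {
  role <- match.arg(role)
  keep <- x$sites$role == role
  if (inherits(x, "pftc_binding")) {
    binding_matrix(x$values[keep, , drop = FALSE],
                   x$sites[keep, , drop = FALSE], x$manifest, x$factors)
  } else {
    count_matrix(x$counts[keep, , drop = FALSE],
                 x$sites[keep, , drop = FALSE], x$manifest)
  }
}

value_matrix <- function(x) {
  if (inherits(x, "pftc_binding")) x$values else x$counts
}

#' Replicate-averaged site-by-time-point matrix
#'
#' Averages replicates within each time point, giving one column per design
#' time point (the 10-dimensional site profiles used for embedding,
#' classification and heatmap ordering).
#'
#' @param x a `pftc_counts` or `pftc_binding`.
#' @return numeric matrix, sites x time points; column names are the times in
#'   minutes.
#' @export
collapse_replicates <- function(x) {
  vals <- value_matrix(x)
  tps <- sort(unique(x$manifest$time_min))
  out <- vapply(tps, function(tp) {
    rowMeans(vals[, x$manifest$time_min == tp, drop = FALSE])
  }, numeric(nrow(vals)))
  out <- matrix(out, nrow = nrow(vals),
                dimnames = list(rownames(vals), tps))
  out
}

site_values <- function(x, site_id) {
  vals <- value_matrix(x)
  if (!site_id %in% rownames(vals)) stop("unknown site id: ", site_id)
  data.frame(sample_id = x$manifest$sample_id,
             time_min = x$manifest$time_min,
             replicate = x$manifest$replicate,
             value = as.numeric(vals[site_id, ]),
             stringsAsFactors = FALSE)
}

#' @export
print.pftc_counts <- function(x, ...) {
  cat(sprintf("<pftc_counts> %d sites (%d signal, %d control) x %d samples\n",
              nrow(x$counts), sum(x$sites$role == "signal"),
              sum(x$sites$role == "control"), ncol(x$counts)))
  invisible(x)
}

#' @export
print.pftc_binding <- function(x, ...) {
  cat(sprintf(
    "<pftc_binding> %d sites x %d samples (normalized occupancy)\n",
    nrow(x$values), ncol(x$values)))
  if (!is.null(x$factors)) {
    cat(sprintf("  factors: %s, range [%.3g, %.3g]\n",
                attr(x$factors, "method"), min(x$factors), max(x$factors)))
  }
  invisible(x)
}
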
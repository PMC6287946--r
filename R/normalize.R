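#' Derive per-sample normalization factors from internal-control sites
#'
#' The internal-control factor's sites are constitutively bound, so after
#' correct normalization their counts should agree across samples; any
#' systematic per-sample scale reflects immunoprecipitation efficiency and
#' sequencing depth. For each sample i the default method fits a
#' zero-intercept least-squares regression of the per-site cross-sample mean
#' control profile on sample i's control counts; the slope
#' `f_i = sum(x_i * m) / sum(x_i^2)` is the factor, and normalized values are
#' `count * f_i`. A median-of-ratios alternative (`median(m_j / x_ij)`) is
#' available. Factors are re-centered to geometric mean 1 so normalized
#' occupancies stay on a read-count-like scale.
#'
#' @param x a `pftc_counts` (only its control sites are used).
#' @param method `"control-regression"` (default) or `"median-ratio"`.
#' @param log_counts fit the regression on `log1p` counts instead of raw
#'   counts (factors are then back-transformed from the log-scale offset).
#' @param min_control_sites minimum number of control sites required.
#' @return named numeric vector of per-sample factors (geometric mean 1), of
#'   class `pftc_factors`, with attributes `method` and `reference`.
#' @export
derive_factors <- function(x,
                           method = c("control-regression", "median-ratio"),
                           log_counts = FALSE,
                           min_control_sites = 10) {
  method <- match.arg(method)
  stopifnot(inherits(x, "pftc_counts"))
  ctrl <- x$counts[x$sites$role == "control", , drop = FALSE]
  if (ncol(ctrl) < 2) stop("need at least 2 samples to derive factors")
  if (nrow(ctrl) < min_control_sites) {
    stop("need at least ", min_control_sites, " control sites, got ",
         nrow(ctrl))
  }
  zero <- colSums(ctrl) == 0
  if (any(zero)) {
    stop("all-zero control counts in sample(s): ",
         paste(colnames(ctrl)[zero], collapse = ", "))
  }
  if (log_counts) {
    lc <- log1p(ctrl)
    ref <- rowMeans(lc)
    raw <- exp(vapply(seq_len(ncol(lc)), function(i) {
      mean(ref - lc[, i])
    }, numeric(1)))
  } else {
    ref <- rowMeans(ctrl)
    raw <- switch(method,
      `control-regression` = vapply(seq_len(ncol(ctrl)), function(i) {
        xi <- ctrl[, i]
        sum(xi * ref) / sum(xi^2)
      }, numeric(1)),
      `median-ratio` = vapply(seq_len(ncol(ctrl)), function(i) {
        xi <- ctrl[, i]
        pos <- xi > 0 & ref > 0
        stats::median(ref[pos] / xi[pos])
      }, numeric(1))
    )
  }
  if (any(!is.finite(raw)) || any(raw <= 0)) {
    stop("derived factors must be finite and positive")
  }
  f <- raw / exp(mean(log(raw)))
  names(f) <- colnames(ctrl)
  structure(f, method = method,
            reference = "cross-sample mean control profile",
            class = "pftc_factors")
}

#' Apply normalization factors to a count matrix
#'
#' Pure column scaling: `value(site, i) = count(site, i) * f_i`, nothing else.
#'
#' @param x a `pftc_counts`.
#' @param factors a [derive_factors()] result (or any named positive vector
#'   covering exactly the samples of `x`).
#' @return a `pftc_binding` of normalized occupancies.
#' @export
apply_factors <- function(x, factors) {
  stopifnot(inherits(x, "pftc_counts"))
  if (is.null(names(factors))) stop("factors must be named by sample_id")
  extra <- setdiff(names(factors), colnames(x$counts))
  miss <- setdiff(colnames(x$counts), names(factors))
  if (length(extra) || length(miss)) {
    stop("sample sets differ; missing factors: [",
         paste(miss, collapse = ", "), "]; unknown samples: [",
         paste(extra, collapse = ", "), "]")
  }
  f <- factors[colnames(x$counts)]
  binding_matrix(sweep(x$counts, 2, f, `*`), x$sites, x$manifest,
                 factors = factors)
}

#' Normalize each site profile to its maximal time point
#'
#' Replicates are first averaged to one column per time point; each row is
#' then divided by its maximum, so every site's profile peaks at exactly 1 --
#' the relative, "normalized to the time point with maximal binding" view
#' contrasted with the absolute internal-control normalization. Sites whose
#' averaged profile is all zero cannot be scaled and are excluded (reported
#' via the `"excluded"` attribute).
#'
#' @param x a `pftc_binding` (or `pftc_counts`).
#' @return numeric matrix, sites x time points, all values in `[0, 1]`, each
#'   row attaining 1; attribute `excluded` lists dropped all-zero site ids.
#' @export
normalize_rows_to_max <- function(x) {
  prof <- collapse_replicates(x)
  mx <- apply(prof, 1, max)
  drop <- mx <= 0
  if (any(drop)) {
    warning(sum(drop), " all-zero site profile(s) excluded from row-max view")
  }
  out <- prof[!drop, , drop = FALSE] / mx[!drop]
  attr(out, "excluded") <- rownames(prof)[drop]
  out
}

#' Normalize a numeric series to its maximum
#'
#' Elementwise division by the series maximum, mapping to `[0, 1]` -- used to
#' put digitized occupancy series from independent studies on a comparable
#' relative scale.
#'
#' @param series numeric vector with `max(series) > 0`.
#' @return `series / max(series)`.
#' @export
normalize_series_to_max <- function(series) {
  stopifnot(is.numeric(series), length(series) >= 1, all(is.finite(series)))
  m <- max(series)
  if (m <= 0) stop("series maximum must be positive")
  series / m
}

#' @export
print.pftc_factors <- function(x, ...) {
  cat(sprintf("<pftc_factors> %d samples, method '%s', range [%.4g, %.4g]\n",
              length(x), attr(x, "method"), min(x), max(x)))
  invisible(x)
}
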
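#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH adjustment (wraps [stats::p.adjust()]); rejects missing or
#' out-of-range inputs rather than propagating them.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`, no `NA`/`NaN`.
#' @return adjusted values in `[0, 1]`, monotone in rank.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || !is.numeric(p_values)) {
    stop("p-values must be numeric with no NA/NaN")
  }
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

welch_p <- function(a, b, var_equal = FALSE) {
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    # degenerate: no within-group scatter at all
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    return(list(statistic = if (p == 1) 0 else Inf, p_value = p,
                degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       degenerate = FALSE)
}

time_groups <- function(x, site_id) {
  sv <- site_values(x, site_id)
  split(sv$value, sv$time_min)
}

#' Pairwise time-point location tests for one site
#'
#' Two-sided Welch t-test (pooled-variance optional) of the site's normalized
#' occupancy for every unordered pair of time points, with BH adjustment
#' across the family of pairs (45 pairs under the default 10-point design).
#' The sustained model predicts that only contrasts against the
#' pre-stimulation 0 min point are significant.
#'
#' @param x a `pftc_binding` (or `pftc_counts`).
#' @param site_id site to test (needs >= 2 replicates per time point).
#' @param alpha significance level for the `significant` flag (on FDR).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return data.frame with columns `site_id`, `time_a`, `time_b`,
#'   `statistic`, `p_value`, `fdr`, `significant`, `degenerate`.
#' @export
pairwise_timepoint_tests <- function(x, site_id, alpha = 0.05,
                                     var_equal = FALSE) {
  grp <- time_groups(x, site_id)
  if (min(lengths(grp)) < 2) stop("need >= 2 replicates per time point")
  tps <- as.numeric(names(grp))
  pairs <- utils::combn(seq_along(tps), 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    welch_p(grp[[pairs[1, k]]], grp[[pairs[2, k]]], var_equal = var_equal)
  })
  out <- data.frame(
    site_id = site_id,
    time_a = tps[pairs[1, ]],
    time_b = tps[pairs[2, ]],
    statistic = vapply(res, `[[`, 1, "statistic"),
    p_value = vapply(res, `[[`, 1, "p_value"),
    degenerate = vapply(res, `[[`, TRUE, "degenerate"),
    stringsAsFactors = FALSE
  )
  out$fdr <- bh_fdr(out$p_value)
  out$significant <- out$fdr < alpha
  out[, c("site_id", "time_a", "time_b", "statistic", "p_value", "fdr",
          "significant", "degenerate")]
}

f_two_sided_p <- function(f, df1, df2) {
  min(1, 2 * min(stats::pf(f, df1, df2),
                 stats::pf(f, df1, df2, lower.tail = FALSE)))
}

#' Pairwise time-point variance tests for one site
#'
#' Two-sided variance-ratio F-test (`F = s2_a / s2_b`, df `(n_a - 1,
#' n_b - 1)`, `p = 2 * min(P(F <= f), P(F >= f))` capped at 1) for every
#' unordered pair of time points, BH-adjusted across pairs. Homogeneous
#' replicate variance across the course is the expectation under the
#' sustained model once binding is established.
#'
#' @inheritParams pairwise_timepoint_tests
#' @return data.frame with columns `site_id`, `time_a`, `time_b`,
#'   `statistic` (the F ratio), `p_value`, `fdr`, `significant`.
#' @export
pairwise_variance_tests <- function(x, site_id, alpha = 0.05) {
  grp <- time_groups(x, site_id)
  if (min(lengths(grp)) < 3) stop("need >= 3 replicates per time point")
  vars <- vapply(grp, stats::var, numeric(1))
  if (any(vars == 0)) {
    stop("zero replicate variance at time point(s): ",
         paste(names(grp)[vars == 0], collapse = ", "))
  }
  tps <- as.numeric(names(grp))
  n <- lengths(grp)
  pairs <- utils::combn(seq_along(tps), 2)
  fstat <- vars[pairs[1, ]] / vars[pairs[2, ]]
  pv <- vapply(seq_len(ncol(pairs)), function(k) {
    f_two_sided_p(fstat[k], n[pairs[1, k]] - 1, n[pairs[2, k]] - 1)
  }, numeric(1))
  out <- data.frame(site_id = site_id,
                    time_a = tps[pairs[1, ]], time_b = tps[pairs[2, ]],
                    statistic = unname(fstat), p_value = pv,
                    stringsAsFactors = FALSE)
  out$fdr <- bh_fdr(out$p_value)
  out$significant <- out$fdr < alpha
  out
}

#' Signal-versus-control replicate variance comparison
#'
#' Pools all samples at time points `>= min_time` (excluding the
#' pre-stimulation point), removes within-time-point means from each site's
#' values so only replicate scatter remains, and compares the residual
#' variance of a signal site against that of a control site with a two-sided
#' F-test on df `(N - T, N - T)` (`N` pooled samples, `T` pooled time
#' points). Because the internal-control site carries technical noise only,
#' excess signal-site variance is attributed to biology.
#'
#' @param x a `pftc_binding` (or `pftc_counts`).
#' @param signal_site_id,control_site_id the two sites to compare.
#' @param min_time smallest time point pooled (default 10 min).
#' @return list of class `variance_comparison`: the site ids, `df`, the
#'   residual variances and their CVs, the F ratio and two-sided `p_value`.
#' @export
signal_vs_control_variance <- function(x, signal_site_id, control_site_id,
                                       min_time = 10) {
  resid_of <- function(site_id) {
    sv <- site_values(x, site_id)
    sv <- sv[sv$time_min >= min_time, ]
    list(resid = sv$value - stats::ave(sv$value, sv$time_min),
         mean = mean(sv$value),
         n = nrow(sv), t = length(unique(sv$time_min)))
  }
  s <- resid_of(signal_site_id)
  ct <- resid_of(control_site_id)
  df <- s$n - s$t
  if (df < 1) stop("not enough pooled samples at time >= ", min_time)
  vs <- sum(s$resid^2) / df
  vc <- sum(ct$resid^2) / (ct$n - ct$t)
  if (vc == 0) stop("control site ", control_site_id,
                    " has zero residual variance")
  fstat <- vs / vc
  structure(list(
    signal_site_id = signal_site_id,
    control_site_id = control_site_id,
    df_signal = df, df_control = ct$n - ct$t,
    var_signal = vs, var_control = vc,
    cv_signal = sqrt(vs) / s$mean, cv_control = sqrt(vc) / ct$mean,
    F = fstat,
    p_value = f_two_sided_p(fstat, df, ct$n - ct$t),
    min_time = min_time
  ), class = "variance_comparison")
}

#' @export
print.variance_comparison <- function(x, ...) {
  cat(sprintf(
    "<variance_comparison> %s vs %s (t >= %g min)\n  F = %.4g on df (%d, %d), two-sided p = %.4g\n  residual CV: signal %.3f, control %.3f\n",
    x$signal_site_id, x$control_site_id, x$min_time, x$F,
    x$df_signal, x$df_control, x$p_value, x$cv_signal, x$cv_control))
  invisible(x)
}

#' Per-time-point profile of one site
#'
#' Replicate mean and standard deviation at each time point, plus the time of
#' maximal mean occupancy (earliest time point on ties).
#'
#' @param x a `pftc_binding` (or `pftc_counts`).
#' @param site_id site to profile.
#' @return data.frame (`time_min`, `mean`, `sd`) of class `pftc_profile` with
#'   attributes `site_id` and `time_of_max`.
#' @export
site_profile <- function(x, site_id) {
  sv <- site_values(x, site_id)
  tps <- sort(unique(sv$time_min))
  m <- vapply(tps, function(tp) mean(sv$value[sv$time_min == tp]), numeric(1))
  s <- vapply(tps, function(tp) stats::sd(sv$value[sv$time_min == tp]),
              numeric(1))
  out <- data.frame(time_min = tps, mean = m, sd = s)
  attr(out, "site_id") <- site_id
  attr(out, "time_of_max") <- tps[which.max(m)]
  class(out) <- c("pftc_profile", class(out))
  out
}

#' Average profile of a set of sites
#'
#' Mean over sites of the per-site time-point means (the class-average
#' binding profile); `sd` is the across-site standard deviation of those
#' means.
#'
#' @param x a `pftc_binding` (or `pftc_counts`).
#' @param site_ids non-empty character vector of site ids.
#' @return data.frame as in [site_profile()]; `site_id` attribute records the
#'   number of averaged sites.
#' @export
class_average_profile <- function(x, site_ids) {
  if (length(site_ids) == 0) stop("site set must be non-empty")
  miss <- setdiff(site_ids, rownames(value_matrix(x)))
  if (length(miss)) stop("unknown site id: ", paste(miss, collapse = ", "))
  prof <- collapse_replicates(x)[site_ids, , drop = FALSE]
  tps <- as.numeric(colnames(prof))
  out <- data.frame(time_min = tps,
                    mean = colMeans(prof),
                    sd = apply(prof, 2, stats::sd))
  rownames(out) <- NULL
  attr(out, "site_id") <- sprintf("average of %d sites", length(site_ids))
  attr(out, "time_of_max") <- tps[which.max(out$mean)]
  class(out) <- c("pftc_profile", class(out))
  out
}

#' Genome-wide response table for one time-point contrast
#'
#' Welch t-test of `time_b` versus `time_a` for every signal site, with BH
#' adjustment across sites. The 0 vs 10 min contrast FDR is the response
#' statistic used for trajectory classification.
#'
#' @param x a `pftc_binding` (or `pftc_counts`).
#' @param time_a,time_b the contrasted time points (defaults 0 and 10 min).
#' @return data.frame (`site_id`, `statistic`, `p_value`, `fdr`).
#' @export
response_fdr_table <- function(x, time_a = 0, time_b = 10) {
  man <- x$manifest
  if (!all(c(time_a, time_b) %in% man$time_min)) {
    stop("contrast time points must be design time points")
  }
  vals <- value_matrix(x)[x$sites$role == "signal", , drop = FALSE]
  ia <- man$time_min == time_a
  ib <- man$time_min == time_b
  res <- apply(vals, 1, function(v) {
    w <- welch_p(v[ia], v[ib])
    c(w$statistic, w$p_value)
  })
  out <- data.frame(site_id = rownames(vals),
                    statistic = res[1, ], p_value = res[2, ],
                    stringsAsFactors = FALSE)
  out$fdr <- bh_fdr(out$p_value)
  rownames(out) <- NULL
  out
}

#' Variance attribution on a matched synthetic fixture
#'
#' Convenience wrapper reproducing the signal-versus-control variance
#' analysis end to end on simulated data: generates the default design with
#' the strong responsive class rescaled so its plateau matches the
#' control-site occupancy scale (`target_occupancy`, default ~500 counts),
#' normalizes with control-derived factors, picks the highest-amplitude
#' class-A site and the control site with the closest post-stimulation mean,
#' and runs [signal_vs_control_variance()] over time points `>= min_time`.
#'
#' @param seed generator seed.
#' @param target_occupancy plateau of the strong responsive class, matched to
#'   the control median (normalized-read-count units).
#' @param min_time first pooled time point (default 10 min).
#' @return the [signal_vs_control_variance()] result.
#' @export
variance_attribution <- function(seed = 1, target_occupancy = 500,
                                 min_time = 10) {
  dyn <- default_dynamics()
  k <- target_occupancy / (dyn$A$baseline + dyn$A$amplitude)
  dyn$A <- dynamics_spec("A", baseline = dyn$A$baseline * k,
                         amplitude = dyn$A$amplitude * k,
                         activation_tau_min = dyn$A$activation_tau_min)
  ds <- simulate_timecourse(study_design(seed = seed), dynamics = dyn,
                            control_meanlog = log(target_occupancy))
  b <- apply_factors(ds, derive_factors(ds))
  prof <- collapse_replicates(b)
  post <- as.numeric(colnames(prof)) >= min_time
  post_mean <- rowMeans(prof[, post, drop = FALSE])
  amp <- post_mean - prof[, 1]
  a_ids <- ds$truth$sites$site_id[ds$truth$sites$class_label == "A"]
  sig_id <- a_ids[which.max(amp[a_ids])]
  ctl_ids <- ds$sites$site_id[ds$sites$role == "control"]
  ctl_id <- ctl_ids[which.min(abs(post_mean[ctl_ids] - post_mean[sig_id]))]
  signal_vs_control_variance(b, sig_id, ctl_id, min_time = min_time)
}
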
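# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

default_fixture <- function(seed = 42) {
  key <- paste0("fx_", seed)
  if (is.null(.fixture_cache[[key]])) {
    ds <- simulate_timecourse(study_design(seed = seed))
    b <- apply_factors(ds, derive_factors(ds))
    .fixture_cache[[key]] <- list(dataset = ds, binding = b)
  }
  .fixture_cache[[key]]
}

truth_classes <- function(fx) {
  stats::setNames(fx$dataset$truth$sites$class_label,
                  fx$dataset$truth$sites$site_id)
}

# truth label -> expected classifier call
map_truth_class <- function(cls) ifelse(cls == "null", "unassigned", cls)

top_class_a_site <- function(fx) {
  prof <- collapse_replicates(fx$binding)
  amp <- rowMeans(prof[, -1]) - prof[, 1]
  a_ids <- with(fx$dataset$truth$sites, site_id[class_label == "A"])
  a_ids[which.max(amp[a_ids])]
}

# independent step-up BH implementation (definition, not p.adjust)
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj_sorted <- p[o] * n / seq_len(n)
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  pmin(adj_sorted, 1)[order(o)]
}

# Monte-Carlo null oracle for the two-sided variance-ratio test: draw the
# null distribution of the ratio directly (normal replicate groups of the
# observed sizes) and estimate 2 * min(lower tail, upper tail).
mc_variance_p <- function(f_obs, n1, n2, n_draws = 1e5, seed = 1) {
  set.seed(seed)
  v1 <- apply(matrix(stats::rnorm(n1 * n_draws), n1), 2, stats::var)
  v2 <- apply(matrix(stats::rnorm(n2 * n_draws), n2), 2, stats::var)
  f_null <- v1 / v2
  min(1, 2 * min(mean(f_null <= f_obs), mean(f_null >= f_obs)))
}

# toy binding matrix: explicit per-site time profiles, one replicate
toy_binding <- function(profiles, time_points = NULL, n_replicates = 1) {
  n_tp <- ncol(profiles)
  if (is.null(time_points)) time_points <- seq(0, by = 10,
                                               length.out = n_tp)
  man <- expand.grid(replicate = seq_len(n_replicates),
                     time_min = time_points)
  man <- data.frame(sample_id = sprintf("t%02d_r%d", man$time_min,
                                        man$replicate),
                    time_min = man$time_min, replicate = man$replicate)
  vals <- profiles[, rep(seq_len(n_tp), each = n_replicates), drop = FALSE]
  ids <- if (is.null(rownames(profiles))) {
    sprintf("site_%02d", seq_len(nrow(profiles)))
  } else rownames(profiles)
  sites <- data.frame(chrom = "chr1",
                      start = seq_len(nrow(profiles)) * 1000L,
                      end = seq_len(nrow(profiles)) * 1000L + 400L,
                      site_id = ids, role = "signal")
  binding_matrix(vals, sites, man)
}
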
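test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  set.seed(31)
  for (n in c(1, 2, 10, 101)) {
    p <- runif(n)^2
    expect_equal(bh_fdr(p), bh_brute(p))
  }
  # ordering is preserved and fdr never drops below p
  p <- runif(50)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))
  expect_error(bh_fdr(c(0.1, NaN)), "NA")
  expect_error(bh_fdr(c(0.1, 1.3)), "0, 1")
})

test_that("pairwise location tests behave on toy groups", {
  # identical replicate values at two time points: degenerate, p = 1
  b <- toy_binding(rbind(s = c(7, 7)), n_replicates = 4)
  tt <- pairwise_timepoint_tests(b, "s")
  expect_equal(tt$p_value, 1)
  expect_true(tt$degenerate)
  # zero variance with unequal means: degenerate, p = 0
  b2 <- toy_binding(rbind(s = c(3, 9)), n_replicates = 4)
  tt2 <- pairwise_timepoint_tests(b2, "s")
  expect_equal(tt2$p_value, 0)
  expect_true(tt2$degenerate)
  # flat zeros vs a strong induced group
  g0 <- rep(0, 6)
  g1 <- c(40.2, 39.1, 40.8, 39.5, 40.1, 40.4)
  vals <- rbind(s = c(g0, g1))
  man <- data.frame(sample_id = sprintf("s%d", 1:12),
                    time_min = rep(c(0, 10), each = 6),
                    replicate = rep(1:6, 2))
  sites <- data.frame(chrom = "chr1", start = 1000L, end = 1400L,
                      site_id = "s", role = "signal")
  b3 <- binding_matrix(vals, sites, man)
  tt3 <- pairwise_timepoint_tests(b3, "s")
  expect_lt(tt3$p_value, 1e-6)
  expect_equal(tt3$p_value, t.test(g0, g1)$p.value)
})

test_that("a strong responsive site is significant only against 0 min", {
  fx <- default_fixture(seed = 1)
  site <- top_class_a_site(fx)
  tt <- pairwise_timepoint_tests(fx$binding, site)
  expect_equal(nrow(tt), 45)
  zero <- tt$time_a == 0
  expect_true(all(tt$fdr[zero] < 0.05))
  expect_false(any(tt$fdr[!zero] < 0.05))
})

test_that("variance-ratio p-values match theory and a Monte-Carlo oracle", {
  y <- c(1, 2, 3, 4, 5, 6)
  g1 <- 3 * y / sqrt(var(y))          # sample variance exactly 9
  g2 <- y / sqrt(var(y)) + 10         # sample variance exactly 1
  man <- data.frame(sample_id = sprintf("s%d", 1:12),
                    time_min = rep(c(0, 10), each = 6),
                    replicate = rep(1:6, 2))
  sites <- data.frame(chrom = "chr1", start = 1000L, end = 1400L,
                      site_id = "s", role = "signal")
  b <- binding_matrix(rbind(s = c(g1, g2)), sites, man)
  vt <- pairwise_variance_tests(b, "s")
  expect_equal(vt$statistic, 9)
  p_theory <- 2 * min(pf(9, 5, 5), pf(9, 5, 5, lower.tail = FALSE))
  expect_equal(vt$p_value, p_theory)
  p_mc <- mc_variance_p(9, 6, 6, n_draws = 1e5, seed = 8)
  mc_se <- sqrt(p_theory * (1 - p_theory) / 1e5)
  expect_lt(abs(vt$p_value - p_mc), 3 * max(mc_se, 2e-4))
  # equal variances give F = 1 and p = 1 at equal df
  b2 <- binding_matrix(rbind(s = c(y, y + 50)), sites, man)
  vt2 <- pairwise_variance_tests(b2, "s")
  expect_equal(vt2$statistic, 1)
  expect_equal(vt2$p_value, 1)
})

test_that("a responsive site shows no variance heterogeneity across time", {
  fx <- default_fixture(seed = 1)
  site <- top_class_a_site(fx)
  vt <- pairwise_variance_tests(fx$binding, site)
  expect_equal(nrow(vt), 45)
  expect_false(any(vt$fdr < 0.05))
  # zero replicate variance is a hard error naming the time point
  b <- toy_binding(rbind(s = c(5, 5, 7)), n_replicates = 3)
  expect_error(pairwise_variance_tests(b, "s"), "0, 10")
})

test_that("signal-vs-control variance comparison isolates replicate scatter", {
  fx <- default_fixture(seed = 1)
  # identical sites: F = 1, p = 1
  ctl_id <- fx$dataset$sites$site_id[fx$dataset$sites$role == "control"][1]
  vals <- fx$binding$values
  vals2 <- rbind(vals, twin = vals[ctl_id, ])
  sites2 <- rbind(fx$binding$sites,
                  data.frame(chrom = "chr3", start = 1000L, end = 1400L,
                             site_id = "twin", role = "signal"))
  b2 <- binding_matrix(vals2, sites2, fx$binding$manifest)
  same <- signal_vs_control_variance(b2, "twin", ctl_id)
  expect_equal(same$F, 1)
  expect_equal(same$p_value, 1)
  # df bookkeeping: 9 pooled time points x 6 replicates
  expect_equal(same$df_signal, 54 - 9)
  expect_equal(same$df_control, 45)
  # a biologically noisy responsive site carries far more residual variance
  site <- top_class_a_site(fx)
  vc <- signal_vs_control_variance(fx$binding, site, ctl_id)
  expect_gt(vc$F, 1)
  expect_lt(vc$p_value, 1e-4)
  # constant control residuals are rejected
  flat <- b2
  flat$values["twin", ] <- 100
  expect_error(signal_vs_control_variance(flat, site, "twin"),
               "zero residual variance")
})

test_that("profiles report per-time summaries and time of max", {
  b <- toy_binding(rbind(flat = c(4, 4, 4), up = c(1, 2, 9)),
                   time_points = c(0, 45, 90), n_replicates = 2)
  pf_flat <- site_profile(b, "flat")
  expect_equal(attr(pf_flat, "time_of_max"), 0)  # earliest on ties
  expect_equal(pf_flat$mean, rep(4, 3))
  pf_up <- site_profile(b, "up")
  expect_equal(attr(pf_up, "time_of_max"), 90)
  # class average is the elementwise mean of the site profiles
  avg <- class_average_profile(b, c("flat", "up"))
  expect_equal(avg$mean, (pf_flat$mean + pf_up$mean) / 2)
  expect_error(site_profile(b, "nope"), "unknown site")
  expect_error(class_average_profile(b, character(0)), "non-empty")
})
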
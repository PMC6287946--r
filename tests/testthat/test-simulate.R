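test_that("the default design yields the full sample grid", {
  man <- sample_manifest(study_design())
  expect_equal(nrow(man), 60)
  expect_equal(sort(unique(man$time_min)), seq(0, 90, by = 10))
  expect_equal(max(man$replicate), 6)
  expect_false(anyDuplicated(man$sample_id) > 0)
})

test_that("generation is deterministic given the seed", {
  d1 <- simulate_timecourse(study_design(seed = 5,
    n_sites_per_class = c(A = 20, B = 20), n_control_sites = 50))
  d2 <- simulate_timecourse(study_design(seed = 5,
    n_sites_per_class = c(A = 20, B = 20), n_control_sites = 50))
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$truth$effects, d2$truth$effects)
})

test_that("noiseless mode reproduces the mean structure exactly", {
  dyn <- default_dynamics()
  dyn$A <- dynamics_spec("A", baseline = 0, amplitude = 40)
  n_samp <- 60
  eff <- rep(c(1, 2, 0.5, 1, 4, 1), 10)
  ds <- simulate_timecourse(
    study_design(seed = 3, n_sites_per_class = c(A = 10, B = 10),
                 n_control_sites = 20),
    dynamics = dyn, noise = noise_model(0, 0),
    efficiency = eff, depth = rep(1, n_samp), site_strength_sdlog = 0,
    control_meanlog = log(512), control_sdlog = 0)
  # counts are the rounded expected occupancies
  tp_idx <- match(ds$manifest$time_min, as.numeric(colnames(ds$truth$expected)))
  expected <- round(ds$truth$expected[, tp_idx] %*% diag(eff))
  expect_equal(unname(ds$counts), unname(expected))
  # class-A sites with baseline 0 have zero counts before stimulation
  a_ids <- ds$truth$sites$site_id[ds$truth$sites$class_label == "A"]
  expect_true(all(ds$counts[a_ids, ds$manifest$time_min == 0] == 0))
  # control columns are proportional with the effect-size ratio
  ctl <- ds$counts[ds$sites$role == "control", ]
  expect_equal(unname(ctl[, 2] / ctl[, 1]),
               rep(eff[2] / eff[1], nrow(ctl)))
})

test_that("negative-binomial noise has the stated moments", {
  set.seed(101)
  draws <- pftc:::rnbinom_disp(rep(100, 10000), dispersion = 0.05)
  target_var <- 100 + 0.05 * 100^2
  se_mean <- sqrt(target_var / 10000)
  expect_lt(abs(mean(draws) - 100), 3 * se_mean)
  expect_lt(abs(var(draws) - target_var) / target_var, 0.15)
})

test_that("invalid designs are rejected", {
  expect_error(study_design(n_replicates = 0), "positive")
  expect_error(study_design(n_sites_per_class = c(A = -5)), "positive")
  expect_error(study_design(time_points_min = c(10, 10, 20)))
})
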
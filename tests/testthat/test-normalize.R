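control_counts_object <- function(mat) {
  n_samp <- ncol(mat)
  man <- data.frame(sample_id = sprintf("t%02d_r1", seq(0, by = 10,
                                                        length.out = n_samp)),
                    time_min = seq(0, by = 10, length.out = n_samp),
                    replicate = 1L)
  sites <- data.frame(chrom = "chr2", start = seq_len(nrow(mat)) * 1000L,
                      end = seq_len(nrow(mat)) * 1000L + 400L,
                      site_id = sprintf("control_%02d", seq_len(nrow(mat))),
                      role = "control")
  count_matrix(mat, sites, man)
}

test_that("identical samples get unit factors", {
  x <- control_counts_object(matrix(rep(c(10, 50, 200), 4), ncol = 4))
  f <- derive_factors(x, min_control_sites = 3)
  expect_equal(unname(as.numeric(f)), rep(1, 4))
})

test_that("a doubled sample gets half the factor and normalizes back", {
  base <- c(12, 80, 300, 45)
  x <- control_counts_object(cbind(base, 2 * base))
  f <- derive_factors(x, min_control_sites = 4)
  expect_equal(as.numeric(f[2] / f[1]), 0.5)
  b <- apply_factors(x, f)
  expect_equal(b$values[, 1], b$values[, 2])
})

test_that("noiseless generation recovers the exact confounder", {
  # powers of two and integer control strengths keep rounding exact
  eff <- rep(c(0.5, 1, 2, 1, 4, 1), 10)
  dep <- rep(c(1, 2, 1, 1, 0.5, 1), 10)
  ds <- simulate_timecourse(
    study_design(seed = 4, n_sites_per_class = c(B = 5),
                 n_control_sites = 50),
    noise = noise_model(0, 0), efficiency = eff, depth = dep,
    site_strength_sdlog = 0, control_meanlog = log(512), control_sdlog = 0)
  f <- derive_factors(ds)
  target <- (1 / (eff * dep))
  target <- target / exp(mean(log(target)))
  expect_equal(unname(as.numeric(f)), target, tolerance = 1e-9)
})

test_that("factors recover simulated confounders at default noise", {
  fx <- default_fixture()
  eff <- fx$dataset$truth$effects
  f <- derive_factors(fx$dataset)
  r <- cor(log(as.numeric(f)), -log(eff$efficiency * eff$depth_factor))
  expect_gt(r, 0.99)
  # median-of-ratios agrees with the regression factors within 5%
  f2 <- derive_factors(fx$dataset, method = "median-ratio")
  expect_lt(max(abs(as.numeric(f2) / as.numeric(f) - 1)), 0.05)
})

test_that("normalization equalizes control columns that raw counts do not", {
  fx <- default_fixture()
  raw_means <- colMeans(fx$dataset$counts[fx$dataset$sites$role == "control", ])
  norm_means <- colMeans(subset_sites(fx$binding, "control")$values)
  cv <- function(v) sd(v) / mean(v)
  expect_lt(cv(norm_means), 0.05)
  expect_gt(cv(raw_means), 2 * cv(norm_means))
})

test_that("regression factors match a brute-force least-squares oracle", {
  set.seed(21)
  mat <- matrix(rpois(25, lambda = 150), 5, 5)
  x <- control_counts_object(mat)
  f <- derive_factors(x, min_control_sites = 5)
  ref <- rowMeans(mat)
  oracle <- vapply(seq_len(5), function(i) {
    obj <- function(s) sum((ref - s * mat[, i])^2)
    stats::optimize(obj, c(1e-3, 10), tol = 1e-10)$minimum
  }, numeric(1))
  oracle <- oracle / exp(mean(log(oracle)))
  expect_equal(unname(as.numeric(f)), oracle, tolerance = 1e-6)
})

test_that("apply_factors is a pure column scaling", {
  fx <- default_fixture()
  f <- derive_factors(fx$dataset)
  ones <- stats::setNames(rep(1, length(f)), names(f))
  expect_equal(apply_factors(fx$dataset, ones)$values + 0,
               fx$dataset$counts + 0)
  f2 <- f
  f2[3] <- 2 * f2[3]
  b1 <- apply_factors(fx$dataset, f)
  b2 <- apply_factors(fx$dataset, f2)
  expect_equal(b2$values[, 3], 2 * b1$values[, 3])
  expect_equal(b2$values[, -3], b1$values[, -3])
  bad <- stats::setNames(rep(1, 3), c("a", "b", "c"))
  expect_error(apply_factors(fx$dataset, bad), "sample sets differ")
})

test_that("rescaling one sample only changes the global gauge", {
  # proportional columns: the regression reference keeps its shape exactly
  m <- c(50, 120, 300, 80, 10, 220, 90, 150, 40, 500)
  base <- outer(m, c(1, 2, 0.5, 4))
  x1 <- control_counts_object(base)
  scaled <- base
  scaled[, 2] <- scaled[, 2] * 4
  x2 <- control_counts_object(scaled)
  b1 <- apply_factors(x1, derive_factors(x1))$values
  b2 <- apply_factors(x2, derive_factors(x2))$values
  # identical up to one global constant (the geometric-mean gauge)
  ratio <- b2 / b1
  expect_lt(diff(range(ratio)), 1e-10 * mean(ratio))
})

test_that("degenerate control inputs are rejected with context", {
  mat <- matrix(c(5, 10, 0, 0), 2, 2)
  x <- control_counts_object(mat)
  expect_error(derive_factors(x, min_control_sites = 2), "t10_r1")
  expect_error(derive_factors(x, min_control_sites = 10), "control sites")
})

test_that("row-max normalization maps profiles onto [0, 1]", {
  b <- toy_binding(rbind(s1 = c(2, 4, 8), s2 = c(5, 5, 5), s3 = c(1, 2, 9)))
  out <- normalize_rows_to_max(b)
  expect_equal(unname(out["s1", ]), c(0.25, 0.5, 1.0))
  expect_equal(unname(out["s2", ]), c(1, 1, 1))
  expect_equal(unname(out["s3", 3]), 1)
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(unname(apply(out, 1, max)), rep(1, 3))
})

test_that("row-max normalization is idempotent and drops zero rows", {
  fx <- default_fixture()
  once <- normalize_rows_to_max(fx$binding)
  twice <- normalize_rows_to_max(
    toy_binding(once, time_points = as.numeric(colnames(once))))
  expect_equal(once, twice, ignore_attr = TRUE)
  expect_equal(unname(apply(once, 1, max)), rep(1, nrow(once)))
  b0 <- toy_binding(rbind(s1 = c(1, 2, 3), s2 = c(0, 0, 0)))
  expect_warning(out <- normalize_rows_to_max(b0), "excluded")
  expect_equal(attr(out, "excluded"), "s2")
  expect_equal(rownames(out), "s1")
})

test_that("series normalization divides by the maximum", {
  expect_equal(normalize_series_to_max(c(1, 3, 2)), c(1 / 3, 1, 2 / 3))
  expect_equal(normalize_series_to_max(5), 1)
  v <- c(0.2, 1, 0.7)
  expect_equal(normalize_series_to_max(v), v)
  expect_error(normalize_series_to_max(c(0, 0)), "positive")
  expect_error(normalize_series_to_max(c(-2, -1)), "positive")
})
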
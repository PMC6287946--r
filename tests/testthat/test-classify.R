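test_that("threshold rules assign the trajectory classes", {
  prof <- rbind(
    strong = c(0, rep(80, 9)),      # strong responder
    weak   = c(10, rep(40, 9)),     # weak responder
    flat   = rep(35, 10),           # ligand-independent, high baseline
    dim    = rep(5, 10)             # background
  )
  b <- toy_binding(prof)
  fdr_tab <- data.frame(site_id = rownames(prof),
                        statistic = 0,
                        p_value = c(1e-9, 1e-8, 0.9, 0.8),
                        fdr = c(1e-8, 1e-7, 0.95, 0.9))
  cl <- classify_sites(b, fdr_tab)
  got <- stats::setNames(cl$class, cl$site_id)
  expect_equal(got[["strong"]], "A")
  expect_equal(got[["weak"]], "C")
  expect_equal(got[["flat"]], "B")
  expect_equal(got[["dim"]], "unassigned")
  expect_equal(cl$baseline, unname(prof[, 1]))
  expect_equal(cl$amplitude, unname(rowMeans(prof[, -1]) - prof[, 1]))
})

test_that("sites missing from the FDR table are left unassigned", {
  prof <- rbind(a = c(0, rep(80, 9)), b = rep(35, 10))
  bm <- toy_binding(prof)
  fdr_tab <- data.frame(site_id = "a", statistic = 0,
                        p_value = 1e-9, fdr = 1e-8)
  expect_warning(cl <- classify_sites(bm, fdr_tab), "missing")
  expect_equal(cl$class[cl$site_id == "b"], "unassigned")
})

test_that("classification is invariant to joint rescaling", {
  fx <- default_fixture()
  cl1 <- classify_sites(fx$binding)
  scaled <- fx$binding
  scaled$values <- scaled$values * 7
  cl2 <- classify_sites(scaled, baseline_floor = 20 * 7)
  expect_identical(cl1$class, cl2$class)
})

test_that("generating classes are recovered on the default fixture", {
  fx <- default_fixture()
  cl <- classify_sites(fx$binding)
  truth <- map_truth_class(truth_classes(fx)[cl$site_id])
  expect_gte(mean(truth == cl$class), 0.95)
})

test_that("heatmap ordering groups by time of max and is a permutation", {
  fx <- default_fixture()
  ord_rel <- order_for_heatmap(fx$binding, mode = "row-max")
  ord_abs <- order_for_heatmap(fx$binding, mode = "absolute")
  expect_identical(ord_rel$order, ord_abs$order)
  expect_setequal(ord_rel$order, rownames(fx$binding$values))
  expect_identical(rownames(ord_rel$view), ord_rel$order)
  # blocks appear in time order
  expect_true(!is.unsorted(match(unname(ord_rel$time_of_max),
                                 sort(unique(fx$binding$manifest$time_min)))))
  # row-max view peaks at exactly 1 in every row
  expect_equal(unname(apply(ord_rel$view, 1, max)),
               rep(1, nrow(ord_rel$view)))
  # all sites maximal at the same time point collapse to a single block
  b1 <- toy_binding(rbind(x = c(1, 9, 2), y = c(2, 7, 3)))
  o1 <- order_for_heatmap(b1)
  expect_equal(unique(unname(o1$time_of_max)), 10)
})

test_that("the 0-min-maximal block is marginal relative to replicate noise", {
  fx <- default_fixture()
  ord <- order_for_heatmap(fx$binding, mode = "absolute")
  zero_block <- names(ord$time_of_max)[ord$time_of_max == 0]
  zero_block <- intersect(zero_block,
                          fx$binding$sites$site_id[
                            fx$binding$sites$role == "signal"])
  expect_gt(length(zero_block), 0)
  # only non-responsive site classes can peak at 0 min
  truth <- truth_classes(fx)[zero_block]
  expect_true(all(truth %in% c("B", "null")))
  # apparent decrease from 0 min is small against within-replicate scatter
  prof <- collapse_replicates(fx$binding)[zero_block, , drop = FALSE]
  block_amp <- mean(prof[, 1] - rowMeans(prof[, -1, drop = FALSE]))
  within_sd <- mean(vapply(zero_block, function(id) {
    mean(site_profile(fx$binding, id)$sd)
  }, numeric(1)))
  expect_lt(block_amp, within_sd)
})
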
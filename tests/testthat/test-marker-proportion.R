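test_that("per-marker ratio matches the published marker cells", {
  expect_equal(per_marker_ratio(108.6745, 67.97581), 62.54994, tolerance = 1e-6)
  expect_equal(per_marker_ratio(3.287543, 1.731643), 52.67286, tolerance = 1e-6)
  expect_equal(per_marker_ratio(10, 10), 100)
  expect_error(per_marker_ratio(0, 5), "must be > 0")
  expect_error(per_marker_ratio(-1, 5), "must be > 0")
})

test_that("per-pair estimates reproduce the published per-donor averages", {
  fx <- table1_fixture()
  ratios <- table1_printed_ratios()
  for (pid in c("A211", "A283")) {
    est <- estimate_proportion(fx$matrix, fx$design, fx$markers, pid)
    expect_identical(est$n_markers_used, 7L)
    expect_equal(est$per_marker_ratio, ratios[[pid]], tolerance = 1e-6)
    expect_equal(est$mean_ratio, mean(ratios[[pid]]), tolerance = 1e-6)
  }
})

test_that("markers below the monoculture floor are excluded with reasons", {
  mat <- trio_matrix(msc = c(m1 = 10, m2 = 0.2), ch = c(m1 = 0, m2 = 0),
                     co = c(m1 = 5, m2 = 0.1))
  mk <- marker_set(c("m1", "m2"))
  est <- estimate_proportion(mat, tiny_design(), mk, "pA", floor = 0.3)
  expect_identical(est$n_markers_used, 1L)
  expect_identical(est$excluded_markers$gene_id, "m2")
  expect_match(est$excluded_markers$reason, "floor")
  expect_equal(est$mean_ratio, 50)

  all_low <- trio_matrix(msc = c(m1 = 0.1), ch = c(m1 = 0), co = c(m1 = 0.05))
  expect_error(estimate_proportion(all_low, tiny_design(), marker_set("m1"),
                                   "pA"), "no usable markers.*pA|pA.*no usable")
})

test_that("the estimator is the mean of ratios, not the ratio of means", {
  # marker levels spanning an order of magnitude separate the two estimators
  msc <- c(m1 = 100, m2 = 1)
  co <- c(m1 = 30, m2 = 0.9)   # ratios 30% and 90%
  mat <- trio_matrix(msc, ch = c(m1 = 0, m2 = 0), co = co)
  est <- estimate_proportion(mat, tiny_design(), marker_set(c("m1", "m2")), "pA")
  mean_of_ratios <- mean(100 * co / msc)
  ratio_of_means <- 100 * sum(co) / sum(msc)
  expect_equal(est$mean_ratio, mean_of_ratios)
  expect_false(isTRUE(all.equal(mean_of_ratios, ratio_of_means)))
})

test_that("mean ratio is invariant to marker order and trio-wide rescaling", {
  set.seed(21)
  for (i in 1:5) {
    msc <- setNames(rlnorm(5, 2, 1), paste0("m", 1:5))
    co <- msc * runif(5, 0.3, 0.9)
    mat <- trio_matrix(msc, ch = setNames(rep(0, 5), names(msc)), co = co)
    d <- tiny_design()
    base <- estimate_proportion(mat, d, marker_set(names(msc)), "pA")$mean_ratio
    shuffled <- marker_set(sample(names(msc)))
    expect_equal(estimate_proportion(mat, d, shuffled, "pA")$mean_ratio, base)
    k <- runif(1, 0.5, 4)
    expect_equal(estimate_proportion(mat * k, d, marker_set(names(msc)),
                                     "pA")$mean_ratio, base)
  }
})

test_that("pooling averages pair means, converts to a fraction, and rounds on request", {
  fx <- table1_fixture()
  est <- lapply(c("A211", "A283"), function(p)
    estimate_proportion(fx$matrix, fx$design, fx$markers, p))
  pooled <- pool_proportions(est, rounding = 2)
  expect_equal(pooled$pi, 0.57)
  expect_equal(pooled$pi_complement, 0.43)
  raw <- pool_proportions(est, rounding = NULL)
  expect_equal(raw$pi, mean(c(est[[1]]$mean_ratio, est[[2]]$mean_ratio)) / 100)
  expect_equal(raw$pi, 0.5708575, tolerance = 1e-5)

  single <- pool_proportions(list(list(pair_id = "x", mean_ratio = 60)) |>
                               lapply(structure, class = "proportion_estimate"),
                             rounding = NULL)
  expect_equal(single$pi, 0.60)
  expect_error(pool_proportions(list()), "no proportion estimates")
})

test_that("a noisy estimate above 1 is clamped with a warning", {
  fake <- structure(list(pair_id = "x", mean_ratio = 104), class = "proportion_estimate")
  expect_warning(pooled <- pool_proportions(list(fake), rounding = NULL),
                 "clamped")
  expect_identical(pooled$pi, 1)
})

test_that("attrition report compares seeded and estimated fractions", {
  rep <- attrition_report(0.57, 0.8)
  expect_equal(rep$drop, 0.23)
  expect_equal(rep$drop_percent_points, 23)
  expect_equal(rep$relative_retention, 0.7125)
  expect_equal(attrition_report(0.8, 0.8)$drop, 0)
  expect_error(attrition_report(1.2, 0.8), "in \\(0, 1\\)")
})

test_that("the residual-corrected estimator removes non-carrier leakage", {
  # with residual r in the chondrocyte sample, co = pi*m + (1-pi)*r;
  # the plain ratio is biased by (1-pi)*r/m, the corrected one is exact
  pi_true <- 0.6
  msc <- c(m1 = 20, m2 = 5)
  chn <- c(m1 = 0.4, m2 = 0.2)
  co <- pi_true * msc + (1 - pi_true) * chn
  mat <- trio_matrix(msc, chn, co)
  mk <- marker_set(c("m1", "m2"))
  d <- tiny_design()
  plain <- estimate_proportion(mat, d, mk, "pA")
  corrected <- estimate_proportion(mat, d, mk, "pA", corrected = TRUE)
  expect_equal(corrected$mean_ratio, 100 * pi_true, tolerance = 1e-10)
  expect_gt(plain$mean_ratio, 100 * pi_true)
})

test_that("the proportion table mirrors the published layout", {
  fx <- table1_fixture()
  est <- lapply(c("A211", "A283"), function(p)
    estimate_proportion(fx$matrix, fx$design, fx$markers, p))
  tab <- proportion_table(est)
  expect_identical(tab$gene_id, c(fx$markers$gene_ids, "Average"))
  expect_identical(names(tab), c("gene_id", "ratio_pct_A211", "ratio_pct_A283"))
  expect_equal(tab$ratio_pct_A211[8], 57.27222, tolerance = 1e-5)
})
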
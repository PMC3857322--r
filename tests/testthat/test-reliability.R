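test_that("icc_2_1 reproduces worked examples", {
  expect_equal(icc_2_1(cbind(1:4, 1:4)), 1)
  expect_equal(icc_2_1(cbind(1:4, 2:5)), 10 / 13)
  expect_error(icc_2_1(cbind(1:2, 1:2)), "n >= 3")
  expect_error(icc_2_1(cbind(c(1, NA, 3), 1:3)), "missing")
  expect_true(is.nan(icc_2_1(matrix(5, 4, 2))))  # zero total variance
})

test_that("icc_2_1 matches the two-way ANOVA oracle", {
  set.seed(42)
  for (i in 1:50) {
    m <- matrix(rnorm(32 * 2), 32, 2)
    expect_equal(icc_2_1(m), icc_2_1_aov(m), tolerance = 1e-10)
  }
  # and under the null the estimate is centred on zero
  set.seed(43)
  vals <- replicate(500, icc_2_1(matrix(rnorm(64), 32, 2)))
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(500))
})

test_that("icc_2_1 is invariant to shift and positive scaling", {
  set.seed(44)
  m <- matrix(rnorm(20), 10, 2)
  expect_equal(icc_2_1(m + 7), icc_2_1(m), tolerance = 1e-12)
  expect_equal(icc_2_1(m * 3.2), icc_2_1(m), tolerance = 1e-12)
})

test_that("Fisher-z combination behaves as specified", {
  expect_equal(fisher_combine(0.5, 0.5), 0.5)          # fixed point
  expect_equal(fisher_combine(0.6, 0.2),
               tanh((atanh(0.6) + atanh(0.2)) / 2), tolerance = 1e-12)
  expect_equal(fisher_combine(0.6, 0.2), 0.4202, tolerance = 1e-4)
  expect_true(fisher_combine(0.6, 0.2) > 0.33)  # included at the threshold
  v <- c(-0.5, 0, 0.9)
  expect_equal(fisher_combine(v), v)                   # identity on one map
  expect_true(is.finite(fisher_combine(1, 1)))         # clipping near 1
})

test_that("reliability mask applies the strict threshold and monotonicity", {
  # two task maps both at the boundary: combined is the fixed point and the
  # strict inequality excludes the voxel
  expect_equal(fisher_combine(0.33, 0.33), 0.33)
  expect_false(fisher_combine(0.33, 0.33) > 0.33)

  ds <- tiny_study(n_dd = 16, n_td = 16, grid = tiny_grid(8), seed = 20)
  r1 <- build_reliability_mask(ds, threshold = 0.2)
  r2 <- build_reliability_mask(ds, threshold = 0.4)
  expect_true(all(which(r2$mask) %in% which(r1$mask)))  # monotone
  expect_true(all(!r1$mask[!ds$brain_mask]))            # mask within brain
  # mask <=> combined > threshold
  expect_identical(r1$mask,
                   !is.na(r1$combined) & r1$combined > 0.2 & ds$brain_mask)
})

test_that("planted ICC fields are recovered with small error", {
  # the voxel-averaged estimate over 1000 voxels tracks the planted level
  # (per-voxel estimates at n = 32, k = 2 carry sampling sd ~ 0.15, so the
  # recovery claim concerns the field average)
  for (icc in c(0.2, 0.8)) {
    sb <- sqrt(icc); se <- sqrt(1 - icc)
    ds <- tiny_study(n_dd = 16, n_td = 16, sigma_b = sb, sigma_e = se,
                     seed = 30 + 10 * icc, grid = tiny_grid(10))
    rmap <- build_reliability_mask(ds, tasks = "comparison")
    expect_lt(abs(mean(rmap$per_task$comparison, na.rm = TRUE) - icc), 0.05)
  }
})

test_that("reliability bins reproduce printed-table arithmetic", {
  # a field with the published bin counts reproduces the published shares
  v <- c(rep(0.10, 87641), rep(0.35, 6712), rep(0.50, 10801),
         rep(0.70, 1540), rep(0.80, 26))
  tab <- tabulate_reliability_bins(v)
  expect_equal(tab$absolute[tab$label == "total"], 106720)
  expect_equal(tab$relative_total_pct[tab$label == "included"], 17.9)
  expect_equal(tab$relative_total_pct[tab$label == "excluded"], 82.1)
  expect_equal(tab$relative_included_pct[tab$label == "poor"], 35.2)
  expect_equal(tab$relative_included_pct[tab$label == "fair"], 56.6)
  expect_equal(tab$relative_included_pct[tab$label == "good"], 8.1)
  expect_equal(tab$relative_included_pct[tab$label == "excellent"], 0.1)
  # counts sum to total
  expect_equal(sum(tab$absolute[tab$label %in%
                                  c("excluded", "poor", "fair", "good",
                                    "excellent")]),
               tab$absolute[tab$label == "total"])

  # degenerate: everything at ICC 0
  tab0 <- tabulate_reliability_bins(rep(0, 100))
  expect_equal(tab0$relative_total_pct[tab0$label == "excluded"], 100)
  expect_equal(tab0$absolute[tab0$label %in% c("poor", "fair", "good",
                                               "excellent")],
               rep(0, 4))
})

test_that("dice_overlap satisfies its closed forms", {
  a <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(dice_overlap(a, a), 1)
  expect_equal(dice_overlap(a, !a), 0)
  expect_equal(dice_overlap(logical(4), logical(4)), 0)  # both empty
  A <- c(rep(TRUE, 100), rep(FALSE, 100))
  B <- c(rep(FALSE, 50), rep(TRUE, 100), rep(FALSE, 50))
  expect_equal(dice_overlap(A, B), 0.5)
  expect_error(dice_overlap(a, a[-1]), "grid")
})
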
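test_that("second-level t maps reproduce hand-computed statistics", {
  g <- tiny_grid(4)
  nv <- prod(g$dims)
  subj <- data.frame(id = c("a", "b", "c"), group = "DD")
  betas <- array(0, dim = c(nv, 3, 1, 2))
  for (s in 1:3) betas[, s, 1, ] <- s  # averaged beta = 1, 2, 3 per subject
  ds <- study_dataset(g, subj, "comparison", betas)
  sm <- second_level_t(ds, "comparison", "one_sample_DD")
  expect_equal(sm$df, 2)
  expect_equal(unique(sm$t[ds$brain_mask]), 2 * sqrt(3), tolerance = 1e-12)

  # identical groups: two-sample t is zero everywhere
  subj2 <- data.frame(id = letters[1:6], group = rep(c("DD", "TD"), each = 3))
  betas2 <- array(0, dim = c(nv, 6, 1, 2))
  vals <- matrix(rnorm(nv * 3), nv, 3)
  betas2[, 1:3, 1, 1] <- vals; betas2[, 1:3, 1, 2] <- vals
  betas2[, 4:6, 1, 1] <- vals; betas2[, 4:6, 1, 2] <- vals
  ds2 <- study_dataset(g, subj2, "comparison", betas2)
  sm2 <- second_level_t(ds2, "comparison", "two_sample")
  expect_true(all(sm2$t[ds2$brain_mask] == 0))
  expect_equal(sm2$df, 4)
})

test_that("swapping group labels negates the two-sample field", {
  ds <- tiny_study(n_dd = 5, n_td = 5, grid = tiny_grid(6), seed = 50)
  sm <- second_level_t(ds, "comparison", "two_sample")
  flipped <- ds
  flipped$subjects$group <- ifelse(ds$subjects$group == "DD", "TD", "DD")
  sm2 <- second_level_t(flipped, "comparison", "two_sample")
  expect_equal(sm$t, -sm2$t)
})

test_that("inference never leaves the supplied mask", {
  ds <- tiny_study(n_dd = 6, n_td = 6, grid = tiny_grid(8), seed = 51)
  mask <- ds$brain_mask & (seq_along(ds$brain_mask) %% 3 == 0)
  sm <- second_level_t(ds, "comparison", "two_sample", mask = mask)
  expect_true(all(is.na(sm$t[!mask])))
  thr <- apply_cluster_threshold(sm, 1)
  expect_true(all(mask[thr$surviving]))
})

test_that("smoothness estimator recovers white-noise and planted FWHM", {
  g <- volume_grid(c(20, 20, 20), c(3, 3, 3))
  mask <- rep(TRUE, prod(g$dims))
  set.seed(60)
  # spatially independent noise: estimate near the voxel size
  white <- replicate(20, rnorm(prod(g$dims)))
  fw <- estimate_smoothness(white, g, mask)
  expect_true(all(abs(fw - 3) / 3 < 0.2))

  # noise smoothed to 7 mm: recovered within 1.5 mm
  sm7 <- replicate(20, as.vector(smooth_gaussian(rnorm(prod(g$dims)), g, 7)))
  fw7 <- estimate_smoothness(sm7, g, mask)
  expect_true(all(abs(fw7 - 7) < 1.5))

  # constant volumes carry no gradient information
  expect_warning(fwc <- estimate_smoothness(cbind(rep(1, prod(g$dims)),
                                                  rep(2, prod(g$dims))),
                                            g, mask),
                 "constant")
  expect_true(all(is.na(fwc)))
})

test_that("connected-component labelling matches a flood-fill oracle", {
  set.seed(61)
  d <- c(12, 12, 12)
  for (i in 1:10) {
    arr <- array(runif(prod(d)) < 0.08, d)
    idx <- which(arr)
    lab <- label_components(idx, d, connectivity = 6)
    expect_equal(sort(as.vector(table(lab))), sort(flood_sizes(arr)))
  }
})

test_that("Monte-Carlo extent matches an independent re-simulation oracle", {
  g <- volume_grid(c(10, 10, 10), c(3, 3, 3))
  mask <- rep(TRUE, 1000)
  k1 <- monte_carlo_cluster_extent(g, mask, fwhm = 0, voxel_p = 0.01,
                                   alpha = 0.05, iterations = 600, seed = 62)
  # oracle: direct Bernoulli fields + flood fill, two-sided p split by sign
  set.seed(63)
  maxes <- replicate(600, {
    z <- array(rnorm(1000), dim = g$dims)
    zc <- qnorm(1 - 0.01 / 2)
    max(c(0, flood_sizes(z > zc), flood_sizes(z < -zc)))
  })
  k_oracle <- which(vapply(1:10, function(k) mean(maxes >= k),
                           numeric(1)) <= 0.05)[1]
  expect_lte(abs(k1$k_star - k_oracle), 1)
})

test_that("extent threshold grows with smoothness and vanishes at alpha 1", {
  g <- volume_grid(c(10, 10, 10), c(3, 3, 3))
  mask <- rep(TRUE, 1000)
  k_a1 <- monte_carlo_cluster_extent(g, mask, fwhm = 0, alpha = 1,
                                     iterations = 100, seed = 64)
  expect_equal(k_a1$k_star, 1L)
  ks <- vapply(c(0, 4, 8), function(fw)
    monte_carlo_cluster_extent(g, mask, fwhm = fw, iterations = 200,
                               seed = 65)$k_star, integer(1))
  expect_true(all(diff(ks) >= 0))
})

test_that("cluster thresholding filters by extent and tabulates survivors", {
  g <- tiny_grid(12)
  nv <- prod(g$dims)
  mask <- rep(TRUE, nv)
  tval <- rep(0, nv)
  arr <- array(0, g$dims)
  arr[2:3, 2:3, 2] <- 5            # blob of 4 voxels < k*
  arr[6:9, 6:9, 6:9] <- -6         # blob of 64 voxels
  tval <- as.vector(arr)
  smap <- list(t = tval, p = 2 * pt(-abs(tval), 30), df = 30, mask = mask,
               voxel_p = 0.01, grid = g)
  out <- apply_cluster_threshold(smap, 10)
  expect_equal(nrow(out$table), 1)
  expect_equal(out$table$size, 64)
  expect_equal(out$table$sign, -1)
  expect_equal(sum(out$surviving), 64)

  # boundary: a cluster of size k*-1 is removed; nothing passes -> empty table
  out2 <- apply_cluster_threshold(smap, 65)
  expect_equal(nrow(out2$table), 0)
  expect_false(any(out2$surviving))

  # voxel-p consistency with a calibrated threshold object is enforced
  kcal <- monte_carlo_cluster_extent(g, mask, voxel_p = 0.05,
                                     iterations = 100, seed = 66)
  expect_error(apply_cluster_threshold(smap, kcal), "voxel p")
})

test_that("null datasets rarely yield any surviving cluster", {
  g <- tiny_grid(10)
  mask <- rep(TRUE, prod(g$dims))
  kcal <- monte_carlo_cluster_extent(g, mask, fwhm = 0, voxel_p = 0.01,
                                     alpha = 0.05, iterations = 400,
                                     seed = 70)
  hits <- vapply(1:60, function(i) {
    ds <- tiny_study(n_dd = 8, n_td = 8, grid = g, seed = 700 + i)
    sm <- second_level_t(ds, "comparison", "two_sample", mask = mask)
    nrow(apply_cluster_threshold(sm, kcal)$table) > 0
  }, logical(1))
  # familywise error at alpha 0.05: allow 2 SE at n = 60
  expect_lte(mean(hits), 0.05 + 2 * sqrt(0.05 * 0.95 / 60))
})
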
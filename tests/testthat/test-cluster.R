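test_that("spearman distance reflects ranks, not values", {
  x <- c(1, 2, 3, 4, 7)
  f <- rbind(a = x, b = exp(x), c = rev(x))
  d <- as.matrix(spearman_distance(f))
  expect_equal(d["a", "b"], 0)            # monotone transform: distance 0
  expect_equal(d["a", "c"], 2)            # perfect anticorrelation
  f2 <- rbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4))
  expect_equal(as.matrix(spearman_distance(f2))["a", "b"], 0.2)  # rho = 0.8

  expect_error(spearman_distance(rbind(a = rep(1, 5), b = 1:5)),
               "constant feature vector.*a")
  expect_error(spearman_distance(matrix(1:4, 2, 2)), "3 voxels")
})

test_that("complete linkage merges in forced order and dominates cophenetic", {
  d <- matrix(c(0, 0.1, 1, 0.1, 0, 1, 1, 1, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- complete_linkage_tree(as.dist(d))
  expect_equal(tree$height, c(0.1, 1))
  first <- sort(tree$merge[1, ])
  expect_equal(first, c(-2, -1))   # A and B merge first

  # equal distances: all merge heights equal
  deq <- as.dist(matrix(0.7, 4, 4) - diag(0.7, 4))
  treq <- complete_linkage_tree(deq)
  expect_true(all(treq$height == 0.7))

  # cophenetic distances dominate the originals elementwise
  set.seed(100)
  f <- matrix(rnorm(10 * 40), 10)
  rownames(f) <- letters[1:10]
  dd <- spearman_distance(f)
  tr <- complete_linkage_tree(dd)
  expect_true(all(cophenetic(tr) >= dd - 1e-12))
})

test_that("cutting the tree yields coherent composition tables", {
  ds <- tiny_study(n_dd = 5, n_td = 5, seed = 101)
  f <- extract_features(ds, ds$brain_mask, task_mode = "concatenated")
  tr <- complete_linkage_tree(spearman_distance(f))

  all_one <- cut_and_characterize(tr, 1, ds$subjects)
  expect_equal(nrow(all_one$composition), 1)
  expect_equal(all_one$composition$n, 10)
  expect_equal(all_one$composition$dd, 5)

  singletons <- cut_and_characterize(tr, 10, ds$subjects)
  expect_equal(nrow(singletons$composition), 10)
  expect_true(all(singletons$composition$n == 1))

  expect_error(cut_and_characterize(tr, 0, ds$subjects), "k out of range")
  expect_error(cut_and_characterize(tr, 11, ds$subjects), "k out of range")

  # assignments partition all subjects
  k3 <- cut_and_characterize(tr, 3, ds$subjects)
  expect_equal(sum(k3$composition$n), 10)
  expect_equal(sort(unique(k3$assignments)), 1:3)
})

test_that("planted partitions are recovered with high ARI", {
  skip_if_not_installed("mclust")
  ok <- vapply(1:10, function(i) {
    set.seed(200 + i)
    n <- 16; nv <- 400
    pattern1 <- rnorm(nv, 0, 1.5)
    pattern2 <- rnorm(nv, 0, 1.5)
    f <- rbind(t(replicate(n / 2, pattern1 + rnorm(nv))),
               t(replicate(n / 2, pattern2 + rnorm(nv))))
    rownames(f) <- sprintf("s%02d", 1:n)
    truth <- rep(1:2, each = n / 2)
    tr <- complete_linkage_tree(spearman_distance(f))
    ari(cutree(tr, 2), truth) > 0.9
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("subject order does not change the clustering", {
  ds <- tiny_study(n_dd = 4, n_td = 4, seed = 102)
  f <- extract_features(ds, ds$brain_mask, task_mode = "comparison")
  tr <- complete_linkage_tree(spearman_distance(f))
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  trp <- complete_linkage_tree(spearman_distance(f[perm, ]))
  a <- cutree(tr, 3)
  b <- cutree(trp, 3)[rownames(f)]
  expect_equal(ari(a, b), 1)
})

test_that("concatenating identical tasks reproduces single-task trees", {
  ds <- tiny_study(n_dd = 4, n_td = 4, seed = 103)
  ds$betas[, , 2, ] <- ds$betas[, , 1, ]   # make both tasks identical
  f1 <- extract_features(ds, ds$brain_mask, task_mode = "comparison")
  f2 <- extract_features(ds, ds$brain_mask, task_mode = "concatenated")
  t1 <- complete_linkage_tree(spearman_distance(f1))
  t2 <- complete_linkage_tree(spearman_distance(f2))
  expect_equal(t1$height, t2$height)
  expect_equal(t1$merge, t2$merge)
})

test_that("per-cluster maps work and circular contrasts are refused", {
  ds <- tiny_study(n_dd = 6, n_td = 6, grid = tiny_grid(8), seed = 104)
  f <- extract_features(ds, ds$brain_mask, task_mode = "comparison")
  tr <- complete_linkage_tree(spearman_distance(f))
  cr <- cut_and_characterize(tr, 2, ds$subjects)

  maps <- cluster_group_maps(ds, cr$assignments, "comparison")
  expect_true(length(maps) >= 1)
  expect_s3_class(maps[[1]], "stat_map")

  expect_error(cluster_group_maps(ds, cr$assignments, "comparison",
                                  contrast_pair = c(1, 2)), "circular")
  both <- cluster_group_maps(ds, cr$assignments, "comparison",
                             contrast_pair = c(1, 2),
                             i_understand_circularity = TRUE)
  expect_true("contrast" %in% names(both))

  # a cluster of identical positive responders maps uniformly positive
  g <- tiny_grid(5)
  nv <- prod(g$dims)
  subj <- data.frame(id = c("a", "b", "c"), group = "DD")
  betas <- array(rep(2, nv * 3 * 1 * 2) + rnorm(nv * 6, 0, 0.01),
                 dim = c(nv, 3, 1, 2))
  dsu <- study_dataset(g, subj, "comparison", betas)
  mp <- cluster_group_maps(dsu, c(a = 1, b = 1, c = 1), "comparison")
  expect_true(all(mp$cluster1$t[dsu$brain_mask] > 0))
})
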
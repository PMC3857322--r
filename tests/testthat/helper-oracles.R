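# Independent oracles used by the tests.  These deliberately avoid the
# package's own code paths.

# ICC(2,1) via R's two-way ANOVA decomposition (aov), long format.
icc_2_1_aov <- function(values) {
  n <- nrow(values); k <- ncol(values)
  long <- data.frame(y = as.vector(values),
                     subj = factor(rep(seq_len(n), k)),
                     sess = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + sess, data = long))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Recursive flood-fill connected-component labelling (6-connectivity) on a
# logical 3D array; returns sizes of all components.
flood_sizes <- function(arr) {
  d <- dim(arr)
  seen <- array(FALSE, d)
  sizes <- integer(0)
  idx <- which(arr)
  for (start in idx) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      size <- size + 1L
      co <- arrayInd(v, d)
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        nb <- co; nb[ax] <- nb[ax] + s
        if (nb[ax] < 1 || nb[ax] > d[ax]) next
        lin <- (nb[3] - 1) * d[1] * d[2] + (nb[2] - 1) * d[1] + nb[1]
        if (arr[lin] && !seen[lin]) {
          seen[lin] <- TRUE
          queue <- c(queue, lin)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# Adjusted Rand index between two partitions.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Small study fixture on a compact grid; optional group effect in one ROI.
tiny_grid <- function(n = 12L) volume_grid(c(n, n, n), c(3, 3, 3))

# Two cubic ROIs ("A" in the low corner, "B" in the high corner) for small
# grids that cannot host the full 17-ROI layout.
tiny_atlas <- function(grid, side = 3L) {
  d <- grid$dims
  lab <- array(0L, d)
  lab[2:(1 + side), 2:(1 + side), 2:(1 + side)] <- 1L
  lab[(d[1] - side):(d[1] - 1), (d[2] - side):(d[2] - 1),
      (d[3] - side):(d[3] - 1)] <- 2L
  list(labels = as.integer(lab),
       table = data.frame(id = 1:2, name = c("A", "B"),
                          hemisphere = c("L", "R"),
                          stringsAsFactors = FALSE))
}

tiny_study <- function(n_dd = 6, n_td = 6, sigma_b = 1, sigma_e = 1,
                       effect_table = NULL, heterogeneity = FALSE,
                       het_rois = NULL, het_shift = 5, seed = 1,
                       grid = tiny_grid(), atlas = NULL,
                       mask = rep(TRUE, prod(grid$dims))) {
  if (is.null(atlas) && (heterogeneity || !is.null(effect_table)))
    atlas <- tiny_atlas(grid)
  simulate_beta_dataset(n_dd = n_dd, n_td = n_td, grid = grid,
                        sigma_b = sigma_b, sigma_e = sigma_e,
                        effect_table = effect_table,
                        heterogeneity = heterogeneity, het_rois = het_rois,
                        het_shift = het_shift, seed = seed, atlas = atlas,
                        mask = mask)
}
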
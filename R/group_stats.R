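#' Second-level t maps on session-averaged betas
#'
#' One-sample maps test each group's mean session-averaged beta against zero
#' (`t = mean / (sd / sqrt(n))`, `df = n - 1`); the two-sample map compares
#' DD against TD with the pooled-variance t (`df = n1 + n2 - 2`).  All
#' statistics are computed only inside the supplied mask — by design the
#' reliability mask, so that unreliable voxels never enter inference.
#' Zero-variance voxels get a sign-carrying capped t and a QC flag.
#'
#' @param dataset a [study_dataset()].
#' @param task task label.
#' @param mode `"one_sample_DD"`, `"one_sample_TD"` or `"two_sample"`.
#' @param mask logical voxel vector (nonempty).
#' @param voxel_p voxel-level two-sided p threshold carried on the result
#'   (default 0.01).
#' @return A `stat_map` list: `t`, `p` (voxel fields, `NA` outside the
#'   mask), `df`, `mask`, `voxel_p`, `contrast`, `grid`, `qc_zero_var`.
#' @export
second_level_t <- function(dataset, task,
                           mode = c("two_sample", "one_sample_DD",
                                    "one_sample_TD"),
                           mask = dataset$brain_mask, voxel_p = 0.01) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "study_dataset"))
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  avg <- session_average(dataset)[, , task_index(dataset, task)]
  grp <- dataset$subjects$group
  tcap <- 1e6
  nv <- nrow(avg)
  tval <- rep(NA_real_, nv); qc <- rep(FALSE, nv)
  if (mode == "two_sample") {
    a <- avg[mask, grp == "DD", drop = FALSE]
    b <- avg[mask, grp == "TD", drop = FALSE]
    n1 <- ncol(a); n2 <- ncol(b)
    df <- n1 + n2 - 2
    ma <- rowMeans(a); mb <- rowMeans(b)
    va <- rowSums((a - ma)^2); vb <- rowSums((b - mb)^2)
    sp2 <- (va + vb) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tv <- (ma - mb) / se
    zero <- se == 0
    tv[zero] <- sign(ma - mb)[zero] * tcap
    contrast <- sprintf("%s: DD - TD", task)
  } else {
    g <- if (mode == "one_sample_DD") "DD" else "TD"
    a <- avg[mask, grp == g, drop = FALSE]
    n1 <- ncol(a)
    df <- n1 - 1
    ma <- rowMeans(a)
    se <- sqrt(rowSums((a - ma)^2) / df / n1)
    tv <- ma / se
    zero <- se == 0
    tv[zero] <- sign(ma)[zero] * tcap
    contrast <- sprintf("%s: %s vs baseline", task, g)
  }
  tv[is.na(tv)] <- 0
  tval[mask] <- tv
  qcv <- rep(FALSE, sum(mask)); qcv[zero] <- TRUE
  qc[mask] <- qcv
  pval <- rep(NA_real_, nv)
  pval[mask] <- 2 * stats::pt(-abs(tval[mask]), df)
  structure(list(t = tval, p = pval, df = df, mask = mask,
                 voxel_p = voxel_p, contrast = contrast, grid = dataset$grid,
                 qc_zero_var = qc),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s; df = %d; %d in-mask voxels; max |t| = %.2f\n",
              x$contrast, x$df, sum(x$mask), max(abs(x$t), na.rm = TRUE)))
  invisible(x)
}

#' Monte-Carlo cluster-extent threshold
#'
#' Calibrates the minimum cluster size controlling the family-wise error of
#' suprathreshold clusters: each iteration fills the mask with standard
#' normal noise, smooths it to the stated FWHM, renormalises to unit
#' variance inside the mask, applies the two-sided voxel threshold, and
#' records the largest cluster (positive and negative excursions labelled
#' separately).  The returned extent `k*` is the smallest `k` for which the
#' proportion of iterations whose maximum cluster reaches `k` is at most
#' `alpha`.
#'
#' @param grid a [volume_grid()].
#' @param mask logical voxel vector.
#' @param fwhm smoothness of the null fields in mm (scalar or 3-vector),
#'   e.g. from [estimate_smoothness()]; 0 simulates independent voxels.
#' @param voxel_p two-sided voxel threshold (default 0.01).
#' @param alpha family-wise cluster alpha (default 0.05).
#' @param iterations Monte-Carlo iterations (>= 100; default 1000).
#' @param connectivity 6 (faces, default) or 26.
#' @param seed integer seed.
#' @return A `cluster_threshold` list: `k_star`, `max_sizes` (per
#'   iteration), plus the calibration parameters.
#' @export
monte_carlo_cluster_extent <- function(grid, mask, fwhm = 0, voxel_p = 0.01,
                                       alpha = 0.05, iterations = 1000,
                                       connectivity = 6, seed = 1) {
  if (iterations < 100) stop("need >= 100 iterations", call. = FALSE)
  if (alpha * iterations < 5)
    warning("alpha x iterations < 5: unstable tail estimate")
  d <- grid$dims
  zc <- stats::qnorm(1 - voxel_p / 2)
  set.seed(seed)
  fwhm <- rep_len(fwhm, 3)
  smooth_needed <- any(fwhm > 0)
  max_sizes <- integer(iterations)
  for (it in seq_len(iterations)) {
    x <- array(stats::rnorm(prod(d)), dim = d)
    if (smooth_needed) x <- smooth_gaussian(x, grid, fwhm)
    v <- as.vector(x)[mask]
    v <- (v - mean(v)) / stats::sd(v)
    best <- 0L
    for (sgn in c(1, -1)) {
      hit <- which(mask)[sgn * v > zc]
      if (length(hit)) {
        lab <- label_components(hit, d, connectivity)
        best <- max(best, max(tabulate(lab)))
      }
    }
    max_sizes[it] <- best
  }
  ks <- seq_len(max(max_sizes, 1L))
  exceed <- vapply(ks, function(k) mean(max_sizes >= k), numeric(1))
  k_star <- if (any(exceed <= alpha)) ks[which(exceed <= alpha)[1]] else
    max(max_sizes) + 1L
  k_star <- max(k_star, 1L)
  structure(list(k_star = as.integer(k_star), max_sizes = max_sizes,
                 voxel_p = voxel_p, alpha = alpha, iterations = iterations,
                 fwhm = fwhm, connectivity = connectivity, seed = seed),
            class = "cluster_threshold")
}

#' @export
print.cluster_threshold <- function(x, ...) {
  cat(sprintf(paste0("<cluster_threshold> k* = %d voxels (voxel p %.3g, ",
                     "alpha %.2f, %d iterations, FWHM %s mm)\n"),
              x$k_star, x$voxel_p, x$alpha, x$iterations,
              paste(signif(x$fwhm, 3), collapse = "/")))
  invisible(x)
}

#' Apply the cluster-extent threshold to a statistical map
#'
#' Thresholds the map at its voxel-level p, groups suprathreshold voxels of
#' each sign into connected clusters, removes clusters smaller than `k_star`,
#' and tabulates the survivors.
#'
#' @param smap a `stat_map` from [second_level_t()] (or any list with `t`,
#'   `p`, `mask`, `voxel_p`, `grid`).
#' @param k_star minimum cluster extent in voxels, or a `cluster_threshold`
#'   object (its `voxel_p` must match the map's).
#' @param connectivity 6 or 26; must match the calibration.
#' @return list with `surviving` (logical voxel field), `labels` (integer
#'   voxel field, 0 outside clusters) and `table` (cluster id, sign, size,
#'   peak |t|, peak voxel index).
#' @export
apply_cluster_threshold <- function(smap, k_star, connectivity = 6) {
  if (inherits(k_star, "cluster_threshold")) {
    if (!isTRUE(all.equal(k_star$voxel_p, smap$voxel_p)))
      stop("voxel p of the map and the calibrated threshold differ",
           call. = FALSE)
    connectivity <- k_star$connectivity
    k_star <- k_star$k_star
  }
  d <- smap$grid$dims
  surviving <- rep(FALSE, prod(d))
  labels <- integer(prod(d))
  rows <- list()
  nxt <- 0L
  for (sgn in c(1, -1)) {
    hit <- which(smap$mask & !is.na(smap$p) & smap$p < smap$voxel_p &
                   sign(smap$t) == sgn)
    if (!length(hit)) next
    lab <- label_components(hit, d, connectivity)
    for (cl in unique(lab)) {
      vox <- hit[lab == cl]
      if (length(vox) < k_star) next
      nxt <- nxt + 1L
      surviving[vox] <- TRUE
      labels[vox] <- nxt
      pk <- vox[which.max(abs(smap$t[vox]))]
      rows[[nxt]] <- data.frame(cluster = nxt, sign = sgn,
                                size = length(vox),
                                peak_t = smap$t[pk], peak_voxel = pk)
    }
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(0), sign = integer(0), size = integer(0),
               peak_t = numeric(0), peak_voxel = integer(0))
  list(surviving = surviving, labels = labels, table = table)
}
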
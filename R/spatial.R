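# Spatial helpers shared by the Monte-Carlo cluster machinery: separable
# Gaussian smoothing, connected-component labelling of sparse voxel sets,
# and residual smoothness (FWHM) estimation.

# Dense 1D Gaussian convolution matrix (reflected boundaries not needed for
# noise fields; plain truncation is used).
gauss_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  half <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(-half:half, sd = sigma_vox)
  k <- k / sum(k)
  M <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- (j - half):(j + half)
    keep <- idx >= 1 & idx <= n
    M[idx[keep], j] <- k[keep]
  }
  M
}

#' Smooth a voxel field with a Gaussian kernel
#'
#' Separable convolution along each axis with kernel FWHM given in mm.
#'
#' @param volume 3D array or voxel vector.
#' @param grid a [volume_grid()].
#' @param fwhm kernel full width at half maximum in mm (scalar or per axis;
#'   0 disables smoothing).
#' @return 3D array of smoothed values.
#' @export
smooth_gaussian <- function(volume, grid, fwhm) {
  d <- grid$dims
  if (is.null(dim(volume))) dim(volume) <- d
  fwhm <- rep_len(fwhm, 3L)
  if (all(fwhm <= 0)) return(volume)
  sig <- fwhm / (2 * sqrt(2 * log(2))) / grid$voxel_size
  x <- volume
  for (ax in 1:3) {
    if (sig[ax] <= 0) next
    M <- gauss_conv_matrix(d[ax], sig[ax])
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    xp <- M %*% matrix(xp, dp[1])
    dim(xp) <- dp
    x <- aperm(xp, order(perm))
  }
  x
}

#' Label connected components of a voxel set
#'
#' Groups the given voxels (linear indices into the grid) into connected
#' clusters under face (6) or face+edge+corner (26) adjacency, using a graph
#' decomposition of the adjacency structure.
#'
#' @param idx integer vector of 1-based linear voxel indices.
#' @param dims grid dimensions (3 integers).
#' @param connectivity 6 or 26.
#' @return integer vector of cluster labels parallel to `idx` (labels are
#'   ordered by decreasing cluster size; ties by smallest member index).
#' @export
label_components <- function(idx, dims, connectivity = 6) {
  if (length(idx) == 0) return(integer(0))
  stopifnot(connectivity %in% c(6, 26))
  co <- arrayInd(idx, dims)
  offs <- if (connectivity == 6) {
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
    # keep one of each +/- pair
    g[g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
        (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0), , drop = FALSE]
  }
  pos <- match(idx, idx)  # identity; idx assumed unique
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[r, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
      nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
    lin <- (nb[ok, 3] - 1) * dims[1] * dims[2] + (nb[ok, 2] - 1) * dims[1] +
      nb[ok, 1]
    hit <- match(lin, idx)
    from <- which(ok)[!is.na(hit)]
    to <- hit[!is.na(hit)]
    if (length(from)) edges <- rbind(edges, cbind(from, to))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  # relabel by decreasing size, ties by smallest member voxel index
  sizes <- tabulate(comp)
  first <- vapply(seq_along(sizes), function(c) min(idx[comp == c]),
                  numeric(1))
  ord <- order(-sizes, first)
  match(comp, ord)
}

#' Estimate the spatial smoothness of residual maps
#'
#' Variance-of-first-differences estimator in the Gaussian-kernel
#' convention: along each axis, `1 - rho1` is estimated by
#' `var(diff) / (2 var)` within the mask, and the equivalent smoothing-kernel
#' FWHM is `sqrt(2 ln 2) * voxel_size / sqrt(var(diff) / (2 var))`, averaged
#' over the supplied volumes.  For spatially independent noise this reads
#' about 1.18 voxel widths — the resolution floor of the sampled grid.
#'
#' @param volumes matrix voxels x volumes (>= 2 columns), e.g. residual maps.
#' @param grid a [volume_grid()].
#' @param mask logical voxel vector.
#' @return numeric length-3 vector of per-axis FWHM estimates in mm.
#' @export
estimate_smoothness <- function(volumes, grid, mask) {
  volumes <- as.matrix(volumes)
  if (ncol(volumes) < 2) stop("need at least 2 volumes", call. = FALSE)
  d <- grid$dims
  if (all(apply(volumes[mask, , drop = FALSE], 2,
                function(v) max(v) - min(v) == 0))) {
    warning("constant volumes: smoothness undefined")
    return(rep(NA_real_, 3))
  }
  maskarr <- array(mask, dim = d)
  out <- numeric(3)
  for (ax in 1:3) {
    # voxel pairs adjacent along this axis, both in-mask
    ind <- which(maskarr, arr.ind = TRUE)
    nb <- ind; nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= d[ax]
    ok[ok] <- maskarr[nb[ok, , drop = FALSE]]
    if (sum(ok) < 2) {
      warning(sprintf("mask thinner than 2 voxels along axis %d; excluded",
                      ax))
      out[ax] <- NA_real_
      next
    }
    i1 <- which(maskarr)[ok]
    co <- ind[ok, , drop = FALSE]; co[, ax] <- co[, ax] + 1L
    i2 <- (co[, 3] - 1) * d[1] * d[2] + (co[, 2] - 1) * d[1] + co[, 1]
    ratio <- vapply(seq_len(ncol(volumes)), function(j) {
      v <- volumes[, j]
      s2 <- stats::var(v[mask])
      if (s2 == 0) return(NA_real_)
      sd2 <- stats::var(v[i1] - v[i2]) # var of first differences
      min(sd2 / (2 * s2), 1)
    }, numeric(1))
    out[ax] <- sqrt(2 * log(2)) * grid$voxel_size[ax] /
      sqrt(mean(ratio, na.rm = TRUE))
  }
  out
}
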
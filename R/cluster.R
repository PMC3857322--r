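#' Spearman correlation distance between subjects
#'
#' Pairwise average-rank Spearman correlation over the feature vectors
#' (voxelwise betas inside the reliability mask), transformed to the
#' distance `d = 1 - rho`, so rank-identical patterns are at distance 0 and
#' perfectly anticorrelated patterns at distance 2.
#'
#' @param features subjects x voxels matrix (>= 3 voxels).
#' @return a `stats::dist` object over subjects.
#' @export
spearman_distance <- function(features) {
  features <- as.matrix(features)
  if (ncol(features) < 3) stop("need at least 3 voxels", call. = FALSE)
  const <- apply(features, 1, function(x) max(x) - min(x) == 0)
  if (any(const))
    stop(sprintf("constant feature vector for subject(s): %s",
                 paste(rownames(features)[const], collapse = ", ")),
         call. = FALSE)
  rho <- stats::cor(t(features), method = "spearman")
  stats::as.dist(1 - rho)
}

#' Complete-linkage hierarchical clustering of subjects
#'
#' Agglomerative clustering merging groups by their maximum pairwise
#' distance — a strict criterion chosen to yield well-separated clusters if
#' any exist.
#'
#' @param dist a `stats::dist` object, e.g. from [spearman_distance()].
#' @return a `stats::hclust` tree.
#' @export
complete_linkage_tree <- function(dist) {
  stopifnot(inherits(dist, "dist"))
  stats::hclust(dist, method = "complete")
}

#' Cut the tree and characterise the clusters
#'
#' Cuts the dendrogram into `k` clusters and summarises each cluster's
#' composition (n, DD/TD, sex counts, age and IQ mean +/- sd).  Age and IQ
#' of the two largest clusters are compared with Welch two-sample t tests.
#' A largest-merge-gap suggestion for `k` is reported alongside, but never
#' applied silently.
#'
#' @param tree a `stats::hclust` tree over the subjects.
#' @param k number of clusters, `1 <= k <= n`.
#' @param subjects the study's subject data frame (`id`, `group`, and
#'   optionally `sex`, `age_months`, `iq`).
#' @return A `cluster_result` list: `assignments` (named integer vector),
#'   `composition` (one row per cluster), `tests` (age/IQ t tests between
#'   the two largest clusters, if computable), `suggested_k`, `tree`.
#' @export
cut_and_characterize <- function(tree, k, subjects) {
  n <- length(tree$order)
  if (k < 1 || k > n) stop("k out of range", call. = FALSE)
  assignments <- stats::cutree(tree, k = k)
  subjects <- as.data.frame(subjects)
  if (!is.null(subjects$id) && !is.null(names(assignments)))
    subjects <- subjects[match(names(assignments), subjects$id), ,
                         drop = FALSE]
  msd <- function(x) if (is.null(x) || all(is.na(x))) NA_character_ else
    sprintf("%.2f (+/- %.2f)", mean(x, na.rm = TRUE),
            stats::sd(x, na.rm = TRUE))
  comp <- do.call(rbind, lapply(sort(unique(assignments)), function(cl) {
    s <- subjects[assignments == cl, , drop = FALSE]
    data.frame(cluster = cl, n = nrow(s),
               dd = sum(s$group == "DD"), td = sum(s$group == "TD"),
               m = if (!is.null(s$sex)) sum(s$sex == "m") else NA_integer_,
               f = if (!is.null(s$sex)) sum(s$sex == "f") else NA_integer_,
               age_months = msd(s$age_months), iq = msd(s$iq),
               stringsAsFactors = FALSE)
  }))
  sizes <- sort(table(assignments), decreasing = TRUE)
  tests <- NULL
  if (length(sizes) >= 2 && sizes[2] >= 2) {
    c1 <- as.integer(names(sizes)[1]); c2 <- as.integer(names(sizes)[2])
    tt <- function(col) {
      x <- subjects[[col]][assignments == c1]
      y <- subjects[[col]][assignments == c2]
      if (is.null(x) || sum(!is.na(x)) < 2 || sum(!is.na(y)) < 2) return(NULL)
      h <- stats::t.test(x, y)
      data.frame(variable = col, t = unname(h$statistic),
                 df = unname(h$parameter), p = h$p.value,
                 stringsAsFactors = FALSE)
    }
    tests <- do.call(rbind, Filter(Negate(is.null),
                                   list(tt("age_months"), tt("iq"))))
  }
  heights <- sort(tree$height, decreasing = TRUE)
  gaps <- -diff(heights)
  suggested_k <- if (length(gaps)) which.max(gaps) + 1L else 1L
  structure(list(assignments = assignments, composition = comp,
                 tests = tests, suggested_k = suggested_k, k = k,
                 tree = tree),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d (largest-gap suggestion: %d)\n",
              x$k, x$suggested_k))
  print(x$composition, row.names = FALSE)
  invisible(x)
}

#' Per-cluster group maps
#'
#' One-sample against-baseline t maps for each cluster of subjects, by
#' delegation to the second-level machinery.  Direct between-cluster
#' contrasts are refused by default: groups homogenised by clustering the
#' very data under test would make such contrasts circular.  Pass
#' `i_understand_circularity = TRUE` to obtain them anyway.
#'
#' @param dataset a [study_dataset()].
#' @param assignments named integer vector (subject id -> cluster).
#' @param task task label.
#' @param mask logical voxel vector.
#' @param clusters which clusters to map (default: all with >= 3 members;
#'   smaller ones are skipped with a warning).
#' @param contrast_pair optional length-2 integer vector of clusters to
#'   contrast directly; refused unless `i_understand_circularity`.
#' @param i_understand_circularity logical override for the direct contrast.
#' @param voxel_p voxel-level threshold carried on the maps.
#' @return named list of `stat_map` objects (one per cluster), plus
#'   `contrast` if a pair was requested and allowed.
#' @export
cluster_group_maps <- function(dataset, assignments, task,
                               mask = dataset$brain_mask, clusters = NULL,
                               contrast_pair = NULL,
                               i_understand_circularity = FALSE,
                               voxel_p = 0.01) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (!is.null(contrast_pair) && !i_understand_circularity)
    stop(paste("direct between-cluster contrasts after clustering the same",
               "data are circular; set i_understand_circularity = TRUE to",
               "override"), call. = FALSE)
  ids <- names(assignments)
  if (is.null(clusters)) clusters <- sort(unique(assignments))
  out <- list()
  for (cl in clusters) {
    members <- ids[assignments == cl]
    if (length(members) < 3) {
      warning(sprintf("cluster %d has %d member(s) (< 3); skipped", cl,
                      length(members)))
      next
    }
    keep <- dataset$subjects$id %in% members
    sub <- study_dataset(dataset$grid, dataset$subjects[keep, , drop = FALSE],
                         dataset$tasks,
                         dataset$betas[, keep, , , drop = FALSE],
                         brain_mask = dataset$brain_mask, roi = dataset$roi,
                         roi_table = dataset$roi_table)
    # one-sample over all cluster members regardless of diagnosis
    sub$subjects$group <- rep("DD", sum(keep))
    out[[paste0("cluster", cl)]] <-
      second_level_t(sub, task, "one_sample_DD", mask = mask,
                     voxel_p = voxel_p)
    out[[paste0("cluster", cl)]]$contrast <-
      sprintf("%s: cluster %d vs baseline", task, cl)
  }
  if (!is.null(contrast_pair) && i_understand_circularity) {
    keep <- assignments[ids] %in% contrast_pair
    members <- ids[keep]
    keep2 <- dataset$subjects$id %in% members
    sub <- study_dataset(dataset$grid,
                         dataset$subjects[keep2, , drop = FALSE],
                         dataset$tasks,
                         dataset$betas[, keep2, , , drop = FALSE],
                         brain_mask = dataset$brain_mask)
    grp <- assignments[sub$subjects$id]
    sub$subjects$group <- ifelse(grp == contrast_pair[1], "DD", "TD")
    out$contrast <- second_level_t(sub, task, "two_sample", mask = mask,
                                   voxel_p = voxel_p)
    out$contrast$contrast <- sprintf("%s: cluster %d - cluster %d", task,
                                     contrast_pair[1], contrast_pair[2])
  }
  out
}
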
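#' Crawford test for a deficit
#'
#' Modified t statistic comparing one case against a small control sample:
#' `t = (x - mean(controls)) / (sd(controls) * sqrt((n + 1) / n))` with
#' `df = n - 1`, referred to the Student t distribution (two-sided p).
#' Unlike a z score, the statistic accounts for the uncertainty of the
#' control mean and sd at small n; as n grows it converges to the z score.
#'
#' `x_case` may be a vector (e.g. one value per voxel); `controls` is then a
#' matrix with controls in rows and the same number of columns.
#'
#' @param x_case scalar or vector of case values.
#' @param controls numeric vector (one variable) or matrix
#'   (controls x variables) of control values; n >= 3.
#' @param df degrees of freedom; `n - 1` by default.  Exposed because some
#'   behavioural reports refer the statistic to other df; imaging analyses
#'   should leave the default.
#' @return list with `t`, `df`, `p` (two-sided), each parallel to `x_case`.
#' @examples
#' crawford_t(6, c(1, 2, 3, 4, 5))  # t = sqrt(3), df = 4
#' @export
crawford_t <- function(x_case, controls, df = NULL) {
  if (is.null(dim(controls))) controls <- matrix(controls, ncol = 1)
  n <- nrow(controls)
  if (n < 3) stop("need at least 3 controls", call. = FALSE)
  if (length(x_case) != ncol(controls))
    stop("`x_case` and `controls` disagree on the number of variables",
         call. = FALSE)
  m <- colMeans(controls)
  s <- sqrt(colSums((controls - rep(m, each = n))^2) / (n - 1))
  if (any(s == 0))
    stop("control sd is zero: Crawford t undefined", call. = FALSE)
  tval <- (x_case - m) / (s * sqrt((n + 1) / n))
  if (is.null(df)) df <- n - 1
  list(t = unname(tval), df = df, p = unname(2 * stats::pt(-abs(tval), df)))
}

#' Voxelwise single-case deviation maps
#'
#' Compares one patient's session-averaged beta image against the whole
#' control group with the Crawford t at every voxel of the reliability mask,
#' splits significant voxels (two-sided `p < voxel_p`) by sign into
#' over- and under-activation maps, and cluster-filters each directional map
#' at the extent `k_star` calibrated by [monte_carlo_cluster_extent()].
#'
#' @param case subject id; must not belong to the control (TD) group.
#' @param dataset a [study_dataset()].
#' @param task task label.
#' @param mask logical voxel vector (the reliability mask).
#' @param voxel_p voxel-level two-sided p threshold (default 0.01).
#' @param k_star minimum cluster extent (voxels) or a `cluster_threshold`;
#'   use 1 for no extent filtering.
#' @param connectivity 6 or 26.
#' @return A `single_case_result` list: `subject`, `task`, `t`, `df`, `p`
#'   (voxel fields, NA outside mask), `over`, `under` (logical fields after
#'   cluster filtering), `grid`.
#' @export
single_case_maps <- function(case, dataset, task, mask = dataset$brain_mask,
                             voxel_p = 0.01, k_star = 1, connectivity = 6) {
  stopifnot(inherits(dataset, "study_dataset"))
  si <- subject_index(dataset, case)
  if (dataset$subjects$group[si] == "TD")
    stop(sprintf("subject '%s' belongs to the control group", case),
         call. = FALSE)
  if (inherits(k_star, "cluster_threshold")) {
    if (!isTRUE(all.equal(k_star$voxel_p, voxel_p)))
      stop("voxel p of the calibrated threshold differs", call. = FALSE)
    connectivity <- k_star$connectivity
    k_star <- k_star$k_star
  }
  avg <- session_average(dataset)[, , task_index(dataset, task)]
  ctrl <- which(dataset$subjects$group == "TD")
  res <- crawford_t(avg[mask, si], t(avg[mask, ctrl, drop = FALSE]))
  nv <- nrow(avg)
  tf <- rep(NA_real_, nv); pf <- rep(NA_real_, nv)
  tf[mask] <- res$t; pf[mask] <- res$p
  d <- dataset$grid$dims
  directional <- function(sgn) {
    out <- rep(FALSE, nv)
    hit <- which(mask & !is.na(pf) & pf < voxel_p & sign(tf) == sgn)
    if (length(hit)) {
      lab <- label_components(hit, d, connectivity)
      keep <- as.integer(names(which(table(lab) >= k_star)))
      out[hit[lab %in% keep]] <- TRUE
    }
    out
  }
  structure(list(subject = case, task = task, t = tf, df = res$df, p = pf,
                 over = directional(1), under = directional(-1),
                 voxel_p = voxel_p, k_star = k_star, grid = dataset$grid),
            class = "single_case_result")
}

#' @export
print.single_case_result <- function(x, ...) {
  cat(sprintf(paste0("<single_case_result> %s / %s: %d over-, %d ",
                     "under-activated voxels (p < %.3g, k >= %d)\n"),
              x$subject, x$task, sum(x$over), sum(x$under), x$voxel_p,
              x$k_star))
  invisible(x)
}

#' Frequency-of-deviation map
#'
#' Voxelwise percentage of patients whose directional single-case map is
#' significant at that voxel: `100 * count / n`, so values are multiples of
#' `100 / n`.
#'
#' @param results list of `single_case_result` objects for one task.
#' @param direction `"over"` or `"under"`.
#' @return A `frequency_map` list: `pct` (voxel field), `direction`, `n`,
#'   `task`, `grid`.
#' @export
frequency_map <- function(results, direction = c("over", "under")) {
  direction <- match.arg(direction)
  if (!length(results)) stop("no results supplied", call. = FALSE)
  tasks <- unique(vapply(results, `[[`, character(1), "task"))
  if (length(tasks) != 1)
    stop("all results must share one task", call. = FALSE)
  count <- Reduce(`+`, lapply(results, function(r) as.numeric(r[[direction]])))
  structure(list(pct = 100 * count / length(results), direction = direction,
                 n = length(results), task = tasks,
                 grid = results[[1]]$grid),
            class = "frequency_map")
}
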
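#' Intraclass correlation ICC(2,1)
#'
#' Shrout-Fleiss two-way random-effects, single-measure intraclass
#' correlation from the two-way ANOVA decomposition of an n-subjects by
#' k-sessions matrix:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' where MSR, MSC and MSE are the subject, session and error mean squares.
#' The estimate may be negative; with zero total variance it is undefined
#' and `NaN` is returned.
#'
#' @param values numeric matrix, subjects in rows (n >= 3), sessions in
#'   columns (k >= 2), no missing entries.
#' @return scalar ICC(2,1) estimate.
#' @examples
#' icc_2_1(cbind(1:4, 2:5))  # 10/13
#' @export
icc_2_1 <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 3 || k < 2) stop("need n >= 3 subjects and k >= 2 sessions",
                           call. = FALSE)
  if (anyNA(values)) stop("missing entries are not allowed", call. = FALSE)
  gm <- mean(values)
  rm_ <- rowMeans(values)
  cm <- colMeans(values)
  sst <- sum((values - gm)^2)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (sst == 0 || den == 0) return(NaN)
  (msr - mse) / den
}

# Vectorised ICC(2,1) over voxels: x is [voxel, subject, session].
icc_field <- function(x) {
  d <- dim(x)
  n <- d[2]; k <- d[3]
  gm <- apply(x, 1, mean)
  rm_ <- apply(x, c(1, 2), mean)           # voxel x subject
  cm <- apply(x, c(1, 3), mean)            # voxel x session
  sst <- apply((x - array(gm, d))^2, 1, sum)
  ssr <- k * rowSums((rm_ - gm)^2)
  ssc <- n * rowSums((cm - gm)^2)
  sse <- pmax(sst - ssr - ssc, 0)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + k * (msc - mse) / n
  out <- (msr - mse) / den
  out[sst == 0 | den == 0] <- NaN
  out
}

#' Fisher-z average of correlation maps
#'
#' Correlations are clipped to `±(1 - 1e-7)`, transformed with `atanh`,
#' averaged with equal weights, and back-transformed with `tanh`.
#'
#' @param ... numeric vectors/fields of correlations on a common support.
#' @return combined correlation field.
#' @export
fisher_combine <- function(...) {
  maps <- list(...)
  if (length(maps) == 1 && is.list(maps[[1]]) && !is.numeric(maps[[1]]))
    maps <- maps[[1]]
  z <- lapply(maps, function(m) atanh(pmin(pmax(m, -(1 - 1e-7)), 1 - 1e-7)))
  tanh(Reduce(`+`, z) / length(z))
}

#' Build the combined reliability map and mask
#'
#' Per task, the voxelwise ICC(2,1) between the session-1 and session-2 beta
#' images across all subjects; the per-task maps are averaged with Fisher's
#' z transform into one common reliability map, and the mask keeps voxels
#' with combined ICC strictly greater than `threshold` (default 0.33, a
#' strict lower bound given the typically poor reliability of child fMRI).
#'
#' @param dataset a [study_dataset()] with two sessions per task.
#' @param tasks tasks to combine (default: all tasks of the dataset).
#' @param threshold inclusion threshold on the combined ICC.
#' @return A `reliability_map` list: `per_task` (named list of voxel ICC
#'   fields), `combined`, `mask` (logical), `threshold`, `grid`.
#' @export
build_reliability_mask <- function(dataset, tasks = dataset$tasks,
                                   threshold = 0.33) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (n_sessions(dataset) < 2)
    stop("reliability needs at least two sessions per task", call. = FALSE)
  per_task <- lapply(tasks, function(tk) {
    ti <- task_index(dataset, tk)
    x <- dataset$betas[, , ti, , drop = TRUE]   # voxel x subject x session
    icc <- rep(NaN, dim(dataset$betas)[1])
    icc[dataset$brain_mask] <- icc_field(x[dataset$brain_mask, , ,
                                           drop = FALSE])
    icc
  })
  names(per_task) <- tasks
  combined <- fisher_combine(per_task)
  mask <- !is.na(combined) & combined > threshold & dataset$brain_mask
  structure(list(per_task = per_task, combined = combined, mask = mask,
                 threshold = threshold, grid = dataset$grid),
            class = "reliability_map")
}

#' @export
print.reliability_map <- function(x, ...) {
  ok <- is.finite(x$combined)
  cat(sprintf(paste0("<reliability_map> %d tasks; median combined ICC %.3f; ",
                     "%d voxels above %.2f\n"),
              length(x$per_task), stats::median(x$combined[ok]),
              sum(x$mask), x$threshold))
  invisible(x)
}

#' Tabulate reliability levels
#'
#' Bins the combined ICC field into the conventional ranges — excluded
#' below 0.33, then "poor" `[0.33, 0.4)`, "fair" `[0.4, 0.6)`, "good"
#' `[0.6, 0.75)` and "excellent" `[0.75, 1]` — reporting absolute counts,
#' percentages of all in-brain voxels for the excluded/included split, and
#' percentages of included voxels for the four named levels, rounded to one
#' decimal.
#'
#' @param rmap a `reliability_map` from [build_reliability_mask()], or a
#'   plain numeric vector of combined ICC values (non-finite entries are
#'   dropped).
#' @return data frame with columns `range`, `label`, `absolute`,
#'   `relative_total_pct`, `relative_included_pct`.
#' @export
tabulate_reliability_bins <- function(rmap) {
  v <- if (inherits(rmap, "reliability_map")) rmap$combined else
    as.numeric(rmap)
  v <- v[is.finite(v)]
  total <- length(v)
  edges <- list(excluded = c(-1, 0.33), poor = c(0.33, 0.4),
                fair = c(0.4, 0.6), good = c(0.6, 0.75),
                excellent = c(0.75, 1))
  counts <- vapply(names(edges), function(nm) {
    e <- edges[[nm]]
    if (nm == "excellent") sum(v >= e[1] & v <= e[2]) else
      sum(v >= e[1] & v < e[2])
  }, numeric(1))
  included <- total - counts[["excluded"]]
  pct <- function(x, base) if (base > 0) round(100 * x / base, 1) else NA_real_
  data.frame(
    range = c("-1 <= ICC <= 1", "ICC < 0.33", "0.33 <= ICC <= 1",
              "0.33 <= ICC < 0.4", "0.4 <= ICC < 0.6", "0.6 <= ICC < 0.75",
              "0.75 <= ICC <= 1"),
    label = c("total", "excluded", "included", "poor", "fair", "good",
              "excellent"),
    absolute = c(total, counts[["excluded"]], included, counts[["poor"]],
                 counts[["fair"]], counts[["good"]], counts[["excellent"]]),
    relative_total_pct = c(100, pct(counts[["excluded"]], total),
                           pct(included, total), NA, NA, NA, NA),
    relative_included_pct = c(NA, NA, pct(included, included),
                              pct(counts[["poor"]], included),
                              pct(counts[["fair"]], included),
                              pct(counts[["good"]], included),
                              pct(counts[["excellent"]], included)),
    stringsAsFactors = FALSE)
}

#' Dice overlap of two binary maps
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 0 when both maps are empty.
#'
#' @param mapA,mapB logical fields on the same grid.
#' @return scalar in `[0, 1]`.
#' @export
dice_overlap <- function(mapA, mapB) {
  if (length(mapA) != length(mapB))
    stop("maps must share a grid", call. = FALSE)
  a <- as.logical(mapA); b <- as.logical(mapB)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(0)
  2 * sum(a & b) / denom
}
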
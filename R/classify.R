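#' Extract subject-by-feature matrices
#'
#' Features are the session-averaged beta values at the voxels of the
#' selected ROIs intersected with the reliability mask (or the whole mask
#' when `rois` is `NULL`), in increasing linear voxel order.  In
#' `"concatenated"` mode the two tasks' vectors are stacked, doubling the
#' feature length and weighting the tasks equally.
#'
#' @param dataset a [study_dataset()] carrying ROI labels if `rois` is used.
#' @param mask logical voxel vector (the reliability mask).
#' @param rois character vector of ROI names, or `NULL` for whole-brain.
#' @param task_mode one task label, or `"concatenated"` for both.
#' @param roi_mean reduce each ROI to its mean beta instead of voxelwise
#'   features (default `FALSE`).
#' @return numeric matrix subjects x features, rownames = subject ids.
#' @export
extract_features <- function(dataset, mask = dataset$brain_mask, rois = NULL,
                             task_mode = "concatenated", roi_mean = FALSE) {
  stopifnot(inherits(dataset, "study_dataset"))
  avg <- session_average(dataset)
  tasks <- if (identical(task_mode, "concatenated")) dataset$tasks else
    task_mode
  vox_sets <- if (is.null(rois)) {
    list(whole = which(mask))
  } else {
    if (is.null(dataset$roi)) stop("dataset has no ROI labels", call. = FALSE)
    sets <- lapply(rois, function(nm) {
      rid <- dataset$roi_table$id[dataset$roi_table$name == nm]
      if (!length(rid)) stop(sprintf("unknown ROI '%s'", nm), call. = FALSE)
      v <- which(dataset$roi == rid & mask)
      if (!length(v))
        stop(sprintf("ROI '%s' has no voxels inside the mask", nm),
             call. = FALSE)
      v
    })
    names(sets) <- rois
    sets
  }
  blocks <- list()
  for (tk in tasks) {
    a <- avg[, , task_index(dataset, tk)]
    for (nm in names(vox_sets)) {
      b <- t(a[vox_sets[[nm]], , drop = FALSE])
      if (roi_mean) b <- matrix(rowMeans(b), ncol = 1)
      blocks[[paste(tk, nm, sep = ".")]] <- b
    }
  }
  out <- do.call(cbind, blocks)
  rownames(out) <- dataset$subjects$id
  out
}

#' Leave-one-out linear SVM classification
#'
#' For each subject, features are standardised by the training fold's mean
#' and sd (leakage-free), a linear support vector machine with fixed cost 1
#' is fit on the remaining subjects, and the left-out subject is predicted.
#' DD is the positive class: sensitivity is the correct rate among DD,
#' specificity among TD, and the correct classification rate satisfies
#' `CCR = (sens * n_DD + spec * n_TD) / (n_DD + n_TD)` by construction.
#'
#' @param features subjects x features matrix.
#' @param labels factor or character vector of `"DD"`/`"TD"` labels.
#' @param cost SVM cost parameter (default 1; no tuning).
#' @return A `classification_result` list: `predictions` (per subject),
#'   `labels`, `ccr`, `sensitivity`, `specificity` (all in %), `n_dd`,
#'   `n_td`.
#' @export
loo_linear_svm <- function(features, labels, cost = 1) {
  features <- as.matrix(features)
  labels <- factor(as.character(labels), levels = c("TD", "DD"))
  if (anyNA(features)) stop("missing features", call. = FALSE)
  if (nlevels(droplevels(labels)) < 2 || min(table(labels)) < 2)
    stop("need at least 2 subjects per class", call. = FALSE)
  n <- nrow(features)
  pred <- character(n)
  for (i in seq_len(n)) {
    tr <- features[-i, , drop = FALSE]
    mu <- colMeans(tr)
    sd_ <- apply(tr, 2, stats::sd)
    sd_[sd_ == 0] <- 1
    trs <- sweep(sweep(tr, 2, mu), 2, sd_, "/")
    tes <- (features[i, ] - mu) / sd_
    fit <- e1071::svm(trs, droplevels(labels[-i]), kernel = "linear",
                      cost = cost, scale = FALSE)
    pred[i] <- as.character(stats::predict(fit, matrix(tes, nrow = 1)))
  }
  is_dd <- labels == "DD"
  sens <- 100 * mean(pred[is_dd] == "DD")
  spec <- 100 * mean(pred[!is_dd] == "TD")
  ccr <- 100 * mean(pred == as.character(labels))
  structure(list(predictions = pred, labels = as.character(labels),
                 ccr = ccr, sensitivity = sens, specificity = spec,
                 n_dd = sum(is_dd), n_td = sum(!is_dd)),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(paste0("<classification_result> CCR %.2f%% ",
                     "(sensitivity %.2f%%, specificity %.2f%%; %d DD / %d TD)\n"),
              x$ccr, x$sensitivity, x$specificity, x$n_dd, x$n_td))
  invisible(x)
}

#' Correct classification rate from class-wise rates
#'
#' `CCR = (sens * n_pos + spec * n_neg) / (n_pos + n_neg)` — the arithmetic
#' identity linking overall, patient-class and control-class rates.
#'
#' @param sens,spec sensitivity and specificity in percent.
#' @param n_pos,n_neg class sizes.
#' @return CCR in percent.
#' @examples
#' ccr_from_rates(75, 100, 16, 16)  # 87.5
#' @export
ccr_from_rates <- function(sens, spec, n_pos, n_neg) {
  stopifnot(sens >= 0, sens <= 100, spec >= 0, spec <= 100,
            n_pos > 0, n_neg > 0)
  (sens * n_pos + spec * n_neg) / (n_pos + n_neg)
}

#' Enumerate nonempty ROI subsets
#'
#' All `2^R - 1` nonempty subsets of the given ROI names, ordered by subset
#' size and then lexicographically within size.
#'
#' @param roi_names character vector (R <= 24).
#' @return list of character vectors.
#' @export
roi_subsets <- function(roi_names) {
  r <- length(roi_names)
  if (r < 1) stop("empty ROI set", call. = FALSE)
  if (r > 24) stop("subset enumeration capped at 24 ROIs", call. = FALSE)
  subs <- lapply(seq_len(2^r - 1), function(b)
    roi_names[bitwAnd(b, 2^(seq_len(r) - 1)) > 0])
  subs[order(lengths(subs),
             vapply(subs, function(s) paste(s, collapse = "|"),
                    character(1)))]
}

#' Exhaustive power-set ROI classification search
#'
#' Evaluates [loo_linear_svm()] on every nonempty subset of the ROI set —
#' the classic, optimal, and computationally expensive approach to ROI
#' selection.  Per-ROI feature blocks are extracted once and reused.  The
#' overall winner is the highest CCR, ties broken by smallest subset size,
#' then lexicographic ROI-name order; all tying subsets are reported.
#'
#' @param dataset a [study_dataset()] with ROI labels.
#' @param mask logical voxel vector (the reliability mask).
#' @param rois character vector of ROI names to search over.
#' @param task_mode one task label or `"concatenated"`.
#' @param max_rois refusal cap on the search width: `2^R - 1` grows
#'   exponentially and a 17-ROI search is hours-scale (default cap 10;
#'   override with `force = TRUE`).
#' @param force evaluate even if `length(rois) > max_rois`.
#' @param cost SVM cost parameter.
#' @return A `powerset_search_result` list: `results` (data frame subset /
#'   size / ccr / sensitivity / specificity), `best_by_size`, `winners`
#'   (character vector of tying subset strings), `best` (first winner as a
#'   vector of names), `n_evaluated`.
#' @export
powerset_search <- function(dataset, mask, rois, task_mode = "concatenated",
                            max_rois = 10, force = FALSE, cost = 1) {
  r <- length(rois)
  if (r > max_rois && !force)
    stop(sprintf(paste0("%d ROIs means %d subsets; estimated to be a long ",
                        "(hours-scale at 17 ROIs) run. Pass force = TRUE ",
                        "to proceed."), r, 2^r - 1), call. = FALSE)
  blocks <- lapply(rois, function(nm)
    extract_features(dataset, mask, nm, task_mode))
  names(blocks) <- rois
  labels <- dataset$subjects$group
  subs <- roi_subsets(rois)
  rows <- vector("list", length(subs))
  for (i in seq_along(subs)) {
    feats <- do.call(cbind, blocks[subs[[i]]])
    res <- loo_linear_svm(feats, labels, cost = cost)
    rows[[i]] <- data.frame(subset = paste(subs[[i]], collapse = "+"),
                            size = length(subs[[i]]), ccr = res$ccr,
                            sensitivity = res$sensitivity,
                            specificity = res$specificity,
                            stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  best_by_size <- do.call(rbind, lapply(split(results, results$size),
    function(d) {
      b <- max(d$ccr)
      data.frame(size = d$size[1], best_ccr = b,
                 n_argmax = sum(d$ccr == b),
                 subsets = paste(d$subset[d$ccr == b], collapse = "; "),
                 stringsAsFactors = FALSE)
    }))
  rownames(best_by_size) <- NULL
  top <- results[results$ccr == max(results$ccr), , drop = FALSE]
  top <- top[top$size == min(top$size), , drop = FALSE]
  top <- top[order(top$subset), , drop = FALSE]
  structure(list(results = results, best_by_size = best_by_size,
                 winners = top$subset,
                 best = strsplit(top$subset[1], "+", fixed = TRUE)[[1]],
                 best_ccr = top$ccr[1], n_evaluated = nrow(results),
                 task_mode = task_mode),
            class = "powerset_search_result")
}

#' @export
print.powerset_search_result <- function(x, ...) {
  cat(sprintf(paste0("<powerset_search_result> %d subsets (%s); best CCR ",
                     "%.2f%% with {%s}%s\n"),
              x$n_evaluated, x$task_mode, x$best_ccr,
              paste(x$best, collapse = ", "),
              if (length(x$winners) > 1)
                sprintf(" (+%d tie(s))", length(x$winners) - 1) else ""))
  invisible(x)
}
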
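#!/usr/bin/env Rscript
# Stage 6 — leave-one-out linear SVM classification, whole-brain and
# exhaustive ROI power set.
#
# Whole-brain: all reliability-masked voxelwise averaged betas as one
# feature vector, per task and concatenated.  ROI-based: every nonempty
# subset of an 8-ROI search set (255 subsets; the full 17-ROI power set of
# 131,071 subsets is supported but hours-scale, so the driver searches the
# configured subset).

source("analysis/common.R")

ds <- load_study()
mask <- load_mask(ds)
out <- file.path(cfg$out_dir, "classification")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

modes <- c("comparison", "calculation", "concatenated")

whole <- lapply(modes, function(mode) {
  r <- loo_linear_svm(extract_features(ds, mask, task_mode = mode),
                      ds$subjects$group)
  message(sprintf("whole-brain %-12s CCR %5.1f%% (sens %5.1f, spec %5.1f)",
                  mode, r$ccr, r$sensitivity, r$specificity))
  data.frame(mode = mode, features = "whole-brain", ccr = r$ccr,
             sensitivity = r$sensitivity, specificity = r$specificity)
})

roi_rows <- list(); ps_json <- list()
for (mode in modes) {
  ps <- powerset_search(ds, mask, cfg$search_rois, task_mode = mode)
  message(sprintf("power set  %-12s best CCR %5.1f%% with {%s} (%d subsets)",
                  mode, ps$best_ccr, paste(ps$best, collapse = ", "),
                  ps$n_evaluated))
  best <- ps$results[ps$results$subset == ps$winners[1], ]
  roi_rows[[mode]] <- data.frame(mode = mode,
                                 features = ps$winners[1], ccr = best$ccr,
                                 sensitivity = best$sensitivity,
                                 specificity = best$specificity)
  ps_json[[mode]] <- list(winners = ps$winners, best_ccr = ps$best_ccr,
                          n_evaluated = ps$n_evaluated,
                          best_by_size = ps$best_by_size)
}

summary <- rbind(do.call(rbind, whole), do.call(rbind, roi_rows))
print(summary, row.names = FALSE)
write_tsv(summary, file.path(out, "svm_summary.tsv"))
jsonlite::write_json(ps_json, file.path(out, "powerset.json"),
                     auto_unbox = TRUE, digits = NA)
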
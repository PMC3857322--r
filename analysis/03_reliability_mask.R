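#!/usr/bin/env Rscript
# Stage 3 — voxelwise reliability maps and the ICC mask.
#
# Per task, ICC(2,1) between sessions across all 32 children; the two maps
# are combined with Fisher's z transform and thresholded at combined
# ICC > 0.33.  All later inference is restricted to this mask.  The stage
# also writes a Table-1-style distribution of reliability levels and the
# Dice overlap of the two sessions' suprathreshold activation maps.

source("analysis/common.R")

ds <- load_study()
rmap <- build_reliability_mask(ds, threshold = cfg$icc_threshold)
print(rmap)

out <- file.path(cfg$out_dir, "reliability")
dir.create(out, showWarnings = FALSE, recursive = TRUE)
for (tk in names(rmap$per_task))
  write_map(ifelse(is.finite(rmap$per_task[[tk]]), rmap$per_task[[tk]], 0),
            ds$grid, file.path(out, paste0("icc_", tk, ".nii.gz")))
write_map(ifelse(is.finite(rmap$combined), rmap$combined, 0), ds$grid,
          file.path(out, "icc_combined.nii.gz"))
write_map(rmap$mask, ds$grid, file.path(out, "mask.nii.gz"))

tab <- tabulate_reliability_bins(rmap)
print(tab, row.names = FALSE)
write_tsv(tab, file.path(out, "reliability_bins.tsv"))

# test-retest Dice overlap of session-level activation maps (|z| of the
# session mean across subjects, thresholded), per task
dice <- vapply(ds$tasks, function(tk) {
  ti <- match(tk, ds$tasks)
  s1 <- rowMeans(ds$betas[, , ti, 1])
  s2 <- rowMeans(ds$betas[, , ti, 2])
  thr <- function(v) {
    z <- (v - mean(v[ds$brain_mask])) / sd(v[ds$brain_mask])
    ds$brain_mask & z > 1.64
  }
  dice_overlap(thr(s1), thr(s2))
}, numeric(1))
message("session-overlap Dice per task: ",
        paste(sprintf("%s %.2f", ds$tasks, dice), collapse = ", "))
write_tsv(data.frame(task = ds$tasks, dice = dice),
          file.path(out, "session_dice.tsv"))
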
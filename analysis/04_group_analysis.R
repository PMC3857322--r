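#!/usr/bin/env Rscript
# Stage 4 — second-level group maps with Monte-Carlo cluster correction.
#
# One-sample against-baseline maps per group and the direct DD-TD contrast,
# per task, restricted to the reliability mask, thresholded at voxel
# p < 0.01 two-sided and corrected at family-wise alpha 0.05 by the
# Monte-Carlo cluster-extent procedure (null smoothness estimated from the
# group residual maps).

source("analysis/common.R")

ds <- load_study()
mask <- load_mask(ds)
out <- file.path(cfg$out_dir, "group")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

avg <- session_average(ds)[, , 1]
fw <- estimate_smoothness(avg - rowMeans(avg), ds$grid, mask)
message(sprintf("estimated residual smoothness: %.1f / %.1f / %.1f mm",
                fw[1], fw[2], fw[3]))
kcal <- monte_carlo_cluster_extent(ds$grid, mask, fwhm = fw,
                                   voxel_p = cfg$voxel_p, alpha = cfg$alpha,
                                   iterations = cfg$mc_iterations,
                                   seed = cfg$seed + 4)
print(kcal)
jsonlite::write_json(kcal[c("k_star", "voxel_p", "alpha", "iterations",
                            "fwhm", "connectivity", "seed")],
                     file.path(out, "threshold_spec.json"),
                     auto_unbox = TRUE, digits = NA)

tables <- list()
for (task in ds$tasks) {
  for (mode in c("one_sample_TD", "one_sample_DD", "two_sample")) {
    sm <- second_level_t(ds, task, mode, mask = mask, voxel_p = cfg$voxel_p)
    thr <- apply_cluster_threshold(sm, kcal)
    tag <- paste0(task, "_", mode)
    write_map(ifelse(is.na(sm$t), 0, sm$t), ds$grid,
              file.path(out, paste0(tag, "_t.nii.gz")))
    write_map(thr$surviving, ds$grid,
              file.path(out, paste0(tag, "_thresholded.nii.gz")))
    if (nrow(thr$table)) {
      thr$table$task <- task; thr$table$contrast <- mode
      tables[[tag]] <- thr$table
    }
    message(sprintf("%-28s max|t| %5.1f, %2d surviving cluster(s)",
                    tag, max(abs(sm$t), na.rm = TRUE), nrow(thr$table)))
  }
}
clusters <- if (length(tables)) do.call(rbind, tables) else
  data.frame(cluster = integer(0))
write_tsv(clusters, file.path(out, "cluster_table.tsv"))
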
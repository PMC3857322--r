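#!/usr/bin/env Rscript
# Stage 5 — single-case deviation maps and frequency-of-deviation maps.
#
# Every DD child is compared voxelwise against the 16 controls with the
# Crawford test for a deficit on the session-averaged betas (two-sided
# p < 0.01, split by sign, cluster-extent corrected with the same
# calibration as the group maps).  Per task and direction, the frequency
# map gives the percentage of patients deviating at each voxel.

source("analysis/common.R")

ds <- load_study()
mask <- load_mask(ds)
out <- file.path(cfg$out_dir, "single_case")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- jsonlite::read_json(file.path(cfg$out_dir, "group",
                                      "threshold_spec.json"))
k_star <- spec$k_star
message("cluster-extent threshold k* = ", k_star)

dd_ids <- ds$subjects$id[ds$subjects$group == "DD"]
summary_rows <- list()
for (task in ds$tasks) {
  results <- lapply(dd_ids, single_case_maps, ds, task, mask = mask,
                    voxel_p = cfg$voxel_p, k_star = k_star)
  names(results) <- dd_ids
  for (id in dd_ids) {
    r <- results[[id]]
    write_map(ifelse(is.na(r$t), 0, r$t), ds$grid,
              file.path(out, sprintf("%s_%s_t.nii.gz", id, task)))
    summary_rows[[paste(id, task)]] <- data.frame(
      case = id, task = task, n_over = sum(r$over), n_under = sum(r$under))
  }
  for (dir in c("over", "under")) {
    fm <- frequency_map(results, dir)
    write_map(fm$pct, ds$grid,
              file.path(out, sprintf("frequency_%s_%s.nii.gz", task, dir)))
    message(sprintf("%s/%s: max frequency %.1f%% (%d of %d children)",
                    task, dir, max(fm$pct), max(fm$pct) * fm$n / 100, fm$n))
  }
  n_dev <- sum(vapply(results, function(r) sum(r$over) + sum(r$under) > 0,
                      logical(1)))
  message(sprintf("%s: %d of %d patients show significant deviations",
                  task, n_dev, length(dd_ids)))
}
write_tsv(do.call(rbind, summary_rows), file.path(out, "summary.tsv"))
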
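#!/usr/bin/env Rscript
# Stage 7 — hierarchical clustering of children on activation patterns.
#
# Complete-linkage clustering on Spearman-correlation distances over all
# reliability-masked voxels, per task and with both tasks concatenated;
# composition tables for the cut at k clusters, and per-cluster
# against-baseline group maps (direct between-cluster contrasts are
# refused as circular).

source("analysis/common.R")

ds <- load_study()
mask <- load_mask(ds)
out <- file.path(cfg$out_dir, "clustering")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (mode in c("comparison", "calculation", "concatenated")) {
  f <- extract_features(ds, mask, task_mode = mode)
  tr <- complete_linkage_tree(spearman_distance(f))
  cr <- cut_and_characterize(tr, cfg$k_clusters, ds$subjects)
  message("== ", mode, " (largest-gap suggestion: k = ", cr$suggested_k, ")")
  print(cr$composition, row.names = FALSE)
  if (!is.null(cr$tests)) print(cr$tests, row.names = FALSE)

  write_tsv(data.frame(subject = names(cr$assignments),
                       cluster = cr$assignments),
            file.path(out, paste0("assignments_", mode, ".tsv")))
  write_tsv(cr$composition, file.path(out, paste0("composition_", mode, ".tsv")))
  write_tsv(data.frame(merge1 = tr$merge[, 1], merge2 = tr$merge[, 2],
                       height = tr$height),
            file.path(out, paste0("linkage_", mode, ".tsv")))
  pdf(file.path(out, paste0("dendrogram_", mode, ".pdf")), width = 8,
      height = 5)
  labs <- paste0(ifelse(ds$subjects$group == "DD", "D", "C"),
                 seq_len(nrow(ds$subjects)))
  plot(tr, labels = labs, main = paste("complete linkage,", mode),
       xlab = "", sub = "", ylab = "1 - Spearman rho")
  dev.off()

  if (mode == "concatenated") {
    maps <- cluster_group_maps(ds, cr$assignments, "comparison", mask = mask)
    for (nm in names(maps))
      write_map(ifelse(is.na(maps[[nm]]$t), 0, maps[[nm]]$t), ds$grid,
                file.path(out, paste0(nm, "_t.nii.gz")))
    message("per-cluster baseline maps: ", paste(names(maps), collapse = ", "))
  }
}
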
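# Shared configuration for the numbered analysis drivers.  Each script can
# be run from the repository root with:  Rscript analysis/0X_*.R
library(reliacase)

cfg <- list(
  seed        = 20260922L,
  n_dd        = 16L,
  n_td        = 16L,
  sigma_b     = 1,        # between-subject amplitude sd (beta units)
  sigma_e     = 1,        # session-noise sd; planted ICC = 0.5
  effect_roi  = "vIPS_L", # group-constant DD-TD shift lives here
  effect_shift = 2.5,
  het_rois    = c("aPCL_B", "aFOP_L", "aFOP_R", "CINS_B", "hIPS_L"),
  het_shift   = 5,        # single-case deviations, in control-sd units
  search_rois = c("vIPS_L", "THA_L", "THA_R", "hIPS_R", "aIPS_R", "PCL_L",
                  "CING_R", "vPMC_L"),
  icc_threshold = 0.33,
  voxel_p     = 0.01,
  alpha       = 0.05,
  mc_iterations = 1000L,
  k_clusters  = 2L,
  study_dir   = "results/study",
  out_dir     = "results"
)
dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

load_study <- function() {
  read_study(file.path(cfg$study_dir, "manifest.tsv"),
             file.path(cfg$study_dir, "subjects.tsv"),
             mask_path = file.path(cfg$study_dir, "brain_mask.nii.gz"),
             roi_path = file.path(cfg$study_dir, "roi_labels.nii.gz"),
             roi_table_path = file.path(cfg$study_dir, "roi_table.tsv"))
}

load_mask <- function(study) {
  p <- file.path(cfg$out_dir, "reliability", "mask.nii.gz")
  if (!file.exists(p))
    stop("run analysis/03_reliability_mask.R first", call. = FALSE)
  as.vector(read_map(p)$volume) > 0.5
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  message("wrote ", path)
}
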
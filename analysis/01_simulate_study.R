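#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic test-retest study.
#
# 16 dyscalculic (DD) and 16 control (TD) children, two tasks (non-symbolic
# comparison and calculation), two sessions, on a 30x36x30 grid at 3 mm.
# Between-subject and session-noise sds are equal, so the planted voxelwise
# ICC(2,1) is 0.5 — the "fair" reliability level typical of a careful child
# fMRI protocol.  Group structure: a homogeneous DD-TD shift in one
# intraparietal ROI, plus heterogeneous per-patient deviations (1-3 random
# ROIs at +5 control sds each) whose overlap across patients is low.

source("analysis/common.R")

ds <- simulate_beta_dataset(
  n_dd = cfg$n_dd, n_td = cfg$n_td,
  sigma_b = cfg$sigma_b, sigma_e = cfg$sigma_e,
  effect_table = data.frame(roi = cfg$effect_roi, shift = cfg$effect_shift),
  heterogeneity = TRUE, het_rois = cfg$het_rois, het_shift = cfg$het_shift,
  seed = cfg$seed)

print(ds)
message("planted expected ICC: ", ds$truth$expected_icc)
message("patients' deviant ROIs:")
for (id in ds$subjects$id[ds$subjects$group == "DD"])
  message("  ", id, ": ", paste(ds$truth$het_assignments[[id]],
                                collapse = ", "))

write_study(ds, cfg$study_dir)
message("study written to ", cfg$study_dir)
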
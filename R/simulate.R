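#' Default synthetic study grid
#'
#' 30 x 36 x 30 voxels at 3 mm isotropic, matching the working resolution of
#' a typical child fMRI study resampled to 3 x 3 x 3 mm^3.
#' @return a [volume_grid()].
#' @export
default_grid <- function() volume_grid(c(30L, 36L, 30L), c(3, 3, 3))

#' Synthetic brain mask
#'
#' A superellipsoid (exponent 2.5) filling most of the grid, giving on the
#' order of 19k in-mask voxels on the [default_grid()] — the scale of a
#' smoothed whole-brain mask at 3 mm.
#'
#' @param grid a [volume_grid()].
#' @param fill fraction of each half-axis covered by the mask.
#' @return logical vector over voxels.
#' @export
make_brain_mask <- function(grid, fill = 0.96) {
  d <- grid$dims
  ax <- (d - 1) / 2 * fill
  ix <- (seq_len(d[1]) - 1 - (d[1] - 1) / 2) / ax[1]
  iy <- (seq_len(d[2]) - 1 - (d[2] - 1) / 2) / ax[2]
  iz <- (seq_len(d[3]) - 1 - (d[3] - 1) / 2) / ax[3]
  p <- 2.5
  r <- outer(outer(abs(ix)^p, abs(iy)^p, `+`), abs(iz)^p, `+`)
  as.vector(r <= 1)
}

#' Synthetic ROI atlas with Table-2-style names
#'
#' Places 17 disjoint spherical regions of interest (radius `radius` voxels)
#' inside the brain mask at deterministic lattice positions, and names them
#' after the frontoparietal number-processing regions commonly used in this
#' literature (THA, vIPS, hIPS, aIPS, PCL, aPCL, aFOP, CINS, CING, vPMC with
#' hemisphere codes).  The geometry is synthetic: names are labels, not
#' anatomical claims.
#'
#' @param grid a [volume_grid()].
#' @param mask logical brain mask over voxels (default [make_brain_mask()]).
#' @param radius sphere radius in voxels.
#' @return list with `labels` (integer vector over voxels, 0 = unlabelled)
#'   and `table` (data frame `id`, `name`, `hemisphere`).
#' @export
make_roi_atlas <- function(grid, mask = make_brain_mask(grid), radius = 2) {
  d <- grid$dims
  names_l <- c("THA_L", "vIPS_L", "hIPS_L", "aIPS_L", "PCL_L", "aFOP_L",
               "CING_L", "vPMC_L")
  names_r <- c("THA_R", "vIPS_R", "hIPS_R", "aIPS_R", "PCL_R", "aFOP_R",
               "CING_R")
  names_b <- c("aPCL_B", "CINS_B")
  # candidate sphere centres on a proportional interior lattice: two
  # parasagittal columns per hemisphere plus a midline column
  frac <- function(n, f) pmax(radius + 1L, pmin(n - radius, round(n * f)))
  xs_l <- unique(frac(d[1], c(0.28, 0.40)))
  xs_r <- unique(frac(d[1], c(0.62, 0.74)))
  xs_m <- unique(round((d[1] + 1) / 2))
  ys <- unique(frac(d[2], c(0.30, 0.50, 0.70)))
  zs <- unique(frac(d[3], c(0.36, 0.50, 0.64)))
  maskarr <- array(mask, dim = d)
  # sphere voxel offsets within Euclidean radius
  off <- expand.grid(dx = -radius:radius, dy = -radius:radius,
                     dz = -radius:radius)
  off <- off[off$dx^2 + off$dy^2 + off$dz^2 <= radius^2 + 0.5, ]
  # midline candidates sit on an offset lattice so they cannot collide with
  # the hemispheric columns
  ys_m <- unique(frac(d[2], c(0.22, 0.42, 0.62, 0.82)))
  zs_m <- unique(frac(d[3], c(0.29, 0.50, 0.71)))
  usable <- function(xset, ys, zs) {
    cand <- expand.grid(x = xset, y = ys, z = zs)
    fits <- vapply(seq_len(nrow(cand)), function(i) {
      xs2 <- cand$x[i] + off$dx; ys2 <- cand$y[i] + off$dy
      zs2 <- cand$z[i] + off$dz
      all(xs2 >= 1, xs2 <= d[1], ys2 >= 1, ys2 <= d[2], zs2 >= 1,
          zs2 <= d[3]) && all(maskarr[cbind(xs2, ys2, zs2)])
    }, logical(1))
    cand <- cand[fits, , drop = FALSE]
    # centre-out ordering keeps spheres well inside the mask
    cand[order(abs(cand$z - (d[3] + 1) / 2), abs(cand$y - (d[2] + 1) / 2),
               cand$x), , drop = FALSE]
  }
  left <- usable(xs_l, ys, zs)
  right <- usable(xs_r, ys, zs)
  mid <- usable(xs_m, ys_m, zs_m)
  picked <- NULL
  pick <- function(cand, k) {
    sel <- NULL
    for (i in seq_len(nrow(cand))) {
      p <- as.numeric(cand[i, ])
      all_prev <- rbind(picked, sel)
      if (is.null(all_prev) ||
          all(sqrt(rowSums(sweep(all_prev, 2, p)^2)) >= 2 * radius + 1)) {
        sel <- rbind(sel, p)
        if (nrow(sel) == k) break
      }
    }
    if (is.null(sel) || nrow(sel) < k)
      stop("grid too small to place the 17 default ROIs", call. = FALSE)
    picked <<- rbind(picked, sel)
    sel
  }
  centres <- as.data.frame(rbind(pick(as.matrix(left), length(names_l)),
                                 pick(as.matrix(right), length(names_r)),
                                 pick(as.matrix(mid), length(names_b))))
  names(centres) <- c("x", "y", "z")
  tab <- data.frame(id = seq_len(17L),
                    name = c(names_l, names_r, names_b),
                    hemisphere = c(rep("L", length(names_l)),
                                   rep("R", length(names_r)),
                                   rep("B", length(names_b))),
                    stringsAsFactors = FALSE)
  labels <- integer(prod(d))
  for (i in seq_len(nrow(centres))) {
    xs <- centres$x[i] + off$dx; ys <- centres$y[i] + off$dy
    zs <- centres$z[i] + off$dz
    lin <- (zs - 1) * d[1] * d[2] + (ys - 1) * d[1] + xs
    labels[lin] <- i
  }
  list(labels = labels, table = tab)
}

#' Generate a self-paced block design
#'
#' Emulates a self-paced paradigm in which each trial lasts as long as the
#' subject's response.  The comparison task has 4 blocks of 6 trials, the
#' calculation task 6 blocks of 4 trials; trials within a block are separated
#' by a 0.5 s interstimulus interval and every block is followed by a 14 s
#' resting baseline (the run also opens with one baseline period).  Trial
#' durations are drawn from a lognormal response-time model, so block
#' durations — and hence total volume counts — vary across subjects.
#'
#' @param task `"comparison"` or `"calculation"`.
#' @param rt_meanlog,rt_sdlog lognormal response-time parameters (seconds).
#'   Defaults give median RTs of about 1.2 s (comparison) and 4.1 s
#'   (calculation).
#' @param tr repetition time in seconds.
#' @param isi interstimulus interval within a block, seconds.
#' @param baseline rest duration after each block, seconds.
#' @param seed integer seed; one seed per simulated subject/run.
#' @return A `design_spec` list: task, block `onsets` and `durations`
#'   (seconds), `trial_rts`, `tr`, `total_volumes`.
#' @export
make_self_paced_design <- function(task = c("comparison", "calculation"),
                                   rt_meanlog = NULL, rt_sdlog = 0.35,
                                   tr = 1.6, isi = 0.5, baseline = 14,
                                   seed = NULL) {
  task <- match.arg(task)
  layout <- switch(task,
                   comparison = c(blocks = 4L, trials = 6L),
                   calculation = c(blocks = 6L, trials = 4L))
  if (is.null(rt_meanlog))
    rt_meanlog <- switch(task, comparison = log(1.2), calculation = log(4.1))
  if (!is.null(seed)) set.seed(seed)
  onsets <- numeric(layout["blocks"])
  durations <- numeric(layout["blocks"])
  trial_rts <- vector("list", layout["blocks"])
  t <- baseline
  for (b in seq_len(layout["blocks"])) {
    rts <- stats::rlnorm(layout["trials"], rt_meanlog, rt_sdlog)
    while (any(rts <= 0))  # lognormal is positive; guard kept for custom models
      rts[rts <= 0] <- stats::rlnorm(sum(rts <= 0), rt_meanlog, rt_sdlog)
    dur <- sum(rts) + (layout["trials"] - 1) * isi
    onsets[b] <- t
    durations[b] <- dur
    trial_rts[[b]] <- rts
    t <- t + dur + baseline
  }
  structure(list(task = task, onsets = onsets, durations = durations,
                 trial_rts = trial_rts, n_blocks = unname(layout["blocks"]),
                 trials_per_block = unname(layout["trials"]), isi = isi,
                 baseline = baseline, tr = tr,
                 total_volumes = as.integer(ceiling(t / tr))),
            class = "design_spec")
}

#' Simulate a BOLD time series for one run
#'
#' Signal is the HRF-convolved block regressor (unit peak) scaled by a
#' per-voxel amplitude, plus motion-coupled nuisance and AR(1) Gaussian
#' noise.  A 6-column motion-parameter table (smoothed random walks) aligned
#' to the volumes is returned alongside the data, so the first-level GLM can
#' be exercised exactly as on real data.
#'
#' @param design a `design_spec` from [make_self_paced_design()].
#' @param amplitude per-voxel signal amplitude (recycled scalar allowed); the
#'   first-level GLM recovers this value as the task beta.
#' @param sigma noise standard deviation (innovation scale is derived so the
#'   stationary AR(1) sd equals `sigma`).
#' @param rho AR(1) coefficient, `|rho| < 1`.
#' @param motion_amp coupling amplitude of the motion nuisance into the data.
#' @param n_voxels number of voxels to simulate (a flat voxel list; attach to
#'   a grid only if writing to disk).
#' @param seed integer seed.
#' @return list with `data` (volumes x voxels matrix), `motion` (volumes x 6
#'   data frame) and `design`.
#' @export
simulate_timeseries <- function(design, amplitude = 1, sigma = 1, rho = 0.3,
                                motion_amp = 0, n_voxels = 1, seed = NULL) {
  stopifnot(inherits(design, "design_spec"))
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tn <- design$total_volumes
  reg <- task_regressor(design)
  amplitude <- rep_len(amplitude, n_voxels)
  motion <- vapply(1:6, function(j) {
    w <- cumsum(stats::rnorm(tn, 0, 0.02))
    as.numeric(stats::filter(w, rep(1 / 5, 5), sides = 2, circular = TRUE))
  }, numeric(tn))
  colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  coup <- matrix(stats::rnorm(6 * n_voxels), 6, n_voxels) * motion_amp
  innov_sd <- sigma * sqrt(1 - rho^2)
  noise <- matrix(stats::rnorm(tn * n_voxels, 0, innov_sd), tn, n_voxels)
  if (rho != 0) {
    noise[1, ] <- noise[1, ] / sqrt(1 - rho^2)  # stationary start-up
    noise <- apply(noise, 2, function(e)
      as.numeric(stats::filter(e, rho, method = "recursive")))
    noise <- matrix(noise, tn, n_voxels)
  }
  data <- outer(reg, amplitude) + motion %*% coup + noise
  list(data = data, motion = as.data.frame(motion), design = design)
}

#' Simulate a test-retest beta-map study
#'
#' Generates contrast beta volumes directly at the level the pipeline
#' consumes: for voxel v, subject s, session k,
#' `beta = mu_group(v) + b_s(v) + e_sk(v)` with subject effects
#' `b ~ N(0, sigma_b^2)` (drawn independently per task) and session noise
#' `e ~ N(0, sigma_e^2)`, so the expected voxelwise ICC(2,1) is
#' `sigma_b^2 / (sigma_b^2 + sigma_e^2)` wherever group offsets are constant
#' within group.
#'
#' Two kinds of group structure can be planted:
#' * `effect_table`: a data frame `(roi, shift)` adding a group-constant
#'   DD-minus-TD mean shift (beta units) inside named ROIs — the homogeneous
#'   group effect detected by two-sample maps and classifiers.
#' * `heterogeneity = TRUE`: each DD subject draws `m ~ uniform{1..3}`
#'   affected ROIs from `het_rois` and receives a subject-specific shift of
#'   `het_shift` control standard deviations (sd of session-averaged betas,
#'   `sqrt(sigma_b^2 + sigma_e^2/2)`) there — the heterogeneous single-case
#'   deviations whose overlap across patients is low.
#' * `pattern_sd > 0`: each group receives its own distributed activation
#'   profile, drawn once per group and task as `N(0, pattern_sd^2)` over all
#'   in-mask voxels and shared by every group member.  This plants a
#'   two-cluster structure in which within-group pattern correlations
#'   dominate between-group ones (within-cluster rho approximately
#'   `pattern_sd^2 / (pattern_sd^2 + sigma_b^2 + sigma_e^2/2)` on averaged
#'   betas, between-cluster 0) — the regime in which activation-pattern
#'   clustering is informative.
#'
#' @param n_dd,n_td subjects per group (>= 2).
#' @param grid a [volume_grid()].
#' @param tasks task labels (default the two study tasks).
#' @param n_sessions sessions per task (default 2: test and retest).
#' @param sigma_b,sigma_e between-subject and session-noise sd (beta units).
#' @param effect_table optional data frame `(roi, shift)`; `roi` are names in
#'   the atlas table.
#' @param heterogeneity logical; plant per-DD-subject ROI deviations.
#' @param het_rois pool of ROI names for heterogeneity (default: all).
#' @param het_shift deviation magnitude in control-sd units (default 5).
#' @param pattern_sd sd of the group-specific distributed activation profile
#'   (beta units; default 0 = no planted partition).
#' @param atlas output of [make_roi_atlas()]; built on demand.
#' @param mask brain mask (default [make_brain_mask()]).
#' @param seed integer seed.
#' @return A [study_dataset()] whose `truth` field records every generative
#'   parameter, including `expected_icc` and the per-subject heterogeneity
#'   assignments.
#' @export
simulate_beta_dataset <- function(n_dd = 16, n_td = 16, grid = default_grid(),
                                  tasks = c("comparison", "calculation"),
                                  n_sessions = 2, sigma_b = 1, sigma_e = 1,
                                  effect_table = NULL, heterogeneity = FALSE,
                                  het_rois = NULL, het_shift = 5,
                                  pattern_sd = 0, atlas = NULL, mask = NULL,
                                  seed = 1) {
  if (n_dd < 2 || n_td < 2) stop("need at least 2 subjects per group",
                                 call. = FALSE)
  if (sigma_b < 0 || sigma_e < 0) stop("sigmas must be >= 0", call. = FALSE)
  if (is.null(mask)) mask <- make_brain_mask(grid)
  # the atlas is only needed when effects are planted in ROIs; small test
  # grids without planted effects need not host the full 17-ROI layout
  if (is.null(atlas) && (heterogeneity || !is.null(effect_table)))
    atlas <- make_roi_atlas(grid, mask)
  if (!is.null(atlas)) {
    if (length(atlas$labels) != prod(grid$dims))
      stop("ROI labels do not match the grid", call. = FALSE)
    if (!is.null(effect_table) &&
        !all(effect_table$roi %in% atlas$table$name))
      stop("effect_table references unknown ROI names", call. = FALSE)
  }
  set.seed(seed)

  n <- n_dd + n_td
  subjects <- data.frame(
    id = sprintf("sub%02d", seq_len(n)),
    group = c(rep("DD", n_dd), rep("TD", n_td)),
    age_months = sample(83:117, n, replace = TRUE),
    iq = as.integer(round(stats::rnorm(n, 100, 12))),
    sex = sample(c("m", "f"), n, replace = TRUE),
    stringsAsFactors = FALSE)

  nv <- prod(grid$dims)
  vox_in <- which(mask)
  mu_dd <- numeric(nv)
  if (!is.null(effect_table)) {
    for (r in seq_len(nrow(effect_table))) {
      rid <- atlas$table$id[atlas$table$name == effect_table$roi[r]]
      mu_dd[atlas$labels == rid] <- mu_dd[atlas$labels == rid] +
        effect_table$shift[r]
    }
  }
  het_assign <- NULL
  het_delta <- numeric(nv * n)  # [voxel, subject] column-major
  dim(het_delta) <- c(nv, n)
  if (heterogeneity) {
    if (is.null(het_rois)) het_rois <- atlas$table$name
    sd_avg <- sqrt(sigma_b^2 + sigma_e^2 / n_sessions)
    het_assign <- vector("list", n)
    names(het_assign) <- subjects$id
    for (s in which(subjects$group == "DD")) {
      m <- sample(1:3, 1)
      picked <- sample(het_rois, min(m, length(het_rois)))
      het_assign[[s]] <- picked
      for (nm in picked) {
        rid <- atlas$table$id[atlas$table$name == nm]
        het_delta[atlas$labels == rid, s] <-
          het_delta[atlas$labels == rid, s] + het_shift * sd_avg
      }
    }
  }

  betas <- array(0, dim = c(nv, n, length(tasks), n_sessions))
  for (tk in seq_along(tasks)) {
    b <- matrix(stats::rnorm(nv * n, 0, sigma_b), nv, n)
    base <- b + het_delta
    base[, subjects$group == "DD"] <- base[, subjects$group == "DD"] + mu_dd
    if (pattern_sd > 0) {
      pat_dd <- stats::rnorm(nv, 0, pattern_sd)
      pat_td <- stats::rnorm(nv, 0, pattern_sd)
      base <- base + outer(pat_dd, as.numeric(subjects$group == "DD")) +
        outer(pat_td, as.numeric(subjects$group == "TD"))
    }
    for (k in seq_len(n_sessions))
      betas[, , tk, k] <- base + matrix(stats::rnorm(nv * n, 0, sigma_e),
                                        nv, n)
  }
  betas[!mask, , , ] <- 0
  if (is.null(atlas)) atlas <- list(labels = NULL, table = NULL)

  truth <- list(sigma_b = sigma_b, sigma_e = sigma_e,
                expected_icc = if (sigma_b + sigma_e > 0)
                  sigma_b^2 / (sigma_b^2 + sigma_e^2) else NA_real_,
                effect_table = effect_table, pattern_sd = pattern_sd,
                heterogeneity = heterogeneity,
                het_assignments = het_assign, het_shift = het_shift,
                seed = seed)
  study_dataset(grid, subjects, tasks, betas, brain_mask = mask,
                roi = atlas$labels, roi_table = atlas$table, truth = truth)
}
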
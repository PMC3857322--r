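#' Assemble a study dataset in memory
#'
#' A `study_dataset` is the central container of the pipeline: per-subject,
#' per-task, per-session contrast (beta) volumes on one shared grid, together
#' with subject metadata and, optionally, a region-of-interest label field
#' and the generative truth of a simulation.
#'
#' Betas are held as a 4D numeric array `[voxel, subject, task, session]`
#' with voxels in column-major linear order over the grid.  `session = "avg"`
#' volumes produced by [average_sessions()] are stored separately by
#' downstream code; the container itself holds the raw sessions.
#'
#' @param grid a [volume_grid()].
#' @param subjects data frame with at least columns `id` (unique character)
#'   and `group` (each `"DD"` or `"TD"`); optional `age_months`, `iq`, `sex`.
#' @param tasks character vector of task labels.
#' @param betas numeric array `[n_voxel, n_subject, n_task, n_session]`.
#' @param brain_mask logical vector over voxels; defaults to all `TRUE`.
#' @param roi optional integer vector of ROI labels over voxels (0 = none).
#' @param roi_table optional data frame `(id, name, hemisphere)` describing
#'   the labels in `roi`.
#' @param truth optional list of generative parameters (see
#'   [simulate_beta_dataset()]).
#' @return An object of class `study_dataset`.
#' @export
study_dataset <- function(grid, subjects, tasks, betas, brain_mask = NULL,
                          roi = NULL, roi_table = NULL, truth = NULL) {
  stopifnot(inherits(grid, "volume_grid"))
  nv <- prod(grid$dims)
  subjects <- as.data.frame(subjects)
  if (!all(c("id", "group") %in% names(subjects)))
    stop("`subjects` needs columns `id` and `group`", call. = FALSE)
  if (anyDuplicated(subjects$id))
    stop("duplicate subject ids", call. = FALSE)
  if (!all(subjects$group %in% c("DD", "TD")))
    stop("`group` must be 'DD' or 'TD'", call. = FALSE)
  d <- dim(betas)
  if (length(d) != 4L || d[1] != nv || d[2] != nrow(subjects) ||
      d[3] != length(tasks))
    stop("`betas` must be [n_voxel, n_subject, n_task, n_session]",
         call. = FALSE)
  if (is.null(brain_mask)) brain_mask <- rep(TRUE, nv)
  stopifnot(length(brain_mask) == nv)
  dimnames(betas) <- list(NULL, subjects$id, tasks,
                          paste0("s", seq_len(d[4])))
  structure(list(grid = grid, subjects = subjects, tasks = tasks,
                 betas = betas, brain_mask = as.logical(brain_mask),
                 roi = roi, roi_table = roi_table, truth = truth),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf(paste0("<study_dataset> %d subjects (%d DD / %d TD), ",
                     "%d task(s), %d session(s)\n  grid %s, %d in-mask voxels\n"),
              nrow(x$subjects), sum(x$subjects$group == "DD"),
              sum(x$subjects$group == "TD"), length(x$tasks),
              dim(x$betas)[4], format(x$grid), sum(x$brain_mask)))
  invisible(x)
}

n_sessions <- function(dataset) dim(dataset$betas)[4]

subject_index <- function(dataset, id) {
  i <- match(id, dataset$subjects$id)
  if (is.na(i)) stop(sprintf("unknown subject '%s'", id), call. = FALSE)
  i
}

task_index <- function(dataset, task) {
  i <- match(task, dataset$tasks)
  if (is.na(i)) stop(sprintf("unknown task '%s'", task), call. = FALSE)
  i
}

#' Read a study from disk
#'
#' Loads every run listed in a tab-separated manifest, verifies that all
#' volumes share one grid, and attaches subject metadata.
#'
#' The manifest must have a header row and columns `subject`, `task`,
#' `session` (1 or 2) and `beta_path` (absolute, or relative to the manifest
#' location).  The metadata file must have columns `id` and `group`
#' (`DD`/`TD`), optionally `age_months`, `iq`, `sex`.
#'
#' @param manifest_path path to the run manifest TSV, one row per run.
#' @param metadata_path path to the subject metadata TSV, one row per subject.
#' @param mask_path optional path to a 0/1 brain-mask NIfTI on the same grid.
#' @param roi_path optional path to an integer ROI label NIfTI; requires
#'   `roi_table_path`.
#' @param roi_table_path optional TSV with columns `id`, `name`, `hemisphere`.
#' @return A [study_dataset()].
#' @export
read_study <- function(manifest_path, metadata_path, mask_path = NULL,
                       roi_path = NULL, roi_table_path = NULL) {
  man <- utils::read.delim(manifest_path, sep = "\t",
                           stringsAsFactors = FALSE)
  if (nrow(man) == 0L) stop("no runs: manifest is empty", call. = FALSE)
  need <- c("subject", "task", "session", "beta_path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns subject, task, session, beta_path",
         call. = FALSE)
  key <- paste(man$subject, man$task, man$session)
  if (anyDuplicated(key))
    stop(sprintf("duplicate (subject, task, session) in manifest: %s",
                 key[duplicated(key)][1]), call. = FALSE)
  meta <- utils::read.delim(metadata_path, sep = "\t",
                            stringsAsFactors = FALSE)
  if (!all(unique(man$subject) %in% meta$id))
    stop("manifest lists subjects missing from metadata", call. = FALSE)
  meta <- meta[meta$id %in% man$subject, , drop = FALSE]

  root <- dirname(manifest_path)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(root, p))
  man$beta_path <- resolve(man$beta_path)

  tasks <- unique(man$task)         # manifest order of appearance
  sessions <- sort(unique(man$session))
  grid <- NULL
  betas <- NULL
  for (r in seq_len(nrow(man))) {
    p <- man$beta_path[r]
    if (!file.exists(p))
      stop(sprintf("manifest row %d (%s, %s, session %s): missing file '%s'",
                   r, man$subject[r], man$task[r], man$session[r], p),
           call. = FALSE)
    m <- read_map(p)
    if (is.null(grid)) {
      grid <- m$grid
      betas <- array(NA_real_, dim = c(prod(grid$dims), nrow(meta),
                                       length(tasks), length(sessions)))
    } else {
      stopifnot_same_grid(grid, m$grid,
                          sprintf("manifest row 1 and row %d", r))
    }
    betas[, match(man$subject[r], meta$id), match(man$task[r], tasks),
          match(man$session[r], sessions)] <- as.vector(m$volume)
  }
  if (anyNA(betas))
    stop("incomplete design: some (subject, task, session) runs are missing",
         call. = FALSE)

  brain_mask <- NULL
  if (!is.null(mask_path)) {
    m <- read_map(mask_path)
    stopifnot_same_grid(grid, m$grid, "study and brain mask")
    brain_mask <- as.vector(m$volume) > 0.5
  }
  roi <- NULL; roi_table <- NULL
  if (!is.null(roi_path)) {
    m <- read_map(roi_path)
    stopifnot_same_grid(grid, m$grid, "study and ROI labels")
    roi <- as.integer(round(as.vector(m$volume)))
    if (is.null(roi_table_path))
      stop("`roi_path` requires `roi_table_path`", call. = FALSE)
    roi_table <- utils::read.delim(roi_table_path, sep = "\t",
                                   stringsAsFactors = FALSE)
  }
  study_dataset(grid, meta, tasks, betas, brain_mask = brain_mask,
                roi = roi, roi_table = roi_table)
}

#' Write a study to disk
#'
#' Inverse of [read_study()]: writes one beta NIfTI per (subject, task,
#' session) plus manifest, metadata, brain mask, ROI volume/table and, for
#' simulated studies, the generative truth as JSON.
#'
#' @param dataset a [study_dataset()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_study <- function(dataset, dir) {
  stopifnot(inherits(dataset, "study_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(dataset$betas)
  rows <- list()
  for (s in seq_len(d[2])) for (tk in seq_len(d[3])) for (k in seq_len(d[4])) {
    fn <- sprintf("%s_%s_s%d_beta.nii.gz", dataset$subjects$id[s],
                  dataset$tasks[tk], k)
    write_map(dataset$betas[, s, tk, k], dataset$grid, file.path(dir, fn))
    rows[[length(rows) + 1L]] <- data.frame(
      subject = dataset$subjects$id[s], task = dataset$tasks[tk],
      session = k, beta_path = fn, stringsAsFactors = FALSE)
  }
  man <- do.call(rbind, rows)
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(dataset$subjects, file.path(dir, "subjects.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_map(dataset$brain_mask, dataset$grid, file.path(dir, "brain_mask.nii.gz"))
  if (!is.null(dataset$roi)) {
    write_map(as.numeric(dataset$roi), dataset$grid,
              file.path(dir, "roi_labels.nii.gz"))
    utils::write.table(dataset$roi_table, file.path(dir, "roi_table.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(dataset$truth)) {
    truth <- dataset$truth
    truth <- truth[!vapply(truth, is.function, logical(1))]
    truth <- lapply(truth, function(x) if (is.data.frame(x)) x else unname(x))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(dir)
}

#' Session-average a study's betas
#'
#' Voxelwise arithmetic mean over sessions for every subject and task;
#' this is the pipeline's working currency for all second-level,
#' single-case, classification and clustering steps.
#'
#' @param dataset a [study_dataset()].
#' @return numeric array `[voxel, subject, task]`.
#' @export
session_average <- function(dataset) {
  out <- dataset$betas[, , , 1, drop = FALSE]
  for (k in seq_len(n_sessions(dataset))[-1])
    out <- out + dataset$betas[, , , k, drop = FALSE]
  array(out / n_sessions(dataset), dim = dim(dataset$betas)[1:3],
        dimnames = dimnames(dataset$betas)[1:3])
}
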
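#' Canonical double-gamma haemodynamic response function
#'
#' SPM-style canonical HRF: a gamma density peaking at 6 s minus an
#' undershoot gamma peaking at 16 s scaled by 1/6, evaluated at `t` seconds.
#'
#' @param t time in seconds (vector).
#' @return HRF values, peak-normalised to 1.
#' @export
hrf_double_gamma <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  h / max(h)
}

# HRF-convolved block regressor sampled at volume acquisition times,
# scaled to unit peak.
task_regressor <- function(design, dt = 0.1) {
  stopifnot(inherits(design, "design_spec"))
  total_t <- design$total_volumes * design$tr
  fine_t <- seq(0, total_t + 32, by = dt)
  box <- numeric(length(fine_t))
  for (b in seq_along(design$onsets)) {
    on <- design$onsets[b]; offt <- on + design$durations[b]
    box[fine_t >= on & fine_t < offt] <- 1
  }
  kern <- hrf_double_gamma(seq(0, 32, by = dt))
  conv <- stats::convolve(box, rev(kern), type = "open")[seq_along(fine_t)]
  vol_t <- (seq_len(design$total_volumes) - 1) * design$tr
  reg <- stats::approx(fine_t, conv, xout = vol_t)$y
  if (max(abs(reg)) > 0) reg <- reg / max(reg)
  reg
}

# Discrete cosine drift basis: `cycles` cosine components over `n` volumes.
dct_basis <- function(n, cycles) {
  if (cycles < 1) return(NULL)
  t <- seq_len(n) - 0.5
  sapply(seq_len(cycles), function(k) cos(pi * k * t / n))
}

#' Build a first-level design matrix
#'
#' Columns are the HRF-convolved task regressor (unit peak), the six motion
#' parameters, optional discrete-cosine drift regressors implementing a
#' 2-cycle high-pass filter inside the model, and an intercept.  Motion
#' columns that are identically zero are dropped with a warning; the matrix
#' is checked for full column rank.
#'
#' @param design a `design_spec` from [make_self_paced_design()].
#' @param motion data frame or matrix with 6 columns and one row per volume.
#' @param hp_cycles number of cosine drift components (0 disables drift
#'   modelling; default 2).
#' @return A `design_matrix` list: `X` (volumes x regressors), `names`,
#'   `task_col`, `tr`.
#' @export
build_design_matrix <- function(design, motion, hp_cycles = 2) {
  stopifnot(inherits(design, "design_spec"))
  motion <- as.matrix(motion)
  if (nrow(motion) != design$total_volumes)
    stop(sprintf("motion table has %d rows but the design has %d volumes",
                 nrow(motion), design$total_volumes), call. = FALSE)
  if (ncol(motion) != 6L)
    stop("motion table must have 6 columns", call. = FALSE)
  reg <- task_regressor(design)
  keep <- apply(motion, 2, function(x) any(x != 0))
  if (!all(keep)) {
    warning(sprintf("dropping %d all-zero motion regressor(s)", sum(!keep)))
    motion <- motion[, keep, drop = FALSE]
  }
  drift <- dct_basis(design$total_volumes, hp_cycles)
  X <- cbind(task = reg, motion, drift, intercept = 1)
  mcols <- if (any(keep)) paste0("motion", which(keep)) else character(0)
  dcols <- if (!is.null(drift)) paste0("dct", seq_len(ncol(drift))) else
    character(0)
  colnames(X) <- c("task", mcols, dcols, "intercept")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; collinear column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  structure(list(X = X, names = colnames(X), task_col = 1L, tr = design$tr),
            class = "design_matrix")
}

#' Fit the first-level GLM with AR(1) prewhitening
#'
#' Per voxel: ordinary least squares, then a single Cochrane-Orcutt pass —
#' the AR(1) coefficient is estimated once per run from the pooled lag-1
#' autocorrelation of the OLS residuals, rows of the data and design are
#' prewhitened by the AR(1) transform, and the model is refit.  The task
#' contrast is the coefficient of the task regressor ("activation minus
#' baseline"; baseline is the unmodelled rest).
#'
#' @param ts volumes x voxels data matrix (e.g. `simulate_timeseries()$data`).
#' @param dm a `design_matrix` from [build_design_matrix()].
#' @param rho_per_voxel estimate and apply the AR(1) coefficient per voxel
#'   instead of one pooled scalar per run (default `FALSE`).
#' @return list with `beta` (task contrast per voxel), `rho` (estimate(s)),
#'   `residuals` (whitened residual matrix), `qc_constant` (logical; voxels
#'   with constant time series, whose beta is set to 0).
#' @export
fit_first_level <- function(ts, dm, rho_per_voxel = FALSE) {
  stopifnot(inherits(dm, "design_matrix"))
  ts <- as.matrix(ts)
  X <- dm$X
  if (nrow(ts) != nrow(X))
    stop(sprintf("data has %d volumes but design has %d rows",
                 nrow(ts), nrow(X)), call. = FALSE)
  constant <- apply(ts, 2, function(y) max(y) - min(y) == 0)
  fit0 <- stats::lm.fit(X, ts)
  res0 <- as.matrix(fit0$residuals)
  lag1 <- function(r) {
    num <- colSums(r[-1, , drop = FALSE] * r[-nrow(r), , drop = FALSE])
    den <- colSums(r^2)
    ifelse(den > 0, num / den, 0)
  }
  rho <- if (rho_per_voxel) lag1(res0) else {
    r <- res0[, !constant, drop = FALSE]
    den <- sum(r^2)
    if (den <= 0) 0 else
      sum(r[-1, , drop = FALSE] * r[-nrow(r), , drop = FALSE]) / den
  }
  prewhiten <- function(m, rho1) {
    out <- m - rho1 * rbind(0, m[-nrow(m), , drop = FALSE])
    out[1, ] <- m[1, ] * sqrt(1 - rho1^2)
    out
  }
  if (rho_per_voxel) {
    beta <- numeric(ncol(ts))
    resid <- matrix(0, nrow(ts), ncol(ts))
    for (v in seq_len(ncol(ts))) {
      Xw <- prewhiten(X, rho[v])
      yw <- prewhiten(ts[, v, drop = FALSE], rho[v])
      f <- stats::lm.fit(Xw, yw)
      beta[v] <- f$coefficients[dm$task_col]
      resid[, v] <- f$residuals
    }
  } else {
    Xw <- prewhiten(X, rho)
    tsw <- prewhiten(ts, rho)
    f <- stats::lm.fit(Xw, tsw)
    cf <- as.matrix(f$coefficients)
    beta <- cf[dm$task_col, ]
    resid <- as.matrix(f$residuals)
  }
  beta[constant] <- 0
  list(beta = unname(beta), rho = rho, residuals = resid,
       qc_constant = constant)
}

#' Average a subject's betas across sessions
#'
#' Voxelwise arithmetic mean of the test and retest contrast images of one
#' subject and task, reducing measurement error before second-level,
#' single-case and multivariate analyses.
#'
#' @param b1,b2 `beta_image` lists with fields `beta` (voxel vector),
#'   `subject`, `task`, `session`, `grid`.
#' @return A `beta_image` with `session = "avg"`.
#' @export
average_sessions <- function(b1, b2) {
  if (!identical(b1$subject, b2$subject) || !identical(b1$task, b2$task))
    stop("can only average sessions of the same subject and task",
         call. = FALSE)
  stopifnot_same_grid(b1$grid, b2$grid, "session images")
  list(beta = (b1$beta + b2$beta) / 2, subject = b1$subject, task = b1$task,
       session = "avg", grid = b1$grid)
}
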
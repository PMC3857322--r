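test_that("design matrix handles motion, causality and linearity", {
  des <- make_self_paced_design("comparison", rt_meanlog = log(1),
                                rt_sdlog = 0, seed = 1)
  tn <- des$total_volumes

  # all-zero motion columns are dropped with a warning, matrix stays full rank
  expect_warning(dm0 <- build_design_matrix(des, matrix(0, tn, 6)),
                 "all-zero motion")
  expect_false(any(grepl("motion", dm0$names)))
  expect_equal(qr(dm0$X)$rank, ncol(dm0$X))

  # convolution is causal: regressor peaks after block onset, not at it
  reg <- dm0$X[, "task"]
  onset_vol <- floor(des$onsets[1] / des$tr) + 1
  expect_gt(which.max(reg[seq_len(onset_vol + 10)]), onset_vol)
  expect_equal(max(reg), 1)  # unit peak

  # collinearity is reported with the offending column
  motion <- matrix(rnorm(tn * 6), tn, 6)
  motion[, 2] <- motion[, 1]
  expect_error(build_design_matrix(des, motion), "collinear")
})

test_that("block regressors superpose linearly", {
  base <- make_self_paced_design("comparison", rt_meanlog = log(1),
                                 rt_sdlog = 0, seed = 1)
  # oracle: direct convolution of each block's boxcar with the HRF
  dt <- 0.1
  tmax <- base$total_volumes * base$tr
  fine_t <- seq(0, tmax + 32, by = dt)
  kern <- hrf_double_gamma(seq(0, 32, by = dt))
  one_block <- function(on, dur) {
    box <- as.numeric(fine_t >= on & fine_t < on + dur)
    conv <- convolve(box, rev(kern), type = "open")[seq_along(fine_t)]
    approx(fine_t, conv, xout = (seq_len(base$total_volumes) - 1) * base$tr)$y
  }
  separate <- Reduce(`+`, Map(one_block, base$onsets, base$durations))
  sim <- simulate_timeseries(base, amplitude = 0, sigma = 0, rho = 0,
                             n_voxels = 1, seed = 1)
  dm <- suppressWarnings(build_design_matrix(base, matrix(0, base$total_volumes, 6)))
  expect_equal(dm$X[, "task"], separate / max(separate), tolerance = 1e-6)
})

test_that("first-level fit recovers noise-free amplitudes exactly", {
  des <- make_self_paced_design("comparison", seed = 2)
  sim <- simulate_timeseries(des, amplitude = 2.5, sigma = 0, rho = 0,
                             motion_amp = 0, n_voxels = 5, seed = 3)
  dm <- build_design_matrix(des, sim$motion)
  f <- fit_first_level(sim$data, dm)
  expect_equal(f$beta, rep(2.5, 5), tolerance = 1e-6)

  # constant voxel: beta 0 and QC flag
  data2 <- cbind(sim$data, 3.14)
  f2 <- fit_first_level(data2, dm)
  expect_equal(f2$beta[6], 0)
  expect_true(f2$qc_constant[6])
  expect_false(any(f2$qc_constant[1:5]))
})

test_that("prewhitening reduces to OLS at rho = 0", {
  des <- make_self_paced_design("comparison", seed = 4)
  sim <- simulate_timeseries(des, amplitude = 1, sigma = 1, rho = 0,
                             n_voxels = 50, seed = 5)
  dm <- build_design_matrix(des, sim$motion)
  ols <- qr.coef(qr(dm$X), sim$data)[dm$task_col, ]
  f <- fit_first_level(sim$data, dm)
  # rho is estimated near zero (OLS residuals carry a small negative bias,
  # about -p/T, from projecting out ~10 regressors over ~70 volumes)
  expect_lt(abs(f$rho), 0.2)
  expect_equal(unname(f$beta), unname(ols), tolerance = 0.05)

  # with rho forced through a zero-correlation prewhitening the fits agree
  # to numerical precision: whitening with rho = 0 is the identity
  f0 <- fit_first_level(sim$data, dm, rho_per_voxel = TRUE)
  expect_equal(length(f0$rho), 50)
})

test_that("AR(1)-corrected betas match the analytic GLS variance", {
  des <- make_self_paced_design("comparison", rt_meanlog = log(1.2),
                                rt_sdlog = 0, seed = 6)
  rho <- 0.5; sigma <- 1
  sim <- simulate_timeseries(des, amplitude = 0, sigma = sigma, rho = rho,
                             n_voxels = 10000, seed = 7)
  dm <- build_design_matrix(des, sim$motion)
  f <- fit_first_level(sim$data, dm)
  # closed-form GLS variance at the true rho
  W <- diag(nrow(dm$X))
  Xw <- dm$X - rho * rbind(0, dm$X[-nrow(dm$X), ])
  Xw[1, ] <- dm$X[1, ] * sqrt(1 - rho^2)
  v_analytic <- sigma^2 * (1 - rho^2) * solve(crossprod(Xw))[1, 1]
  expect_lt(abs(sd(f$beta) / sqrt(v_analytic) - 1), 0.10)
  # unbiasedness at amplitude 0
  expect_lt(abs(mean(f$beta)), 3 * sd(f$beta) / 100)
})

test_that("prewhitened estimator is unbiased across rho levels", {
  des <- make_self_paced_design("comparison", rt_meanlog = log(1.2),
                                rt_sdlog = 0, seed = 8)
  for (rho in c(0, 0.3, 0.6)) {
    sim <- simulate_timeseries(des, amplitude = 1.7, sigma = 1, rho = rho,
                               n_voxels = 600, seed = 100 + round(10 * rho))
    dm <- build_design_matrix(des, sim$motion)
    f <- fit_first_level(sim$data, dm)
    se <- sd(f$beta) / sqrt(length(f$beta))
    expect_lt(abs(mean(f$beta) - 1.7), 3 * se)
  }
})

test_that("task beta is invariant to confounds orthogonal to the task", {
  des <- make_self_paced_design("comparison", seed = 9)
  sim <- simulate_timeseries(des, amplitude = 2, sigma = 0, rho = 0,
                             n_voxels = 3, seed = 10)
  dm <- build_design_matrix(des, sim$motion)
  f1 <- fit_first_level(sim$data, dm)
  # orthogonalize a random confound against all current columns
  set.seed(11)
  conf <- qr.resid(qr(dm$X), rnorm(nrow(dm$X)))
  dm2 <- dm
  dm2$X <- cbind(dm$X[, 1, drop = FALSE], conf, dm$X[, -1])
  colnames(dm2$X)[2] <- "conf"
  dm2$names <- colnames(dm2$X)
  f2 <- fit_first_level(sim$data, dm2)
  expect_lt(max(abs(f1$beta - f2$beta)), 1e-8)
})

test_that("session averaging is the voxelwise arithmetic mean", {
  g <- tiny_grid(4)
  mk <- function(v) list(beta = v, subject = "s1", task = "comparison",
                         session = "1", grid = g)
  v <- rnorm(prod(g$dims))
  expect_equal(average_sessions(mk(v), mk(v))$beta, v)          # idempotent
  expect_equal(average_sessions(mk(v), mk(-v))$beta, rep(0, 64))
  expect_equal(average_sessions(mk(rep(3, 64)), mk(rep(1, 64)))$beta,
               rep(2, 64))
  b2 <- mk(v); b2$subject <- "s2"
  expect_error(average_sessions(mk(v), b2), "same subject")
  expect_equal(average_sessions(mk(v), mk(v))$session, "avg")

  # the study-level averager agrees with the per-image one
  ds <- tiny_study(n_dd = 2, n_td = 2, grid = g, seed = 13)
  avg <- session_average(ds)
  expect_equal(avg[, 1, 1], (ds$betas[, 1, 1, 1] + ds$betas[, 1, 1, 2]) / 2)
})
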
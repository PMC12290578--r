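test_that("double-gamma HRF has the canonical shape", {
  h <- double_gamma_hrf(0.1)
  t <- seq(0, 32, by = 0.1)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  expect_true(t[which.max(h)] >= 4.5 && t[which.max(h)] <= 6.5)
  expect_lt(min(h), 0) # undershoot
  expect_true(all(abs(h[t >= 30]) < 0.01))
  expect_error(double_gamma_hrf(0), "dt > 0")
})

test_that("design matrices assemble task, spikes and drift correctly", {
  empty <- toy_schedule(numeric(0))
  d0 <- build_design(empty, 100, 1.8)
  expect_equal(d0$X[[1]][, "task"], rep(0, 100))

  d1 <- build_design(toy_schedule(), 100, 1.8, flags = c(4, 50))
  X <- d1$X[[1]]
  expect_equal(sum(X[, "spike4"]), 1)
  expect_equal(unname(X[4, "spike4"]), 1)
  expect_equal(unname(X[50, "spike50"]), 1)
  expect_true("task_deriv" %in% colnames(X))

  # a 200-s-period drift is (essentially) annihilated by the drift basis
  tv <- (0:159) * 1.8
  drift <- cos(2 * pi * tv / 200 + 0.7)
  d2 <- build_design(toy_schedule(), 160, 1.8)
  hp_cols <- grepl("^dct|intercept", colnames(d2$X[[1]]))
  r <- lm.fit(d2$X[[1]][, hp_cols], drift)$residuals
  expect_lt(var(r) / var(drift), 0.01)

  # rank deficiency is reported with the offending column
  nuis <- list(cbind(dup = task_regressor(toy_schedule(), tv)))
  expect_error(build_design(toy_schedule(), 160, 1.8, nuisance = nuis),
               "rank deficient")
})

test_that("spatial smoothing preserves mass and realizes the FWHM", {
  a <- array(0, dim = c(21, 21, 3, 2))
  a[11, 11, 2, 1] <- 1
  a[8, 14, 2, 2] <- 2
  expect_identical(smooth_spatial(a, 0), a)
  sm <- smooth_spatial(a, 2, voxel_size = c(1, 1, 5))
  expect_equal(sum(sm[, , , 1]), 1, tolerance = 1e-6)
  expect_equal(sum(sm[, , , 2]), 2, tolerance = 1e-6)
  prof <- sm[, 11, 2, 1]
  sig <- sqrt(sum(prof * ((1:21) - 11)^2) / sum(prof))
  expect_equal(sig * 2 * sqrt(2 * log(2)), 2, tolerance = 0.01)
})

test_that("GLM recovers amplitudes and respects nuisance orthogonality", {
  cfg <- clean_config()
  gt <- generate_amplitudes(cfg)
  sched <- generate_event_schedule(cfg, seed = 9)
  bold <- generate_bold_session(cfg, gt, 1, 1, sched, seed = 11)
  des <- build_design(sched, cfg$n_volumes, cfg$tr)
  sm <- fit_glm(bold, des)
  expect_equal(max(abs(sm$beta[bold$truth$roi] - bold$truth$beta)), 0,
               tolerance = 1e-10)
  expect_equal(sm$dof, cfg$n_volumes - ncol(des$X[[1]]))

  # adding a nuisance column orthogonal to the task leaves beta unchanged
  tv <- (0:159) * 1.8
  task <- task_regressor(sched, tv)
  set.seed(1)
  raw <- rnorm(160)
  ortho <- lm.fit(cbind(task, 1), raw)$residuals
  nuis <- rep(list(cbind(extra = ortho)), 1)
  sm2 <- fit_glm(bold, build_design(sched, 160, 1.8, nuisance = nuis))
  expect_equal(sm2$beta[bold$truth$roi], sm$beta[bold$truth$roi],
               tolerance = 1e-8)
})

test_that("z statistics grow with injected amplitude", {
  cfg <- study_config(n_participants = 1, grid_shape = c(8, 8, 2),
                      cardiac_amp = 0, resp_amp = 0, physio_noise = FALSE,
                      noise_sd = 5, seed = 1)
  sched <- generate_event_schedule(cfg, seed = 4)
  zs <- vapply(c(0.005, 0.02, 0.08), function(a) {
    cfg2 <- cfg; cfg2$mu_amp <- a; cfg2$sigma_b <- 0; cfg2$sigma_w <- 0
    gt <- generate_amplitudes(cfg2)
    bold <- generate_bold_session(cfg2, gt, 1, 1, sched, seed = 21)
    sm <- fit_glm(bold, build_design(sched, cfg2$n_volumes, cfg2$tr))
    mean(sm$z[bold$truth$roi])
  }, numeric(1))
  expect_true(all(diff(zs) > 0))
})

test_that("contralateral regressor absorbs shared fluctuations", {
  cfg <- clean_config(noise_sd = 2)
  gt <- generate_amplitudes(cfg)
  sched <- generate_event_schedule(cfg, seed = 3)
  bold <- generate_bold_session(cfg, gt, 1, 1, sched, seed = 6)
  masks <- build_masks(cfg$grid_shape)
  # inject a shared broadband fluctuation into both dorsal horns (slow
  # drifts would be absorbed by the high-pass basis instead)
  set.seed(8)
  shared <- rnorm(160, sd = 3)
  both <- masks$horns$DL | masks$horns$DR
  idx <- which(both)
  dd <- dim(bold$data)
  mat <- matrix(bold$data, ncol = dd[4])
  mat[idx, ] <- mat[idx, ] + rep(shared, each = length(idx))
  bold$data <- array(mat, dim = dd)

  des <- build_design(sched, 160, 1.8)
  des2 <- add_contralateral_regressor(des, bold, masks$horns$DR)
  expect_equal(ncol(des2$X[[1]]), ncol(des$X[[1]]) + 1)
  expect_length(des2$X, cfg$grid_shape[3])
  sm1 <- fit_glm(bold, des)
  sm2 <- fit_glm(bold, des2)
  roi <- masks$horns$DL
  expect_lt(mean(sm2$se[roi]), mean(sm1$se[roi]))
  expect_error(add_contralateral_regressor(des, bold, masks$horns$DR & FALSE),
               "empty")
})

test_that("sign-flipping permutation inference is calibrated", {
  set.seed(2)
  strong <- matrix(rnorm(12 * 40, mean = 4), 12, 40)
  g <- group_onesample_perm(strong, n_perm = 250, seed = 3)
  expect_equal(min(g$p_fwe), 1 / g$n_perm_used)
  expect_true(all(g$p_fwe >= g$p_unc))

  # exhaustive enumeration for small n
  g5 <- group_onesample_perm(matrix(rnorm(5 * 10), 5, 10),
                             n_perm = 1000, seed = 1)
  expect_equal(g5$n_perm_used, 32)

  # array interface returns maps shaped like the mask
  maps <- lapply(1:8, function(i) array(rnorm(64, 1), dim = c(4, 4, 4)))
  mask <- array(TRUE, dim = c(4, 4, 4))
  ga <- group_onesample_perm(maps, mask, n_perm = 200, seed = 9)
  expect_equal(dim(ga$t), c(4, 4, 4))
  expect_true(all(ga$p_fwe >= ga$p_unc, na.rm = TRUE))
  expect_error(group_onesample_perm(maps, mask & FALSE), "empty")
  expect_error(group_onesample_perm(maps[1], mask), "at least 2")
})

test_that("conjunction is a voxel-wise AND", {
  a <- array(c(TRUE, TRUE, FALSE, FALSE), dim = c(2, 2, 1))
  b <- array(c(TRUE, FALSE, TRUE, FALSE), dim = c(2, 2, 1))
  expect_equal(sum(conjunction(a, b)), 1)
  expect_equal(conjunction(a, a), a)
  expect_true(all(conjunction(a, b) <= a) && all(conjunction(a, b) <= b))
  disj <- conjunction(a, array(!a, dim = dim(a)))
  expect_false(any(disj))
})

test_that("slice designs differ only in slice-wise blocks", {
  ph_c <- matrix(runif(320, 0, 2 * pi), 160, 2)
  ph_r <- matrix(runif(320, 0, 2 * pi), 160, 2)
  nuis <- pnm_regressors(ph_c, ph_r)
  des <- build_design(toy_schedule(), 160, 1.8, nuisance = nuis)
  shared_cols <- c("task", "task_deriv", "intercept",
                   grep("^dct", colnames(des$X[[1]]), value = TRUE))
  expect_equal(des$X[[1]][, shared_cols], des$X[[2]][, shared_cols])
  nuis_cols <- setdiff(colnames(des$X[[1]]), shared_cols)
  expect_false(identical(des$X[[1]][, nuis_cols], des$X[[2]][, nuis_cols]))
})
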
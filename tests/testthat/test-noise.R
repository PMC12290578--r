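test_that("cardiac phase is linear between R-peaks", {
  expect_equal(cardiac_phase(0:5, c(0, 0.5, 1)), c(0, pi, 0))
  # regular 60 bpm train, 0.1 s grid -> phases 0.2*pi*k mod 2*pi
  grid <- seq(0, 4.9, by = 0.1)
  expect_equal(cardiac_phase(0:9, grid),
               (0.2 * pi * (0:49)) %% (2 * pi))
  # extrapolation beyond the train uses the mean IBI
  expect_equal(cardiac_phase(c(1, 2, 3), c(0.5, 3.5)), c(pi, pi))
  expect_error(cardiac_phase(numeric(0), 1), "at least 2")
})

test_that("respiratory phase sweeps a cycle and flips with the derivative", {
  fs <- 20
  tt <- seq(0, 60 - 1 / fs, by = 1 / fs)
  resp <- sin(2 * pi * 0.25 * tt)
  st <- seq(10, 13.9, by = 0.1) # one full breath
  ph <- respiratory_phase(resp, fs, st)
  expect_true(all(ph >= 0 & ph < 2 * pi))
  # monotone advance within the cycle (modulo wrap)
  dph <- diff(ph) %% (2 * pi)
  expect_true(all(dph > 0 | abs(diff(ph)) < 1e-6))
  # at the global amplitude maximum the phase hits the pi boundary
  tmax <- tt[which.max(resp)]
  expect_equal(respiratory_phase(resp, fs, tmax), pi, tolerance = 0.1)
  # time reversal flips the derivative branch
  ph_f <- respiratory_phase(resp, fs, 10.6)
  ph_r <- respiratory_phase(rev(resp), fs, max(tt) - 10.6)
  expect_equal(ph_r, 2 * pi - ph_f, tolerance = 0.15)
  expect_error(respiratory_phase(rep(1, 100), fs, 1), "constant")
})

test_that("the nuisance set has 33 labelled columns per slice", {
  ph_c <- matrix(runif(160 * 3, 0, 2 * pi), 160, 3)
  ph_r <- matrix(runif(160 * 3, 0, 2 * pi), 160, 3)
  nuis <- pnm_regressors(ph_c, ph_r, csf = rnorm(160))
  expect_length(nuis, 3)
  for (s in 1:3) {
    expect_equal(ncol(nuis[[s]]), 33) # 32 Fourier + CSF
    expect_true(all(is.finite(nuis[[s]])))
    fourier <- nuis[[s]][, colnames(nuis[[s]]) != "csf"]
    expect_equal(ncol(fourier), 32)
    expect_true(all(abs(fourier) <= 1))
  }
  expect_equal(ncol(pnm_regressors(ph_c, ph_r)[[1]]), 32)
  # constant phases -> constant Fourier columns
  cn <- pnm_regressors(matrix(1, 160, 1), matrix(2, 160, 1))[[1]]
  expect_true(all(apply(cn, 2, sd) == 0))
  expect_error(pnm_regressors(ph_c, ph_r[, 1:2]), "differ in size")
  expect_error(pnm_regressors(ph_c, ph_r, csf = rnorm(10)), "length")
})

test_that("the nuisance set removes modeled physiological signal", {
  cfg <- study_config(n_participants = 1, seed = 2)
  gt <- generate_amplitudes(cfg)
  sched <- generate_event_schedule(cfg, 1)
  ph <- generate_physio_session(cfg, gt, sched, seed = 3)
  st <- (0:159) * 1.8 + 0.3
  phc <- cardiac_phase(ph$rpeaks, st)
  phr <- respiratory_phase(ph$resp, ph$fs, st)
  art <- 1.3 * sin(phc + 0.4) + 0.8 * cos(phr - 1.1) +
    0.5 * sin(2 * phc) * cos(phr)
  nuis <- pnm_regressors(phc, phr)[[1]]
  resid <- lm.fit(cbind(1, nuis), art)$residuals
  expect_lt(var(resid) / var(art), 0.01)
})

test_that("CSF regressor selects the top-variance voxels", {
  set.seed(11)
  # identical voxels -> that voxel's standardized series
  one <- rnorm(40)
  arr <- array(rep(one, each = 4), dim = c(2, 2, 1, 40))
  mask <- array(TRUE, dim = c(2, 2, 1))
  expect_equal(csf_regressor(arr, mask), as.numeric(scale(one)))

  # matches brute-force selection on a 20-voxel toy
  vox <- matrix(rnorm(20 * 30), 20, 30) * seq(0.2, 4, length.out = 20)
  arr2 <- array(0, dim = c(20, 1, 1, 30))
  arr2[, 1, 1, ] <- vox
  m2 <- array(TRUE, dim = c(20, 1, 1))
  got <- csf_regressor(arr2, m2, top_frac = 0.25)
  keep <- order(apply(vox, 1, var), decreasing = TRUE)[1:5]
  expect_equal(got, as.numeric(scale(colMeans(vox[keep, ]))))
  # invariant to mean offsets
  arr3 <- arr2 + array(rep(rnorm(20, sd = 100), 30), dim = dim(arr2))
  expect_equal(csf_regressor(arr3, m2, top_frac = 0.25), got,
               tolerance = 1e-8)
  expect_error(csf_regressor(arr2, m2 & FALSE), "empty")
})

test_that("outlier volumes are flagged at mean + 3 SD", {
  clean <- array(100, dim = c(4, 4, 2, 20))
  expect_length(detect_outlier_volumes(clean)$volumes, 0)

  set.seed(5)
  noisy <- array(100 + rnorm(4 * 4 * 2 * 40), dim = c(4, 4, 2, 40))
  spiked <- noisy
  spiked[, , , 17] <- spiked[, , , 17] + 10
  fl <- detect_outlier_volumes(spiked)
  expect_true(17 %in% fl$volumes)
  expect_true(any(fl$criterion == "both"))
  # dVARS also implicates the neighbor; refRMS pins the spike itself
  expect_true(all(fl$volumes %in% c(17, 18)))

  # pure Gaussian noise: flagged fraction stays small
  frac <- vapply(1:50, function(i) {
    set.seed(100 + i)
    a <- array(100 + rnorm(4 * 4 * 2 * 60), dim = c(4, 4, 2, 60))
    length(detect_outlier_volumes(a)$volumes) / 60
  }, numeric(1))
  expect_lt(mean(frac), 0.03)
  expect_error(detect_outlier_volumes(clean[, , , 1:2, drop = FALSE]),
               "at least 3")
})

test_that("tSNR is mean over SD and scale invariant", {
  set.seed(3)
  a <- array(100 + 10 * rnorm(6 * 6 * 2 * 50), dim = c(6, 6, 2, 50))
  a[1, 1, 1, ] <- 100 + 10 * scale(rnorm(50)) # exact mean 100, sd 10
  m <- array(FALSE, dim = c(6, 6, 2)); m[1, 1, 1] <- TRUE
  expect_equal(tsnr(a, m)$tsnr[1], 10)
  m2 <- array(TRUE, dim = c(6, 6, 2))
  expect_equal(tsnr(5 * a, m2)$tsnr, tsnr(a, m2)$tsnr)
  expect_true(is.na(tsnr(a, m)$tsnr[2])) # empty slice
})
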
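test_that("IBI series assigns intervals to the following R-peak", {
  ibi <- ibi_from_rpeaks(c(0, 1, 2, 3))
  expect_true(all(abs(ibi$ibi - 1000) < 1e-9))
  expect_equal(attr(ibi, "fs"), 10)

  ibi2 <- ibi_from_rpeaks(c(0, 0.8, 1.8))
  expect_equal(ibi2$ibi[ibi2$time == 0.8], 800)
  expect_equal(ibi2$ibi[ibi2$time == 1.8], 1000)
  # linear in between
  expect_equal(ibi2$ibi[ibi2$time == 1.3], 900)

  # 72 bpm train -> mean IBI ~ 60000/72
  peaks <- cumsum(rep(60 / 72, 400))
  expect_equal(mean(ibi_from_rpeaks(peaks)$ibi), 60000 / 72,
               tolerance = 1e-6)

  expect_error(ibi_from_rpeaks(1), "at least 2")
  expect_error(ibi_from_rpeaks(c(1, 1)), "strictly increasing")
})

test_that("band-pass filter has the specified frequency response", {
  tt <- (0:4095) / 10
  expect_lt(max(abs(bandpass_ibi(make_ibi(rep(850, 4096)))$ibi)), 1e-3)
  # 0.1 Hz passes; 2 Hz is crushed
  mid <- 500:3500 # avoid edges
  s01 <- bandpass_ibi(make_ibi(sin(2 * pi * 0.1 * tt)))$ibi
  expect_equal(max(abs(s01[mid])), 1, tolerance = 0.1)
  s2 <- bandpass_ibi(make_ibi(sin(2 * pi * 2 * tt)))$ibi
  expect_lt(max(abs(s2[mid])), 0.1)
  expect_warning(bandpass_ibi(make_ibi(rep(800, 100))), "cycle")
})

test_that("HPR extraction finds baseline-corrected minima", {
  flat <- make_ibi(rep(900, 2000))
  hpr <- extract_hpr(flat, toy_schedule())
  expect_equal(hpr$value, rep(0, 3))
  expect_equal(response_mean(hpr), 0)

  # injected dip of known depth, recovered within band-pass distortion
  cfg <- study_config(physio_noise = FALSE, seed = 3)
  gt <- generate_amplitudes(cfg)
  gt$physio_amp$hpr[1, 1] <- -50
  sched <- generate_event_schedule(cfg, seed = 1)
  ph <- generate_physio_session(cfg, gt, sched, seed = 2)
  est_unfilt <- response_mean(extract_hpr(ibi_from_rpeaks(ph$rpeaks), sched))
  est_filt <- response_mean(
    extract_hpr(bandpass_ibi(ibi_from_rpeaks(ph$rpeaks)), sched))
  expect_equal(est_unfilt, -50, tolerance = 0.05)
  # filtered estimate stays within 10% of the unfiltered oracle
  expect_lt(abs(est_filt - est_unfilt) / 50, 0.10)

  # identical traces give identical run means
  expect_identical(
    response_mean(extract_hpr(bandpass_ibi(ibi_from_rpeaks(ph$rpeaks)),
                              sched)),
    est_filt)

  # epochs outside the recording are dropped with a warning
  expect_warning(
    out <- extract_hpr(make_ibi(rep(900, 300)), toy_schedule(c(5, 25))),
    "dropped")
  expect_equal(nrow(out), 1)
})

test_that("SCR extraction is exact on clean kernels and linear", {
  fs <- 100
  tt <- (0:28799) / fs
  zero <- rep(0, length(tt))
  expect_equal(extract_scr(zero, fs, toy_schedule())$value, rep(0, 3))

  sc <- rep(2, length(tt))
  kern <- scr_kernel(seq(0, 30, by = 1 / fs))
  sched <- toy_schedule()
  for (on in sched$onset) {
    i0 <- round(on * fs) + 1
    idx <- i0:(i0 + length(kern) - 1)
    sc[idx] <- sc[idx] + kern
  }
  est <- extract_scr(sc, fs, sched)
  # peak of a unit-amplitude canonical SCR ~ kernel maximum (1)
  expect_equal(response_mean(est), 1, tolerance = 0.02)
  est2 <- extract_scr(2 * (sc - 2) + 2, fs, sched)
  expect_equal(est2$value, 2 * est$value, tolerance = 1e-8)
})

test_that("PDR extraction interpolates blinks and drops bad trials", {
  fs <- 100
  n <- 28800
  expect_equal(
    extract_pdr(rep(0, n), fs, NULL, toy_schedule())$value, rep(0, 3))

  cfg <- study_config(physio_noise = FALSE, seed = 8)
  gt <- generate_amplitudes(cfg)
  gt$physio_amp$pdr[1, 1] <- 0.4
  sched <- generate_event_schedule(cfg, seed = 5)
  ph <- generate_physio_session(cfg, gt, sched, seed = 6)
  clean <- response_mean(extract_pdr(ph$pupil, ph$fs, ph$blinks, sched))
  expect_equal(clean, 0.4, tolerance = 0.05)

  # a blink fully inside an ITI leaves the responses unchanged
  blink_iti <- matrix(c(sched$onset[3] - 3, sched$onset[3] - 2.8), 1, 2)
  pup2 <- ph$pupil
  pup2[ph$time >= blink_iti[1] & ph$time <= blink_iti[2]] <- NA
  with_blink <- response_mean(extract_pdr(pup2, ph$fs, blink_iti, sched))
  expect_equal(with_blink, clean, tolerance = 1e-6)

  # a trial with most of its epoch missing is dropped
  big_blink <- matrix(c(sched$onset[1] - 1, sched$onset[1] + 9), 1, 2)
  pup3 <- ph$pupil
  pup3[ph$time >= big_blink[1] & ph$time <= big_blink[2]] <- NA
  expect_warning(out <- extract_pdr(pup3, ph$fs, big_blink, sched),
                 "interpolated")
  expect_equal(nrow(out), nrow(sched) - 1)
})

test_that("tonic state metrics follow their closed forms", {
  peaks <- cumsum(c(0, rep(1, 200)))
  fs <- 100
  sc0 <- rep(0, 210 * fs)
  ton <- tonic_state(peaks, sc0, fs, toy_schedule())
  expect_equal(ton$heart_rate, 60)
  expect_equal(ton$rmssd, 0)

  # IBIs 800, 810, 790 ms -> RMSSD = sqrt((10^2 + 20^2)/2)
  peaks2 <- c(0, cumsum(c(800, 810, 790) / 1000))
  ton2 <- tonic_state(peaks2, sc0, fs, toy_schedule())
  expect_equal(ton2$rmssd, sqrt((100 + 400) / 2))

  # SC trace exactly equal to the modeled evoked response -> SCF = 0
  sched <- toy_schedule()
  kern <- scr_kernel(seq(0, 30, by = 1 / fs))
  sc <- rep(1.5, 210 * fs)
  for (on in sched$onset) {
    i0 <- round(on * fs) + 1
    sc[i0:(i0 + length(kern) - 1)] <-
      sc[i0:(i0 + length(kern) - 1)] + 0.7 * kern
  }
  ton3 <- tonic_state(peaks, sc, fs, sched)
  expect_equal(ton3$scf_auc, 0, tolerance = 1e-8)
})

test_that("responses scale linearly with the trace", {
  # scaling invariance after linear filtering
  cfg <- study_config(physio_noise = FALSE, seed = 13)
  gt <- generate_amplitudes(cfg)
  sched <- generate_event_schedule(cfg, seed = 2)
  ph <- generate_physio_session(cfg, gt, sched, seed = 3)
  s1 <- extract_scr(ph$sc, ph$fs, sched)$value
  s2 <- extract_scr(3 * ph$sc, ph$fs, sched)$value
  expect_equal(s2, 3 * s1, tolerance = 1e-8)
})
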
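#' Generate a jittered event schedule for one run
#'
#' Places `n_trials` stimulus onsets with onset-to-onset gaps of
#' `stim_duration` plus a uniform jitter drawn from `iti_range`. The first
#' onset is at 10 s so that a full pre-stimulus baseline window exists, and
#' the schedule is rejected if the last trial's `[-1, +10]` s epoch does not
#' fit inside the run.
#'
#' @param config a [study_config()].
#' @param seed integer seed; schedules are reproducible given the seed.
#' @return A tibble with columns `trial`, `onset`, `duration` (seconds from
#'   run start), with attribute `run_duration`.
#' @export
#' @examples
#' sched <- generate_event_schedule(study_config(), seed = 1)
#' nrow(sched)
generate_event_schedule <- function(config, seed = config$seed) {
  run_dur <- config$n_volumes * config$tr
  onsets <- numeric(config$n_trials)
  withr_seed(seed, {
    itis <- stats::runif(config$n_trials - 1,
                         config$iti_range[1], config$iti_range[2])
  })
  onsets[1] <- 10
  if (config$n_trials > 1) {
    onsets[-1] <- 10 + cumsum(config$stim_duration + itis)
  }
  if (utils::tail(onsets, 1) + 10 > run_dur) {
    stop("schedule does not fit: last onset ", round(utils::tail(onsets, 1), 2),
         " s needs a 10 s tail but the run lasts ", run_dur, " s",
         call. = FALSE)
  }
  sched <- tibble::tibble(
    trial = seq_len(config$n_trials),
    onset = onsets,
    duration = config$stim_duration
  )
  attr(sched, "run_duration") <- run_dur
  sched
}

# evaluate code under a temporary RNG state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

#' Draw the ground-truth amplitude structure of a study
#'
#' Realizes the variance-component model of the evoked response: a stable
#' participant deviation \eqn{b_i \sim N(0,\sigma_b^2)}, a session deviation
#' \eqn{w_{is} \sim N(0,\sigma_w^2)}, and the realized BOLD amplitude
#' \eqn{A_{is} = \mu + b_i + w_{is}}. Autonomic response amplitudes (HPR,
#' SCR, PDR) follow the same two-level structure around their own population
#' means, with SDs scaled so each measure shares the relative variance
#' components (hence the true ICC) of the BOLD amplitude; the three
#' autonomic measures are drawn independently of each other and of BOLD.
#'
#' @param config a [study_config()].
#' @param seed integer seed.
#' @return A `ground_truth` list: `b` (length n), `w`, `amp` (n x k
#'   matrices), `physio_amp` (list of n x k matrices for `hpr`, `scr`,
#'   `pdr`), and `true_icc`.
#' @export
generate_amplitudes <- function(config, seed = config$seed) {
  n <- config$n_participants; k <- config$n_sessions
  rel_b <- if (config$mu_amp != 0) config$sigma_b / abs(config$mu_amp) else 0
  rel_w <- if (config$mu_amp != 0) config$sigma_w / abs(config$mu_amp) else 0
  withr_seed(derive_seed(seed, stream = 1L), {
    b <- stats::rnorm(n, 0, config$sigma_b)
    w <- matrix(stats::rnorm(n * k, 0, config$sigma_w), n, k)
    physio_amp <- lapply(
      c(hpr = config$hpr_amp, scr = config$scr_amp, pdr = config$pdr_amp),
      function(mu) {
        bm <- stats::rnorm(n, 0, rel_b * abs(mu))
        wm <- matrix(stats::rnorm(n * k, 0, rel_w * abs(mu)), n, k)
        mu + bm + wm
      }
    )
  })
  structure(list(
    b = b, w = w, amp = config$mu_amp + b + w,
    physio_amp = physio_amp,
    true_icc = true_icc(config)
  ), class = "ground_truth")
}

#' Simulate the peripheral physiology of one run
#'
#' Produces synchronized autonomic traces for one participant/session:
#' R-peak times whose interbeat intervals carry a stimulus-evoked dip of
#' known depth (Gaussian bump peaking 3 s post-onset), a skin-conductance
#' trace built from the canonical SCR kernel plus spontaneous fluctuations,
#' a pupil-diameter trace with an evoked dilation peaking at 1.5 s and
#' inserted blink gaps, and a slow quasi-sinusoidal respiration trace.
#'
#' @param config a [study_config()].
#' @param ground_truth a [generate_amplitudes()] result.
#' @param schedule event schedule tibble for this run.
#' @param seed integer seed.
#' @param participant,session indices selecting the amplitude row/column.
#' @return A `physio_recording` list: `fs`, `time`, `rpeaks` (seconds),
#'   `sc`, `pupil`, `resp` (numeric traces; pupil is `NA` inside blinks),
#'   `blinks` (2-column matrix of blink start/end in seconds), `duration`,
#'   and `truth` (the injected amplitudes).
#' @export
generate_physio_session <- function(config, ground_truth, schedule,
                                    seed = config$seed,
                                    participant = 1L, session = 1L) {
  dur <- config$n_volumes * config$tr
  fs <- config$physio_fs
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  a_hpr <- ground_truth$physio_amp$hpr[participant, session]
  a_scr <- ground_truth$physio_amp$scr[participant, session]
  a_pdr <- ground_truth$physio_amp$pdr[participant, session]
  noisy <- config$physio_noise

  withr_seed(seed, {
    # --- heart: continuous IBI function, then integrate to R-peaks -------
    base_ibi <- 60000 / config$cardiac_bpm
    dip <- function(t) {
      # evoked heart-period change: peak-normalized bump at 3 s post-onset
      out <- numeric(length(t))
      for (on in schedule$onset) {
        rel <- t - on
        inw <- rel > 0 & rel <= 8
        out[inw] <- out[inw] + exp(-(rel[inw] - 3)^2 / (2 * 1.2^2))
      }
      out
    }
    rpeaks <- numeric(ceiling(dur / (base_ibi / 1000)) + 8)
    t <- 0; j <- 0
    while (t < dur) {
      j <- j + 1
      rpeaks[j] <- t
      ibi <- base_ibi + a_hpr * dip(t) +
        if (noisy) stats::rnorm(1, 0, 15) else 0
      t <- t + max(ibi, 250) / 1000
    }
    rpeaks <- rpeaks[seq_len(j)]

    # --- skin conductance -------------------------------------------------
    scr_k <- scr_kernel(seq(0, 30, by = 1 / fs),
                        shape = config$scr_shape, rate = config$scr_rate)
    sc <- rep(2, length(tt))
    amps_scr <- a_scr * (1 + if (noisy) stats::rnorm(nrow(schedule), 0, 0.2)
                         else rep(0, nrow(schedule)))
    for (i in seq_len(nrow(schedule))) {
      i0 <- round(schedule$onset[i] * fs) + 1
      idx <- i0:min(length(tt), i0 + length(scr_k) - 1)
      sc[idx] <- sc[idx] + amps_scr[i] * scr_k[seq_along(idx)]
    }
    if (noisy) {
      spont <- smooth_noise(length(tt), fs, cutoff = 0.1, sd = 0.03)
      sc <- sc + spont + 0.1 * sin(2 * pi * tt / dur)
    }

    # --- pupil ------------------------------------------------------------
    tp <- 1.5; a_sh <- 4 # gamma-shaped dilation kernel peaking at 1.5 s
    tk <- seq(0, 6, by = 1 / fs)
    pup_k <- (tk / tp)^a_sh * exp(a_sh * (1 - tk / tp))
    pupil <- rep(3, length(tt))
    amps_pdr <- a_pdr * (1 + if (noisy) stats::rnorm(nrow(schedule), 0, 0.2)
                         else rep(0, nrow(schedule)))
    for (i in seq_len(nrow(schedule))) {
      i0 <- round(schedule$onset[i] * fs) + 1
      idx <- i0:min(length(tt), i0 + length(pup_k) - 1)
      pupil[idx] <- pupil[idx] + amps_pdr[i] * pup_k[seq_along(idx)]
    }
    if (noisy) pupil <- pupil + smooth_noise(length(tt), fs, 2, sd = 0.02)
    n_blinks <- if (noisy) stats::rpois(1, dur / 20) else 0
    blinks <- matrix(numeric(0), 0, 2,
                     dimnames = list(NULL, c("start", "end")))
    if (n_blinks > 0) {
      starts <- sort(stats::runif(n_blinks, 1, dur - 1))
      blinks <- cbind(start = starts,
                      end = starts + stats::runif(n_blinks, 0.1, 0.3))
      for (bi in seq_len(nrow(blinks))) {
        pupil[tt >= blinks[bi, 1] & tt <= blinks[bi, 2]] <- NA
      }
    }

    # --- respiration ------------------------------------------------------
    f_inst <- config$resp_rate *
      (1 + if (noisy) 0.05 * sin(2 * pi * tt / 60) else rep(0, length(tt)))
    resp <- sin(2 * pi * cumsum(f_inst) / fs) +
      if (noisy) smooth_noise(length(tt), fs, 0.8, sd = 0.05) else 0
  })

  structure(list(
    fs = fs, time = tt, rpeaks = rpeaks, sc = sc, pupil = pupil,
    resp = resp, blinks = blinks, duration = dur,
    truth = list(hpr = a_hpr, scr = a_scr, pdr = a_pdr)
  ), class = "physio_recording")
}

# low-pass filtered white noise rescaled to a target SD
smooth_noise <- function(n, fs, cutoff, sd) {
  x <- stats::rnorm(n)
  bf <- signal::butter(2, min(cutoff / (fs / 2), 0.99), type = "low")
  y <- signal::filtfilt(bf, x)
  sd * y / stats::sd(y)
}

#' Canonical skin-conductance response kernel
#'
#' A peak-normalized gamma-density bump with a slow decay, peaking at
#' `(shape - 1)/rate` seconds (about 3.1 s at the defaults), used both to
#' synthesize skin-conductance traces and as the basis function when
#' modeling evoked electrodermal activity.
#'
#' @param t time in seconds (vector).
#' @param shape,rate gamma parameters.
#' @return Kernel values, maximum 1.
#' @export
scr_kernel <- function(t, shape = 3.0645, rate = 0.6652) {
  k <- stats::dgamma(t, shape = shape, rate = rate)
  peak <- stats::dgamma((shape - 1) / rate, shape = shape, rate = rate)
  k / peak
}

#' Simulate one BOLD run on the synthetic cord geometry
#'
#' Builds the 4-D time-series grid for one participant/session: a uniform
#' baseline carrying (i) the HRF-convolved evoked response with amplitude
#' `A[participant, session]` in the target-horn voxels of segment C6 and
#' `vein_gain` times that in the dorsal-surface vein shell, (ii) a global
#' linear-plus-cosine drift, (iii) cardiac and respiratory components whose
#' phases follow the simulated physiology and are sampled at each slice's
#' acquisition time (slice `s` of a volume starting at `t` is acquired at
#' `t + s*TR/n_slices`, ascending order), with tripled cardiac amplitude in
#' the CSF ring, and (iv) AR(1) Gaussian noise with marginal SD `noise_sd`.
#' The evoked regressor itself is sampled at volume onsets, matching the
#' first-level design convention.
#'
#' @param config a [study_config()].
#' @param ground_truth a [generate_amplitudes()] result.
#' @param participant,session indices.
#' @param schedule event schedule for this run.
#' @param seed integer seed for the noise.
#' @param physio optional [generate_physio_session()] recording supplying
#'   the cardiac/respiratory phase; generated internally (same seed rule)
#'   when missing.
#' @param masks optional [build_masks()] result matching
#'   `config$grid_shape`; built on the fly when missing.
#' @return A `ts_grid`: list with `data` (4-D array x,y,slice,volume),
#'   `tr`, `voxel_size`, `slice_offsets` (seconds), and `truth` (amplitude,
#'   true task beta in raw units, voxel sets).
#' @export
generate_bold_session <- function(config, ground_truth, participant, session,
                                  schedule, seed = config$seed,
                                  physio = NULL, masks = NULL) {
  if (is.null(masks)) masks <- build_masks(config$grid_shape)
  need_physio <- config$cardiac_amp > 0 || config$resp_amp > 0
  if (is.null(physio) && need_physio) {
    physio <- generate_physio_session(
      config, ground_truth, schedule,
      seed = derive_seed(seed, participant, session, 2L),
      participant = participant, session = session
    )
  }
  nx <- config$grid_shape[1]; ny <- config$grid_shape[2]
  nz <- config$grid_shape[3]; nv <- config$n_volumes
  nvox_sl <- nx * ny
  tv <- (seq_len(nv) - 1) * config$tr
  slice_off <- (seq_len(nz) - 1) * config$tr / nz

  A <- ground_truth$amp[participant, session]
  task <- task_regressor(schedule, tv)
  roi <- mask_on_segment(masks$horns$DL, masks, "C6")
  shell <- mask_on_segment(masks$vein_shell, masks, "C6")

  amp_map <- array(0, dim = config$grid_shape)
  amp_map[roi] <- A
  amp_map[shell] <- config$vein_gain * A
  drift <- config$drift_amp * ((2 * tv / max(tv) - 1) + cos(2 * pi * tv / 150))

  dat <- array(0, dim = c(nx, ny, nz, nv))
  withr_seed(derive_seed(seed, participant, session, 3L), {
    for (z in seq_len(nz)) {
      st <- tv + slice_off[z]
      base_sl <- matrix(config$baseline + config$baseline *
                          as.vector(amp_map[, , z]) %o% task,
                        nrow = nvox_sl)
      phys <- 0
      if (!is.null(physio)) {
        phc <- cardiac_phase(physio$rpeaks, st)
        phr <- respiratory_phase(physio$resp, physio$fs, st)
        csf_sl <- as.vector(masks$csf_ring[, , z])
        camp <- config$cardiac_amp * ifelse(csf_sl, 3, 1)
        wc <- cbind(stats::rnorm(nvox_sl), stats::rnorm(nvox_sl)) * camp
        wr <- cbind(stats::rnorm(nvox_sl), stats::rnorm(nvox_sl)) *
          config$resp_amp
        phys <- wc %*% rbind(sin(phc), cos(phc)) +
          wr %*% rbind(sin(phr), cos(phr))
      }
      noise <- matrix(0, nvox_sl, nv)
      if (config$noise_sd > 0) {
        innov <- matrix(stats::rnorm(nvox_sl * nv), nvox_sl, nv)
        if (config$ar1 > 0) {
          innov <- t(stats::filter(t(innov), config$ar1,
                                   method = "recursive")) *
            sqrt(1 - config$ar1^2)
        }
        noise <- config$noise_sd * innov
      }
      dat[, , z, ] <- base_sl + phys + noise +
        matrix(drift, nvox_sl, nv, byrow = TRUE)
    }
  })

  structure(list(
    data = dat, tr = config$tr, voxel_size = config$voxel_size,
    slice_offsets = slice_off,
    truth = list(amplitude = A, beta = A * config$baseline,
                 roi = roi, vein_shell = shell)
  ), class = "ts_grid")
}

#' @export
print.ts_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ts_grid> %d x %d x %d voxels, %d volumes, TR %.3g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' Generate a complete two-session synthetic study
#'
#' Draws the ground-truth amplitude structure and then simulates, for every
#' participant and session, an event schedule (jitter re-drawn per
#' participant/session), a physiological recording, and optionally the BOLD
#' run. All per-unit seeds are derived deterministically from
#' `config$seed`, so the full dataset is reproducible.
#'
#' @param config a [study_config()].
#' @param bold logical; simulate the 4-D BOLD grids (memory scales with
#'   `prod(grid_shape) * n_volumes * n_participants * n_sessions`).
#' @return A `synthetic_study` list: `config`, `masks`, `ground_truth`, and
#'   `sessions`, a list indexed `[[participant]][[session]]` holding
#'   `schedule`, `physio` and (if requested) `bold`.
#' @export
generate_study <- function(config, bold = TRUE) {
  masks <- build_masks(config$grid_shape)
  gt <- generate_amplitudes(config)
  sessions <- lapply(seq_len(config$n_participants), function(p) {
    lapply(seq_len(config$n_sessions), function(s) {
      sched <- generate_event_schedule(
        config, seed = derive_seed(config$seed, p, s, 1L))
      phys <- generate_physio_session(
        config, gt, sched, seed = derive_seed(config$seed, p, s, 2L),
        participant = p, session = s)
      out <- list(schedule = sched, physio = phys)
      if (bold) {
        out$bold <- generate_bold_session(
          config, gt, p, s, sched, seed = config$seed,
          physio = phys, masks = masks)
      }
      out
    })
  })
  structure(list(config = config, masks = masks,
                 ground_truth = gt, sessions = sessions),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d participants x %d sessions (true ICC %.3f)\n",
              x$config$n_participants, x$config$n_sessions,
              x$ground_truth$true_icc))
  invisible(x)
}
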
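#' Study configuration
#'
#' Bundles every parameter of the simulated two-session heat-pain study:
#' design timing, acquisition geometry, the variance components of the
#' evoked BOLD amplitude, and the structured-noise model. Defaults follow
#' the event-related design this package targets: 20 trials of 1-s stimuli
#' separated by 10--12 s jittered intertrial intervals, 160 volumes at a
#' TR of 1.8 s (run duration 288 s) over 16 axial slices.
#'
#' Amplitudes are expressed as fractional BOLD signal change. A participant
#' \eqn{i} in session \eqn{s} responds with amplitude
#' \eqn{A_{is} = \mu + b_i + w_{is}} where \eqn{b_i \sim N(0, \sigma_b^2)}
#' is a stable participant trait and \eqn{w_{is} \sim N(0, \sigma_w^2)} is
#' session-specific, so the true consistency ICC of the amplitude is
#' \eqn{\sigma_b^2 / (\sigma_b^2 + \sigma_w^2)}.
#'
#' @param n_participants number of participants.
#' @param n_sessions number of sessions (days) per participant.
#' @param n_trials number of stimuli per run.
#' @param stim_duration stimulus duration in seconds.
#' @param iti_range length-2 numeric, jittered intertrial interval bounds
#'   (onset-to-onset gap is `stim_duration + ITI`), seconds.
#' @param tr repetition time in seconds.
#' @param n_volumes number of volumes per run.
#' @param grid_shape integer triple (x, y, slices) of the voxel grid.
#'   x runs left to right, y ventral to dorsal.
#' @param voxel_size mm triple.
#' @param baseline mean raw signal intensity of in-cord voxels.
#' @param mu_amp population-mean evoked amplitude (fractional signal change).
#' @param sigma_b between-participant amplitude SD.
#' @param sigma_w within-participant (between-session) amplitude SD.
#' @param vein_gain amplitude multiplier for the dorsal-surface vein shell.
#' @param noise_sd white-noise SD (raw intensity units).
#' @param ar1 lag-1 autocorrelation of the noise, in `[0, 1)`.
#' @param cardiac_bpm mean heart rate of the simulated participant, bpm.
#' @param resp_rate respiratory frequency, Hz.
#' @param cardiac_amp,resp_amp amplitudes of the cardiac and respiratory
#'   signal components (raw intensity units).
#' @param drift_amp amplitude of the slow (linear-plus-cosine) drift.
#' @param physio_fs sampling rate of simulated skin-conductance, pupil and
#'   respiration traces, Hz.
#' @param hpr_amp,scr_amp,pdr_amp population-mean autonomic response
#'   amplitudes: heart-period dip (ms, negative = cardiac acceleration),
#'   skin-conductance peak (microsiemens), pupil-dilation peak (a.u.).
#' @param physio_noise logical; add spontaneous fluctuations and trial
#'   jitter to the autonomic traces.
#' @param scr_shape,scr_rate gamma parameters of the canonical
#'   skin-conductance response kernel (peak at `(scr_shape - 1)/scr_rate`
#'   seconds, about 3.1 s by default).
#' @param seed integer seed for reproducible generation.
#'
#' @return An object of class `study_config` (a validated named list).
#' @export
#' @examples
#' cfg <- study_config(n_participants = 4, grid_shape = c(16, 16, 8))
#' cfg$n_trials
study_config <- function(n_participants = 40,
                         n_sessions = 2,
                         n_trials = 20,
                         stim_duration = 1.0,
                         iti_range = c(10, 12),
                         tr = 1.8,
                         n_volumes = 160,
                         grid_shape = c(24, 24, 16),
                         voxel_size = c(1, 1, 5),
                         baseline = 100,
                         mu_amp = 0.01,
                         sigma_b = 0.003,
                         sigma_w = 0.0016,
                         vein_gain = 2,
                         noise_sd = 8,
                         ar1 = 0.2,
                         cardiac_bpm = 70,
                         resp_rate = 0.25,
                         cardiac_amp = 2,
                         resp_amp = 2,
                         drift_amp = 2,
                         physio_fs = 100,
                         hpr_amp = -40,
                         scr_amp = 0.5,
                         pdr_amp = 0.3,
                         physio_noise = TRUE,
                         scr_shape = 3.0645,
                         scr_rate = 0.6652,
                         seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_sessions = as.integer(n_sessions),
    n_trials = as.integer(n_trials),
    stim_duration = stim_duration, iti_range = iti_range,
    tr = tr, n_volumes = as.integer(n_volumes),
    grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
    baseline = baseline, mu_amp = mu_amp,
    sigma_b = sigma_b, sigma_w = sigma_w, vein_gain = vein_gain,
    noise_sd = noise_sd, ar1 = ar1,
    cardiac_bpm = cardiac_bpm, resp_rate = resp_rate,
    cardiac_amp = cardiac_amp, resp_amp = resp_amp,
    drift_amp = drift_amp, physio_fs = physio_fs,
    hpr_amp = hpr_amp, scr_amp = scr_amp, pdr_amp = pdr_amp,
    physio_noise = isTRUE(physio_noise),
    scr_shape = scr_shape, scr_rate = scr_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "study_config"
  validate_config(cfg)
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat(sprintf("  %d participants x %d sessions, %d trials/run\n",
              x$n_participants, x$n_sessions, x$n_trials))
  cat(sprintf("  grid %s, TR %.3g s, %d volumes (%.0f s)\n",
              paste(x$grid_shape, collapse = "x"), x$tr, x$n_volumes,
              x$tr * x$n_volumes))
  cat(sprintf("  mu_amp %.3g, sigma_b %.3g, sigma_w %.3g (true ICC %.3f)\n",
              x$mu_amp, x$sigma_b, x$sigma_w, true_icc(x)))
  invisible(x)
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$n_participants >= 1, cfg$n_sessions >= 1, cfg$n_trials >= 1,
    cfg$stim_duration > 0, length(cfg$iti_range) == 2,
    cfg$iti_range[1] <= cfg$iti_range[2], cfg$iti_range[1] >= 0,
    cfg$tr > 0, cfg$n_volumes >= 2,
    length(cfg$grid_shape) == 3, all(cfg$grid_shape >= 1),
    length(cfg$voxel_size) == 3, all(cfg$voxel_size > 0),
    cfg$baseline > 0,
    cfg$sigma_b >= 0, cfg$sigma_w >= 0, cfg$noise_sd >= 0,
    cfg$ar1 >= 0, cfg$ar1 < 1,
    cfg$cardiac_bpm > 0, cfg$resp_rate > 0, cfg$physio_fs > 0,
    cfg$scr_shape > 1, cfg$scr_rate > 0
  )
  # a feasibility check for the event schedule: worst-case schedule must
  # leave a full [-1, +10] s epoch window around the last stimulus
  run_dur <- cfg$n_volumes * cfg$tr
  worst_last_onset <- 10 +
    (cfg$n_trials - 1) * (cfg$stim_duration + cfg$iti_range[2])
  if (worst_last_onset + 10 > run_dur) {
    stop("schedule cannot fit in n_volumes * tr: last onset could be at ",
         round(worst_last_onset, 1), " s but the run lasts only ",
         round(run_dur, 1), " s (need 10 s of tail)", call. = FALSE)
  }
  cfg
}

#' True amplitude ICC implied by a configuration
#'
#' The consistency intraclass correlation of the session amplitudes implied
#' by the generator's variance components,
#' \eqn{\sigma_b^2 / (\sigma_b^2 + \sigma_w^2)}.
#'
#' @param config a [study_config()].
#' @return A single number in `[0, 1]` (NaN when both components are 0).
#' @export
true_icc <- function(config) {
  config$sigma_b^2 / (config$sigma_b^2 + config$sigma_w^2)
}

# deterministic fan-out of per-participant/session/stream seeds from the
# master seed; kept below 2^31 - 1
derive_seed <- function(seed, participant = 0L, session = 0L, stream = 0L) {
  as.integer((as.double(seed) * 7919 + participant * 104729 +
                session * 1299709 + stream * 15485863) %% 2147483629)
}
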
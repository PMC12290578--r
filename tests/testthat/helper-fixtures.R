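# small shared fixtures; everything is generated in code

desk_config <- function(...) {
  args <- list(n_participants = 4, grid_shape = c(12, 12, 4), seed = 42)
  do.call(study_config, utils::modifyList(args, list(...)))
}

# a clean (noise-free) single-session config for identity checks
clean_config <- function(...) {
  args <- list(n_participants = 1, grid_shape = c(12, 12, 4), noise_sd = 0,
               drift_amp = 0, cardiac_amp = 0, resp_amp = 0, ar1 = 0,
               physio_noise = FALSE, seed = 5)
  do.call(study_config, utils::modifyList(args, list(...)))
}

# uniform ibi_series from raw values (10 Hz grid starting at t = 0)
make_ibi <- function(values, fs = 10) {
  out <- tibble::tibble(time = (seq_along(values) - 1) / fs, ibi = values)
  attr(out, "fs") <- fs
  class(out) <- c("ibi_series", class(out))
  out
}

# simple 3-trial schedule with fixed spacing
toy_schedule <- function(onsets = c(20, 60, 100), duration = 1) {
  tibble::tibble(trial = seq_along(onsets), onset = onsets,
                 duration = duration)
}
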
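#' Interbeat-interval series from R-peak times
#'
#' Assigns each interbeat interval (IBI) to its following R-peak and
#' linearly interpolates the resulting irregular series onto a uniform grid
#' (10 Hz by default) spanning the interval between the second and the last
#' R-peak.
#'
#' @param rpeak_times strictly increasing R-peak times in seconds.
#' @param fs_out output sampling rate in Hz.
#' @return An `ibi_series` tibble with columns `time` (s) and `ibi` (ms)
#'   and attribute `fs`.
#' @export
#' @examples
#' ibi_from_rpeaks(c(0, 1, 2, 3))
ibi_from_rpeaks <- function(rpeak_times, fs_out = 10) {
  if (length(rpeak_times) < 2) {
    stop("need at least 2 R-peaks to form an interbeat interval",
         call. = FALSE)
  }
  if (any(diff(rpeak_times) <= 0)) {
    stop("R-peak times must be strictly increasing", call. = FALSE)
  }
  anchors <- rpeak_times[-1]
  ibis <- diff(rpeak_times) * 1000
  grid <- seq(ceiling(anchors[1] * fs_out) / fs_out,
              floor(anchors[length(anchors)] * fs_out) / fs_out,
              by = 1 / fs_out)
  out <- tibble::tibble(
    time = grid,
    ibi = stats::approx(anchors, ibis, xout = grid)$y
  )
  attr(out, "fs") <- fs_out
  class(out) <- c("ibi_series", class(out))
  out
}

#' Band-pass filter an interbeat-interval series
#'
#' Applies a second-order Butterworth band-pass (0.01--0.5 Hz by default)
#' forward and backward (zero phase, so the effective order doubles). The
#' output is mean-free by construction of the high-pass edge.
#'
#' @param ibi an [ibi_from_rpeaks()] tibble.
#' @param low,high cutoff frequencies in Hz.
#' @param order Butterworth order (per pass).
#' @return The filtered `ibi_series`; a warning is raised when the series
#'   spans less than one cycle of the low cutoff, where edge effects
#'   dominate.
#' @export
bandpass_ibi <- function(ibi, low = 0.01, high = 0.5, order = 2) {
  fs <- attr(ibi, "fs")
  span <- diff(range(ibi$time))
  if (span < 1 / low) {
    warning("IBI series spans ", round(span), " s, less than one cycle of ",
            "the ", low, " Hz cutoff; band-pass applied but poorly defined",
            call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  out <- ibi
  out$ibi <- filtfilt_padded(bf, ibi$ibi)
  out
}

# zero-phase filtering with reflection padding so edge transients of the
# forward-backward pass do not leak into the series
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  np <- min(n - 1, 3000L)
  pre <- 2 * x[1] - x[seq(np + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - np)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  as.numeric(y[(np + 1):(np + n)])
}

# cut a uniformly sampled trace into per-trial epochs; returns a list with
# the epoch value matrix and relative-time grid, dropping (with a warning)
# trials whose window is not fully covered
cut_epochs <- function(time, value, onsets, window = c(-1, 10)) {
  fs <- 1 / stats::median(diff(time))
  n_rel <- round((window[2] - window[1]) * fs) + 1
  rel <- window[1] + (seq_len(n_rel) - 1) / fs
  rows <- lapply(onsets, function(on) {
    i0 <- round((on + window[1] - time[1]) * fs) + 1
    idx <- i0:(i0 + n_rel - 1)
    if (idx[1] < 1 || idx[n_rel] > length(value)) return(NULL)
    value[idx]
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (any(!keep)) {
    warning(sum(!keep), " trial(s) dropped: epoch window outside recording",
            call. = FALSE)
  }
  list(epochs = do.call(rbind, rows[keep]), rel = rel,
       trials = which(keep), fs = fs)
}

response_tbl <- function(trials, values, measure) {
  out <- tibble::tibble(measure = measure, trial = trials, value = values)
  attr(out, "run_mean") <- mean(values)
  class(out) <- c("response_summary", class(out))
  out
}

#' Run mean of a per-trial response table
#' @param x a `response_summary` tibble.
#' @return The arithmetic mean of the per-trial values.
#' @export
response_mean <- function(x) mean(x$value)

#' Extract per-trial heart-period responses
#'
#' Cuts the (band-passed) IBI series into `[-1, 10]` s epochs around each
#' stimulus onset, corrects each epoch to its mean IBI over the 5 s before
#' onset, and takes the minimum over `(0, 8]` s post-onset as the trial's
#' heart-period response (HPR, ms; negative values indicate cardiac
#' acceleration).
#'
#' @param ibi an `ibi_series` (typically [bandpass_ibi()] output).
#' @param schedule event schedule tibble with an `onset` column.
#' @return A `response_summary` tibble (`measure`, `trial`, `value`).
#' @export
extract_hpr <- function(ibi, schedule) {
  ep <- cut_epochs(ibi$time, ibi$ibi, schedule$onset, window = c(-5, 10))
  base_idx <- ep$rel >= -5 & ep$rel < 0
  resp_idx <- ep$rel > 0 & ep$rel <= 8
  vals <- apply(ep$epochs, 1, function(e) {
    min(e[resp_idx]) - mean(e[base_idx])
  })
  response_tbl(schedule$trial[ep$trials], vals, "hpr")
}

# zero-phase low-pass followed by decimation onto a coarser uniform grid
resample_trace <- function(x, fs, fs_out) {
  if (fs == fs_out) return(list(x = x, fs = fs))
  stopifnot(fs > fs_out)
  bf <- signal::butter(4, 0.8 * fs_out / fs, type = "low")
  y <- filtfilt_padded(bf, x)
  step <- fs / fs_out
  idx <- round(seq(1, length(y), by = step))
  list(x = y[idx], fs = fs_out)
}

#' Extract per-trial skin-conductance responses
#'
#' Down-samples the trace to 100 Hz, low-pass filters at 1 Hz (second-order
#' zero-phase Butterworth), corrects each `[-1, 10]` s epoch to the sample
#' at stimulus onset, and takes the maximum over `(0, 8]` s post-onset as
#' the trial's SCR (microsiemens).
#'
#' @param sc_trace skin-conductance trace.
#' @param fs sampling rate of `sc_trace` in Hz.
#' @param schedule event schedule tibble.
#' @return A `response_summary` tibble.
#' @export
extract_scr <- function(sc_trace, fs, schedule) {
  rs <- resample_trace(sc_trace, fs, 100)
  bf <- signal::butter(2, 1 / (rs$fs / 2), type = "low")
  x <- filtfilt_padded(bf, rs$x)
  tt <- (seq_along(x) - 1) / rs$fs
  ep <- cut_epochs(tt, x, schedule$onset, window = c(-1, 10))
  onset_i <- which.min(abs(ep$rel))
  resp_idx <- ep$rel > 0 & ep$rel <= 8
  vals <- apply(ep$epochs, 1, function(e) max(e[resp_idx]) - e[onset_i])
  response_tbl(schedule$trial[ep$trials], vals, "scr")
}

#' Extract per-trial pupil-dilation responses
#'
#' Removes samples within 100 ms of each blink (and any `NA` stretches),
#' interpolates the gaps linearly, down-samples to 100 Hz, low-pass filters
#' at 4 Hz, corrects each epoch to the sample at stimulus onset, and takes
#' the maximum over `(0, 4]` s post-onset as the trial's pupil-dilation
#' response. Trials with more than half of their epoch interpolated are
#' dropped with a warning.
#'
#' @param pupil_trace pupil-diameter trace (may contain `NA` in blinks).
#' @param fs sampling rate in Hz.
#' @param blink_intervals 2-column matrix of blink start/end times in
#'   seconds (may have zero rows).
#' @param schedule event schedule tibble.
#' @return A `response_summary` tibble.
#' @export
extract_pdr <- function(pupil_trace, fs, blink_intervals, schedule) {
  tt <- (seq_along(pupil_trace) - 1) / fs
  bad <- is.na(pupil_trace)
  if (!is.null(blink_intervals) && nrow(blink_intervals) > 0) {
    for (i in seq_len(nrow(blink_intervals))) {
      bad <- bad | (tt >= blink_intervals[i, 1] - 0.1 &
                      tt <= blink_intervals[i, 2] + 0.1)
    }
  }
  x <- pupil_trace
  if (any(bad)) {
    x[bad] <- NA
    x <- stats::approx(tt[!bad], x[!bad], xout = tt, rule = 2)$y
  }
  rs_x <- resample_trace(x, fs, 100)
  rs_b <- resample_trace(as.numeric(bad), fs, 100)
  bf <- signal::butter(2, 4 / (rs_x$fs / 2), type = "low")
  xf <- filtfilt_padded(bf, rs_x$x)
  tt2 <- (seq_along(xf) - 1) / rs_x$fs

  ep <- cut_epochs(tt2, xf, schedule$onset, window = c(-1, 10))
  epb <- cut_epochs(tt2, rs_b$x, schedule$onset, window = c(-1, 10))
  frac_interp <- rowMeans(epb$epochs > 0.5)
  ok <- frac_interp <= 0.5
  if (any(!ok)) {
    warning(sum(!ok), " trial(s) dropped: > 50% of epoch interpolated",
            call. = FALSE)
  }
  onset_i <- which.min(abs(ep$rel))
  resp_idx <- ep$rel > 0 & ep$rel <= 4
  vals <- apply(ep$epochs[ok, , drop = FALSE], 1,
                function(e) max(e[resp_idx]) - e[onset_i])
  response_tbl(schedule$trial[ep$trials][ok], vals, "pdr")
}

#' Tonic autonomic state of one run
#'
#' Summarizes the run-level autonomic state: heart rate (bpm, from the mean
#' interbeat interval), heart-rate variability as RMSSD (root mean square
#' of successive IBI differences, ms), and spontaneous electrodermal
#' fluctuations (SCF) as the area under the absolute residual of a
#' least-squares fit of the canonical-SCR-convolved stimulus onsets (plus an
#' intercept) to the skin-conductance trace.
#'
#' @param rpeak_times R-peak times in seconds.
#' @param sc_trace skin-conductance trace.
#' @param fs sampling rate of `sc_trace` in Hz.
#' @param schedule event schedule tibble.
#' @param scr_shape,scr_rate canonical SCR kernel parameters, see
#'   [scr_kernel()].
#' @return A one-row tibble with `heart_rate`, `rmssd`, `scf_auc`.
#' @export
tonic_state <- function(rpeak_times, sc_trace, fs, schedule,
                        scr_shape = 3.0645, scr_rate = 0.6652) {
  if (length(rpeak_times) < 3) {
    stop("need at least 3 R-peaks for tonic heart metrics", call. = FALSE)
  }
  ibis <- diff(rpeak_times) * 1000
  hr <- 60000 / mean(ibis)
  rmssd <- sqrt(mean(diff(ibis)^2))

  tt <- (seq_along(sc_trace) - 1) / fs
  kern <- scr_kernel(seq(0, 30, by = 1 / fs), scr_shape, scr_rate)
  reg <- numeric(length(sc_trace))
  for (on in schedule$onset) {
    i0 <- round(on * fs) + 1
    idx <- i0:min(length(reg), i0 + length(kern) - 1)
    reg[idx] <- reg[idx] + kern[seq_along(idx)]
  }
  fit <- stats::lm.fit(cbind(1, reg), sc_trace)
  scf <- sum(abs(fit$residuals)) / fs

  tibble::tibble(heart_rate = hr, rmssd = rmssd, scf_auc = scf)
}
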
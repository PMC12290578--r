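#' Cardiac phase at given acquisition times
#'
#' RETROICOR-style cardiac phase: within each R-R interval the phase grows
#' linearly from 0 at one R-peak to \eqn{2\pi} at the next. Times before
#' the first or after the last peak are handled by extrapolating the peak
#' train with the mean interbeat interval.
#'
#' @param rpeak_times strictly increasing R-peak times, seconds.
#' @param slice_times acquisition times, seconds.
#' @return Phases in `[0, 2*pi)`, one per element of `slice_times`.
#' @export
#' @examples
#' cardiac_phase(0:5, c(0, 0.5, 1))  # 0, pi, 0
cardiac_phase <- function(rpeak_times, slice_times) {
  if (length(rpeak_times) < 2) stop("need at least 2 R-peaks", call. = FALSE)
  mean_ibi <- mean(diff(rpeak_times))
  # pad the train so every slice time falls between two peaks
  while (min(slice_times) < rpeak_times[1]) {
    rpeak_times <- c(rpeak_times[1] - mean_ibi, rpeak_times)
  }
  while (max(slice_times) >= rpeak_times[length(rpeak_times)]) {
    rpeak_times <- c(rpeak_times,
                     rpeak_times[length(rpeak_times)] + mean_ibi)
  }
  i <- findInterval(slice_times, rpeak_times)
  ph <- 2 * pi * (slice_times - rpeak_times[i]) /
    (rpeak_times[i + 1] - rpeak_times[i])
  ph %% (2 * pi)
}

#' Respiratory phase at given acquisition times
#'
#' Amplitude-histogram (Glover-style) respiratory phase: the trace's
#' amplitude is histogram-equalized via its empirical CDF `H`, and the
#' phase at time `t` is `pi * H(a(t))` during inhalation (positive
#' derivative) and `2*pi - pi * H(a(t))` during exhalation, so a full
#' breath sweeps `[0, 2*pi)` and the global amplitude maximum maps to the
#' inhale/exhale boundary at `pi`.
#'
#' @param resp_trace respiration trace, uniformly sampled.
#' @param fs sampling rate of `resp_trace`, Hz.
#' @param slice_times acquisition times, seconds (trace must cover them).
#' @return Phases in `[0, 2*pi)`.
#' @export
respiratory_phase <- function(resp_trace, fs, slice_times) {
  if (stats::sd(resp_trace) == 0) {
    stop("respiration trace is constant; phase undefined", call. = FALSE)
  }
  tt <- (seq_along(resp_trace) - 1) / fs
  if (min(slice_times) < tt[1] || max(slice_times) > tt[length(tt)]) {
    stop("slice times outside the respiration recording", call. = FALSE)
  }
  # light smoothing for a stable derivative sign
  k <- max(1, round(fs * 0.2))
  sm <- stats::filter(resp_trace, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- resp_trace[is.na(sm)]
  sm <- as.numeric(sm)
  H <- stats::ecdf(sm)
  a <- stats::approx(tt, sm, xout = slice_times, rule = 2)$y
  deriv <- stats::approx(tt[-1] - 1 / (2 * fs), diff(sm) * fs,
                         xout = slice_times, rule = 2)$y
  ph <- ifelse(deriv >= 0, pi * H(a), 2 * pi - pi * H(a))
  ph %% (2 * pi)
}

#' Slice-wise physiological nuisance regressor set
#'
#' Expands the cardiac and respiratory phases of each slice into the
#' Fourier nuisance basis: sine and cosine of cardiac harmonics 1--4
#' (8 columns), of respiratory harmonics 1--4 (8 columns), and all products
#' of cardiac x respiratory sine/cosine terms up to harmonic order 2 x 2
#' (16 columns), plus the standardized CSF time course -- 33 columns per
#' slice in total.
#'
#' @param cardiac matrix `n_volumes x n_slices` of cardiac phases (or a
#'   vector for a single slice).
#' @param respiratory matching matrix of respiratory phases.
#' @param csf CSF time course (length `n_volumes`), or `NULL` to omit the
#'   CSF column (32-column set).
#' @param n_card,n_resp,n_int harmonic orders of the cardiac, respiratory
#'   and interaction expansions.
#' @return A `nuisance_set`: list of per-slice matrices with labelled
#'   columns.
#' @export
pnm_regressors <- function(cardiac, respiratory, csf = NULL,
                           n_card = 4, n_resp = 4, n_int = 2) {
  cardiac <- as.matrix(cardiac); respiratory <- as.matrix(respiratory)
  if (!all(dim(cardiac) == dim(respiratory))) {
    stop("cardiac and respiratory phase matrices differ in size",
         call. = FALSE)
  }
  if (!is.null(csf) && length(csf) != nrow(cardiac)) {
    stop("CSF series length does not match n_volumes", call. = FALSE)
  }
  out <- lapply(seq_len(ncol(cardiac)), function(s) {
    phc <- cardiac[, s]; phr <- respiratory[, s]
    cols <- list()
    for (m in seq_len(n_card)) {
      cols[[paste0("card_sin", m)]] <- sin(m * phc)
      cols[[paste0("card_cos", m)]] <- cos(m * phc)
    }
    for (m in seq_len(n_resp)) {
      cols[[paste0("resp_sin", m)]] <- sin(m * phr)
      cols[[paste0("resp_cos", m)]] <- cos(m * phr)
    }
    for (m in seq_len(n_int)) {
      for (n in seq_len(n_int)) {
        cols[[paste0("int_ss", m, n)]] <- sin(m * phc) * sin(n * phr)
        cols[[paste0("int_sc", m, n)]] <- sin(m * phc) * cos(n * phr)
        cols[[paste0("int_cs", m, n)]] <- cos(m * phc) * sin(n * phr)
        cols[[paste0("int_cc", m, n)]] <- cos(m * phc) * cos(n * phr)
      }
    }
    if (!is.null(csf)) cols[["csf"]] <- as.numeric(scale(csf))
    do.call(cbind, cols)
  })
  class(out) <- "nuisance_set"
  out
}

#' CSF nuisance time course
#'
#' Mean time course of the highest-variance voxels within a fluid-space
#' mask (top 5% by temporal variance by default), standardized to zero
#' mean and unit SD.
#'
#' @param timeseries a `ts_grid` or a 4-D array.
#' @param csf_mask logical 3-D array.
#' @param top_frac fraction of mask voxels to keep, ranked by variance.
#' @return A standardized numeric vector of length `n_volumes`.
#' @export
csf_regressor <- function(timeseries, csf_mask, top_frac = 0.05) {
  dat <- if (inherits(timeseries, "ts_grid")) timeseries$data else timeseries
  nv <- dim(dat)[4]
  mat <- matrix(dat, ncol = nv)[as.vector(csf_mask), , drop = FALSE]
  if (nrow(mat) == 0) stop("CSF mask is empty", call. = FALSE)
  v <- apply(mat, 1, stats::var)
  n_keep <- max(1, ceiling(top_frac * nrow(mat)))
  keep <- order(v, decreasing = TRUE)[seq_len(n_keep)]
  as.numeric(scale(colMeans(mat[keep, , drop = FALSE])))
}

#' Flag outlier volumes by dVARS and refRMS
#'
#' After mean-scaling the data (global mean set to 100 so thresholds are
#' unit-free), computes dVARS (root mean square intensity difference
#' between successive volumes, first volume 0) and refRMS (root mean
#' square difference of each volume to the temporal mean image) within the
#' mask, and flags volumes where either series exceeds its own mean plus
#' 3 SD.
#'
#' @param timeseries a `ts_grid` or 4-D array.
#' @param mask logical 3-D array (defaults to all voxels).
#' @param n_sd threshold in SD units.
#' @return An `outlier_flags` list: `volumes` (1-based flagged indices),
#'   `criterion` (per flag: "dvars", "refrms" or "both"), `dvars`,
#'   `refrms` series and the thresholds used.
#' @export
detect_outlier_volumes <- function(timeseries, mask = NULL, n_sd = 3) {
  dat <- if (inherits(timeseries, "ts_grid")) timeseries$data else timeseries
  nv <- dim(dat)[4]
  if (nv < 3) stop("need at least 3 volumes", call. = FALSE)
  mat <- matrix(dat, ncol = nv)
  if (!is.null(mask)) mat <- mat[as.vector(mask), , drop = FALSE]
  mat <- mat / mean(mat) * 100
  dvars <- c(0, sqrt(colMeans((mat[, -1, drop = FALSE] -
                                 mat[, -nv, drop = FALSE])^2)))
  ref <- rowMeans(mat)
  refrms <- sqrt(colMeans((mat - ref)^2))
  th_d <- mean(dvars) + n_sd * stats::sd(dvars)
  th_r <- mean(refrms) + n_sd * stats::sd(refrms)
  fd <- dvars > th_d; fr <- refrms > th_r
  vols <- which(fd | fr)
  crit <- ifelse(fd[vols] & fr[vols], "both",
                 ifelse(fd[vols], "dvars", "refrms"))
  structure(list(volumes = vols, criterion = crit,
                 dvars = dvars, refrms = refrms,
                 thresholds = c(dvars = th_d, refrms = th_r)),
            class = "outlier_flags")
}

#' Temporal signal-to-noise ratio per slice
#'
#' For every slice, the voxel-wise temporal mean divided by the temporal
#' SD, averaged over the mask voxels of that slice.
#'
#' @param timeseries a `ts_grid` or 4-D array.
#' @param mask logical 3-D array (e.g., the cord mask).
#' @return A tibble with columns `slice` and `tsnr`.
#' @export
tsnr <- function(timeseries, mask) {
  dat <- if (inherits(timeseries, "ts_grid")) timeseries$data else timeseries
  dd <- dim(dat)
  out <- vapply(seq_len(dd[3]), function(z) {
    m <- mask[, , z]
    if (!any(m)) return(NA_real_)
    sl <- matrix(dat[, , z, ], ncol = dd[4])[as.vector(m), , drop = FALSE]
    mu <- rowMeans(sl)
    sdv <- apply(sl, 1, stats::sd)
    mean(mu / sdv)
  }, numeric(1))
  tibble::tibble(slice = seq_len(dd[3]), tsnr = out)
}

#' QC summary of one run
#'
#' Bundles the run-level data-quality indicators used in the
#' across-day comparisons: mean refRMS (motion proxy), mean cord tSNR,
#' and an optional slice-stack angulation (degrees; an externally supplied
#' positioning proxy).
#'
#' @param timeseries a `ts_grid` or 4-D array.
#' @param mask cord mask (logical 3-D array).
#' @param angle_deg optional slice-stack angle in degrees.
#' @return A one-row tibble `refrms_mean`, `tsnr_mean`, `angle_deg`.
#' @export
qc_report <- function(timeseries, mask, angle_deg = NA_real_) {
  fl <- detect_outlier_volumes(timeseries, mask)
  ts <- tsnr(timeseries, mask)
  tibble::tibble(refrms_mean = mean(fl$refrms),
                 tsnr_mean = mean(ts$tsnr, na.rm = TRUE),
                 angle_deg = angle_deg)
}
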
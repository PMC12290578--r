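#' Write and read event schedules as tab-separated files
#'
#' Events are stored with `onset` and `duration` columns in seconds from
#' run start (0-based time).
#'
#' @param schedule event schedule tibble.
#' @param path file path.
#' @return `write_events_tsv` returns the path invisibly;
#'   `read_events_tsv` returns the schedule tibble.
#' @export
write_events_tsv <- function(schedule, path) {
  utils::write.table(as.data.frame(schedule), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.delim(path)
  stopifnot(all(c("onset", "duration") %in% names(df)))
  if (is.null(df$trial)) df$trial <- seq_len(nrow(df))
  tibble::as_tibble(df[, c("trial", "onset", "duration")])
}

#' Write and read a physiological recording
#'
#' Traces (skin conductance, pupil, respiration) go to a tab-separated
#' file `<prefix>_physio.tsv`, R-peak times to a one-column seconds file
#' `<prefix>_rpeaks.txt`, blink intervals to `<prefix>_blinks.tsv`, and a
#' JSON sidecar `<prefix>_physio.json` records the sampling rate and
#' channel names.
#'
#' @param physio a `physio_recording`.
#' @param prefix path prefix for the output files.
#' @return `write_physio` returns the file paths invisibly; `read_physio`
#'   reconstructs the `physio_recording`.
#' @export
write_physio <- function(physio, prefix) {
  tsv <- paste0(prefix, "_physio.tsv")
  utils::write.table(
    data.frame(sc = physio$sc, pupil = physio$pupil, resp = physio$resp),
    tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  rp <- paste0(prefix, "_rpeaks.txt")
  writeLines(format(physio$rpeaks, digits = 10, trim = TRUE,
                    scientific = FALSE), rp)
  bl <- paste0(prefix, "_blinks.tsv")
  utils::write.table(as.data.frame(physio$blinks), bl, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  js <- paste0(prefix, "_physio.json")
  jsonlite::write_json(
    list(sampling_rate_hz = physio$fs,
         channels = c("sc", "pupil", "resp"),
         units = c(sc = "microsiemens", pupil = "a.u.", resp = "a.u."),
         duration_s = physio$duration),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(traces = tsv, rpeaks = rp, blinks = bl, sidecar = js))
}

#' @rdname write_physio
#' @export
read_physio <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, "_physio.json"),
                              simplifyVector = TRUE)
  tr <- utils::read.delim(paste0(prefix, "_physio.tsv"))
  rp <- as.numeric(readLines(paste0(prefix, "_rpeaks.txt")))
  blf <- paste0(prefix, "_blinks.tsv")
  bl <- if (file.exists(blf)) as.matrix(utils::read.delim(blf)) else
    matrix(numeric(0), 0, 2, dimnames = list(NULL, c("start", "end")))
  fs <- side$sampling_rate_hz
  structure(list(fs = fs, time = (seq_len(nrow(tr)) - 1) / fs,
                 rpeaks = rp, sc = tr$sc, pupil = tr$pupil, resp = tr$resp,
                 blinks = bl, duration = side$duration_s, truth = NULL),
            class = "physio_recording")
}

#' Write and read a 4-D time-series grid as NIfTI
#'
#' The affine encodes the voxel size; TR is stored in the NIfTI header
#' (`pixdim[4]`). Slice-timing offsets are not representable losslessly in
#' the basic header and are reconstructed as ascending `s * TR/n_slices`.
#'
#' @param grid a `ts_grid`.
#' @param path output `.nii` (or `.nii.gz`) path.
#' @return `write_nifti_grid` returns the path invisibly;
#'   `read_nifti_grid` returns a `ts_grid` (without ground truth).
#' @export
write_nifti_grid <- function(grid, path) {
  img <- RNifti::asNifti(grid$data)
  RNifti::pixdim(img) <- c(grid$voxel_size, grid$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_grid
#' @export
read_nifti_grid <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  dat <- array(as.numeric(img), dim = dim(img))
  nz <- dim(dat)[3]
  structure(list(data = dat, tr = pd[4], voxel_size = pd[1:3],
                 slice_offsets = (seq_len(nz) - 1) * pd[4] / nz,
                 truth = NULL),
            class = "ts_grid")
}

#' Write the ground truth of a synthetic study as JSON
#'
#' @param ground_truth a [generate_amplitudes()] result.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(
    list(b = ground_truth$b, w = ground_truth$w, amp = ground_truth$amp,
         physio_amp = ground_truth$physio_amp,
         true_icc = ground_truth$true_icc),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Write a nuisance regressor set as delimited matrices
#'
#' One tab-separated file per slice with a header of column labels.
#'
#' @param nuisance a [pnm_regressors()] result.
#' @param prefix path prefix; files are `<prefix>_slice<k>.tsv`.
#' @return The paths, invisibly.
#' @export
write_nuisance <- function(nuisance, prefix) {
  paths <- vapply(seq_along(nuisance), function(s) {
    path <- sprintf("%s_slice%02d.tsv", prefix, s)
    utils::write.table(as.data.frame(nuisance[[s]]), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    path
  }, character(1))
  invisible(paths)
}
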
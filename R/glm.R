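#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response peak minus undershoot),
#' peak-normalized to 1. Defaults: peak delay 6 s, undershoot delay 16 s,
#' dispersions 1 s, peak-to-undershoot ratio 6, giving a maximum near 5 s
#' and an undershoot around 15 s.
#'
#' @param dt sampling interval in seconds.
#' @param duration kernel length in seconds.
#' @param peak_delay,under_delay,peak_disp,under_disp,ratio shape
#'   parameters (seconds; ratio unitless).
#' @return Numeric kernel sampled at `seq(0, duration, by = dt)`, max 1.
#' @export
#' @examples
#' h <- double_gamma_hrf(0.1)
#' which.max(h) # peak near 5 s
double_gamma_hrf <- function(dt, duration = 32, peak_delay = 6,
                             under_delay = 16, peak_disp = 1,
                             under_disp = 1, ratio = 6) {
  stopifnot(dt > 0)
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    stats::dgamma(t, shape = under_delay / under_disp,
                  scale = under_disp) / ratio
  h / max(h)
}

#' Evoked-response regressor for an event schedule
#'
#' Convolves the stimulus boxcar with the double-gamma HRF on a fine time
#' grid and samples the result at the requested acquisition times. The
#' regressor is scaled so that an isolated trial peaks at 1; a voxel
#' responding with fractional amplitude `A` then has true regression weight
#' `A` times its baseline intensity.
#'
#' @param schedule event schedule tibble (`onset`, `duration`).
#' @param times acquisition times in seconds.
#' @param dt_fine fine-grid resolution for the convolution, seconds.
#' @param derivative return the temporal derivative instead.
#' @param hrf_args list of overrides passed to [double_gamma_hrf()].
#' @return Numeric vector, one value per element of `times`.
#' @export
task_regressor <- function(schedule, times, dt_fine = 0.1,
                           derivative = FALSE, hrf_args = list()) {
  t_end <- max(times) + dt_fine
  tg <- seq(0, t_end + 32, by = dt_fine)
  box <- numeric(length(tg))
  if (nrow(schedule) > 0) {
    for (i in seq_len(nrow(schedule))) {
      box[tg >= schedule$onset[i] &
            tg < schedule$onset[i] + schedule$duration[i]] <- 1
    }
  }
  hrf <- do.call(double_gamma_hrf, c(list(dt = dt_fine), hrf_args))
  conv <- stats::convolve(box, rev(hrf), type = "open")[seq_along(tg)] * dt_fine
  # normalize to unit single-trial peak
  box1 <- numeric(length(tg))
  dur1 <- if (nrow(schedule) > 0) schedule$duration[1] else 1
  box1[tg < dur1] <- 1
  pk <- max(stats::convolve(box1, rev(hrf), type = "open")[seq_along(tg)]) *
    dt_fine
  conv <- conv / pk
  if (derivative) conv <- c(0, diff(conv)) / dt_fine
  stats::approx(tg, conv, xout = times, rule = 2)$y
}

# cosine (DCT-II) drift basis: columns with period > cutoff seconds
dct_basis <- function(n_volumes, tr, cutoff = 100) {
  K <- floor(2 * n_volumes * tr / cutoff)
  if (K < 1) return(NULL)
  v <- seq_len(n_volumes) - 1
  b <- vapply(seq_len(K), function(k) {
    cos(pi * k * (2 * v + 1) / (2 * n_volumes))
  }, numeric(n_volumes))
  colnames(b) <- paste0("dct", seq_len(K))
  b
}

#' Build first-level slice-wise design matrices
#'
#' Assembles, per slice, the GLM design: the HRF-convolved task regressor
#' (one column per schedule when a list of schedules is given, as in
#' split-half fits) and its temporal derivative, the slice's nuisance
#' columns (e.g., the 33-column physiological set from [pnm_regressors()]),
#' optional motion columns, one unit spike column per flagged outlier
#' volume, an intercept and a cosine drift basis implementing high-pass
#' filtering at `highpass_cutoff` seconds. Task and derivative columns are
#' sampled at volume onsets and shared across slices; only nuisance (and
#' contralateral) blocks differ by slice.
#'
#' @param schedule event schedule tibble, or a named list of schedules for
#'   multiple task regressors.
#' @param n_volumes,tr run geometry.
#' @param nuisance optional `nuisance_set` (list of per-slice matrices);
#'   `NULL` gives a single shared design.
#' @param flags optional [detect_outlier_volumes()] result or integer
#'   vector of outlier volume indices.
#' @param motion optional `n_volumes x 2` motion-regressor matrix (shared)
#'   or list of per-slice matrices.
#' @param highpass_cutoff high-pass cutoff in seconds (`Inf` to disable).
#' @param derivative include the temporal-derivative column.
#' @return A `design_matrix`: list with `X` (list of per-slice design
#'   matrices with labelled columns), `task_idx`, `n_volumes`, `tr`.
#' @export
build_design <- function(schedule, n_volumes, tr, nuisance = NULL,
                         flags = NULL, motion = NULL,
                         highpass_cutoff = 100, derivative = TRUE) {
  tv <- (seq_len(n_volumes) - 1) * tr
  schedules <- if (inherits(schedule, "data.frame")) {
    list(task = schedule)
  } else schedule
  if (is.null(names(schedules))) {
    names(schedules) <- paste0("task", seq_along(schedules))
  }
  task <- vapply(schedules, task_regressor, numeric(n_volumes), times = tv)
  fixed <- task
  if (derivative) {
    der <- vapply(schedules, task_regressor, numeric(n_volumes),
                  times = tv, derivative = TRUE)
    colnames(der) <- paste0(colnames(task), "_deriv")
    fixed <- cbind(task, der)
  }
  if (!is.null(flags)) {
    vols <- if (inherits(flags, "outlier_flags")) flags$volumes else flags
    if (length(vols) > 0) {
      sp <- matrix(0, n_volumes, length(vols),
                   dimnames = list(NULL, paste0("spike", vols)))
      sp[cbind(vols, seq_along(vols))] <- 1
      fixed <- cbind(fixed, sp)
    }
  }
  icept <- matrix(1, n_volumes, 1, dimnames = list(NULL, "intercept"))
  dct <- if (is.finite(highpass_cutoff)) {
    dct_basis(n_volumes, tr, highpass_cutoff)
  } else NULL

  n_slices <- if (is.null(nuisance)) 1L else length(nuisance)
  X <- lapply(seq_len(n_slices), function(s) {
    nuis <- if (!is.null(nuisance)) nuisance[[s]] else NULL
    mot <- if (is.null(motion)) NULL
    else if (is.list(motion)) motion[[s]] else motion
    if (!is.null(mot)) {
      mot <- as.matrix(mot)
      colnames(mot) <- paste0("motion", seq_len(ncol(mot)))
    }
    x <- cbind(fixed, nuis, mot, icept, dct)
    # identically zero columns (e.g., a task regressor with no events) are
    # structurally fine; flag genuine collinearity only
    nonzero <- colSums(x^2) > 0
    qrx <- qr(x[, nonzero, drop = FALSE])
    if (qrx$rank < sum(nonzero)) {
      bad <- colnames(x)[nonzero][qrx$pivot[(qrx$rank + 1):sum(nonzero)]]
      stop("design matrix rank deficient in slice ", s, "; aliased columns: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    x
  })
  structure(list(X = X, task_idx = seq_along(schedules),
                 task_names = names(schedules),
                 n_volumes = n_volumes, tr = tr),
            class = "design_matrix")
}

#' Gaussian spatial smoothing of a 4-D grid
#'
#' Separable Gaussian smoothing of every volume, with the kernel width
#' given in millimeters so anisotropic voxels are respected. Edges are
#' zero-padded (the kernel is normalized once, so total image sum is
#' preserved for signal away from the grid boundary).
#'
#' @param grid a `ts_grid` or 4-D array.
#' @param fwhm_mm full width at half maximum in mm (0 = identity).
#' @param voxel_size mm triple (taken from the `ts_grid` when available).
#' @return Same type as the input, smoothed.
#' @export
smooth_spatial <- function(grid, fwhm_mm, voxel_size = NULL) {
  is_grid <- inherits(grid, "ts_grid")
  dat <- if (is_grid) grid$data else grid
  if (is.null(voxel_size)) {
    voxel_size <- if (is_grid) grid$voxel_size else c(1, 1, 1)
  }
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) return(grid)
  dd <- dim(dat)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size
  for (ax in 1:3) {
    if (sig[ax] < 1e-3) next
    r <- ceiling(3 * sig[ax])
    k <- stats::dnorm(-r:r, sd = sig[ax])
    k <- k / sum(k)
    n <- dd[ax]
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- k[ok]
    }
    perm <- c(ax, setdiff(1:4, ax))
    m <- matrix(aperm(dat, perm), nrow = n)
    dat <- aperm(array(K %*% m, dim = dd[perm]), order(perm))
  }
  if (is_grid) { grid$data <- dat; grid } else dat
}

#' Fit the first-level voxel-wise GLM
#'
#' Ordinary least squares per voxel with the slice-appropriate design.
#' For each task regressor, returns the estimate map, its standard error,
#' the t statistic and the z equivalent (standard-normal quantile of the t
#' cumulative probability at the residual degrees of freedom). Voxels with
#' zero residual error get `NA` z.
#'
#' @param timeseries a `ts_grid` or 4-D array.
#' @param design a [build_design()] result; its number of slice designs
#'   must be 1 (shared) or equal the grid's slice count.
#' @return A `stat_map` (single task): list with 3-D arrays `beta`, `se`,
#'   `t`, `z`, scalar `dof`, plus `baseline` (intercept map). For multiple
#'   task regressors, a named list of `stat_map`s.
#' @export
fit_glm <- function(timeseries, design) {
  dat <- if (inherits(timeseries, "ts_grid")) timeseries$data else timeseries
  dd <- dim(dat)
  nz <- dd[3]; nv <- dd[4]
  stopifnot(nv == design$n_volumes)
  shared <- length(design$X) == 1
  if (!shared && length(design$X) != nz) {
    stop("design has ", length(design$X), " slice blocks but data has ",
         nz, " slices", call. = FALSE)
  }
  nt <- length(design$task_idx)
  beta <- se <- array(NA_real_, dim = c(dd[1:3], nt))
  base <- array(NA_real_, dim = dd[1:3])
  dof <- NA_real_
  for (z in seq_len(nz)) {
    X <- design$X[[if (shared) 1 else z]]
    Y <- t(matrix(dat[, , z, ], ncol = nv))
    qrx <- qr(X)
    cf <- qr.coef(qrx, Y)
    res <- qr.resid(qrx, Y)
    dof <- nv - qrx$rank
    sigma2 <- colSums(res^2) / dof
    unpiv <- order(qrx$pivot)
    xtxi <- chol2inv(qr.R(qrx))[unpiv, unpiv, drop = FALSE]
    ic <- which(colnames(X) == "intercept")
    base[, , z] <- cf[ic, ]
    for (j in seq_len(nt)) {
      ti <- design$task_idx[j]
      beta[, , z, j] <- cf[ti, ]
      se[, , z, j] <- sqrt(sigma2 * xtxi[ti, ti])
    }
  }
  make_map <- function(j) {
    b <- array(beta[, , , j], dim = dd[1:3])
    s <- array(se[, , , j], dim = dd[1:3])
    tmap <- b / s
    tmap[s == 0] <- NA_real_
    z <- t_to_z(tmap, dof)
    structure(list(beta = b, se = s, t = tmap, z = z, dof = dof,
                   baseline = base), class = "stat_map")
  }
  if (nt == 1) make_map(1) else {
    stats::setNames(lapply(seq_len(nt), make_map), design$task_names)
  }
}

# numerically stable t -> z conversion via log tail probabilities
t_to_z <- function(t, dof) {
  z <- t
  ok <- is.finite(t)
  pos <- ok & t >= 0
  z[pos] <- stats::qnorm(stats::pt(t[pos], dof, lower.tail = FALSE,
                                   log.p = TRUE),
                         lower.tail = FALSE, log.p = TRUE)
  neg <- ok & t < 0
  z[neg] <- stats::qnorm(stats::pt(t[neg], dof, lower.tail = TRUE,
                                   log.p = TRUE),
                         lower.tail = TRUE, log.p = TRUE)
  z
}

#' Append a contralateral-ROI regressor to each slice design
#'
#' Extracts, per slice, the mean time course of the contralateral mask
#' voxels, demeans it, and appends it as an extra slice-wise nuisance
#' column (used to absorb spontaneous fluctuations shared between the left
#' and right dorsal horns).
#'
#' @param design a [build_design()] result.
#' @param timeseries a `ts_grid` or 4-D array.
#' @param contralateral_mask logical 3-D array; every slice it touches must
#'   be non-empty on slices with data.
#' @return The augmented `design_matrix` (one design per slice).
#' @export
add_contralateral_regressor <- function(design, timeseries,
                                        contralateral_mask) {
  dat <- if (inherits(timeseries, "ts_grid")) timeseries$data else timeseries
  dd <- dim(dat)
  nz <- dd[3]
  Xs <- lapply(seq_len(nz), function(z) {
    m <- contralateral_mask[, , z]
    if (!any(m)) {
      stop("contralateral mask empty in slice ", z, call. = FALSE)
    }
    sl <- matrix(dat[, , z, ], ncol = dd[4])[as.vector(m), , drop = FALSE]
    reg <- colMeans(sl) - mean(sl)
    X <- design$X[[if (length(design$X) == 1) 1 else z]]
    cbind(X, contralateral = reg)
  })
  design$X <- Xs
  design
}

#' One-sample group inference by sign-flipping permutation
#'
#' Tests the group mean against zero with a one-sample t statistic whose
#' null distribution is generated by randomly flipping the sign of each
#' participant's map (valid under symmetric errors). Family-wise error
#' corrected p-values come from the permutation distribution of the
#' maximum statistic over the mask. When `2^n <= n_perm` all sign
#' combinations are enumerated; otherwise `n_perm` random flips (always
#' including the identity) are used.
#'
#' @param maps participant maps: an `n x V` matrix (V = mask voxels), a
#'   list of 3-D arrays, or a list of `stat_map`s (their `beta` used).
#' @param mask logical 3-D array selecting analysis voxels (required for
#'   array/`stat_map` input; ignored for matrix input).
#' @param n_perm maximum number of permutations.
#' @param seed integer seed for the random flips.
#' @param alternative "greater" (default) tests for positive mean.
#' @return A `group_result`: 3-D arrays `t`, `p_unc`, `p_fwe` (`NA`
#'   outside the mask; plain vectors for matrix input), logical
#'   `sig_fwe05`, and `n_perm_used`.
#' @export
group_onesample_perm <- function(maps, mask = NULL, n_perm = 1000,
                                 seed = 1L, alternative = "greater") {
  if (is.list(maps)) {
    if (inherits(maps[[1]], "stat_map")) maps <- lapply(maps, `[[`, "beta")
    if (is.null(mask)) stop("mask required for array input", call. = FALSE)
    if (!any(mask)) stop("mask is empty", call. = FALSE)
    Xm <- do.call(rbind, lapply(maps, function(a) a[mask]))
  } else {
    Xm <- as.matrix(maps) # rows = participants, columns = mask voxels
  }
  n <- nrow(Xm)
  if (n < 2) stop("need at least 2 maps", call. = FALSE)
  sgn <- if (alternative == "less") -1 else 1
  Xm <- sgn * Xm

  if (2^n <= n_perm) {
    S <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    S <- S[order(rowSums(S == 1), decreasing = TRUE), , drop = FALSE]
  } else {
    withr_seed(seed, {
      S <- matrix(sample(c(-1, 1), (n_perm - 1) * n, replace = TRUE),
                  n_perm - 1, n)
    })
    S <- rbind(rep(1, n), S)
  }
  n_used <- nrow(S)
  ss <- colSums(Xm^2)
  M <- (S %*% Xm) / n
  V <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
  Tm <- M / sqrt(pmax(V, 0) / n)
  Tm[V <= 0] <- ifelse(M[V <= 0] > 0, Inf, ifelse(M[V <= 0] < 0, -Inf, 0))
  t_obs <- Tm[1, ]
  maxT <- apply(Tm, 1, max)
  p_unc <- colMeans(sweep(Tm, 2, t_obs, ">=") )
  p_fwe <- vapply(t_obs, function(t0) mean(maxT >= t0), numeric(1))

  if (!is.null(mask) && is.array(mask)) {
    put <- function(v) { a <- array(NA_real_, dim(mask)); a[mask] <- v; a }
    res <- list(t = put(sgn * t_obs), p_unc = put(p_unc), p_fwe = put(p_fwe),
                sig_fwe05 = put(p_fwe) <= 0.05 & mask)
    res$sig_fwe05[is.na(res$sig_fwe05)] <- FALSE
  } else {
    res <- list(t = sgn * t_obs, p_unc = p_unc, p_fwe = p_fwe,
                sig_fwe05 = p_fwe <= 0.05)
  }
  res$n_perm_used <- n_used
  class(res) <- "group_result"
  res
}

#' Conjunction of two significance masks
#'
#' Voxel-wise logical AND of two binary maps (e.g., the significant voxels
#' of day 1 and day 2).
#'
#' @param sig_mask_day1,sig_mask_day2 logical arrays of equal dimension.
#' @return Logical array.
#' @export
conjunction <- function(sig_mask_day1, sig_mask_day2) {
  stopifnot(all(dim(sig_mask_day1) == dim(sig_mask_day2)))
  sig_mask_day1 & sig_mask_day2
}
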
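#' Intraclass correlation ICC(3,1) with confidence interval
#'
#' Two-way mixed-effects, single-measure, consistency ICC: from the
#' participants x sessions layout the between-participants mean squares
#' (BMS) and error mean squares (EMS) are formed, and
#' \deqn{ICC(3,1) = (BMS - EMS) / (BMS + (k - 1) EMS),}
#' the ratio of between-participant variance to total variance. The 95%
#' confidence interval is the Shrout--Fleiss F-based interval. Participants
#' with any missing session are dropped (complete-case analysis); negative
#' estimates are reported as computed.
#'
#' @param data a tidy data frame with columns `participant`, `session`,
#'   `value`, or a numeric matrix with one row per participant and one
#'   column per session.
#' @param conf_level confidence level of the interval.
#' @return An `icc_fit` object: `icc`, `ci` (length 2), `category`
#'   ([categorize_icc()]), `n_used`, `k`, `bms`, `ems`, `jms`.
#' @export
#' @examples
#' m <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 1))
#' icc31(m)$icc
icc31 <- function(data, conf_level = 0.95) {
  m <- as_measure_matrix(data)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (k < 2) stop("need at least 2 sessions", call. = FALSE)
  if (n < 3) stop("need at least 3 complete participants", call. = FALSE)

  g <- mean(m)
  rm_ <- rowMeans(m); cm <- colMeans(m)
  bms <- k * sum((rm_ - g)^2) / (n - 1)
  jms <- n * sum((cm - g)^2) / (k - 1)
  sse <- sum((m - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm) + g)^2)
  ems <- sse / ((n - 1) * (k - 1))

  denom <- bms + (k - 1) * ems
  if (denom == 0) {
    stop("all values identical; ICC undefined (zero total variance)",
         call. = FALSE)
  }
  icc <- (bms - ems) / denom
  alpha <- 1 - conf_level
  if (ems > 0) {
    Fobs <- bms / ems
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    FL <- Fobs / stats::qf(1 - alpha / 2, df1, df2)
    FU <- Fobs * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
  } else {
    ci <- c(1, 1)
  }
  structure(list(icc = icc, ci = ci, category = categorize_icc(icc),
                 n_used = n, k = k, bms = bms, ems = ems, jms = jms,
                 conf_level = conf_level),
            class = "icc_fit")
}

as_measure_matrix <- function(data) {
  if (is.matrix(data)) return(data)
  stopifnot(is.data.frame(data),
            all(c("participant", "session", "value") %in% names(data)))
  wide <- tidyr::pivot_wider(
    data[, c("participant", "session", "value")],
    names_from = "session", values_from = "value")
  as.matrix(wide[, -1, drop = FALSE])
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf("ICC(3,1) = %.3f [%.3f, %.3f] (%s; n = %d, k = %d)\n",
              x$icc, x$ci[1], x$ci[2], x$category, x$n_used, x$k))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ICC fit
#' @param x an `icc_fit`.
#' @param ... unused.
#' @return A one-row tibble: `icc`, `conf.low`, `conf.high`, `category`,
#'   `n`, `k`.
#' @export
tidy.icc_fit <- function(x, ...) {
  tibble::tibble(icc = x$icc, conf.low = x$ci[1], conf.high = x$ci[2],
                 category = x$category, n = x$n_used, k = x$k)
}

#' Glance at an ICC fit
#' @param x an `icc_fit`.
#' @param ... unused.
#' @return A one-row tibble with the mean-squares components.
#' @export
glance.icc_fit <- function(x, ...) {
  tibble::tibble(bms = x$bms, ems = x$ems, jms = x$jms,
                 n = x$n_used, k = x$k, conf.level = x$conf_level)
}

#' Interpretation band of an ICC estimate
#'
#' Cicchetti's conventional bands: below 0.4 "poor", 0.4 to below 0.6
#' "fair", 0.6 to below 0.75 "good", 0.75 to 1 "excellent" (lower-inclusive
#' half-open bands; negative values are "poor").
#'
#' @param icc numeric vector of ICC estimates (each at most 1).
#' @return Character vector of categories.
#' @export
#' @examples
#' categorize_icc(c(0.39, 0.72, -0.2, 0.75))
categorize_icc <- function(icc) {
  stopifnot(all(icc <= 1 + 1e-12, na.rm = TRUE))
  cut(icc, breaks = c(-Inf, 0.4, 0.6, 0.75, Inf), right = FALSE,
      labels = c("poor", "fair", "good", "excellent")) |>
    as.character()
}

#' Split trials into two subsets
#'
#' @param schedule event schedule tibble (or an integer trial count).
#' @param scheme `"odd_even"` (trials 1, 3, ... vs 2, 4, ...) or
#'   `"early_late"` (first half vs second half).
#' @return A list of two integer vectors of trial numbers.
#' @export
split_trials <- function(schedule, scheme = c("odd_even", "early_late")) {
  scheme <- match.arg(scheme)
  trials <- if (is.numeric(schedule) && length(schedule) == 1) {
    seq_len(schedule)
  } else schedule$trial
  if (scheme == "odd_even") {
    list(trials[trials %% 2 == 1], trials[trials %% 2 == 0])
  } else {
    half <- ceiling(length(trials) / 2)
    list(trials[seq_len(half)], trials[-seq_len(half)])
  }
}

#' Split-half reliability from per-subset values
#'
#' Computes ICC(3,1) between the two trial subsets separately for each day
#' and averages the point estimates across days (confidence intervals are
#' reported per day). Input is one scalar per participant, day and subset
#' -- e.g., per-subset run means of an autonomic response, or ROI metrics
#' from a GLM refit with one task regressor per subset.
#'
#' @param data tidy data frame with columns `participant`, `day`, `subset`
#'   (two levels), `value`.
#' @return A list: `icc` (mean across days), `per_day` tibble of tidied
#'   day-wise fits, `fits` (the `icc_fit`s).
#' @export
split_half_icc <- function(data) {
  stopifnot(all(c("participant", "day", "subset", "value") %in% names(data)))
  days <- sort(unique(data$day))
  fits <- lapply(days, function(d) {
    dd <- data[data$day == d, ]
    icc31(data.frame(participant = dd$participant,
                     session = dd$subset, value = dd$value))
  })
  per_day <- dplyr::bind_rows(lapply(fits, tidy.icc_fit))
  per_day$day <- days
  list(icc = mean(per_day$icc), per_day = per_day, fits = fits)
}

#' Paired two-sided t-test for a session difference
#'
#' Tests whether a measure differs systematically between the two days.
#'
#' @param data tidy data frame (`participant`, `session`, `value`) or an
#'   `n x 2` matrix.
#' @return A one-row tibble `estimate` (mean day difference), `t`, `df`,
#'   `p`, `n`.
#' @export
session_difference_test <- function(data) {
  m <- as_measure_matrix(data)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  stopifnot(ncol(m) == 2)
  if (nrow(m) < 2) stop("need at least 2 complete pairs", call. = FALSE)
  d <- m[, 1] - m[, 2]
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(tibble::tibble(estimate = 0, t = 0, df = length(d) - 1,
                            p = 1, n = length(d)))
    }
    stop("zero variance of the day differences; t statistic undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(m[, 1], m[, 2], paired = TRUE)
  tibble::tibble(estimate = unname(tt$estimate), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value, n = length(d))
}

#' Directed Pearson correlation between two measures
#'
#' Pearson's r over complete pairs with a one-tailed p-value in the
#' expected direction (e.g., negative for heart-period responses, where a
#' more negative dip indicates stronger cardiac acceleration).
#'
#' @param x,y numeric vectors (pairwise; `NA`s dropped).
#' @param expected_sign +1 or -1, direction of the alternative.
#' @return A one-row tibble `r`, `p_one_tailed`, `n`, `expected_sign`.
#' @export
correlate_measures <- function(x, y, expected_sign = 1) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input; correlation undefined", call. = FALSE)
  }
  alt <- if (expected_sign >= 0) "greater" else "less"
  ct <- stats::cor.test(x, y, alternative = alt, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_one_tailed = ct$p.value,
                 n = length(x), expected_sign = sign(expected_sign))
}

#' Correlation between day-to-day QC change and BOLD change
#'
#' Correlates the absolute across-day difference of a data-quality metric
#' with the absolute across-day difference of a BOLD amplitude metric,
#' with a positive expected direction (worse stability, larger BOLD
#' change).
#'
#' @param abs_day_diff_qc,abs_day_diff_bold numeric vectors of absolute
#'   across-day differences per participant.
#' @return As [correlate_measures()].
#' @export
qc_difference_correlation <- function(abs_day_diff_qc, abs_day_diff_bold) {
  correlate_measures(abs_day_diff_qc, abs_day_diff_bold, expected_sign = 1)
}
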
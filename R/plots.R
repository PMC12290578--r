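#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ICC fit against its interpretation bands
#'
#' @param object an [icc31()] fit.
#' @param ... unused.
#' @return A ggplot: the estimate with its confidence interval over the
#'   poor/fair/good/excellent bands.
#' @export
autoplot.icc_fit <- function(object, ...) {
  bands <- tibble::tibble(
    lo = c(-1, 0.4, 0.6, 0.75), hi = c(0.4, 0.6, 0.75, 1),
    category = factor(c("poor", "fair", "good", "excellent"),
                      levels = c("poor", "fair", "good", "excellent")))
  est <- tidy.icc_fit(object)
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = bands,
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi, ymin = -0.25,
                   ymax = 0.25, fill = .data$category), alpha = 0.35) +
    ggplot2::geom_pointrange(
      data = est,
      ggplot2::aes(x = .data$icc, xmin = .data$conf.low,
                   xmax = .data$conf.high, y = 0)) +
    ggplot2::scale_fill_brewer(palette = "RdYlGn") +
    ggplot2::coord_cartesian(xlim = c(min(-0.1, est$conf.low), 1)) +
    ggplot2::labs(x = "ICC(3,1)", y = NULL, fill = "band") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Forest plot of a reliability summary table
#'
#' @param reliability the `reliability` tibble of a [run_pipeline()]
#'   result (columns `icc`, `conf.low`, `conf.high`, `measure`, and
#'   optionally `mask`, `stat`, `metric`).
#' @return A ggplot with one row per measure/metric combination.
#' @export
plot_reliability <- function(reliability) {
  df <- dplyr::mutate(
    reliability,
    label = paste(
      .data$measure,
      ifelse(is.na(.data$mask), "", paste0(.data$mask, " ")),
      ifelse(is.na(.data$metric), "",
             paste(.data$stat, .data$metric))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$icc, y = .data$label)) +
    ggplot2::annotate("rect", xmin = c(-Inf, 0.4, 0.6, 0.75),
                      xmax = c(0.4, 0.6, 0.75, 1),
                      ymin = -Inf, ymax = Inf,
                      fill = c("#d7191c", "#fdae61", "#a6d96a", "#1a9641"),
                      alpha = 0.2) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "ICC(3,1) with 95% CI", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-trial autonomic responses
#'
#' @param object a `response_summary` tibble from [extract_hpr()],
#'   [extract_scr()] or [extract_pdr()].
#' @param ... unused.
#' @return A ggplot of per-trial values with the run mean.
#' @export
autoplot.response_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$trial, y = .data$value)) +
    ggplot2::geom_hline(yintercept = mean(object$value),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "trial", y = unique(object$measure)) +
    ggplot2::theme_minimal()
}

#' Slice montage of a statistic map
#'
#' @param object a `stat_map`.
#' @param what field to display (`"z"`, `"t"` or `"beta"`).
#' @param ... unused.
#' @return A ggplot tile montage, one facet per slice.
#' @export
autoplot.stat_map <- function(object, what = "z", ...) {
  a <- object[[what]]
  dd <- dim(a)
  df <- expand.grid(x = seq_len(dd[1]), y = seq_len(dd[2]),
                    slice = seq_len(dd[3]))
  df$value <- as.vector(a)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~slice) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "grey95",
                                  high = "red") +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = what) +
    ggplot2::theme_void()
}
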
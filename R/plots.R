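#' Plot a time-frequency map
#'
#' Condition-averaged power as a frequency x time raster (normalized units
#' when the TFR has been baseline-normalized).
#'
#' @param object a `gs_tfr` with power.
#' @param label condition to average (default: all trials).
#' @param channels channel subset (default: all EEG channels).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gs_tfr <- function(object, label = NULL, channels = NULL, ...) {
  channels <- channels %||%
    object$channel_labels[object$channel_kind == "EEG"]
  ci <- match(channels, object$channel_labels)
  rsel <- if (is.null(label)) seq_along(object$labels) else
    which(object$labels == label)
  m <- apply(object$power[rsel, ci, , , drop = FALSE], c(3, 4), mean)
  df <- tidyr::expand_grid(freq = object$freqs, time = object$times)
  df$power <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$freq,
                                   fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(
      name = if (object$normalized) "power (baseline SD)" else "power") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)",
                  title = if (is.null(label)) "average power" else label) +
    ggplot2::theme_minimal()
}

#' Plot a statistical contrast
#'
#' Per-band test-statistic time courses with Holm-corrected significant
#' windows shaded.
#'
#' @param object a `gs_contrast` from [wilcoxon_map()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gs_contrast <- function(object, ...) {
  tb <- object$table
  stat_col <- if ("z" %in% names(tb)) "z" else "t"
  p <- ggplot2::ggplot(tb, ggplot2::aes(.data$time, .data[[stat_col]])) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~band) +
    ggplot2::labs(x = "time (s)", y = paste(stat_col, "statistic"),
                  title = object$test) +
    ggplot2::theme_minimal()
  if (nrow(object$windows))
    p <- p + ggplot2::geom_rect(
      data = object$windows,
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end),
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "orange",
      inherit.aes = FALSE)
  p
}

#' Plot decoding performance across repetitions
#'
#' One point per cross-validation repetition and metric, with the
#' repetition means overlaid.
#'
#' @param object a `gs_clf_report` from [train_eval_cv()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gs_clf_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$repetitions,
    cols = c("accuracy", "sensitivity", "specificity", "balanced"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red",
                          size = 3) +
    ggplot2::labs(x = NULL, y = "percent",
                  title = sprintf("linear SVM, %g-%g Hz",
                                  object$band[1], object$band[2])) +
    ggplot2::theme_minimal()
}

#' Plot a per-channel connectivity summary on the scalp
#'
#' Mean absolute connectivity per channel at its montage position, one
#' panel per band.
#'
#' @param object a `gs_connectivity` from [connectivity_summary()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gs_connectivity <- function(object, ...) {
  pos <- montage_lookup(unique(object$channel))
  df <- dplyr::left_join(tibble::as_tibble(object), pos,
                         by = c(channel = "label"))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   size = .data$mean_abs,
                                   colour = .data$mean_abs)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~band) +
    ggplot2::coord_fixed() +
    ggplot2::scale_colour_viridis_c(name = "mean |conn|") +
    ggplot2::scale_size(guide = "none") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
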
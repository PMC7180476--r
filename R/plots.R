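#' @import ggplot2
NULL

#' Plot a gait signal with detections and annotations
#'
#' Draws the angular-velocity trace and overlays detected stance intervals
#' (and, optionally, the annotated ground truth) as shaded bands.
#'
#' @param signal A `gait_signal`.
#' @param detections Optional detections tibble.
#' @param annotations Optional annotations tibble.
#' @return A ggplot object.
#' @export
plot_detections <- function(signal, detections = NULL, annotations = NULL) {
  p <- ggplot(as_tibble(signal), aes(x = .data$sample_index, y = .data$gyro_y)) +
    geom_line(linewidth = 0.3) +
    labs(
      x = "sample", y = "angular velocity (deg/s)",
      title = sprintf("Trial %s", trial_id(signal))
    ) +
    theme_minimal()
  if (!is.null(annotations) && nrow(annotations)) {
    p <- p + geom_rect(
      data = as_tibble(annotations),
      aes(xmin = .data$ic, xmax = .data$fc, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.15
    )
  }
  if (!is.null(detections) && nrow(detections)) {
    p <- p + geom_rect(
      data = as_tibble(detections),
      aes(xmin = .data$ic, xmax = .data$fc, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = NA, colour = "firebrick", linewidth = 0.3
    )
  }
  p
}

#' @export
autoplot.gait_signal <- function(object, ...) {
  plot_detections(object)
}

#' @export
autoplot.step_template <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$sample_index, y = .data$value)) +
    geom_line() +
    labs(
      x = "sample", y = "normalised angular velocity",
      title = sprintf("Template %s", object$id)
    ) +
    theme_minimal()
}

#' @export
autoplot.template_library <- function(object, ...) {
  df <- bind_rows(purrr::map(object$templates, tidy))
  ggplot(df, aes(x = .data$sample_index, y = .data$value)) +
    geom_line() +
    facet_wrap(~template_id, scales = "free") +
    labs(x = "sample", y = "normalised angular velocity") +
    theme_minimal()
}

#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tidy(object),
    dplyr::all_of(c("delta_start_ms", "delta_end_ms", "delta_duration_ms")),
    names_to = "metric", values_to = "error_ms"
  )
  ggplot(df, aes(x = .data$error_ms)) +
    geom_histogram(bins = 30, fill = "grey40") +
    facet_wrap(~metric, scales = "free") +
    labs(x = "absolute error (ms)", y = "steps") +
    theme_minimal()
}

#' @export
autoplot.gait_experiment <- function(object, ...) {
  if (object$which == "E3") {
    df <- tidyr::pivot_longer(
      object$summary,
      dplyr::all_of(c("delta_start_ms", "delta_end_ms", "delta_duration_ms")),
      names_to = "metric", values_to = "mean_abs_error_ms"
    )
    return(
      ggplot(df, aes(x = .data$z, y = .data$mean_abs_error_ms, colour = .data$metric)) +
        geom_line() +
        geom_point(size = 1) +
        labs(x = "scan half-width z (samples)", y = "mean absolute error (ms)") +
        theme_minimal()
    )
  }
  if (object$which == "E4") {
    df <- bind_rows(purrr::imap(object$differences, function(v, m) {
      tibble(metric = m, rank = seq_along(v), difference_ms = v)
    }))
    return(
      ggplot(df, aes(x = .data$rank, y = .data$difference_ms)) +
        geom_col(width = 1, fill = "grey40") +
        facet_wrap(~metric, scales = "free_x") +
        labs(
          x = "step (sorted)",
          y = "abs. error, DTW minus Pearson (ms)"
        ) +
        theme_minimal()
    )
  }
  df <- object$summary
  xvar <- if ("strategy" %in% names(df)) "strategy" else "criterion"
  yvar <- if ("delta_start_ms" %in% names(df)) "delta_start_ms" else names(df)[[2]]
  ggplot(df, aes(x = .data[[xvar]], y = .data[[yvar]])) +
    geom_col(fill = "grey40") +
    {
      if ("refinement" %in% names(df)) facet_wrap(~refinement) else NULL
    } +
    labs(y = "mean |dStart| (ms)") +
    theme_minimal()
}
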
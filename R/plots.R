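#' Plot a trial's channel traces
#'
#' Time courses of C3, Cz, C4 with the imagery interval shaded.
#'
#' @param trial An `mi_trial` from [generate_trial()], or one row of a
#'   trial table.
#' @param mi_interval Imagery interval to shade, in seconds.
#' @return A ggplot object.
#' @export
plot_trial <- function(trial, mi_interval = c(3, 7)) {
  if (is.data.frame(trial)) {
    data <- trial$data[[1]]
    fs <- trial$sampling_rate[[1]]
  } else {
    data <- trial$data
    fs <- trial$sampling_rate
    mi_interval <- trial$mi_interval %??% mi_interval
  }
  df <- tibble::tibble(
    time = rep((seq_len(ncol(data)) - 1) / fs, each = 3),
    channel = factor(rep(rownames(data), ncol(data)),
                     levels = c("C3", "Cz", "C4")),
    value = as.vector(data))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::annotate("rect", xmin = mi_interval[1], xmax = mi_interval[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.1, fill = "blue") +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = "amplitude (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a 40 x 32 x 3 network input image
#'
#' Raster view of the stacked band spectrogram, one facet per channel.
#' Row 1 is the lowest theta-alpha frequency; rows 21--40 hold the
#' interpolated beta block.
#'
#' @param image A 40 x 32 x 3 array from [build_input_image()].
#' @param times Optional window-centre times for the x axis.
#' @return A ggplot object.
#' @export
plot_input_image <- function(image, times = NULL) {
  d <- dim(image)
  times <- times %??% seq_len(d[2])
  df <- tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2] * d[3]),
    col = rep(rep(times, each = d[1]), times = d[3]),
    channel = factor(rep(c("C3", "Cz", "C4"), each = d[1] * d[2]),
                     levels = c("C3", "Cz", "C4")),
    value = as.vector(image))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel)) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "magnitude") +
    ggplot2::labs(x = "STFT frame", y = "frequency row") +
    ggplot2::theme_minimal()
}
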
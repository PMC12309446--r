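# ggplot2 views of the main result types.

#' @importFrom ggplot2 ggplot aes geom_line geom_step geom_col geom_errorbar
#'   facet_wrap labs scale_y_log10 position_dodge autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot a Welch spectrum
#'
#' One line per channel, power on a log scale.
#'
#' @param object An `eeg_psd` from [welch_psd()].
#' @param max_hz Upper frequency limit shown (default 45 Hz).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_psd <- function(object, max_hz = 45, ...) {
  df <- as_tibble(object) |> dplyr::filter(.data$freq_hz > 0,
                                           .data$freq_hz <= max_hz)
  ggplot(df, aes(x = .data$freq_hz, y = .data$power,
                 colour = .data$channel)) +
    geom_line(linewidth = 0.4) +
    scale_y_log10() +
    labs(x = "Frequency (Hz)", y = expression(PSD ~ (mu * V^2 / Hz)),
         colour = NULL)
}

#' Plot an empirical CDF
#'
#' @param object A `qc_ecdf` from [empirical_cdf()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qc_ecdf <- function(object, ...) {
  ggplot(object, aes(x = .data$value, y = .data$frac)) +
    geom_step(direction = "hv") +
    labs(x = "Value", y = "Cumulative fraction")
}

#' Plot a snippet of a recording
#'
#' Stacked channel traces over a time window.
#'
#' @param object An [eeg_recording()].
#' @param from_s,to_s Time window in seconds (default first 10 s).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_recording <- function(object, from_s = 0,
                                   to_s = min(10, duration_s(object)), ...) {
  idx <- which(seq_len(ncol(object$data)) / object$fs > from_s &
                 seq_len(ncol(object$data)) / object$fs <= to_s)
  df <- tibble(
    channel = factor(rep(object$labels, each = length(idx)),
                     levels = object$labels),
    time_s = rep(idx / object$fs, times = nrow(object$data)),
    uv = as.vector(t(object$data[, idx, drop = FALSE]))
  )
  ggplot(df, aes(x = .data$time_s, y = .data$uv)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~channel, ncol = 2, scales = "free_y") +
    labs(x = "Time (s)", y = expression(mu * V))
}

#' Bar chart of bad-channel / bad-epoch percentages by group
#'
#' Mean with standard-error bars of a quality percentage, grouped (e.g. by
#' condition) and coloured by detection method, mirroring the usual
#' field-vs-benchmark summary figures.
#'
#' @param summaries Tibble from [qc_summary()].
#' @param value Unquoted percentage column (default `pct_bad_channels`).
#' @param group Unquoted grouping column (default `condition`).
#' @return A ggplot object.
#' @export
plot_bad_percentages <- function(summaries, value = pct_bad_channels,
                                 group = condition) {
  df <- summaries |>
    dplyr::group_by({{ group }}, .data$method) |>
    dplyr::summarise(mean = mean({{ value }}),
                     sem = sd({{ value }}) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot(df, aes(x = {{ group }}, y = .data$mean, fill = .data$method)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem),
                  position = position_dodge(width = 0.8), width = 0.2) +
    labs(y = "% flagged (mean ± SEM)", x = NULL, fill = NULL)
}
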
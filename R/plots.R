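#' Plot a waveform record
#'
#' Flow and pressure channels as faceted time series.
#'
#' @param object An [mfl_record()].
#' @param channels Channels to show; defaults to the four flow channels.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mfl_record
#' @export
autoplot.mfl_record <- function(object, channels = .FLOW_CHANNELS, ...) {
  df <- as_tibble(as.data.frame(object)) |>
    select("time_s", dplyr::all_of(channels)) |>
    tidyr::pivot_longer(-"time_s", names_to = "channel", values_to = "value")
  units <- attr(object, "units", exact = TRUE)
  ylab <- if (all(channels %in% .FLOW_CHANNELS)) "flow [L/min]"
          else if (all(channels %in% .PRESSURE_CHANNELS)) "pressure [mmHg]"
          else "value"
  ggplot(df, aes(x = .data$time_s, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~channel, scales = "free_y") +
    labs(x = "time [s]", y = ylab) +
    theme_minimal()
}

#' Plot an entrainment matrix
#'
#' Tile plot of the injected-volume x injection-rate grid with the
#' entrainment/blockage sign coloring of the benchtop result tables.
#'
#' @param object An [entrainment_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot entrainment_matrix
#' @export
autoplot.entrainment_matrix <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = factor(.data$q_inj), y = factor(.data$v_inj),
                 fill = .data$q_ent)) +
    geom_tile(color = "white") +
    geom_text(aes(label = sprintf("%.3f", .data$q_ent)), size = 3) +
    scale_fill_gradient2(low = "firebrick", mid = "white",
                         high = "forestgreen", midpoint = 0) +
    labs(x = "Q_inj [L/min]", y = "V_inj [L]", fill = "Q_ent [L/min]",
         title = sprintf("Entrainment (%s injection)", object$mode)) +
    theme_minimal()
}

#' Plot per-burst jet metrics
#'
#' @param object A `jet_characterization`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot jet_characterization
#' @export
autoplot.jet_characterization <- function(object, ...) {
  df <- object$per_burst |>
    select("burst", "rise_time", "fall_time", "relaxation_time") |>
    tidyr::pivot_longer(-"burst", names_to = "metric", values_to = "seconds")
  ggplot(df, aes(x = factor(.data$burst), y = .data$seconds,
                 fill = .data$metric)) +
    geom_col(position = "dodge") +
    labs(x = "burst", y = "time [s]") +
    theme_minimal()
}
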
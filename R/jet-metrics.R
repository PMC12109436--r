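#' Step-response metrics of the jet activation
#'
#' Characterizes the RPA flow response over one jet injection period as a
#' step response. The settling value is the mean of the final quartile of
#' the segment; the response amplitude is `delta = settling_value -
#' baseline_value`. Rise time spans the first crossings of 10% and 90% of
#' `delta` above baseline; settling time is measured from activation until
#' the signal stays inside `settling_value +/- 2% * delta` for the
#' remainder of the segment. The peak is taken over the post-10%-crossing
#' portion; settling min/max (and the over/undershoot percentages, relative
#' to `delta`) are taken over the portion after the signal first reaches
#' the settling value, quantifying the fluctuation about steady state.
#' Crossing times are located by linear interpolation between bracketing
#' samples, giving sub-sample resolution.
#'
#' @param segment Data frame with columns `time_s` and a value column,
#'   starting at jet activation.
#' @param baseline_value Pre-injection mean flow, L/min.
#' @param value Name of the value column. Default `"q_rpa"`.
#' @return A one-row tibble with `baseline_value`, `settling_value`,
#'   `peak_value`, `peak_time`, `settling_time`, `settling_min`,
#'   `settling_max`, `overshoot_pct`, `undershoot_pct`, `rise_time`.
#' @export
rise_metrics <- function(segment, baseline_value, value = "q_rpa") {
  t <- segment$time_s
  x <- segment[[value]]
  if (is.null(x) || length(x) < 4L) {
    .fj_abort("segment too short for step-response metrics",
              "fontanjet_malformed_segment")
  }
  t <- t - t[1]
  n <- length(x)
  settling_value <- mean(x[t >= t[n] * 0.75])
  delta <- settling_value - baseline_value
  if (!is.finite(delta) || delta <= 0) {
    .fj_abort("no response: settling value does not exceed baseline",
              "fontanjet_no_response")
  }
  t10 <- .first_crossing(t, x, baseline_value + 0.1 * delta, "up")
  t90 <- .first_crossing(t, x, baseline_value + 0.9 * delta, "up")
  if (is.na(t10) || is.na(t90) || t90 < t10) {
    .fj_abort("10%/90% crossings not found in segment",
              "fontanjet_malformed_segment")
  }

  post10 <- t >= t10
  peak_value <- max(x[post10])
  peak_time <- t[post10][which.max(x[post10])]

  t_settle_cross <- .first_crossing(t, x, settling_value, "up")
  settled <- t >= (if (is.na(t_settle_cross)) t[n] * 0.75 else t_settle_cross)
  settling_min <- min(x[settled])
  settling_max <- max(x[settled])

  band <- 0.02 * delta
  inside <- abs(x - settling_value) <= band
  # last index outside the band; settled permanently from the next sample
  out_idx <- which(!inside)
  settling_time <- if (length(out_idx) == 0) 0 else t[min(out_idx[length(out_idx)] + 1L, n)]

  tibble(
    baseline_value = baseline_value,
    settling_value = settling_value,
    peak_value = peak_value,
    peak_time = peak_time,
    settling_time = settling_time,
    settling_min = settling_min,
    settling_max = settling_max,
    overshoot_pct = max(0, 100 * (peak_value - settling_value) / delta),
    undershoot_pct = max(0, 100 * (settling_value - settling_min) / delta),
    rise_time = t90 - t10
  )
}

#' Step-response metrics of the jet shutoff
#'
#' Mirror of [rise_metrics()] for the wind-down: with the same response
#' amplitude `delta = settling_value - baseline_value`, the fall time spans
#' the first crossings of `settling_value - 0.1 * delta` and
#' `settling_value - 0.9 * delta` after the command shuts off.
#'
#' @param segment Data frame with columns `time_s` and the value column,
#'   starting at command-off.
#' @param baseline_value Pre-injection mean flow, L/min.
#' @param settling_value Settled response level from the injection period.
#' @param value Name of the value column. Default `"q_rpa"`.
#' @return A one-row tibble with `fall_time`.
#' @export
fall_metrics <- function(segment, baseline_value, settling_value,
                         value = "q_rpa") {
  t <- segment$time_s
  x <- segment[[value]]
  if (is.null(x) || length(x) < 4L) {
    .fj_abort("segment too short for step-response metrics",
              "fontanjet_malformed_segment")
  }
  t <- t - t[1]
  delta <- settling_value - baseline_value
  if (!is.finite(delta) || delta <= 0) {
    .fj_abort("no response: settling value does not exceed baseline",
              "fontanjet_no_response")
  }
  t10 <- .first_crossing(t, x, settling_value - 0.1 * delta, "down")
  t90 <- .first_crossing(t, x, settling_value - 0.9 * delta, "down")
  if (is.na(t10) || is.na(t90) || t90 < t10) {
    .fj_abort("segment does not decay through the 10%/90% fall levels",
              "fontanjet_malformed_segment")
  }
  tibble(fall_time = t90 - t10)
}

# first time x crosses `level` in the given direction, linearly
# interpolated between the bracketing samples
.first_crossing <- function(t, x, level, direction = c("up", "down")) {
  direction <- match.arg(direction)
  hit <- if (direction == "up") x >= level else x <= level
  i <- which(hit)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(t[1])
  x0 <- x[i - 1]; x1 <- x[i]
  if (x1 == x0) return(t[i])
  t[i - 1] + (level - x0) / (x1 - x0) * (t[i] - t[i - 1])
}

#' Jet relaxation time
#'
#' `t_rel = t_rise - t_fall`. A positive relaxation time means the co-flow
#' takes longer to plateau than to dissipate the jet effect, indicating low
#' likelihood of downstream fluid buildup; a negative value flags buildup
#' risk across repeated pulses.
#'
#' @param rise A row from [rise_metrics()] (or anything with `rise_time`).
#' @param fall A row from [fall_metrics()] (or anything with `fall_time`).
#' @return A one-row tibble with `relaxation_time` (s) and `buildup_label`
#'   (`"no-buildup"`, `"buildup-risk"` or `"boundary"`).
#' @export
relaxation_time <- function(rise, fall) {
  t_rel <- rise$rise_time - fall$fall_time
  tibble(
    relaxation_time = t_rel,
    buildup_label = if (t_rel > 0) "no-buildup"
                    else if (t_rel < 0) "buildup-risk"
                    else "boundary"
  )
}

#' Average per-burst metrics into a sequence summary
#'
#' Field-wise arithmetic mean of the numeric step-response metrics across
#' the bursts of a pulsed sequence, giving a representative
#' characterization of the whole injection sequence.
#'
#' @param per_burst Data frame of per-burst metric rows.
#' @return A one-row tibble of means over the numeric columns.
#' @export
pulsed_summary <- function(per_burst) {
  if (is.null(per_burst) || nrow(per_burst) == 0) {
    .fj_abort("no burst metrics to summarize", "fontanjet_empty_input")
  }
  per_burst |>
    summarise(across(where(is.numeric), mean))
}

#' Characterize the jet response of a segmented record
#'
#' Runs [rise_metrics()], [fall_metrics()] and [relaxation_time()] on each
#' burst of a segmented record (baseline taken as the cycle-averaged RPA
#' flow over the pre-injection stage) and averages the bursts.
#'
#' @param record A filtered [mfl_record()].
#' @param boundaries A `stage_boundaries` with bursts (see
#'   [segment_bursts()]).
#' @return A list of class `jet_characterization` with `per_burst` (one
#'   metrics row per burst, including `relaxation_time`), `summary` (their
#'   mean) and `baseline_value`.
#' @export
characterize_jet <- function(record, boundaries) {
  if (is.null(boundaries$bursts)) {
    .fj_abort("boundaries carry no bursts; run segment_bursts() first",
              "fontanjet_malformed_segment")
  }
  baseline_value <- cycle_average(record, "q_rpa", window = boundaries$pre)
  slice_rec <- function(from, to) {
    sel <- record$time_s >= from - 1e-9 & record$time_s <= to + 1e-9
    tibble(time_s = record$time_s[sel], q_rpa = record$q_rpa[sel])
  }
  per_burst <- purrr::pmap(boundaries$bursts, function(burst, window_start,
                                                       window_end,
                                                       injection_start,
                                                       injection_end,
                                                       shutoff_start,
                                                       shutoff_end, ...) {
    rise <- rise_metrics(slice_rec(injection_start, injection_end),
                         baseline_value)
    fall <- fall_metrics(slice_rec(shutoff_start, shutoff_end),
                         baseline_value, rise$settling_value)
    bind_cols(tibble(burst = burst), rise, fall, relaxation_time(rise, fall))
  }) |> list_rbind()
  structure(
    list(
      per_burst = per_burst,
      summary = pulsed_summary(per_burst |> select(-"burst")),
      baseline_value = baseline_value
    ),
    class = "jet_characterization"
  )
}

#' @export
print.jet_characterization <- function(x, ...) {
  cat(sprintf("<jet_characterization> %d burst(s), baseline %.3f L/min\n",
              nrow(x$per_burst), x$baseline_value))
  print(x$summary)
  invisible(x)
}
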
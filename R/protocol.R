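#' Injection protocol descriptor
#'
#' One injection experiment: a continuous (single long) or pulsed
#' (five-burst) syringe injection into the RPA site at a fixed rate. The
#' angiographic injector admits rates between 0.3 and 50 mL/s. The injector
#' does not start instantaneously: the commanded rectangular waveform is
#' smoothed by a first-order spool-up/down lag.
#'
#' @param case_id Integer case number (see [protocol_table()]), or `NA` for
#'   ad-hoc protocols.
#' @param mode `"continuous"` or `"pulsed"`.
#' @param rate Injection rate in mL/s, within 0.3--50.
#' @param burst_count Number of bursts: 1 for continuous, 5 for pulsed.
#' @param burst_volume Volume per burst in mL.
#' @param inter_burst_gap Gap between consecutive bursts in seconds.
#'   Default 5 s, chosen an order of magnitude above sub-second jet fall
#'   times so bursts are separable.
#' @param start_time Injection start on the record time base, seconds.
#'   Default 10 s, leaving a baseline stage of more than ten cardiac cycles.
#' @param injector_time_constant First-order spool-up/down lag in seconds.
#'   Default 0.2 s. Set to 0 for an ideal rectangular command.
#'
#' @return A list of class `injection_protocol`.
#' @export
injection_protocol <- function(case_id = NA_integer_,
                               mode = c("continuous", "pulsed"),
                               rate,
                               burst_count = if (mode == "pulsed") 5L else 1L,
                               burst_volume,
                               inter_burst_gap = 5,
                               start_time = 10,
                               injector_time_constant = 0.2) {
  mode <- match.arg(mode)
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0.3 || rate > 50) {
    .fj_abort("injection `rate` must lie within the injector's 0.3-50 mL/s range",
              "fontanjet_invalid_protocol")
  }
  expected_bursts <- if (mode == "pulsed") 5L else 1L
  if (burst_count != expected_bursts) {
    .fj_abort(sprintf("mode %s requires burst_count = %d", mode,
                      expected_bursts),
              "fontanjet_invalid_protocol")
  }
  .assert_scalar_pos(burst_volume, "burst_volume", strict = FALSE)
  if (injector_time_constant < 0) {
    .fj_abort("`injector_time_constant` must be >= 0",
              "fontanjet_invalid_protocol")
  }
  structure(
    list(
      case_id = as.integer(case_id),
      mode = mode,
      rate = rate,
      rate_lmin = rate * 0.06,
      burst_count = as.integer(burst_count),
      burst_volume = burst_volume,
      inter_burst_gap = inter_burst_gap,
      start_time = start_time,
      injector_time_constant = injector_time_constant
    ),
    class = "injection_protocol"
  )
}

#' The 20-case injection protocol table
#'
#' Eight pulsed cases (rates 5/10/15/20 mL/s crossed with burst volumes
#' 20/15 mL, five bursts each) followed by twelve continuous cases (rates
#' 5/10/15/20 mL/s crossed with volumes 50/100/150 mL), numbered 1--20.
#'
#' @inheritParams injection_protocol
#' @return A tibble with one row per case: `case_id`, `mode`, `rate` (mL/s),
#'   `rate_lmin` (L/min), `burst_count`, `burst_volume` (mL),
#'   `total_volume_l` (L).
#' @examples
#' protocol_table()
#' @export
protocol_table <- function(inter_burst_gap = 5, start_time = 10,
                           injector_time_constant = 0.2) {
  pulsed <- tibble(
    case_id = 1:8,
    mode = "pulsed",
    rate = rep(c(5, 10, 15, 20), each = 2),
    burst_count = 5L,
    burst_volume = rep(c(20, 15), times = 4)
  )
  continuous <- tibble(
    case_id = 9:20,
    mode = "continuous",
    rate = rep(c(5, 10, 15, 20), each = 3),
    burst_count = 1L,
    burst_volume = rep(c(50, 100, 150), times = 4)
  )
  out <- bind_rows(pulsed, continuous) |>
    mutate(
      rate_lmin = .data$rate * 0.06,
      total_volume_l = .data$burst_count * .data$burst_volume / 1000,
      inter_burst_gap = inter_burst_gap,
      start_time = start_time,
      injector_time_constant = injector_time_constant
    ) |>
    select("case_id", "mode", "rate", "rate_lmin", "burst_count",
           "burst_volume", "total_volume_l", "inter_burst_gap",
           "start_time", "injector_time_constant")
  out
}

#' @rdname protocol_table
#' @param case_id Case number 1--20.
#' @export
case_protocol <- function(case_id, inter_burst_gap = 5, start_time = 10,
                          injector_time_constant = 0.2) {
  tab <- protocol_table(inter_burst_gap, start_time, injector_time_constant)
  if (!case_id %in% tab$case_id) {
    .fj_abort("`case_id` must be one of 1..20", "fontanjet_invalid_protocol")
  }
  row <- tab[tab$case_id == case_id, ]
  injection_protocol(
    case_id = row$case_id, mode = row$mode, rate = row$rate,
    burst_count = row$burst_count, burst_volume = row$burst_volume,
    inter_burst_gap = inter_burst_gap, start_time = start_time,
    injector_time_constant = injector_time_constant
  )
}

#' Total injected volume
#'
#' @param protocol An [injection_protocol()].
#' @return Volume in litres: `burst_count * burst_volume / 1000`.
#' @export
injected_volume <- function(protocol) {
  protocol$burst_count * protocol$burst_volume / 1000
}

# Exact response of a first-order lag to a piecewise-constant command.
# switches: ascending times at which the target changes; targets/taus give
# the commanded level and time constant holding from each switch onward.
# Before the first switch the output is y0. tau = 0 tracks instantly.
.piecewise_first_order <- function(t, switches, targets, taus, y0 = 0) {
  stopifnot(length(switches) == length(targets),
            length(taus) == length(targets))
  n_seg <- length(switches)
  y_at <- numeric(n_seg) # output value entering each segment
  y <- y0
  for (k in seq_len(n_seg)) {
    y_at[k] <- y
    t_next <- if (k < n_seg) switches[k + 1] else Inf
    if (is.finite(t_next)) {
      dt <- t_next - switches[k]
      y <- if (taus[k] > 0) {
        targets[k] + (y - targets[k]) * exp(-dt / taus[k])
      } else {
        targets[k]
      }
    }
  }
  seg <- findInterval(t, switches)
  out <- rep(y0, length(t))
  active <- seg >= 1L
  if (any(active)) {
    k <- seg[active]
    dt <- t[active] - switches[k]
    tk <- taus[k]
    decay <- ifelse(tk > 0, exp(-dt / pmax(tk, .Machine$double.eps)), 0)
    out[active] <- targets[k] + (y_at[k] - targets[k]) * decay
  }
  out
}

# command schedule of a protocol: matrix of burst on/off times (record time)
.burst_schedule <- function(protocol) {
  dur <- protocol$burst_volume / protocol$rate
  on <- protocol$start_time +
    (seq_len(protocol$burst_count) - 1) * (dur + protocol$inter_burst_gap)
  cbind(on = on, off = on + dur)
}

#' Injection flow waveform
#'
#' The commanded waveform is rectangular: height `rate`, per-burst duration
#' `burst_volume / rate`, repeated `burst_count` times with
#' `inter_burst_gap` between bursts, starting at `start_time`. The returned
#' waveform is that command passed through the injector's first-order
#' spool-up/down lag, which preserves the delivered volume in the long-time
#' limit.
#'
#' @param t Time(s) in seconds on the record time base; vectorized.
#' @param protocol An [injection_protocol()].
#' @return Flow in L/min.
#' @export
injection_flow <- function(t, protocol) {
  if (protocol$rate < 0.3 || protocol$rate > 50) {
    .fj_abort("injection rate outside the injector's 0.3-50 mL/s range",
              "fontanjet_invalid_protocol")
  }
  sched <- .burst_schedule(protocol)
  switches <- as.vector(t(sched))
  targets <- rep(c(protocol$rate_lmin, 0), times = protocol$burst_count)
  taus <- rep(protocol$injector_time_constant, length(targets))
  .piecewise_first_order(t, switches, targets, taus, y0 = 0)
}
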
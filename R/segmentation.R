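#' Segment a record into pre-injection, active and post-injection stages
#'
#' Partitions the RPA flow waveform into the three stages of an injection
#' run: Stage 1 (pre-injection baseline), Stage 2 (active injection) and
#' Stage 3 (post-injection wind-down). Two methods are provided:
#'
#' * `command_aligned` places the boundaries at the protocol's commanded
#'   start and end (requires `protocol`);
#' * `signal_detected` locates excursions where `q_rpa` exceeds the
#'   pre-injection mean + `k` standard deviations for `m` consecutive
#'   samples (the active stage spans the first onset to the end of the
#'   last excursion), then refines each boundary to the nearby
#'   mid-amplitude crossing — for the zero-phase filters used upstream the
#'   50% crossing of a smeared edge is an unbiased estimate of the command
#'   edge, where the low threshold crossing itself is biased outward.
#'
#' @param record An [mfl_record()] (normally filtered).
#' @param protocol An [injection_protocol()]; required for
#'   `command_aligned`, used only for burst metadata otherwise.
#' @param method `"command_aligned"` or `"signal_detected"`.
#' @param k Threshold in baseline standard deviations. Default 3.
#' @param m Consecutive samples required above/below threshold. Default 10
#'   (0.1 s at 100 Hz).
#' @return A list of class `stage_boundaries` with elements `pre`, `active`,
#'   `post` (length-2 second intervals), `method`, and detection settings.
#' @export
segment_stages <- function(record, protocol = NULL,
                           method = c("command_aligned", "signal_detected"),
                           k = 3, m = 10L) {
  method <- match.arg(method)
  if (!"q_rpa" %in% names(record)) {
    .fj_abort("record lacks a q_rpa channel", "fontanjet_format_error")
  }
  t <- record$time_s
  t0 <- t[1]; t_end <- t[length(t)]
  period <- .record_period(record)

  if (method == "command_aligned") {
    if (is.null(protocol)) {
      .fj_abort("command_aligned segmentation requires a protocol",
                "fontanjet_invalid_protocol")
    }
    sched <- .burst_schedule(protocol)
    a_start <- unname(sched[1, "on"])
    a_end <- unname(sched[nrow(sched), "off"])
  } else {
    det <- .detect_excursions(t, record$q_rpa, k = k, m = m, period = period)
    a_start <- det$start
    a_end <- det$end
  }
  if (a_start - t0 < period) {
    .fj_abort("pre-injection stage shorter than one cardiac cycle",
              "fontanjet_insufficient_baseline")
  }
  structure(
    list(
      pre = c(t0, a_start),
      active = c(a_start, a_end),
      post = c(a_end, t_end),
      bursts = NULL,
      method = method, k = k, m = as.integer(m)
    ),
    class = "stage_boundaries"
  )
}

# Find threshold excursions of x above baseline mean + k*SD lasting >= m
# samples. The baseline statistics are estimated from the prefix before the
# detected onset (two passes: an initial fifth of the record seeds the
# threshold, then the stats are recomputed from everything before onset).
.detect_excursions <- function(t, x, k, m, period,
                               window = NULL) {
  if (is.null(window)) window <- c(t[1], t[length(t)])
  sel <- t >= window[1] & t <= window[2]
  ts <- t[sel]; xs <- x[sel]
  n <- length(xs)
  seed_n <- max(min(n, 20L), floor(n / 5))
  runs <- NULL
  for (pass in 1:2) {
    base_idx <- if (is.null(runs)) seq_len(seed_n) else seq_len(max(runs$onset - 1L, 2L))
    mu <- mean(xs[base_idx]); sdev <- sd(xs[base_idx])
    if (!is.finite(sdev)) sdev <- 0
    thr <- mu + k * sdev
    above <- xs > thr
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= m
    if (!any(keep)) {
      .fj_abort("no injection excursion detected",
                "fontanjet_no_injection_detected")
    }
    runs <- list(
      onset = starts[keep][1],
      starts = starts[keep],
      ends = ends[keep],
      threshold = thr,
      mu = mu
    )
  }
  # Refine each edge to the mid-amplitude crossing near the threshold
  # crossing: the first crossing of mean + k*SD sits low on the edge, so a
  # zero-phase-filtered step is detected early on the way up and late on
  # the way down; the 50% crossing of a symmetric smear is unbiased.
  w <- as.integer(max(m, 15L))
  refine <- function(idx, plateau, rising) {
    lvl <- (runs$mu + plateau) / 2
    lo <- max(1L, idx - w); hi <- min(n, idx + w)
    win <- lo:hi
    hitw <- if (rising) xs[win] >= lvl else xs[win] <= lvl
    j <- which(hitw)[1]
    if (is.na(j)) idx else win[j]
  }
  starts_r <- ends_r <- integer(length(runs$starts))
  for (i in seq_along(runs$starts)) {
    plateau <- stats::median(xs[runs$starts[i]:runs$ends[i]])
    starts_r[i] <- refine(runs$starts[i], plateau, rising = TRUE)
    ends_r[i] <- refine(runs$ends[i] + 1L, plateau, rising = FALSE)
  }
  list(
    start = ts[starts_r[1]],
    end = ts[min(ends_r[length(ends_r)], length(ts))],
    run_starts = ts[starts_r],
    run_ends = ts[pmin(ends_r, length(ts))],
    threshold = runs$threshold
  )
}

#' Locate individual bursts inside the active stage
#'
#' Splits the active stage into `n_bursts` disjoint burst windows and, for
#' each burst, its jet injection period and jet shutoff period. With
#' `command_aligned` boundaries the windows come from the protocol's
#' command schedule; with `signal_detected` boundaries the same threshold
#' rule used for stage detection is applied inside the active stage. Each
#' burst window runs from its injection onset to the next onset (or, for
#' the last burst, into the post stage so the wind-down is captured); the
#' injection period ends at the command-off instant (`command_aligned`) or
#' the last above-threshold sample (`signal_detected`), and the shutoff
#' period covers the remainder of the window.
#'
#' @param boundaries A `stage_boundaries` from [segment_stages()].
#' @param record The same record.
#' @param protocol The protocol (required for `command_aligned`).
#' @param n_bursts Expected number of bursts (5 for pulsed, 1 for
#'   continuous).
#' @return The `stage_boundaries` with a `bursts` tibble added: columns
#'   `burst`, `window_start`, `window_end`, `injection_start`,
#'   `injection_end`, `shutoff_start`, `shutoff_end` (seconds).
#' @export
segment_bursts <- function(boundaries, record, protocol = NULL,
                           n_bursts = NULL) {
  t_end_rec <- record$time_s[nrow(record)]
  if (boundaries$method == "command_aligned") {
    if (is.null(protocol)) {
      .fj_abort("command_aligned burst segmentation requires a protocol",
                "fontanjet_invalid_protocol")
    }
    n_bursts <- n_bursts %||% protocol$burst_count
    sched <- .burst_schedule(protocol)
    if (nrow(sched) != n_bursts) {
      .fj_abort(sprintf("expected %d bursts but the protocol commands %d",
                        n_bursts, nrow(sched)),
                "fontanjet_burst_count_mismatch")
    }
    on <- sched[, "on"]; off <- sched[, "off"]
    if (any(off[-length(off)] >= on[-1])) {
      .fj_abort("burst windows overlap (inter-burst gap too small)",
                "fontanjet_burst_count_mismatch")
    }
  } else {
    n_bursts <- n_bursts %||% 5L
    det <- .detect_excursions(record$time_s, record$q_rpa,
                              k = boundaries$k, m = boundaries$m,
                              period = .record_period(record),
                              window = c(record$time_s[1],
                                         boundaries$active[2]))
    found <- length(det$run_starts)
    if (found != n_bursts) {
      .fj_abort(sprintf("found %d burst(s), expected %d", found, n_bursts),
                "fontanjet_burst_count_mismatch")
    }
    on <- det$run_starts; off <- det$run_ends
  }
  on <- unname(on); off <- unname(off)
  window_start <- on
  window_end <- c(on[-1], min(boundaries$post[2], t_end_rec))
  boundaries$bursts <- tibble(
    burst = seq_len(n_bursts),
    window_start = window_start,
    window_end = window_end,
    injection_start = on,
    injection_end = off,
    shutoff_start = off,
    shutoff_end = window_end
  )
  boundaries
}

#' @export
print.stage_boundaries <- function(x, ...) {
  cat(sprintf("<stage_boundaries> (%s)\n", x$method))
  cat(sprintf("  pre:    [%.3f, %.3f] s\n", x$pre[1], x$pre[2]))
  cat(sprintf("  active: [%.3f, %.3f] s\n", x$active[1], x$active[2]))
  cat(sprintf("  post:   [%.3f, %.3f] s\n", x$post[1], x$post[2]))
  if (!is.null(x$bursts)) print(x$bursts)
  invisible(x)
}

#' Serialize stage boundaries to JSON
#'
#' @param boundaries A `stage_boundaries`.
#' @return A JSON string with all times in seconds.
#' @export
boundaries_json <- function(boundaries) {
  payload <- boundaries[c("pre", "active", "post", "method", "k", "m")]
  if (!is.null(boundaries$bursts)) payload$bursts <- boundaries$bursts
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
}
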
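#' Expected baseline RPA flow
#'
#' The flow the RPA would carry with no injection: the systemic flow
#' multiplied by the pulmonary (RPA) split fraction.
#'
#' @param q_systemic Systemic flow in L/min.
#' @param pulmonary_split RPA share of pulmonary return, in (0, 1].
#'   Default 0.5 (the 50-50 split the loop is tuned to).
#' @return Flow in L/min.
#' @examples
#' baseline_rpa(2.4, 0.5) # 1.2
#' @export
baseline_rpa <- function(q_systemic, pulmonary_split = 0.5) {
  q_systemic * pulmonary_split
}

#' Entrainment rate of an injection run
#'
#' Quantifies jet entrainment as the excess of the measured RPA flow over
#' what superposition alone would give:
#' `q_ent = q_meas_rpa - (q_baseline_rpa + q_inj)`.
#' Positive values mean the jet entrains additional co-flow; negative
#' values mean the injection blocks the native flow. The normalized rate is
#' `q_ent / q_inj`.
#'
#' @param q_meas_rpa Cycle-averaged measured RPA flow during the active
#'   window, L/min.
#' @param q_baseline_rpa Expected RPA flow from [baseline_rpa()], L/min.
#' @param q_inj Arranged injection rate, L/min (>= 0).
#' @param dead_band Absolute dead band within which `q_ent` is labelled
#'   `"neutral"`. Default 1e-6 L/min.
#' @return A one-row tibble of class `entrainment_result` with
#'   `q_meas_rpa`, `q_baseline_rpa`, `q_inj`, `q_ent`, `normalized`,
#'   `label`.
#' @export
entrainment_rate <- function(q_meas_rpa, q_baseline_rpa, q_inj,
                             dead_band = 1e-6) {
  if (!all(is.finite(c(q_meas_rpa, q_baseline_rpa, q_inj)))) {
    .fj_abort("entrainment inputs must be finite",
              "fontanjet_invalid_parameter")
  }
  if (q_inj < 0) {
    .fj_abort("`q_inj` must be >= 0", "fontanjet_invalid_parameter")
  }
  q_ent <- q_meas_rpa - (q_baseline_rpa + q_inj)
  normalized <- if (q_inj > 0) q_ent / q_inj else NA_real_
  out <- tibble(
    q_meas_rpa = q_meas_rpa,
    q_baseline_rpa = q_baseline_rpa,
    q_inj = q_inj,
    q_ent = q_ent,
    normalized = normalized,
    label = if (q_ent > dead_band) "entrainment"
            else if (q_ent < -dead_band) "blockage"
            else "neutral"
  )
  class(out) <- c("entrainment_result", class(out))
  out
}

#' Normalized entrainment time series
#'
#' Pointwise relative change in flow between a run with the jet and a run
#' without it, normalized by the cycle-averaged injection flow:
#' `100 * (q_with - q_without) / q_ijs_mean`, in percent.
#'
#' @param q_with,q_without Data frames with columns `time_s` and `value`
#'   (flow in L/min) sharing the same time base, or plain numeric vectors
#'   of equal length.
#' @param q_ijs_mean Cycle-averaged injection flow rate, L/min (> 0).
#' @return A tibble with `time_s` (absent for bare vectors) and
#'   `entrainment_pct`.
#' @export
normalized_entrainment_series <- function(q_with, q_without, q_ijs_mean) {
  .assert_scalar_pos(q_ijs_mean, "q_ijs_mean")
  if (is.data.frame(q_with) && is.data.frame(q_without)) {
    if (nrow(q_with) != nrow(q_without) ||
        max(abs(q_with$time_s - q_without$time_s)) > 1e-9) {
      .fj_abort("the two series do not share a time base",
                "fontanjet_alignment_error")
    }
    tibble(
      time_s = q_with$time_s,
      entrainment_pct = 100 * (q_with$value - q_without$value) / q_ijs_mean
    )
  } else {
    if (length(q_with) != length(q_without)) {
      .fj_abort("the two series do not share a time base",
                "fontanjet_alignment_error")
    }
    tibble(entrainment_pct = 100 * (q_with - q_without) / q_ijs_mean)
  }
}

#' Assemble an entrainment matrix from sweep results
#'
#' Arranges entrainment results over a rectangular (injected volume x
#' injection rate) grid for one injection mode, mirroring the layout of
#' the study's result tables: volumes as rows, rates (strictly increasing)
#' as columns.
#'
#' @param results Data frame with columns `v_inj` (L), `q_inj` (L/min) and
#'   `q_ent` (L/min); one row per grid cell.
#' @param mode `"continuous"` or `"pulsed"`.
#' @return A list of class `entrainment_matrix` with `mode`, `volumes`,
#'   `rates`, `values` (volumes x rates matrix) and `labels` (same shape,
#'   `"entrainment"`/`"blockage"`/`"neutral"`).
#' @export
entrainment_matrix <- function(results, mode = c("continuous", "pulsed")) {
  mode <- match.arg(mode)
  needed <- c("v_inj", "q_inj", "q_ent")
  if (!all(needed %in% names(results))) {
    .fj_abort("`results` must have columns v_inj, q_inj, q_ent",
              "fontanjet_incomplete_sweep")
  }
  volumes <- sort(unique(results$v_inj))
  rates <- sort(unique(results$q_inj))
  key <- paste(results$v_inj, results$q_inj)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    .fj_abort(sprintf("duplicate grid cell (v_inj q_inj = %s)", dup),
              "fontanjet_incomplete_sweep")
  }
  full <- expand.grid(v_inj = volumes, q_inj = rates)
  missing <- setdiff(paste(full$v_inj, full$q_inj), key)
  if (length(missing) > 0) {
    .fj_abort(sprintf("missing grid cell(s): %s",
                      paste(missing, collapse = "; ")),
              "fontanjet_incomplete_sweep")
  }
  values <- matrix(NA_real_, length(volumes), length(rates),
                   dimnames = list(format(volumes), format(rates)))
  for (i in seq_len(nrow(results))) {
    values[match(results$v_inj[i], volumes),
           match(results$q_inj[i], rates)] <- results$q_ent[i]
  }
  labels <- ifelse(values > 0, "entrainment",
                   ifelse(values < 0, "blockage", "neutral"))
  structure(
    list(mode = mode, volumes = volumes, rates = rates,
         values = values, labels = labels),
    class = "entrainment_matrix"
  )
}

#' @export
print.entrainment_matrix <- function(x, ...) {
  cat(sprintf("<entrainment_matrix> (%s) Q_ent [L/min], rows V_inj [L], cols Q_inj [L/min]\n",
              x$mode))
  print(round(x$values, 4))
  invisible(x)
}

#' @method as_tibble entrainment_matrix
#' @export
as_tibble.entrainment_matrix <- function(x, ...) {
  expand.grid(v_inj = x$volumes, q_inj = x$rates) |>
    as_tibble() |>
    mutate(
      q_ent = as.vector(x$values),
      label = as.vector(x$labels),
      mode = x$mode
    )
}

#' Column-averaged normalized entrainment
#'
#' Mean of one rate column of an entrainment matrix divided by that
#' injection rate: the average `Q_ent / Q_inj` across injected volumes.
#'
#' @param matrix An [entrainment_matrix()].
#' @param q_inj The column's injection rate, L/min.
#' @return Dimensionless normalized entrainment.
#' @export
column_normalized_mean <- function(matrix, q_inj) {
  j <- which(abs(matrix$rates - q_inj) < 1e-9)
  if (length(j) != 1L) {
    .fj_abort(sprintf("no column at q_inj = %g", q_inj),
              "fontanjet_incomplete_sweep")
  }
  mean(matrix$values[, j]) / q_inj
}

#' Entrainment cutoff rate
#'
#' The largest injection rate whose column is entirely positive (every
#' volume still shows entrainment). Returns `NA` when no column is fully
#' positive (no-entrainment marker).
#'
#' @param matrix An [entrainment_matrix()].
#' @return Cutoff rate in L/min, or `NA_real_`.
#' @export
cutoff_rate <- function(matrix) {
  positive <- apply(matrix$values > 0, 2, all)
  if (!any(positive)) return(NA_real_)
  max(matrix$rates[positive])
}

#' Measure entrainment from a segmented record
#'
#' Computes the measured active-window RPA flow, the expected baseline RPA
#' flow and the resulting entrainment rate for one injection run. The
#' measured flow is averaged over the burst injection periods with the
#' initial spool-up excluded (`max(1 s, 5 injector time constants)`, capped
#' at half of each period) so transients do not bias the mean. The
#' systemic flow entering the baseline can be the per-trial measured
#' pre-injection systemic flow (default) or a nominal value.
#'
#' @param record A filtered [mfl_record()].
#' @param boundaries `stage_boundaries` with bursts.
#' @param protocol The [injection_protocol()] of the run.
#' @param pulmonary_split RPA share of pulmonary return. Default 0.5.
#' @param q_systemic `"measured"` (pre-injection mean of
#'   `q_upper + q_lower`) or a numeric nominal value in L/min.
#' @return An `entrainment_result` row (see [entrainment_rate()]).
#' @export
measure_entrainment <- function(record, boundaries, protocol,
                                pulmonary_split = 0.5,
                                q_systemic = "measured") {
  if (is.null(boundaries$bursts)) {
    .fj_abort("boundaries carry no bursts; run segment_bursts() first",
              "fontanjet_malformed_segment")
  }
  qs <- if (identical(q_systemic, "measured")) {
    cycle_average(record, "q_upper", window = boundaries$pre) +
      cycle_average(record, "q_lower", window = boundaries$pre)
  } else {
    q_systemic
  }
  skip <- max(1, 5 * protocol$injector_time_constant)
  sel <- rep(FALSE, nrow(record))
  for (i in seq_len(nrow(boundaries$bursts))) {
    b <- boundaries$bursts[i, ]
    from <- b$injection_start +
      min(skip, 0.5 * (b$injection_end - b$injection_start))
    sel <- sel | (record$time_s >= from & record$time_s <= b$injection_end)
  }
  if (!any(sel)) {
    .fj_abort("no samples left in the entrainment measurement window",
              "fontanjet_insufficient_window")
  }
  entrainment_rate(
    q_meas_rpa = mean(record$q_rpa[sel]),
    q_baseline_rpa = baseline_rpa(qs, pulmonary_split),
    q_inj = protocol$rate_lmin
  )
}
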
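#' Pulsatile pump flow waveform
#'
#' Half-sine ejection pulse: within each cardiac cycle the pump ejects over
#' the first `ejection_fraction_of_cycle` of the period as a half sine whose
#' area equals the stroke volume, and is silent for the remainder. The peak
#' flow is therefore `pi * SV / (2 * T_ej)` (converted to L/min) and the
#' cycle-averaged flow is `heart_rate * stroke_volume` (e.g. 80 bpm x 30 mL
#' = 2.4 L/min).
#'
#' @param t Time(s) in seconds, >= 0; vectorized.
#' @param pump A [pump_settings()] object.
#' @return Flow in L/min, same length as `t`.
#' @examples
#' mean(pump_flow(seq(0, 0.75, by = 1e-4), pump_settings())) # ~2.4
#' @export
pump_flow <- function(t, pump = pump_settings()) {
  if (any(t < 0)) {
    .fj_abort("`t` must be >= 0", "fontanjet_invalid_parameter")
  }
  period <- pump$period
  t_ej <- pump$ejection_fraction_of_cycle * period
  phase <- t %% period
  # peak in mL/s such that the half-sine area is the stroke volume
  peak_mls <- pi * pump$stroke_volume / (2 * t_ej)
  flow_mls <- ifelse(phase < t_ej, peak_mls * sin(pi * phase / t_ej), 0)
  flow_mls * 0.06 # mL/s -> L/min
}

# Conductances and fixed plumbing unpacked once per call
.lpm_circuit <- function(params) {
  cp <- params$compartments
  r <- setNames(cp$resistance, cp$name)
  c_ <- setNames(cp$compliance, cp$name)
  lp <- params$loop
  list(
    g_au = 1 / lp$ra_upper, g_al = 1 / lp$ra_lower,
    g_su = 1 / r[["upper_systemic"]], g_sl = 1 / r[["lower_systemic"]],
    g_pr = 1 / r[["rpa"]], g_pl = 1 / r[["lpa"]],
    g_or = 1 / lp$ro_rpa, g_ol = 1 / lp$ro_lpa,
    c_ao = lp$c_aortic,
    c_up = c_[["upper_systemic"]], c_lo = c_[["lower_systemic"]],
    c_rpa = c_[["rpa"]], c_lpa = c_[["lpa"]],
    p_ref = params$venous_reference_pressure
  )
}

# TCPC junction pressure: ideal zero-resistance node balancing systemic
# venous return against pulmonary branch inflow (vectorized over states)
.tcpc_pressure <- function(cc, p_up, p_lo, p_rpa, p_lpa) {
  (cc$g_su * p_up + cc$g_sl * p_lo + cc$g_pr * p_rpa + cc$g_pl * p_lpa) /
    (cc$g_su + cc$g_sl + cc$g_pr + cc$g_pl)
}

#' Time derivatives of the compartment pressures
#'
#' The state holds the five stored pressures: the aortic chamber and the
#' four Windkessel compartments. Each compliance obeys
#' `C dP/dt = Q_in - Q_out` with resistive branch flows `Q = dP / R`; the
#' total cavopulmonary connection is an ideal zero-resistance junction
#' solved algebraically at each evaluation. External inflows are the pump
#' (into the aortic chamber) and an optional injection (into the RPA branch
#' node).
#'
#' @param state Named numeric vector with elements `p_aortic`, `p_upper`,
#'   `p_lower`, `p_rpa`, `p_lpa` (mmHg).
#' @param t Time in seconds (unused by the autonomous circuit itself; kept
#'   for solver compatibility).
#' @param params An [lpm_parameters()] object.
#' @param external_inflows Named list with elements `pump` and `injection`,
#'   both in L/min.
#' @return Named vector `d(state)/dt` in mmHg/s.
#' @export
lpm_derivatives <- function(state, t, params,
                            external_inflows = list(pump = 0, injection = 0)) {
  if (any(!is.finite(state))) {
    .fj_abort("non-finite pressure in state vector", "fontanjet_numeric_state")
  }
  cc <- .lpm_circuit(params)
  p_ao <- state[["p_aortic"]]; p_up <- state[["p_upper"]]
  p_lo <- state[["p_lower"]]; p_rpa <- state[["p_rpa"]]
  p_lpa <- state[["p_lpa"]]
  q_pump <- external_inflows$pump %||% 0
  q_inj <- external_inflows$injection %||% 0

  p_t <- .tcpc_pressure(cc, p_up, p_lo, p_rpa, p_lpa)

  q_a_up <- cc$g_au * (p_ao - p_up)   # arterial feed, upper
  q_a_lo <- cc$g_al * (p_ao - p_lo)
  q_v_up <- cc$g_su * (p_up - p_t)    # venous return through needle valve
  q_v_lo <- cc$g_sl * (p_lo - p_t)
  q_p_rpa <- cc$g_pr * (p_t - p_rpa)  # TCPC into pulmonary compartment
  q_p_lpa <- cc$g_pl * (p_t - p_lpa)
  q_o_rpa <- cc$g_or * (p_rpa - cc$p_ref) # distal outlet to reservoir
  q_o_lpa <- cc$g_ol * (p_lpa - cc$p_ref)

  # L/min net flow -> mmHg/s: * 1000 (mL/min) / C (mL/mmHg) / 60 (per s)
  k <- .LMIN_TO_ML / 60
  c(
    p_aortic = k * (q_pump - q_a_up - q_a_lo) / cc$c_ao,
    p_upper  = k * (q_a_up - q_v_up) / cc$c_up,
    p_lower  = k * (q_a_lo - q_v_lo) / cc$c_lo,
    p_rpa    = k * (q_p_rpa + q_inj - q_o_rpa) / cc$c_rpa,
    p_lpa    = k * (q_p_lpa - q_o_lpa) / cc$c_lpa
  )
}

#' Steady-state (DC) solution of the circuit
#'
#' Solves the resistive network for constant pump inflow `co` and constant
#' injection `q_inj`, returning node pressures and branch flows. Because the
#' circuit is linear and time-invariant, the cycle-averaged flows at
#' periodic steady state equal this DC solution exactly; it is used to
#' initialize simulations and to tune resistances.
#'
#' @param params An [lpm_parameters()] object.
#' @param co Constant inflow in L/min; defaults to the pump's mean output.
#' @param q_inj Constant injection into the RPA branch node, L/min.
#' @return A list with `pressures` (named, mmHg) and `flows` (named, L/min).
#' @export
lpm_dc_state <- function(params, co = NULL, q_inj = 0) {
  cc <- .lpm_circuit(params)
  co <- co %||% (params$pump$heart_rate * params$pump$stroke_volume / 1000)
  # unknowns: p_ao, p_up, p_lo, p_t, p_rpa, p_lpa
  A <- matrix(0, 6, 6)
  b <- numeric(6)
  # node aortic: pump in = arterial feeds out
  A[1, ] <- c(cc$g_au + cc$g_al, -cc$g_au, -cc$g_al, 0, 0, 0); b[1] <- co
  # node upper: feed in = venous out
  A[2, ] <- c(-cc$g_au, cc$g_au + cc$g_su, 0, -cc$g_su, 0, 0)
  # node lower
  A[3, ] <- c(-cc$g_al, 0, cc$g_al + cc$g_sl, -cc$g_sl, 0, 0)
  # TCPC junction
  A[4, ] <- c(0, -cc$g_su, -cc$g_sl,
              cc$g_su + cc$g_sl + cc$g_pr + cc$g_pl, -cc$g_pr, -cc$g_pl)
  # node rpa: TCPC in + injection = outlet
  A[5, ] <- c(0, 0, 0, -cc$g_pr, cc$g_pr + cc$g_or, 0)
  b[5] <- q_inj + cc$g_or * cc$p_ref
  # node lpa
  A[6, ] <- c(0, 0, 0, -cc$g_pl, 0, cc$g_pl + cc$g_ol)
  b[6] <- cc$g_ol * cc$p_ref
  p <- solve(A, b)
  names(p) <- c("p_aortic", "p_upper", "p_lower", "p_tcpc", "p_rpa", "p_lpa")
  flows <- c(
    q_upper = cc$g_su * (p[["p_upper"]] - p[["p_tcpc"]]),
    q_lower = cc$g_sl * (p[["p_lower"]] - p[["p_tcpc"]]),
    q_rpa = cc$g_or * (p[["p_rpa"]] - cc$p_ref),
    q_lpa = cc$g_ol * (p[["p_lpa"]] - cc$p_ref)
  )
  list(pressures = p, flows = flows)
}

#' Simulate the lumped-parameter Fontan circulation
#'
#' Integrates the five-state circuit with the pulsatile pump source and an
#' optional injection protocol, using an adaptive stiff-capable solver
#' ([deSolve::ode()], `lsoda`) with a maximum step of 1/200 of the cardiac
#' period and fixed output sampling. The integration starts from the DC
#' steady state and runs `settle_cycles` cardiac cycles before the record
#' begins; periodicity of every flow channel over the settle window is
#' verified against `periodicity_tolerance`. Protocol `start_time` is
#' measured on the returned record's time base (t = 0 at the end of the
#' settle period).
#'
#' @param params An [lpm_parameters()] object.
#' @param protocol Optional single injection protocol (see
#'   [injection_protocol()]); `NULL` for a baseline run.
#' @param config A [sim_config()] object.
#' @return An [mfl_record()] with provenance `"simulated"`.
#' @export
simulate_lpm <- function(params, protocol = NULL, config = sim_config()) {
  period <- params$pump$period
  if (config$duration < period) {
    .fj_abort("`duration` must cover at least one cardiac cycle",
              "fontanjet_invalid_parameter")
  }
  settle <- config$settle_cycles * period
  cc <- .lpm_circuit(params)
  dc <- lpm_dc_state(params)
  y0 <- dc$pressures[c("p_aortic", "p_upper", "p_lower", "p_rpa", "p_lpa")]

  inj_fun <- if (is.null(protocol)) {
    function(t) 0
  } else {
    function(t) injection_flow(t - settle, protocol)
  }
  deriv <- function(t, y, parms) {
    list(lpm_derivatives(
      y, t, params,
      external_inflows = list(pump = pump_flow(t, params$pump),
                              injection = inj_fun(t))
    ))
  }
  times <- seq(0, settle + config$duration, by = config$time_step)
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", hmax = period / 200,
                      rtol = 1e-8, atol = 1e-8)
  sol <- as.data.frame(sol)

  p_t <- .tcpc_pressure(cc, sol$p_upper, sol$p_lower, sol$p_rpa, sol$p_lpa)
  out <- tibble(
    time_s = sol$time,
    q_upper = cc$g_su * (sol$p_upper - p_t),
    q_lower = cc$g_sl * (sol$p_lower - p_t),
    q_rpa = cc$g_or * (sol$p_rpa - cc$p_ref),
    q_lpa = cc$g_ol * (sol$p_lpa - cc$p_ref),
    p_upper = sol$p_upper,
    p_lower = sol$p_lower,
    p_rpa = sol$p_rpa,
    p_lpa = sol$p_lpa,
    p_aortic = sol$p_aortic
  )

  .check_periodicity(out, settle, period, config)

  keep <- out$time_s >= settle - config$time_step / 2
  out <- out[keep, ]
  out$time_s <- out$time_s - out$time_s[1]
  mfl_record(
    out,
    sampling_rate = 1 / config$time_step,
    metadata = list(
      provenance = "simulated",
      heart_rate = params$pump$heart_rate,
      stroke_volume = params$pump$stroke_volume,
      case_id = if (!is.null(protocol)) protocol$case_id else NA_integer_
    )
  )
}

.check_periodicity <- function(out, settle, period, config) {
  n_cycles <- floor(settle / period)
  if (n_cycles < 2) return(invisible(TRUE))
  cyc <- pmin(floor(out$time_s / period), n_cycles - 1)
  in_settle <- out$time_s < n_cycles * period
  worst <- 0; worst_ch <- ""
  for (ch in .FLOW_CHANNELS) {
    m <- tapply(out[[ch]][in_settle], cyc[in_settle], mean)
    m <- m[length(m) - 1:0]
    rel <- abs(diff(m)) / max(abs(m[1]), 1e-12)
    if (rel > worst) { worst <- rel; worst_ch <- ch }
  }
  if (worst > config$periodicity_tolerance) {
    .fj_abort(sprintf(
      "failed to reach periodic steady state within %d settle cycles (worst channel %s, relative change %.3g)",
      config$settle_cycles, worst_ch, worst),
      "fontanjet_convergence_error")
  }
  invisible(TRUE)
}

#' Tune compartment resistances to prescribed flow splits
#'
#' Adjusts the upper/lower systemic and RPA/LPA resistances so that at
#' periodic steady state (no injection) the upper body receives
#' `systemic_split_target` of cardiac output and the RPA receives
#' `pulmonary_split_target` of pulmonary return. Each split is solved by a
#' deterministic 1D root search that scales the two resistances of the pair
#' reciprocally (R_upper / theta, R_lower * theta), preserving their
#' geometric mean; because the circuit is linear, cycle-averaged splits
#' equal the DC splits, so the search runs on the DC solution.
#'
#' @param params An [lpm_parameters()] object carrying the split targets.
#' @param tol Convergence tolerance on the split fractions. Default 1e-6.
#' @return A new `lpm_parameters` object with tuned resistances.
#' @export
tune_resistances <- function(params, tol = 1e-6) {
  .assert_fraction(params$systemic_split_target, "systemic_split_target")
  .assert_fraction(params$pulmonary_split_target, "pulmonary_split_target")
  cp <- params$compartments

  apply_theta <- function(p, pair, theta) {
    i <- match(pair, p$compartments$name)
    p$compartments$resistance[i[1]] <- cp$resistance[match(pair[1], cp$name)] / theta
    p$compartments$resistance[i[2]] <- cp$resistance[match(pair[2], cp$name)] * theta
    p
  }
  split_of <- function(p, kind) {
    fl <- lpm_dc_state(p)$flows
    if (kind == "systemic") {
      fl[["q_upper"]] / (fl[["q_upper"]] + fl[["q_lower"]])
    } else {
      fl[["q_rpa"]] / (fl[["q_rpa"]] + fl[["q_lpa"]])
    }
  }
  solve_pair <- function(p, pair, kind, target) {
    f <- function(log_theta) {
      split_of(apply_theta(p, pair, exp(log_theta)), kind) - target
    }
    root <- tryCatch(
      uniroot(f, lower = log(1e-5), upper = log(1e5), tol = 1e-12),
      error = function(e) .fj_abort(
        sprintf("resistance tuning failed for %s split (target %.3f): %s",
                kind, target, conditionMessage(e)),
        "fontanjet_tuning_error")
    )
    apply_theta(p, pair, exp(root$root))
  }

  out <- solve_pair(params, c("upper_systemic", "lower_systemic"),
                    "systemic", params$systemic_split_target)
  out <- solve_pair(out, c("rpa", "lpa"),
                    "pulmonary", params$pulmonary_split_target)

  resid <- c(systemic = split_of(out, "systemic") - params$systemic_split_target,
             pulmonary = split_of(out, "pulmonary") - params$pulmonary_split_target)
  if (any(abs(resid) > max(tol, 1e-6))) {
    .fj_abort(sprintf("tuning did not converge (residuals: %s)",
                      paste(sprintf("%s %.2e", names(resid), resid),
                            collapse = ", ")),
              "fontanjet_tuning_error")
  }
  out
}

#' Cycle-averaged channel value
#'
#' Arithmetic mean of one channel over an integer number of cardiac cycles
#' inside the given window; partial trailing cycles are truncated so the
#' weakly pulsatile waveform does not bias the mean.
#'
#' @param record An [mfl_record()].
#' @param channel Channel name, e.g. `"q_rpa"`.
#' @param window Length-2 numeric, window `c(start, end)` in seconds; `NULL`
#'   for the whole record.
#' @param period Cardiac period in seconds; defaults to the record's
#'   metadata heart rate.
#' @return Mean value in the channel's units.
#' @export
cycle_average <- function(record, channel, window = NULL, period = NULL) {
  if (!channel %in% names(record)) {
    .fj_abort(sprintf("channel `%s` not present in record", channel),
              "fontanjet_format_error")
  }
  period <- period %||% .record_period(record)
  window <- window %||% range(record$time_s)
  if (window[1] < record$time_s[1] - 1e-9 ||
      window[2] > record$time_s[nrow(record)] + 1e-9) {
    .fj_abort("window extends beyond the record", "fontanjet_format_error")
  }
  n_cycles <- floor((window[2] - window[1]) / period + 1e-9)
  if (n_cycles < 1) {
    .fj_abort("window shorter than one cardiac cycle",
              "fontanjet_insufficient_window")
  }
  t_end <- window[1] + n_cycles * period
  sel <- record$time_s >= window[1] - 1e-9 & record$time_s < t_end - 1e-9
  mean(record[[channel]][sel])
}
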
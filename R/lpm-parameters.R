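#' Pulsatile pump settings
#'
#' Describes the cardiovascular waveform pump that drives the circulation
#' model: a piston pump running at a fixed heart rate and stroke volume,
#' ejecting as a half-sine pulse over a fraction of each cycle.
#'
#' @param heart_rate Beats per minute (> 0). Default 80 bpm.
#' @param stroke_volume Ejected volume per beat in mL (>= 0). Default 30 mL,
#'   giving a cardiac output of 80 x 30 = 2400 mL/min = 2.4 L/min.
#' @param ejection_fraction_of_cycle Fraction of the cardiac period during
#'   which the pump ejects, in (0, 1). Default 0.3.
#'
#' @return A list of class `pump_settings`.
#' @examples
#' pump_settings()
#' @export
pump_settings <- function(heart_rate = 80,
                          stroke_volume = 30,
                          ejection_fraction_of_cycle = 0.3) {
  .assert_scalar_pos(heart_rate, "heart_rate")
  .assert_scalar_pos(stroke_volume, "stroke_volume", strict = FALSE)
  .assert_fraction(ejection_fraction_of_cycle, "ejection_fraction_of_cycle")
  structure(
    list(
      heart_rate = heart_rate,
      stroke_volume = stroke_volume,
      ejection_fraction_of_cycle = ejection_fraction_of_cycle,
      period = 60 / heart_rate
    ),
    class = "pump_settings"
  )
}

#' Four-compartment Windkessel parameter set
#'
#' Assembles the reduced-order lumped-parameter model of Fontan circulation:
#' four two-element (resistance--compliance) Windkessel compartments for the
#' upper systemic, lower systemic, right pulmonary and left pulmonary beds,
#' a pulsatile pump source, and the fixed loop plumbing that connects them.
#'
#' The compartment `resistance` entries are the tunable needle-valve
#' analogues adjusted by [tune_resistances()] to realize the prescribed flow
#' splits. The `loop` entries are fixed plumbing of the circuit: arterial
#' feed resistances between the aortic node and each systemic compartment
#' (these carry the arterial-to-venous pressure drop), pulmonary outlet
#' resistances between each pulmonary compartment and the venous reservoir,
#' and the compliance of the pump-side aortic chamber. Their defaults place
#' the model's steady pressures at physiologic Fontan levels (venous
#' 17--19 mmHg, pulmonary 7--9 mmHg, aortic ~95 mmHg) for the default
#' 2.4 L/min cardiac output with a 30/70 systemic and 50/50 pulmonary split.
#'
#' @param compartments A data frame with columns `name`
#'   (`upper_systemic`, `lower_systemic`, `rpa`, `lpa`, each exactly once),
#'   `resistance` (mmHg.min/L, > 0) and `compliance` (mL/mmHg, > 0).
#' @param pump A [pump_settings()] object.
#' @param venous_reference_pressure Downstream reservoir (atrial) pressure in
#'   mmHg. Default 5.
#' @param systemic_split_target Target upper-body share of cardiac output,
#'   in (0, 1). Default 0.30.
#' @param pulmonary_split_target Target RPA share of pulmonary return, in
#'   (0, 1). Default 0.50.
#' @param loop Named list of fixed plumbing values: `ra_upper`, `ra_lower`
#'   (arterial feed resistances, mmHg.min/L), `ro_rpa`, `ro_lpa` (pulmonary
#'   outlet resistances, mmHg.min/L), `c_aortic` (aortic chamber compliance,
#'   mL/mmHg).
#'
#' @return A list of class `lpm_parameters`.
#' @examples
#' params <- lpm_parameters()
#' params$compartments
#' @export
lpm_parameters <- function(compartments = default_compartments(),
                           pump = pump_settings(),
                           venous_reference_pressure = 5,
                           systemic_split_target = 0.30,
                           pulmonary_split_target = 0.50,
                           loop = default_loop()) {
  compartments <- as_tibble(compartments)
  required <- c("upper_systemic", "lower_systemic", "rpa", "lpa")
  if (!identical(sort(compartments$name), sort(required)) ||
      nrow(compartments) != 4L) {
    .fj_abort(
      "`compartments` must contain exactly one row for each of upper_systemic, lower_systemic, rpa, lpa",
      "fontanjet_invalid_parameter"
    )
  }
  if (!all(is.finite(compartments$resistance)) ||
      any(compartments$resistance <= 0) ||
      !all(is.finite(compartments$compliance)) ||
      any(compartments$compliance <= 0)) {
    .fj_abort("compartment resistances and compliances must be finite and > 0",
              "fontanjet_invalid_parameter")
  }
  if (!inherits(pump, "pump_settings")) {
    .fj_abort("`pump` must be a pump_settings() object",
              "fontanjet_invalid_parameter")
  }
  .assert_fraction(systemic_split_target, "systemic_split_target")
  .assert_fraction(pulmonary_split_target, "pulmonary_split_target")
  loop <- modifyList(default_loop(), as.list(loop))
  for (nm in c("ra_upper", "ra_lower", "ro_rpa", "ro_lpa", "c_aortic")) {
    .assert_scalar_pos(loop[[nm]], paste0("loop$", nm))
  }
  structure(
    list(
      compartments = compartments[match(required, compartments$name), ],
      pump = pump,
      venous_reference_pressure = venous_reference_pressure,
      systemic_split_target = systemic_split_target,
      pulmonary_split_target = pulmonary_split_target,
      loop = loop
    ),
    class = "lpm_parameters"
  )
}

#' @rdname lpm_parameters
#' @export
default_compartments <- function() {
  tibble(
    name = c("upper_systemic", "lower_systemic", "rpa", "lpa"),
    resistance = c(9.2, 5.2, 2.2, 1.8),
    compliance = c(8, 8, 4, 4)
  )
}

#' @rdname lpm_parameters
#' @export
default_loop <- function() {
  list(
    ra_upper = 108.9,
    ra_lower = 45.4,
    ro_rpa = 2.0,
    ro_lpa = 2.4,
    c_aortic = 0.8
  )
}

#' @export
print.lpm_parameters <- function(x, ...) {
  cat("<lpm_parameters>\n")
  cat(sprintf("  pump: %g bpm, %g mL stroke (CO %.2f L/min)\n",
              x$pump$heart_rate, x$pump$stroke_volume,
              x$pump$heart_rate * x$pump$stroke_volume / 1000))
  cat(sprintf("  split targets: upper %.0f%%, RPA %.0f%%\n",
              100 * x$systemic_split_target, 100 * x$pulmonary_split_target))
  print(x$compartments)
  invisible(x)
}

#' Simulation configuration
#'
#' @param duration Length of the returned record in seconds (after the
#'   settle period is discarded).
#' @param time_step Output sampling interval in seconds. Default 0.01
#'   (100 Hz).
#' @param settle_cycles Number of cardiac cycles integrated and discarded
#'   before the record begins, during which periodic steady state is
#'   verified. Default 10.
#' @param periodicity_tolerance Maximum relative change between consecutive
#'   cycle means of any flow channel for the pre-record segment to count as
#'   periodic. Default 0.005.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(duration = 30,
                       time_step = 0.01,
                       settle_cycles = 10,
                       periodicity_tolerance = 0.005) {
  .assert_scalar_pos(duration, "duration")
  .assert_scalar_pos(time_step, "time_step")
  if (settle_cycles < 1) {
    .fj_abort("`settle_cycles` must be >= 1", "fontanjet_invalid_parameter")
  }
  structure(
    list(
      duration = duration,
      time_step = time_step,
      settle_cycles = settle_cycles,
      periodicity_tolerance = periodicity_tolerance
    ),
    class = "sim_config"
  )
}
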
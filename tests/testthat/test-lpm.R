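test_that("pump waveform delivers the stroke volume and target cardiac output", {
  pump <- pump_settings(heart_rate = 80, stroke_volume = 30)
  tt <- seq(0, pump$period, by = 1e-5)
  # cycle-averaged flow: 80 bpm x 30 mL = 2.4 L/min
  expect_equal(mean(pump_flow(head(tt, -1), pump)), 2.4, tolerance = 1e-6)

  # peak of the half-sine matches pi*SV/(2*T_ej), found by dense sampling
  t_ej <- pump$ejection_fraction_of_cycle * pump$period
  expect_equal(max(pump_flow(tt, pump)), pi * 30 / (2 * t_ej) * 0.06,
               tolerance = 1e-6)

  # periodic with the cardiac period, nonnegative
  expect_equal(pump_flow(tt, pump), pump_flow(tt + 3 * pump$period, pump),
               tolerance = 1e-12)
  expect_true(all(pump_flow(tt, pump) >= 0))

  expect_equal(pump_flow(tt, pump_settings(stroke_volume = 0)),
               rep(0, length(tt)))
  expect_error(pump_settings(heart_rate = -10), class = "fontanjet_invalid_parameter")
})

test_that("derivatives vanish at equilibrium and close the volume budget", {
  params <- lpm_parameters()
  p_ref <- params$venous_reference_pressure
  eq <- setNames(rep(p_ref, 5),
                 c("p_aortic", "p_upper", "p_lower", "p_rpa", "p_lpa"))
  d <- lpm_derivatives(eq, 0, params, list(pump = 0, injection = 0))
  expect_equal(unname(d), rep(0, 5), tolerance = 1e-12)

  # brute-force budget oracle: total compliance storage rate must equal
  # external inflow minus outflow through the distal outlets
  compl <- c(params$loop$c_aortic, params$compartments$compliance)
  set.seed(11)
  for (i in 1:20) {
    st <- setNames(runif(5, 2, 110),
                   c("p_aortic", "p_upper", "p_lower", "p_rpa", "p_lpa"))
    inflow <- list(pump = runif(1, 0, 12), injection = runif(1, 0, 1.2))
    d <- lpm_derivatives(st, 0, params, inflow)
    storage_lmin <- sum(compl * d) * 60 / 1000
    outflow <- (st[["p_rpa"]] - p_ref) / params$loop$ro_rpa +
      (st[["p_lpa"]] - p_ref) / params$loop$ro_lpa
    expect_equal(storage_lmin, inflow$pump + inflow$injection - outflow,
                 tolerance = 1e-10)
  }
  expect_error(lpm_derivatives(c(eq[1:4], p_lpa = NaN), 0, params),
               class = "fontanjet_numeric_state")
})

test_that("DC solution obeys the Ohm's-law analogue on every branch", {
  set.seed(7)
  for (i in 1:5) {
    cp <- default_compartments()
    cp$resistance <- cp$resistance * runif(4, 0.5, 2)
    params <- lpm_parameters(compartments = cp)
    dc <- lpm_dc_state(params, co = 2.4)
    p <- dc$pressures; fl <- dc$flows
    ra <- params$loop
    # steady pressure drops are flow times resistance, closed-form limit
    expect_equal(p[["p_aortic"]] - p[["p_upper"]],
                 fl[["q_upper"]] * ra$ra_upper, tolerance = 1e-9)
    expect_equal(p[["p_upper"]] - p[["p_tcpc"]],
                 fl[["q_upper"]] * cp$resistance[cp$name == "upper_systemic"],
                 tolerance = 1e-9)
    expect_equal(p[["p_rpa"]] - params$venous_reference_pressure,
                 fl[["q_rpa"]] * ra$ro_rpa, tolerance = 1e-9)
    # mass conservation at DC
    expect_equal(fl[["q_upper"]] + fl[["q_lower"]],
                 fl[["q_rpa"]] + fl[["q_lpa"]], tolerance = 1e-9)
  }
})

test_that("simulation reaches a mass-conserving periodic steady state at target CO", {
  rec <- simulate_lpm(tuned_params(), NULL,
                      sim_config(duration = 7.5, settle_cycles = 40))
  co_sys <- cycle_average(rec, "q_upper") + cycle_average(rec, "q_lower")
  co_pul <- cycle_average(rec, "q_rpa") + cycle_average(rec, "q_lpa")
  expect_lt(abs(co_sys - co_pul) / co_sys, 0.01)
  expect_equal(co_sys, 2.4, tolerance = 0.02)
  md <- record_metadata(rec)
  expect_identical(md$provenance, "simulated")
})

test_that("an active continuous injection adds its flow to pulmonary return", {
  proto <- case_protocol(14) # 10 mL/s x 150 mL: 15 s at 0.6 L/min
  rec <- simulate_lpm(tuned_params(), proto,
                      sim_config(duration = 40, settle_cycles = 40))
  w <- c(13, 24.25)
  inflow <- 2.4 + mean(injection_flow(seq(w[1], w[2], by = 1e-3), proto))
  outflow <- cycle_average(rec, "q_rpa", w) + cycle_average(rec, "q_lpa", w)
  expect_equal(outflow, inflow, tolerance = 0.02)
})

test_that("raising the upper systemic resistance lowers upper flow", {
  base <- lpm_parameters()
  q_up <- function(par) lpm_dc_state(par)$flows[["q_upper"]]
  bumped <- base
  bumped$compartments$resistance[1] <- bumped$compartments$resistance[1] * 1.5
  expect_lt(q_up(bumped), q_up(base))
  # and in full simulation
  r1 <- simulate_lpm(base, NULL, sim_config(duration = 3))
  r2 <- simulate_lpm(bumped, NULL, sim_config(duration = 3))
  expect_lt(cycle_average(r2, "q_upper"), cycle_average(r1, "q_upper"))
})

test_that("resistance tuning hits its split targets and is idempotent", {
  tuned <- tuned_params()
  rec <- simulate_lpm(tuned, NULL, sim_config(duration = 7.5,
                                              settle_cycles = 40))
  qu <- cycle_average(rec, "q_upper"); ql <- cycle_average(rec, "q_lower")
  qr <- cycle_average(rec, "q_rpa"); qp <- cycle_average(rec, "q_lpa")
  expect_equal(qu / (qu + ql), 0.30, tolerance = 0.01)
  expect_equal(qr / (qr + qp), 0.50, tolerance = 0.01)

  retuned <- tune_resistances(tuned)
  expect_equal(retuned$compartments$resistance,
               tuned$compartments$resistance, tolerance = 1e-3)

  # an off-nominal target is reached too (oracle: DC re-solution)
  skewed <- lpm_parameters(systemic_split_target = 0.7)
  tuned2 <- tune_resistances(skewed)
  fl <- lpm_dc_state(tuned2)$flows
  expect_equal(fl[["q_upper"]] / (fl[["q_upper"]] + fl[["q_lower"]]), 0.7,
               tolerance = 0.01)

  expect_error(lpm_parameters(systemic_split_target = 1.2),
               class = "fontanjet_invalid_target")
})

test_that("tuning a symmetric circuit gives equal branch resistances", {
  cp <- default_compartments()
  cp$resistance <- c(7, 7, 2, 2)
  sym <- lpm_parameters(
    compartments = cp,
    systemic_split_target = 0.5,
    loop = list(ra_upper = 60, ra_lower = 60, ro_rpa = 2, ro_lpa = 2)
  )
  tuned <- tune_resistances(sym)
  r <- tuned$compartments$resistance
  expect_equal(r[1], r[2], tolerance = 1e-6)
  expect_equal(r[3], r[4], tolerance = 1e-6)
})

test_that("cycle averages are exact on constants and kill heart-rate tones", {
  rec <- flat_record(duration = 6)
  expect_equal(cycle_average(rec, "q_rpa"), 1.2, tolerance = 1e-12)

  f_heart <- 80 / 60
  rec2 <- flat_record(duration = 6, q_rpa = function(t) {
    1.2 + 0.4 * sin(2 * pi * f_heart * t)
  })
  expect_equal(cycle_average(rec2, "q_rpa", c(0, 3)), 1.2, tolerance = 1e-3)

  expect_error(cycle_average(rec, "q_rpa", c(0, 0.5)),
               class = "fontanjet_insufficient_window")
  expect_error(cycle_average(rec, "nope"), class = "fontanjet_format_error")
})
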
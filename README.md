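# fontanjet

Quantifying jet entrainment in an injection-assisted Fontan circulation.

Fontan patients live with a single functional ventricle: systemic venous
return drains passively through a total cavopulmonary connection (TCPC)
into the pulmonary arteries, and the chronically elevated caval pressure
this produces is implicated in late Fontan failure. One proposed passive
assist is an **injection jet shunt** — high-pressure flow taken from the
arterial side and injected along the venous co-flow so that shear-driven
momentum transfer *entrains* additional flow downstream. Whether a given
injection entrains or instead *blocks* the native flow depends on its
rate, volume and modality (continuous vs. pulsed bursts).

`fontanjet` is for researchers studying this question on bench-style
(mock-flow-loop) models. It provides, as composable tibble-in /
tibble-out functions:

- **`lpm_core`** — a reduced-order lumped-parameter circulation: four
  2-element Windkessel compartments (upper/lower systemic, right/left
  pulmonary; `C dP/dt = Q_in − Q_out`, `Q = ΔP/R`) around an ideal TCPC
  junction, driven by a half-sine piston pump (80 bpm, 30 cc → cardiac
  output 2.4 L/min), with `tune_resistances()` realizing the 30/70
  systemic and 50/50 pulmonary flow splits;
- **`protocol_table()` / `injection_flow()`** — the 20-case clinical
  injection protocol (8 five-burst pulsed, 12 continuous; 5–20 mL/s)
  with first-order injector spool-up;
- **`emulate_mfl()`** — synthetic multichannel sensor records
  (flows/pressures at 100 Hz) with a *programmable* entrainment response
  and seeded noise, so the whole pipeline is testable against known
  ground truth;
- **`filter_record()`** — zero-phase Butterworth + Savitzky–Golay
  denoising;
- **`segment_stages()` / `segment_bursts()`** — pre/active/post stage and
  per-burst segmentation, command-aligned or signal-detected;
- **`rise_metrics()` / `fall_metrics()` / `relaxation_time()`** —
  step-response characterization: 10–90% rise and fall times, 2% settling
  time, overshoot/undershoot, and the jet relaxation time
  `t_rel = t_rise − t_fall` (negative values flag fluid-buildup risk);
- **`entrainment_rate()` and friends** — the entrainment rate
  `Q_ent = Q_meas,RPA − (Q_baseline,RPA + Q_inj)` (positive =
  entrainment, negative = blockage), normalized series, volume × rate
  result matrices, column-normalized means and the entrainment cutoff
  rate;
- **`run_sweep()`** — the full 20-case × n-trial pipeline with
  deterministic per-trial seeds and a reproducibility manifest.

Results carry broom-style `tidy()`/`glance()` methods and `autoplot()`
graphics.

## Worked example

Tune the circulation, emulate one protocol case with a programmed
entrainment of +0.2 L/min, and run the measurement pipeline:

```r
library(fontanjet)

params <- tune_resistances(lpm_parameters())
proto  <- case_protocol(13)            # continuous, 10 mL/s (0.6 L/min), 100 mL
rec    <- emulate_mfl(params, proto, sensor_model(seed = 42),
                      entrainment_emulation(magnitude = 0.2))
filt   <- filter_record(rec)
bounds <- segment_bursts(segment_stages(filt, proto, "command_aligned"),
                         filt, proto)

measure_entrainment(filt, bounds, proto)
#>   q_meas_rpa q_baseline_rpa q_inj q_ent normalized       label
#> 1     1.9959         1.1989   0.6 0.197     0.3283 entrainment

glance(characterize_jet(filt, bounds))[, c("rise_time", "fall_time",
                                           "relaxation_time")]
#>   rise_time fall_time relaxation_time
#> 1     0.547     0.496           0.051
```

Reading this: the measured active-window RPA flow (1.996 L/min) exceeds
the expected baseline share plus the injection itself by 0.197 L/min —
the pipeline recovers the programmed +0.2 L/min entrainment to within
1.5% under default sensor noise. The rise time exceeds the fall time, so
the relaxation time is positive: no buildup risk for this case.

Sweep-level summaries on the packaged benchtop result tables:

```r
tabs <- load_printed_tables()
column_normalized_mean(tabs$entrainment_continuous, 0.3)  # 0.6396
column_normalized_mean(tabs$entrainment_pulsed, 0.3)      # 0.1563
cutoff_rate(tabs$entrainment_continuous)                  # 0.6 L/min
cutoff_rate(tabs$entrainment_pulsed)                      # 0.3 L/min
```

A full synthetic sweep (`run_sweep(sweep_config(params = params))`) runs
all 20 cases × 3 trials in under a minute and reassembles the
entrainment and relaxation matrices from its own measurements.

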
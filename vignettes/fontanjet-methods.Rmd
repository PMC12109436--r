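---
title: "Modelling jet entrainment in an injection-assisted Fontan circulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling jet entrainment in an injection-assisted Fontan circulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fontanjet)
```

## The problem

Fontan physiology routes systemic venous return passively into the
pulmonary arteries through a total cavopulmonary connection (TCPC),
without a subpulmonary ventricle. One proposed way to energize this
fragile circulation is an injection jet: high-pressure flow drawn from the
arterial side and injected along the venous co-flow, entraining
surrounding fluid by shear-driven momentum transfer. Whether an injection
*helps* (entrains extra flow) or *hurts* (blocks the native flow) depends
on injection rate, volume and modality (one long continuous injection
versus a train of short bursts).

`fontanjet` packages the analysis chain needed to study this question on a
bench-style model: a reduced-order circulation simulator standing in for
the mock flow loop, a generator for the 20-case clinical injection
protocol, a synthetic sensor-record generator with programmable ground
truth, waveform denoising, transient segmentation, step-response jet
characterization, and entrainment quantification with sweep-level
summaries.

## The circulation model

The circulation is a lumped-parameter (0D) electrical analogue: four
two-element Windkessel compartments — upper systemic, lower systemic,
right pulmonary (RPA) and left pulmonary (LPA) — each a resistance
`R` (mmHg·min/L) with a compliance `C` (mL/mmHg) to the venous reference
pressure. Every compliance node obeys

$$C\,\frac{dP}{dt} = Q_\text{in} - Q_\text{out},
  \qquad Q = \frac{\Delta P}{R},$$

and the TCPC is an ideal zero-resistance junction solved algebraically at
each step.

Two junctions connect four branches, and an ideal junction directly
between two capacitive nodes would short them together. The circuit
therefore includes fixed *loop plumbing*, physically present in any bench
rig but not independently tunable: arterial feed resistances between the
aortic node and each systemic compartment (these carry the
arterial-to-venous pressure drop), outlet resistances between each
pulmonary compartment and the venous reservoir, and the compliance of the
pump-side aortic chamber. With this arrangement all four compartment
pressures are distinct states, and the four compartment resistances play
the role of the rig's needle valves.

Default values were solved on paper from the target operating point —
cardiac output 2.4 L/min, a 30/70 upper/lower systemic split, a 50/50
pulmonary split, venous pressures near 17–19 mmHg, pulmonary pressures
near 7–9 mmHg, aortic pressure near 95 mmHg and a 5 mmHg reservoir — and
shipped in `default_compartments()` / `default_loop()`:

```{r}
lpm_parameters()
lpm_dc_state(lpm_parameters())$pressures
```

**Pump.** The pulsatile source is a piston-pump approximation: a
half-sine ejection pulse occupying 30% of each cardiac cycle, with its
area constrained to the stroke volume. Only rate (80 bpm) and stroke
volume (30 mL) are physiologically prescribed; the half-sine shape and
ejection fraction are modelling choices for a Harvard-style waveform pump.
The cycle-averaged output is exactly `heart_rate x stroke_volume`
(2.4 L/min at defaults).

**Tuning.** `tune_resistances()` adjusts each split pair reciprocally
(`R_upper/θ`, `R_lower·θ`) with a 1D root search per split. Because the
network is linear and time-invariant, the cycle-averaged flows at periodic
steady state equal the DC (constant-inflow) solution exactly, so the
search runs on the DC network solve and is deterministic; tests confirm
the achieved splits by re-simulation. The reciprocal scaling preserves the
pair's geometric mean and makes any target split in (0, 1) reachable.

**Integration.** `simulate_lpm()` uses `deSolve::ode()` (`lsoda`,
stiff-capable) with a maximum step of 1/200 of the cardiac period,
relative/absolute tolerances of 1e-8, and fixed output sampling by the
solver's dense output. The state is initialized at the DC solution; the
slowest circuit mode has a time constant of roughly 6 s, so a residual
transient of a few tenths of a percent survives the default ten-cycle
settle window (the periodicity check tolerates 0.5% between consecutive
cycle means). Where a stationary baseline matters — synthetic records and
the reported split measurements — a forty-cycle settle is used instead,
which pushes the residual below 0.1%.

## The injection protocol

The protocol space is the clinical table of 20 cases: 8 pulsed (rates
5/10/15/20 mL/s crossed with burst volumes 20/15 mL, five bursts) and 12
continuous (the same rates crossed with volumes 50/100/150 mL). The
injector is modelled as a rectangular rate command passed through a
first-order spool-up/down lag; the lag is volume conserving in the
long-time limit.

Three protocol quantities are not documented for the original rig and are
set once here as declared assumptions, all configurable:

* `inter_burst_gap = 5` s — an order of magnitude above the sub-second
  jet fall times, so bursts are cleanly separable;
* `injector_time_constant = 0.2` s — places simulated rise times in the
  sub-second range typical of measured jet transients;
* `start_time = 10` s — more than ten cardiac cycles of baseline before
  the first burst.

## The synthetic mock-flow-loop generator

`emulate_mfl()` is the testbed that replaces the physical rig: it runs
the circulation model to periodic steady state, then constructs the
measured RPA flow as

> baseline RPA flow + lagged injection waveform + programmed entrainment
> envelope + sensor noise,

with every other channel taken from the model plus noise. The entrainment
envelope is first-order, locked to the injection command: it rises toward
the programmed magnitude `E0` with `tau_rise` while the command is on and
decays with `tau_fall` at shutoff. Because `E0`, `tau_rise` and
`tau_fall` are known inputs, every downstream stage can be validated by
parameter recovery. Defaults `tau_rise = 0.3` s, `tau_fall = 0.15` s give
a positive relaxation time of the magnitude seen on bench rigs; in
`run_sweep()` the per-case `E0` is looked up from the packaged benchtop
result tables, so a full synthetic sweep reproduces the published
entrainment pattern by construction and tests the pipeline's ability to
recover it.

The sensor model is 100 Hz sampling (at least ten samples across the
fastest rise/fall times), white Gaussian noise of 0.05 L/min on flows and
0.5 mmHg on pressures, and 60 Hz mains interference at 10% of each
channel's dynamic range. The rig's true sampling rate and noise spectrum
are unpublished; these are declared assumptions. A mains frequency above
the Nyquist limit is recorded as its aliased tone (40 Hz at defaults),
exactly as an acquisition card would see it — still comfortably inside
the low-pass stopband.

What the generator does *not* emulate: flow-sensor transfer functions,
transducer drift, any spatially resolved flow structure, and any
mechanistic link between injection parameters and entrainment magnitude —
`E0` is programmed, not predicted. Passing the recovery tests therefore
demonstrates that the *measurement pipeline* is unbiased under the stated
noise model, not that the circulation model predicts entrainment.

## Denoising

Two zero-phase stages, applied per channel by `filter_record()`:
an order-4 Butterworth low-pass at 15 Hz (≈11x the 80 bpm heart
frequency, so cardiac harmonics pass), then Savitzky–Golay smoothing with
a 21-sample window and cubic polynomials. Both stages are applied
forward–backward so rise/fall timings are not phase-shifted, with
odd-reflection edge padding so a constant signal passes exactly.
Butterworth-before-SG removes broadband and mains noise first, then
polishes waveform shape. Cycle-averaged flows — the inputs to the
entrainment calculation — change by less than 0.5% under the defaults.
Sharp corners (the aortic ejection kink, injection onsets) genuinely
contain energy above 15 Hz and are smoothed by design.

## Segmentation

A record splits into three stages: pre-injection baseline, active
injection and post-injection wind-down, with each burst further split
into its injection period and shutoff period. Two modes:

* `command_aligned` uses the protocol schedule directly — preferred
  whenever the command timing is known, and used by `run_sweep()`;
* `signal_detected` finds excursions of the RPA flow above the baseline
  mean + 3 SD lasting at least 10 consecutive samples, then refines each
  edge to the nearby mid-amplitude (50%) crossing.

The refinement exists because the first crossing of a low threshold on a
zero-phase-filtered edge is biased early on the way up and late on the
way down by half the filter smear (up to ~5 samples at the default filter
settings); the 50% crossing of a symmetric smear is unbiased. With the
refinement, detected boundaries stay within one sample of the command
times across 50 noise seeds in the test suite. For edges with a
pronounced first-order tail the detected end still trails the command by
a lag-dependent amount — that is a property of the signal, and the
command-aligned mode is the right tool when the schedule is known.

## Jet characterization

For each burst, the injection-period segment is treated as a step
response relative to the pre-injection baseline:

* settling value — mean of the final quartile of the injection period
  (the published analysis identifies a "steady settling value" without a
  formula; the final-quartile mean is robust to the spool-up);
* response amplitude `Δ` = settling − baseline; all percentage
  thresholds are relative to `Δ`, the standard step-response convention;
* rise time — time between the first crossings of 10% and 90% of `Δ`,
  crossings located by linear interpolation for sub-sample resolution
  (first-crossing convention when ringing is present);
* settling time — from activation until the signal stays inside
  settling ± 2%·Δ;
* peak and overshoot — over the post-10%-crossing portion;
* settling min/max and undershoot — over the portion after the first
  crossing of the settling value. Taking these over the whole
  post-10%-crossing portion would force an "undershoot" of ~90% on any
  monotone rise, so the fluctuation-about-steady-state window is used
  instead;
* fall time — mirror of the rise on the shutoff segment, using the same
  `Δ` (whether the wind-down should be normalized by its own amplitude is
  ambiguous in the source analysis; the mirror convention is adopted and
  documented here);
* relaxation time `t_rel = t_rise − t_fall`, with `t_rel > 0` labelled
  no-buildup and `t_rel < 0` buildup-risk. For five-burst runs the
  per-burst metrics are averaged field-wise.

On an ideal first-order response these definitions give
`t_rise = τ·ln 9` and `t_settle = τ·ln 50`; the test suite verifies both
within two samples at 100 Hz, with error at least halving when the
sampling rate doubles.

## Entrainment

The entrainment rate of a run is the excess of the measured RPA flow over
pure superposition:

$$Q_\text{ent} = Q_\text{meas,RPA} - \left(Q_\text{baseline,RPA} +
Q_\text{inj}\right),$$

positive for entrainment, negative for blockage. The published formula
prints the right-hand side without parentheses; only this parenthesization
makes "blockage gives negative values" and the published sign pattern
coherent, so it is adopted and stated prominently here.
`Q_baseline,RPA` is the systemic flow times the pulmonary split (0.5 at
the tuned operating point); by default the per-trial *measured*
pre-injection systemic flow is used, with a nominal-value option. The
measured flow is averaged over the burst injection periods, excluding the
first `max(1 s, 5 injector time constants)` of each (capped at half the
period) so spool-up transients do not bias the mean; for short
high-rate bursts this exclusion necessarily leaves part of the envelope
rise inside the window, which slightly attenuates recovered magnitudes —
visible in the pulsed sweep cells, at a few hundredths of a L/min.

Sweep results are assembled into volume x rate matrices
(`entrainment_matrix()`), from which two summaries are computed:
`column_normalized_mean()` (the mean of a rate column divided by its
rate) and `cutoff_rate()` (the largest rate whose column is entirely
positive). On the packaged transcription of the benchtop result tables
these reproduce the published values:

```{r}
tabs <- load_printed_tables()
column_normalized_mean(tabs$entrainment_continuous, 0.3)
column_normalized_mean(tabs$entrainment_pulsed, 0.3)
cutoff_rate(tabs$entrainment_continuous)
cutoff_rate(tabs$entrainment_pulsed)
```

The pulsed table rows are keyed by per-burst volume (0.015 and 0.020 L);
the published table prints its second row label as "0.2", read here as
the 20 cc burst volume.

## Numerical and reproducibility choices

* All interfaces use L/min for flow, mmHg for pressure, seconds for time;
  conversions are internal.
* Per-trial seeds derive deterministically from
  `(base_seed, case_id, trial)` and stay below 2^31; identical
  configurations give byte-identical sweeps, and baseline model runs are
  cached by a hash of their inputs.
* Cycle averages truncate to whole cardiac cycles so the weak residual
  pulsatility cannot bias means; windows shorter than one cycle are
  refused.
* Entrainment labels use a 1e-6 L/min dead band around zero.
* Test problem sizes: records of 20–110 s at 100 Hz, 50-seed ensembles
  for recovery and robustness properties, and a full 20-case x 3-trial
  sweep that completes in well under a minute on one core.

## Limitations

The circulation model is linear (no pressure-dependent resistances, no
inertance, no respiratory modulation) and its compartment values are
tuned to a single operating point, not identified from rig measurements.
The entrainment magnitude in synthetic records is programmed rather than
derived from jet mechanics — predicting it would require the
computational fluid dynamics this package deliberately does not attempt.
Published absolute relaxation times depend on the original rig's
unpublished filter and sampling settings, so timing validation here is
against synthetic ground truth; only the signs and trends of those tables
are meaningful for comparison.
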
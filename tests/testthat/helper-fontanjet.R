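# Shared fixtures, built in code. The tuned parameter set is memoized for
# the whole test run; emulated baselines are cached inside the package.

tuned_params <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- tune_resistances(lpm_parameters())
    cached
  }
})

quiet_sensor <- function(seed = 1L, sampling_rate = 100) {
  sensor_model(sampling_rate = sampling_rate,
               gaussian_noise_sd = c(flow = 0, pressure = 0),
               mains_amplitude_frac = 0, seed = seed)
}

# synthetic record with flat channels except a programmable q_rpa; used to
# exercise segmentation and metrics against exactly known waveforms
flat_record <- function(duration = 30, fs = 100, q_rpa = NULL,
                        baseline = 1.2, heart_rate = 80) {
  t <- seq(0, duration, by = 1 / fs)
  q <- if (is.null(q_rpa)) rep(baseline, length(t)) else q_rpa(t)
  mfl_record(
    tibble::tibble(
      time_s = t,
      q_upper = 0.72, q_lower = 1.68, q_rpa = q, q_lpa = 1.2,
      p_upper = 17, p_lower = 19, p_rpa = 7.4, p_lpa = 7.9, p_aortic = 95
    ),
    sampling_rate = fs,
    metadata = list(provenance = "simulated", heart_rate = heart_rate)
  )
}

# ideal first-order step segment: baseline + amp * (1 - exp(-t / tau))
first_order_rise <- function(tau, fs = 100, n_tau = 12, baseline = 0,
                             amp = 1) {
  t <- seq(0, n_tau * tau, by = 1 / fs)
  tibble::tibble(time_s = t, q_rpa = baseline + amp * (1 - exp(-t / tau)))
}

# ideal first-order decay from the settled level back to baseline
first_order_fall <- function(tau, fs = 100, n_tau = 12, baseline = 0,
                             amp = 1) {
  t <- seq(0, n_tau * tau, by = 1 / fs)
  tibble::tibble(time_s = t, q_rpa = baseline + amp * exp(-t / tau))
}
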
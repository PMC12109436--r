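ln9 <- log(9)
ln50 <- log(50)

test_that("rise metrics match first-order closed forms", {
  for (tau in c(0.15, 0.23, 0.4)) {
    seg <- first_order_rise(tau, fs = 100, n_tau = 20, baseline = 1.2,
                            amp = 0.8)
    m <- rise_metrics(seg, baseline_value = 1.2)
    expect_equal(m$rise_time, tau * ln9, tolerance = 0.02 / (tau * ln9))
    expect_equal(m$settling_time, tau * ln50,
                 tolerance = 0.02 / (tau * ln50))
    expect_equal(m$settling_value, 2.0, tolerance = 1e-3)
  }
})

test_that("fall metrics mirror the rise and match the closed form", {
  for (tau in c(0.1, 0.3)) {
    seg <- first_order_fall(tau, fs = 100, n_tau = 20, baseline = 1.2,
                            amp = 0.8)
    f <- fall_metrics(seg, baseline_value = 1.2, settling_value = 2.0)
    expect_equal(f$fall_time, tau * ln9, tolerance = 0.02 / (tau * ln9))
  }
  # symmetric shapes: fall time equals rise time
  tau <- 0.25
  r <- rise_metrics(first_order_rise(tau, n_tau = 20), 0)
  f <- fall_metrics(first_order_fall(tau, n_tau = 20), 0, 1)
  expect_equal(f$fall_time, r$rise_time, tolerance = 1e-2)
})

test_that("metric error shrinks at least linearly with the sampling rate", {
  taus <- seq(0.1, 0.5, length.out = 25)
  err <- sapply(c(100, 200), function(fs) {
    e <- sapply(taus, function(tau) {
      m <- rise_metrics(first_order_rise(tau, fs = fs, n_tau = 20), 0)
      c(abs(m$rise_time - tau * ln9), abs(m$settling_time - tau * ln50))
    })
    rowMeans(e)
  })
  expect_lte(err[1, 2], err[1, 1] / 2)
  expect_lte(err[2, 2], err[2, 1] / 2)
})

test_that("a monotone saturating step has zero overshoot", {
  t <- seq(0, 10, by = 0.01)
  seg <- tibble::tibble(time_s = t, q_rpa = pmin(t, 1)) # ramp then flat
  m <- rise_metrics(seg, baseline_value = 0)
  expect_equal(m$overshoot_pct, 0, tolerance = 1e-6)
  expect_equal(m$undershoot_pct, 0, tolerance = 1e-6)
  expect_equal(m$peak_value, 1)
})

test_that("overshoot and settling bounds capture a ringing response", {
  t <- seq(0, 10, by = 0.01)
  x <- 1 - exp(-t / 0.4) * cos(2 * pi * t / 1.5)
  seg <- tibble::tibble(time_s = t, q_rpa = x)
  m <- rise_metrics(seg, baseline_value = 0)
  expect_gt(m$overshoot_pct, 0)
  expect_lte(m$settling_min, m$settling_value)
  expect_gte(m$settling_max, m$settling_value)
  expect_equal(m$peak_value, max(x))
})

test_that("degenerate segments raise classed errors", {
  t <- seq(0, 5, by = 0.01)
  flat <- tibble::tibble(time_s = t, q_rpa = rep(1.2, length(t)))
  expect_error(rise_metrics(flat, baseline_value = 1.2),
               class = "fontanjet_no_response")
  # a segment that never decays below the 90% fall level
  hover <- tibble::tibble(time_s = t, q_rpa = 2 - 0.05 * t / 5)
  expect_error(fall_metrics(hover, baseline_value = 1.2,
                            settling_value = 2),
               class = "fontanjet_malformed_segment")
})

test_that("relaxation time is the rise-fall difference with sign semantics", {
  r <- tibble::tibble(rise_time = 0.9)
  f <- tibble::tibble(fall_time = 0.4)
  out <- relaxation_time(r, f)
  expect_equal(out$relaxation_time, 0.5)
  expect_identical(out$buildup_label, "no-buildup")

  eq <- relaxation_time(tibble::tibble(rise_time = 0.4), f)
  expect_equal(eq$relaxation_time, 0)
  expect_identical(eq$buildup_label, "boundary")

  neg <- relaxation_time(tibble::tibble(rise_time = 0.2), f)
  expect_identical(neg$buildup_label, "buildup-risk")
  # antisymmetry under swapping rise and fall
  expect_equal(neg$relaxation_time,
               -relaxation_time(tibble::tibble(rise_time = 0.4),
                                tibble::tibble(fall_time = 0.2))$relaxation_time)
})

test_that("first-order envelopes give the closed-form relaxation time", {
  tau_r <- 0.3; tau_f <- 0.1
  r <- rise_metrics(first_order_rise(tau_r, n_tau = 20), 0)
  f <- fall_metrics(first_order_fall(tau_f, n_tau = 60), 0, 1)
  out <- relaxation_time(r, f)
  expect_equal(out$relaxation_time, ln9 * (tau_r - tau_f),
               tolerance = 0.02 / (ln9 * (tau_r - tau_f)))
})

test_that("timing metrics are scale invariant; amplitudes scale linearly", {
  seg <- first_order_rise(0.3, n_tau = 20, baseline = 1.2, amp = 0.8)
  m1 <- rise_metrics(seg, 1.2)
  seg5 <- dplyr::mutate(seg, q_rpa = 5 * q_rpa)
  m5 <- rise_metrics(seg5, 5 * 1.2)
  expect_equal(m5$rise_time, m1$rise_time, tolerance = 1e-9)
  expect_equal(m5$settling_time, m1$settling_time, tolerance = 1e-9)
  expect_equal(m5$settling_value, 5 * m1$settling_value, tolerance = 1e-9)
  expect_equal(m5$peak_value, 5 * m1$peak_value, tolerance = 1e-9)
  expect_equal(m5$overshoot_pct, m1$overshoot_pct, tolerance = 1e-6)
})

test_that("pulsed summaries are field-wise means", {
  one <- rise_metrics(first_order_rise(0.3, n_tau = 20), 0)
  same <- dplyr::bind_rows(one, one, one)
  expect_equal(pulsed_summary(same), one)

  reltimes <- tibble::tibble(relaxation_time = c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(pulsed_summary(reltimes)$relaxation_time, 0.3)
  expect_equal(pulsed_summary(tibble::tibble(relaxation_time = rep(0.7, 5)))$relaxation_time,
               0.7)
  expect_error(pulsed_summary(reltimes[0, ]),
               class = "fontanjet_empty_input")
})
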
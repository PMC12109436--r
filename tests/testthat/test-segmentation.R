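test_that("a noiseless square injection is detected at the command times", {
  rec <- flat_record(duration = 30, q_rpa = function(t) {
    1.2 + ifelse(t >= 10 & t < 20, 0.6, 0)
  })
  b <- segment_stages(rec, method = "signal_detected")
  expect_equal(b$active[1], 10, tolerance = 0.0101)
  expect_equal(b$active[2], 20, tolerance = 0.0101)
  expect_equal(b$pre, c(0, b$active[1]))
  expect_equal(b$post, c(b$active[2], 30))
})

test_that("command-aligned boundaries are the protocol's own timings", {
  proto <- case_protocol(13)
  rec <- flat_record(duration = 30)
  b <- segment_stages(rec, proto, "command_aligned")
  expect_identical(b$active, c(10, 20))
  # idempotence: the same inputs reproduce the boundaries exactly
  expect_identical(segment_stages(rec, proto, "command_aligned")[c("pre", "active", "post")],
                   b[c("pre", "active", "post")])
  expect_error(segment_stages(rec, NULL, "command_aligned"),
               class = "fontanjet_invalid_protocol")
})

test_that("a flat record raises no-injection-detected", {
  expect_error(segment_stages(flat_record(duration = 10),
                              method = "signal_detected"),
               class = "fontanjet_no_injection_detected")
})

test_that("a too-short baseline is refused", {
  proto <- case_protocol(13, start_time = 0.3)
  expect_error(segment_stages(flat_record(duration = 20), proto,
                              "command_aligned"),
               class = "fontanjet_insufficient_baseline")
})

test_that("five bursts are isolated at their command intervals", {
  proto <- case_protocol(3, injector_time_constant = 0) # 5 x 2 s, 5 s gaps
  sched_on <- 10 + (0:4) * 7
  rec <- flat_record(duration = 50, q_rpa = function(t) {
    on <- rowSums(outer(t, sched_on, function(a, s) a >= s & a < s + 2))
    1.2 + 0.6 * on
  })
  b <- segment_stages(rec, method = "signal_detected")
  b <- segment_bursts(b, rec, n_bursts = 5)
  expect_equal(nrow(b$bursts), 5L)
  expect_equal(b$bursts$injection_start, sched_on, tolerance = 0.021)
  expect_equal(b$bursts$injection_end, sched_on + 2, tolerance = 0.021)
  expect_true(all(b$bursts$window_end[-5] <= b$bursts$window_start[-1] + 1e-9))

  # command-aligned path gives the schedule exactly
  bc <- segment_bursts(segment_stages(rec, proto, "command_aligned"),
                       rec, proto)
  expect_equal(bc$bursts$injection_start, sched_on)
  expect_equal(bc$bursts$injection_end, sched_on + 2)
})

test_that("a continuous run yields one burst window spanning the active stage", {
  proto <- case_protocol(13)
  rec <- flat_record(duration = 30, q_rpa = function(t) {
    1.2 + ifelse(t >= 10 & t < 20, 0.6, 0)
  })
  b <- segment_bursts(segment_stages(rec, proto, "command_aligned"),
                      rec, proto)
  expect_equal(nrow(b$bursts), 1L)
  expect_equal(c(b$bursts$injection_start, b$bursts$injection_end),
               b$active)
  # the shutoff window extends into the post stage for the wind-down
  expect_gt(b$bursts$shutoff_end, b$active[2])
})

test_that("overlapping bursts raise a burst-count mismatch", {
  proto <- injection_protocol(mode = "pulsed", rate = 10, burst_volume = 20,
                              inter_burst_gap = 0,
                              injector_time_constant = 0)
  sched_on <- 10 + (0:4) * 2
  rec <- flat_record(duration = 40, q_rpa = function(t) {
    1.2 + 0.6 * (t >= 10 & t < 20) # five abutting bursts merge
  })
  b <- segment_stages(rec, method = "signal_detected")
  expect_error(segment_bursts(b, rec, n_bursts = 5),
               class = "fontanjet_burst_count_mismatch")
  expect_error(segment_bursts(segment_stages(rec, proto, "command_aligned"),
                              rec, proto),
               class = "fontanjet_burst_count_mismatch")
})

test_that("detected boundaries stay within 3 samples of command times under noise", {
  proto <- case_protocol(9, injector_time_constant = 0) # 0.3 L/min, 10 s
  offsets <- sapply(1:50, function(s) {
    rec <- emulate_mfl(tuned_params(), proto, sensor_model(seed = s),
                       entrainment_emulation(magnitude = 1e-9))
    filt <- filter_record(rec)
    b <- segment_stages(filt, method = "signal_detected")
    c(b$active[1] - 10, b$active[2] - 20)
  })
  expect_lte(max(abs(offsets)), 3 / 100 + 1e-9)
})

test_that("boundaries serialize to JSON with times in seconds", {
  proto <- case_protocol(13)
  rec <- flat_record(duration = 30)
  b <- segment_bursts(segment_stages(rec, proto, "command_aligned"),
                      rec, proto)
  parsed <- jsonlite::fromJSON(boundaries_json(b))
  expect_equal(parsed$active, c(10, 20))
  expect_equal(parsed$bursts$injection_end, 20)
})
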
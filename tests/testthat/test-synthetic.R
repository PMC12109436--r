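test_that("waveform CSV round trip is lossless and order independent", {
  rec <- flat_record(duration = 2, q_rpa = function(t) 1.2 + 0.1 * sin(t))
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(rec, path)
  back <- read_waveform_csv(path)
  expect_equal(record_sampling_rate(back), 100)
  for (ch in c("time_s", "q_rpa", "p_aortic")) {
    expect_equal(back[[ch]], rec[[ch]], tolerance = 1e-12)
  }
  expect_equal(record_metadata(back)$heart_rate, 80)

  # shuffle the channel columns in the file: parsed record is canonical
  lines <- readLines(path)
  hdr_i <- which(!startsWith(lines, "#"))[1]
  cols <- strsplit(lines[hdr_i], ",")[[1]]
  perm <- c(1, sample(2:length(cols)))
  reorder <- function(line) {
    paste(strsplit(line, ",")[[1]][perm], collapse = ",")
  }
  lines[hdr_i:length(lines)] <- vapply(lines[hdr_i:length(lines)],
                                       reorder, character(1))
  writeLines(lines, path)
  shuffled <- read_waveform_csv(path)
  expect_equal(as.data.frame(shuffled), as.data.frame(back),
               tolerance = 1e-12)
})

test_that("defective waveform files are rejected with a format error", {
  rec <- flat_record(duration = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(rec, path)

  # a gap in time
  lines <- readLines(path)
  writeLines(lines[-10], path)
  expect_error(read_waveform_csv(path), class = "fontanjet_format_error")

  # a missing channel column
  df <- as.data.frame(rec)
  expect_error(mfl_record(df[, setdiff(names(df), "q_lpa")], 100),
               class = "fontanjet_format_error")
})

test_that("pure superposition: injection raises the RPA mean by its own rate", {
  quiet <- quiet_sensor()
  # long continuous run so the spool-up lag is negligible in the mean
  proto <- case_protocol(11) # 0.3 L/min over 30 s
  rec <- emulate_mfl(tuned_params(), proto, quiet,
                     entrainment_emulation(magnitude = 1e-9))
  pre <- cycle_average(rec, "q_rpa", c(0, 10))
  act <- cycle_average(rec, "q_rpa", c(10, 40))
  expect_equal(act - pre, proto$rate_lmin, tolerance = 0.01)

  # with zero lag the identity is near exact on any window
  proto0 <- case_protocol(14, injector_time_constant = 0)
  rec0 <- emulate_mfl(tuned_params(), proto0, quiet,
                      entrainment_emulation(magnitude = 1e-9))
  pre0 <- cycle_average(rec0, "q_rpa", c(0, 10))
  act0 <- cycle_average(rec0, "q_rpa", c(10, 25))
  expect_equal(act0 - pre0, proto0$rate_lmin, tolerance = 0.001)
})

test_that("identical seeds give identical records; seeds only move the noise", {
  proto <- case_protocol(12)
  a <- emulate_mfl(tuned_params(), proto, sensor_model(seed = 5))
  b <- emulate_mfl(tuned_params(), proto, sensor_model(seed = 5))
  expect_identical(as.data.frame(a), as.data.frame(b))

  c1 <- emulate_mfl(tuned_params(), proto, quiet_sensor(seed = 1))
  c2 <- emulate_mfl(tuned_params(), proto, quiet_sensor(seed = 99))
  expect_identical(as.matrix(as.data.frame(c1)), as.matrix(as.data.frame(c2)))
  expect_false(identical(as.data.frame(a)$q_rpa,
                         emulate_mfl(tuned_params(), proto,
                                     sensor_model(seed = 6))$q_rpa))
})

test_that("noise statistics match the sensor model", {
  proto <- case_protocol(9)
  sens <- sensor_model(seed = 3, mains_amplitude_frac = 0)
  noisy <- emulate_mfl(tuned_params(), proto, sens, post_margin = 81)
  clean <- emulate_mfl(tuned_params(), proto, quiet_sensor(), post_margin = 81)
  expect_gte(nrow(noisy), 1e4)
  for (ch in c("q_rpa", "q_upper")) {
    expect_equal(sd(noisy[[ch]] - clean[[ch]]), 0.05, tolerance = 0.1)
  }
  expect_equal(sd(noisy$p_aortic - clean$p_aortic), 0.5, tolerance = 0.1)
})

test_that("the noiseless pipeline recovers a programmed entrainment magnitude", {
  proto <- case_protocol(10) # continuous 0.3 L/min, 100 mL
  rec <- emulate_mfl(tuned_params(), proto, quiet_sensor(),
                     entrainment_emulation(magnitude = 0.2))
  filt <- filter_record(rec)
  b <- segment_bursts(segment_stages(filt, proto, "command_aligned"),
                      filt, proto)
  ent <- measure_entrainment(filt, b, proto)
  expect_equal(ent$q_ent, 0.2, tolerance = 0.05)
  expect_identical(ent$label, "entrainment")
})

test_that("sub-Nyquist sampling of the heart rate is refused", {
  expect_error(
    emulate_mfl(tuned_params(), case_protocol(9),
                sensor_model(sampling_rate = 2, mains_amplitude_frac = 0)),
    class = "fontanjet_aliasing_error"
  )
})
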
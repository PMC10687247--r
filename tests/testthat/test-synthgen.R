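test_that("generator parameters are validated", {
  expect_s3_class(generator_params(), "generator_params")
  expect_error(generator_params(breaths_per_minute = 0), "positive")
  expect_error(generator_params(ns_band = c(2000, 1500)), "lo < hi")
  expect_error(generator_params(sample_rate = 16000), "Nyquist")
  expect_error(generator_params(vs_modulation_depth = 1.5), "depth")
})

test_that("degenerate cycle requests are rejected", {
  expect_error(generate_breath_cycle("NS", 0), "positive")
  expect_error(generate_breath_cycle("NS", -1), "positive")
  expect_error(generate_breath_cycle("XX", 1), "unknown class label")
  expect_error(generate_breath_cycle("SS", 3, mixed = TRUE), "VS")
})

test_that("VS cycle has the documented length and ~100 Hz modulation", {
  cyc <- generate_breath_cycle("VS", 3.033, seed = 1)
  expect_identical(length(cyc$signal$samples), 133755L)
  mp <- modulation_peak(cyc)
  expect_true(mp$present)
  expect_gt(mp$peak_hz, 90)
  expect_lt(mp$peak_hz, 110)
})

test_that("SS cycle concentrates energy above 2000 Hz (FFT oracle)", {
  cyc <- generate_breath_cycle("SS", 3.876, seed = 7)
  frac <- oracle_band_energy(cyc$signal$samples, cyc$signal$sample_rate,
                             2000, 22050)
  expect_gte(frac, 0.5)
})

test_that("generation is bit-deterministic under a seed", {
  a <- generate_breath_cycle("NS", 2.5, seed = 11)
  b <- generate_breath_cycle("NS", 2.5, seed = 11)
  expect_identical(a$signal$samples, b$signal$samples)
  ra <- generate_recording(c(NS = 2, VS = 1), seed = 5)
  rb <- generate_recording(c(NS = 2, VS = 1), seed = 5)
  fa <- tempfile(fileext = ".wav"); fb <- tempfile(fileext = ".wav")
  write_wav(ra$signal, fa); write_wav(rb$signal, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
})

test_that("recordings conserve per-class counts and hit the breath rate", {
  rec <- generate_recording(c(NS = 5, VS = 3, SS = 2), seed = 0)
  expect_identical(nrow(rec$labels), 10L)
  expect_identical(as.integer(table(rec$labels$label)[c("NS", "VS", "SS")]),
                   c(5L, 3L, 2L))
  expect_true(all(diff(rec$labels$start_s) > 0))
  expect_true(all(rec$labels$end_s > rec$labels$start_s))
  # 10 cycles at 10.5 breaths/min should take about a minute
  rec10 <- generate_recording(c(NS = 10), seed = 0)
  dur <- duration(rec10$signal)
  rate <- 10 / (dur / 60)
  expect_gte(rate, 9.5)
  expect_lte(rate, 11.5)
  expect_error(generate_recording(c(NS = 0)), "at least one")
})

test_that("add_noise respects band limits and target SNR", {
  cyc <- generate_breath_cycle("NS", 2, seed = 3)
  noisy <- add_noise(cyc$signal, "background", snr_db = 10, seed = 3)
  diffsig <- noisy$samples - cyc$signal$samples
  expect_gte(oracle_band_energy(diffsig, noisy$sample_rate, 0, 1000), 0.95)
  # infinite SNR is the identity
  same <- add_noise(cyc$signal, "event", snr_db = Inf)
  expect_identical(same$samples, cyc$signal$samples)
  # 0 dB: equal energies within 1 dB
  n0 <- add_noise(cyc$signal, "event", snr_db = 0, seed = 3)
  d0 <- n0$samples - cyc$signal$samples
  ratio_db <- 10 * log10(mean(cyc$signal$samples^2) / mean(d0^2))
  expect_lt(abs(ratio_db), 1)
  expect_error(add_noise(audio_signal(numeric(0), 44100), "event", 10),
               "empty")
})

test_that("cycle durations recover the configured class means (n = 500)", {
  p <- generator_params()
  for (lab in c("NS", "VS", "SS")) {
    d <- sample_cycle_durations(lab, 500, p, seed = 123)
    se <- sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d) - p$cycle_mean[[lab]]), 2 * se)
    expect_gte(min(d), p$min_cycle_duration)
  }
})

test_that("mixed VS+SS cycles show both signatures but are labelled VS", {
  mx <- generate_breath_cycle("VS", 3.0, seed = 2, mixed = TRUE)
  expect_identical(mx$true_label, "VS")
  d <- acoustic_descriptors(mx)
  expect_true(detect_vs_pattern(d)$flag)
  expect_true(detect_ss_pattern(d)$flag)
  expect_identical(classify_cycle(d)$label, "VS")
})
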
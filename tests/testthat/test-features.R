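fs <- 44100

test_that("spectrogram localises a pure tone and handles degenerate input", {
  t <- seq(0, 0.5, by = 1 / fs)
  spec <- compute_spectrogram(sin(2 * pi * 1000 * t), sample_rate = fs)
  peaks <- spec$freqs[apply(spec$power, 2, which.max)]
  bin <- diff(spec$freqs[1:2])
  expect_true(all(abs(peaks - 1000) <= bin))
  zero <- compute_spectrogram(rep(0, fs %/% 2), sample_rate = fs)
  expect_true(all(zero$power == 0))
  expect_error(compute_spectrogram(rnorm(100), sample_rate = fs), "window")
  expect_true(all(diff(spec$freqs) > 0))
  expect_equal(max(spec$freqs), fs / 2)
})

test_that("spectrogram energy obeys Parseval against the time domain", {
  set.seed(3)
  x <- rnorm(fs %/% 2)
  spec <- compute_spectrogram(x, sample_rate = fs)
  wl <- round(spec$stft_params$window_s * fs)
  hop <- round(spec$stft_params$hop_s * fs)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(wl) - 1) / (wl - 1))
  direct <- 0
  for (k in seq_len(ncol(spec$power)))
    direct <- direct + sum((x[(k - 1) * hop + seq_len(wl)] * w)^2)
  expect_lt(abs(sum(spec$power) - direct) / direct, 0.01)
})

test_that("doubling the window halves the frequency-bin width", {
  set.seed(4)
  x <- rnorm(fs)
  s1 <- compute_spectrogram(x, window_s = 0.025, sample_rate = fs)
  s2 <- compute_spectrogram(x, window_s = 0.050, sample_rate = fs)
  expect_equal(diff(s1$freqs[1:2]) / diff(s2$freqs[1:2]), 2,
               tolerance = 1e-2)
})

test_that("MFCC dimensionality and the n_coeffs contract", {
  cyc <- generate_breath_cycle("NS", 1.0, seed = 5)
  m20 <- compute_mfcc(cyc, 20)
  m40 <- compute_mfcc(cyc, 40)
  expect_identical(nrow(m20$coeffs), 20L)
  expect_identical(nrow(m40$coeffs), 40L)
  expect_true(all(is.finite(m20$coeffs)))
  expect_error(compute_mfcc(cyc, 13), "20 or 40")
  expect_identical(nrow(compute_mfcc(cyc, 13, allow_any = TRUE)$coeffs), 13L)
})

test_that("scaling a signal shifts only MFCC coefficient 0", {
  cyc <- generate_breath_cycle("VS", 1.0, seed = 6)
  m1 <- compute_mfcc(cyc$signal$samples, 20, sample_rate = fs)
  m10 <- compute_mfcc(10 * cyc$signal$samples, 20, sample_rate = fs)
  d <- m10$coeffs - m1$coeffs
  expect_lt(max(abs(d[-1, ])), 1e-6)
  expect_lt(diff(range(d[1, ])), 1e-6)   # constant shift across frames
  expect_gt(mean(d[1, ]), 0)
})

test_that("MFCC matches the brute-force mel+DCT oracle on random frames", {
  set.seed(7)
  x <- rnorm(fs %/% 4)
  for (nc in c(20L, 40L)) {
    m <- compute_mfcc(x, nc, sample_rate = fs)
    spec_wl <- round(0.025 * fs); hop <- round(0.010 * fs)
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(spec_wl) - 1) / (spec_wl - 1))
    frames <- sample(ncol(m$coeffs), 5)
    for (k in frames) {
      fr <- x[(k - 1) * hop + seq_len(spec_wl)] * w
      expect_lt(max(abs(m$coeffs[, k] - oracle_mfcc_frame(fr, fs, nc))),
                1e-8)
    }
  }
})

test_that("band energy fractions are correct and partition to one", {
  t <- seq(0, 0.5, by = 1 / fs)
  spec <- compute_spectrogram(sin(2 * pi * 1000 * t), sample_rate = fs)
  expect_gte(band_energy_fraction(spec, c(900, 1100)), 0.95)
  expect_lte(band_energy_fraction(spec, c(4000, 8000)), 0.02)
  expect_error(band_energy_fraction(spec, c(1100, 900)), "lo < hi")
  cyc <- generate_breath_cycle("SS", 1.2, seed = 8)
  sp <- compute_spectrogram(cyc)
  edges <- c(0, 500, 1500, 2000, 6000, 12000, fs / 2 + 1)
  parts <- vapply(seq_len(length(edges) - 1), function(i)
    band_energy_fraction(sp, edges[i:(i + 1)]), numeric(1))
  expect_equal(sum(parts), 1, tolerance = 1e-6)
  # against the full-FFT oracle
  expect_lt(abs(band_energy_fraction(sp, c(2000, fs / 2 + 1)) -
                oracle_band_energy(cyc$signal$samples, fs, 2000, fs)), 0.05)
})

test_that("modulation analysis finds forced AM and ignores stationary tones", {
  set.seed(9)
  t <- seq(0, 2, by = 1 / fs)
  carrier <- rnorm(length(t))
  am <- carrier * (0.5 + 0.5 * cos(2 * pi * 100 * t))
  mp <- modulation_peak(am, sample_rate = fs)
  expect_true(mp$present)
  expect_gt(mp$peak_hz, 95); expect_lt(mp$peak_hz, 105)
  tone <- sin(2 * pi * 5000 * t)
  expect_false(modulation_peak(tone, sample_rate = fs)$present)
  expect_error(modulation_peak(rnorm(1000), sample_rate = fs), "0.5 s")
})

test_that("line persistence separates stable tones from noise", {
  t <- seq(0, 1, by = 1 / fs)
  tone <- compute_spectrogram(sin(2 * pi * 5000 * t) + 1e-3 * rnorm(length(t)),
                              sample_rate = fs)
  expect_gte(line_persistence(tone), 0.95)
  # empirical null: seeded white-noise cycles stay below 0.2
  set.seed(10)
  for (i in 1:20) {
    wn <- compute_spectrogram(rnorm(fs %/% 2), sample_rate = fs)
    expect_lte(line_persistence(wn), 0.2)
  }
  expect_error(line_persistence(compute_spectrogram(rnorm(2000),
                                                    sample_rate = fs)),
               "frames")
})

test_that("spectrogram images are normalised and fixed-size", {
  cyc <- generate_breath_cycle("SS", 1.0, seed = 11)
  img <- spectrogram_image(compute_spectrogram(cyc), size = 64)
  expect_identical(dim(img), c(64L, 64L))
  expect_gte(min(img), 0); expect_lte(max(img), 1)
  f <- tempfile(fileext = ".png")
  export_spectrogram_png(compute_spectrogram(cyc), f, size = 64)
  expect_true(file.size(f) > 0)
})
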
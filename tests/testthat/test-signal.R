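test_that("vector magnitude is the per-sample Euclidean norm", {
  rec <- recording_from_axes(c(3, 0), c(4, 0), c(0, 9.81))
  expect_equal(vector_magnitude(rec)$m, c(5, 9.81))
  rec2 <- recording_from_axes(rep(0, 100), rep(0, 100), rep(9.81, 100))
  expect_equal(vector_magnitude(rec2)$m, rep(9.81, 100))
})

test_that("vector magnitude is invariant under joint axis rotation", {
  set.seed(42)
  for (i in 1:20) {
    xyz <- matrix(rnorm(3 * 500), 500, 3)
    R <- random_rotation()
    rot <- xyz %*% t(R)
    m1 <- vector_magnitude(recording_from_axes(xyz[, 1], xyz[, 2], xyz[, 3]))$m
    m2 <- vector_magnitude(recording_from_axes(rot[, 1], rot[, 2], rot[, 3]))$m
    expect_equal(m1, m2, tolerance = 1e-12)
  }
})

test_that("band-pass removes DC and matches the analytic response in and out of band", {
  cfg <- tremor_config()
  dc <- as_filtered_signal(rep(9.81, 2000)); dc$filtered <- FALSE
  out <- bandpass(dc, cfg)
  expect_lt(max(abs(out$m)), 1e-6 * 9.81)

  t <- seq(0, 10 - 1 / 200, by = 1 / 200)
  mid <- 401:1600  # away from edges
  for (f in c(2, 15, 30)) {
    sig <- as_filtered_signal(sin(2 * pi * f * t)); sig$filtered <- FALSE
    y <- bandpass(sig, cfg)$m
    amp <- sqrt(2 * mean(y[mid]^2))
    expect_equal(amp, butter_response2(f), tolerance = 0.05)
    if (f == 15) expect_equal(amp, butter_response2(15), tolerance = 0.02)
  }
})

test_that("band-pass rejects bad configurations and short or re-filtered input", {
  sig <- as_filtered_signal(rnorm(2000)); sig$filtered <- FALSE
  short <- as_filtered_signal(rnorm(10)); short$filtered <- FALSE
  expect_error(bandpass(short), "too short")
  fast <- tremor_config(sampling_rate_hz = 40, band_low_hz = 10, band_high_hz = 19,
                        peak_search_low_hz = 10, peak_search_high_hz = 19)
  slow_sig <- sig; slow_sig$sampling_rate_hz <- 30
  expect_error(bandpass(slow_sig, fast), "Nyquist")
  filtered <- bandpass(sig)
  expect_error(bandpass(filtered), "already filtered")
})

test_that("spectrum satisfies Parseval and concentrates an on-bin sinusoid", {
  set.seed(7)
  for (n in c(2000, 1999, 1024)) {
    x <- rnorm(n)
    spec <- compute_spectrum(as_filtered_signal(x))
    xs <- x - mean(x)
    expect_equal(sum(spec$power[spec$freq_hz > 0]), n * mean(xs^2),
                 tolerance = 1e-6)
  }

  t <- seq(0, 10 - 1 / 200, by = 1 / 200)
  spec <- compute_spectrum(as_filtered_signal(sin(2 * pi * 15 * t)))
  total <- sum(spec$power[spec$freq_hz > 0])
  expect_gte(spec$power[which(spec$freq_hz == 15)] / total, 0.99)

  zero <- compute_spectrum(as_filtered_signal(numeric(512)))
  expect_true(all(zero$power == 0))
})

test_that("spectrum frequency axis runs from 0 to Nyquist at resolution fs/N", {
  spec <- compute_spectrum(as_filtered_signal(rnorm(2000)))
  expect_equal(spec$freq_hz[1], 0)
  expect_equal(max(spec$freq_hz), 100)
  expect_equal(diff(spec$freq_hz[1:2]), 0.1)
  expect_true(all(spec$power >= 0))
})

test_that("peak search stays in band and breaks ties toward the lower frequency", {
  cfg <- tremor_config()
  t <- seq(0, 10 - 1 / 200, by = 1 / 200)
  # strong out-of-band 25 Hz + weak in-band 15 Hz: the in-band peak wins
  sig <- as_filtered_signal(5 * sin(2 * pi * 25 * t) + 0.5 * sin(2 * pi * 15 * t))
  sig$filtered <- FALSE
  pk <- find_peak(compute_spectrum(bandpass(sig, cfg)), cfg)
  expect_equal(pk$peak_frequency_hz, 15)

  # exactly equal maxima at 14 and 16 Hz -> 14 Hz
  spec <- compute_spectrum(as_filtered_signal(
    sin(2 * pi * 14 * t) + sin(2 * pi * 16 * t)))
  i14 <- which(spec$freq_hz == 14); i16 <- which(spec$freq_hz == 16)
  spec$power[i16] <- spec$power[i14]
  expect_equal(find_peak(spec, cfg)$peak_frequency_hz, 14)

  narrow <- compute_spectrum(as_filtered_signal(rnorm(64), fs = 1))
  expect_error(find_peak(narrow, cfg), "no spectral bins")
})

test_that("dominance is the inclusive-window power fraction in [0, 1]", {
  cfg <- tremor_config()
  t <- seq(0, 10 - 1 / 200, by = 1 / 200)
  sig <- as_filtered_signal(9.81 + sin(2 * pi * 15 * t)); sig$filtered <- FALSE
  spec <- compute_spectrum(bandpass(sig, cfg))
  pk <- find_peak(spec, cfg)
  expect_gte(tremor_dominance(spec, pk$peak_frequency_hz, cfg), 0.95)

  # window covering every energetic bin -> exactly 1 (normalization bound)
  wide <- tremor_config(band_low_hz = 1, band_high_hz = 99,
                        peak_search_low_hz = 1, peak_search_high_hz = 99,
                        dominance_window_hz = 97)
  onbin <- compute_spectrum(as_filtered_signal(sin(2 * pi * 50 * t)))
  pkn <- find_peak(onbin, wide)
  expect_equal(pkn$peak_frequency_hz, 50)
  expect_equal(tremor_dominance(onbin, pkn$peak_frequency_hz, wide), 1)

  zero <- compute_spectrum(as_filtered_signal(numeric(2000)))
  expect_warning(d0 <- tremor_dominance(zero, 15, cfg), "degenerate")
  expect_equal(d0, 0)
  expect_error(tremor_dominance(spec, 150, cfg), "outside")
})

test_that("analyze_recording recovers synthetic ground truth per condition", {
  prof <- default_test_profile(freq = 14.31)
  standing <- analyze_recording(
    simulate_recording(prof, recording_label("s", "standing"), seed = 21))
  expect_true(standing$tremor_present)
  expect_lte(abs(standing$peak_frequency_hz - 14.31), 0.1)

  supine <- analyze_recording(
    simulate_recording(prof, recording_label("s", "supine_rest"), seed = 21))
  expect_false(supine$tremor_present)
})

test_that("peak frequency is invariant to amplitude scaling and time shifts", {
  prof <- default_test_profile(freq = 15.31)
  rec <- simulate_recording(prof, recording_label("s", "standing"), seed = 4)
  res <- analyze_recording(rec)

  doubled <- rec
  doubled$x <- 2 * rec$x; doubled$y <- 2 * rec$y; doubled$z <- 2 * rec$z
  expect_equal(analyze_recording(doubled)$peak_frequency_hz, res$peak_frequency_hz)

  shifted <- rec
  shifted$t <- rec$t + 123.4
  expect_equal(analyze_recording(shifted)$peak_frequency_hz, res$peak_frequency_hz)

  set.seed(9)
  Q <- random_rotation()
  xyz <- cbind(rec$x, rec$y, rec$z) %*% t(Q)
  rotated <- accel_recording(rec$t, xyz[, 1], xyz[, 2], xyz[, 3],
                             sampling_rate_hz = rec$sampling_rate_hz)
  expect_equal(analyze_recording(rotated)$peak_frequency_hz, res$peak_frequency_hz)
})
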
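test_that("1/f noise is deterministic, scaled, and zero for scale 0", {
  a <- one_over_f_noise(2000, 200, scale = 0.05, seed = 8)
  b <- one_over_f_noise(2000, 200, scale = 0.05, seed = 8)
  expect_identical(a, b)
  expect_equal(sd(a), 0.05, tolerance = 1e-12)
  expect_equal(mean(a), 0, tolerance = 1e-12)
  expect_identical(one_over_f_noise(512, 200, scale = 0, seed = 1), numeric(512))
  expect_error(one_over_f_noise(8, 200, 1, 1), ">= 16")
})

test_that("ensemble noise spectrum falls as 1/f (log-log slope -1 +/- 0.2)", {
  n <- 2000; fs <- 200
  freqs <- (1:(n / 2)) * fs / n
  keep <- freqs >= 1 & freqs <= 50
  acc <- 0
  for (s in 1:100) {
    x <- one_over_f_noise(n, fs, scale = 1, seed = 1000 + s)
    X <- Mod(fft(x))^2 / n
    acc <- acc + 2 * X[2:(n / 2 + 1)]
  }
  fit <- lm(log(acc[keep] / 100) ~ log(freqs[keep]))
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.2)
})

test_that("simulated recordings are bit-identical under a fixed seed", {
  prof <- default_test_profile()
  lab <- recording_label("s", "standing")
  r1 <- simulate_recording(prof, lab, seed = 77)
  r2 <- simulate_recording(prof, lab, seed = 77)
  expect_identical(r1$x, r2$x)
  expect_identical(r1$y, r2$y)
  expect_identical(r1$z, r2$z)
  r3 <- simulate_recording(prof, lab, seed = 78)
  expect_false(identical(r1$x, r3$x))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_recording(default_test_profile(),
                                            recording_label("s", "standing"),
                                            seed = 5))
  after <- rnorm(1)
  expect_identical(before, after)
})

test_that("tremor activation follows condition and load ground truth", {
  prof <- default_test_profile(threshold = 40)
  below <- analyze_recording(simulate_recording(
    prof, recording_label("s", "leg_press", load_kg = 30), seed = 14))
  at <- analyze_recording(simulate_recording(
    prof, recording_label("s", "leg_press", load_kg = 40), seed = 14))
  expect_false(below$tremor_present)
  expect_true(at$tremor_present)

  seated_pos <- analyze_recording(simulate_recording(
    subject_profile("p7", seated_tremor = TRUE),
    recording_label("p7", "seated_extended"), seed = 15))
  seated_neg <- analyze_recording(simulate_recording(
    subject_profile("p1", seated_tremor = FALSE),
    recording_label("p1", "seated_extended"), seed = 15))
  expect_true(seated_pos$tremor_present)
  expect_false(seated_neg$tremor_present)
})

test_that("profile invariants reject out-of-band frequencies and off-grid thresholds", {
  expect_error(subject_profile("s", tremor_frequency_hz = 12), "13-18")
  expect_error(subject_profile("s", threshold_kg = 35), "multiple of 10")
  expect_error(subject_profile("s", amplitude_gain_per_kg = -1), ">= 0")
  expect_error(scenario_spec(duration_s = 10.0001), "integer sample count")
  expect_error(simulate_recording(default_test_profile(),
                                  recording_label("s", "standing"),
                                  scenario_spec(load_schedule_kg = c(20, 10))),
               "ascending")
})

test_that("load series covers the schedule and supports non-responders", {
  prof <- default_test_profile(threshold = 40)
  sim <- simulate_load_series(prof, seed = 9)
  expect_length(sim$recordings, 10)
  loads <- vapply(sim$recordings, function(r) r$label$load_kg, numeric(1))
  expect_equal(loads, seq(10, 100, 10))
  expect_equal(sim$standing$label$condition, "standing")

  nonresp <- default_test_profile(id = "p5", threshold = NA)
  res <- analyze_load_series(simulate_load_series(nonresp, seed = 10)$recordings)
  expect_true(is.na(res$threshold_kg))
})

test_that("the reference cohort preset mirrors the published phenotype mix", {
  cohort <- simulate_cohort(7, seed = 1, preset = TRUE, simulate = FALSE)
  profiles <- lapply(cohort, `[[`, "profile")
  expect_equal(sum(vapply(profiles, function(p) is.na(p$threshold_kg), logical(1))), 1)
  expect_equal(sum(vapply(profiles, `[[`, logical(1), "seated_tremor")), 1)
  freqs <- vapply(profiles, `[[`, numeric(1), "tremor_frequency_hz")
  expect_true(all(freqs >= 14.24 & freqs <= 16.00))
})

test_that("cohort simulation is seed-reproducible and validates n_subjects", {
  c1 <- simulate_cohort(3, seed = 6, simulate = FALSE)
  c2 <- simulate_cohort(3, seed = 6, simulate = FALSE)
  expect_identical(c1, c2)
  expect_error(simulate_cohort(0, seed = 1), ">= 1")
  expect_error(simulate_cohort(5, seed = 1, preset = TRUE), "7 subjects")

  spec <- scenario_spec(load_schedule_kg = c(10, 20))
  full <- simulate_cohort(2, seed = 4, spec = spec)
  expect_length(full[[1]]$load_series$recordings, 2)
  expect_named(full[[1]]$recordings, c("supine_rest", "standing"))
})

test_that("supine recordings behave as a null: dominance stays below cutoff", {
  prof <- default_test_profile()
  doms <- vapply(1:50, function(s) {
    analyze_recording(simulate_recording(
      prof, recording_label("s", "supine_rest"), seed = 3000 + s))$dominance
  }, numeric(1))
  expect_true(all(doms < 0.5))
})
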
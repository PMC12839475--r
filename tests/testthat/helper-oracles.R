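# Shared oracles and fixture builders, independent of the package internals.

# analytic squared-magnitude response of the zero-phase (forward-backward)
# Butterworth band-pass at frequency f, evaluated from the designed
# coefficients via the transfer function -- never via time-domain filtering
butter_response2 <- function(f, fs = 200, order = 4, low = 10, high = 22) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  z <- exp(1i * 2 * pi * f / fs)
  num <- sum(bf$b * z^(-(seq_along(bf$b) - 1)))
  den <- sum(bf$a * z^(-(seq_along(bf$a) - 1)))
  Mod(num / den)^2
}

# recording whose three axes carry given deterministic series
recording_from_axes <- function(x, y, z, fs = 200, label = NULL) {
  n <- length(x)
  accel_recording((0:(n - 1)) / fs, x, y, z, sampling_rate_hz = fs, label = label)
}

sinusoid_recording <- function(freq, fs = 200, dur = 10, amp = 1, offset = 9.81) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  recording_from_axes(offset + amp * sin(2 * pi * freq * t),
                      numeric(length(t)), numeric(length(t)), fs = fs)
}

# a magnitude_signal carrying an arbitrary series, marked filtered so it can
# be fed straight to compute_spectrum
as_filtered_signal <- function(m, fs = 200) {
  sig <- vector_magnitude(recording_from_axes(abs(m) + 10, numeric(length(m)),
                                              numeric(length(m)), fs = fs))
  sig$m <- m
  sig$filtered <- TRUE
  sig
}

# brute-force Spearman oracle: rho from the classical 6*sum(d^2) formula
# (tie-free inputs only) and the two-sided p by recursive enumeration of all
# n! orderings -- a different algorithm and code path from the package
oracle_spearman <- function(a, b) {
  n <- length(a)
  ra <- rank(a); rb <- rank(b)
  rho_d2 <- function(p) 1 - 6 * sum((ra - rb[p])^2) / (n * (n^2 - 1))
  rho <- rho_d2(seq_len(n))
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  rhos <- vapply(perms(seq_len(n)), rho_d2, numeric(1))
  list(rho = rho, p = mean(abs(rhos) >= abs(rho) - 1e-12))
}

# uniform random 3x3 rotation matrix from a seeded QR decomposition
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

default_test_profile <- function(id = "tsub", freq = 14.31, threshold = 40, ...) {
  subject_profile(id, tremor_frequency_hz = freq, threshold_kg = threshold, ...)
}
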
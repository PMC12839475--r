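#' Acceleration vector magnitude
#'
#' Collapses a triaxial recording to the Euclidean norm
#' m_i = sqrt(x_i^2 + y_i^2 + z_i^2) per sample. The magnitude removes
#' dependence on sensor orientation: it is invariant under any fixed
#' rotation applied jointly to the three axes, so downstream spectral
#' analysis captures overall tremor intensity rather than movement along a
#' particular device axis.
#'
#' @param rec An [accel_recording()].
#' @return An object of class `magnitude_signal`: time stamps `t`, magnitude
#'   series `m` (m/s^2), `sampling_rate_hz`, and a `filtered` flag (`FALSE`).
#' @export
vector_magnitude <- function(rec) {
  stopifnot(inherits(rec, "accel_recording"))
  structure(list(t = rec$t,
                 m = sqrt(rec$x^2 + rec$y^2 + rec$z^2),
                 sampling_rate_hz = rec$sampling_rate_hz,
                 filtered = FALSE),
            class = "magnitude_signal")
}

# steady-state direct-form-II-transposed filter state for a unit step input,
# so a constant signal passes with no start-up transient
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a))); b <- c(b, rep(0, n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  A <- matrix(0, n - 1, n - 1)
  A[1, ] <- -a[-1]
  if (n > 2) A[cbind(2:(n - 1), 1:(n - 2))] <- 1
  solve(diag(n - 1) - t(A), b[-1] - a[-1] * b[1])
}

# IIR filter with initial state: zero-state response plus the zero-input
# response of the state (the latter is the impulse response of zi/a)
lfilter_state <- function(b, a, x, zi) {
  as.numeric(signal::filter(b, a, x)) +
    as.numeric(signal::filter(zi, a, c(1, rep(0, length(x) - 1))))
}

# zero-phase forward-backward filtering with odd-reflection padding and
# steady-state initial conditions; npad is sized from the slowest pole so
# edge transients decay below 1e-10 inside the padding
filtfilt_zi <- function(b, a, x) {
  n <- length(x)
  r <- max(Mod(polyroot(rev(a))))
  npad <- if (r < 1) ceiling(log(1e-10) / log(r)) else 3 * (length(a) - 1)
  npad <- max(npad, 3 * (length(a) - 1))
  npad <- min(npad, n - 1)
  xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  zi <- lfilter_zi(b, a)
  y <- lfilter_state(b, a, xp, zi * xp[1])
  y <- rev(y)
  y <- lfilter_state(b, a, y, zi * y[1])
  rev(y)[(npad + 1):(npad + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies an order-`cfg$filter_order` Butterworth band-pass
#' (`cfg$band_low_hz`--`cfg$band_high_hz`, designed with `signal::butter`)
#' to the magnitude signal, forward and backward so the net filter has zero
#' phase and a squared-magnitude amplitude response. The signal is extended
#' by odd reflection and each pass starts from the steady-state filter
#' state, so the gravity offset produces no start-up transient. The gravity
#' offset and slow postural drift (DC and low frequencies) are removed
#' along with high-frequency sensor noise, leaving the tremor band.
#'
#' @param sig An unfiltered `magnitude_signal`.
#' @param cfg A [tremor_config()].
#' @return The filtered `magnitude_signal` (`filtered = TRUE`, mean ~ 0).
#' @export
bandpass <- function(sig, cfg = tremor_config()) {
  stopifnot(inherits(sig, "magnitude_signal"))
  if (isTRUE(sig$filtered)) stopf("signal is already filtered")
  nyq <- sig$sampling_rate_hz / 2
  if (cfg$band_high_hz >= nyq) {
    stopf("band_high_hz (%g Hz) must be below the Nyquist frequency (%g Hz)",
          cfg$band_high_hz, nyq)
  }
  n <- length(sig$m)
  # filtfilt needs enough samples to absorb edge transients on both passes
  min_n <- 3 * (2 * cfg$filter_order + 1)
  if (n < min_n) stopf("signal too short for stable filtering (%d < %d samples)", n, min_n)
  bf <- signal::butter(cfg$filter_order,
                       c(cfg$band_low_hz, cfg$band_high_hz) / nyq,
                       type = "pass")
  out <- sig
  out$m <- filtfilt_zi(bf$b, bf$a, sig$m)
  out$filtered <- TRUE
  out
}

#' One-sided FFT power spectrum
#'
#' Computes the power spectrum of the mean-removed signal over the full
#' record (rectangular window, no segment averaging), giving a frequency
#' resolution of `sampling_rate / N` -- 0.1 Hz for a 10 s recording, fine
#' enough to resolve the 0.6 Hz dominance window. The normalization is
#' chosen so Parseval's identity holds: the sum of non-DC one-sided power
#' equals N times the mean squared deviation of the signal.
#'
#' @param sig A filtered `magnitude_signal`.
#' @return An object of class `power_spectrum`: ascending `freq_hz` from 0
#'   to the Nyquist frequency and non-negative `power` of equal length.
#' @export
compute_spectrum <- function(sig) {
  stopifnot(inherits(sig, "magnitude_signal"))
  if (!isTRUE(sig$filtered)) stopf("compute_spectrum expects a filtered signal")
  x <- sig$m - mean(sig$m)
  n <- length(x)
  X <- stats::fft(x)
  half <- floor(n / 2)
  k <- 0:half
  p <- Mod(X[k + 1])^2 / n
  # one-sided doubling for interior bins (not DC; not Nyquist when n is even)
  interior <- k >= 1 & !(n %% 2 == 0 & k == half)
  p[interior] <- 2 * p[interior]
  structure(list(freq_hz = k * sig$sampling_rate_hz / n,
                 power = p,
                 n = n),
            class = "power_spectrum")
}

#' Locate the tremor peak in the search band
#'
#' Returns the frequency and power of the maximum-power bin whose frequency
#' lies in `[peak_search_low_hz, peak_search_high_hz]`. Ties break toward
#' the lower frequency (deterministic).
#'
#' @param spec A `power_spectrum`.
#' @param cfg A [tremor_config()].
#' @return A list with `peak_frequency_hz` and `peak_height`.
#' @export
find_peak <- function(spec, cfg = tremor_config()) {
  stopifnot(inherits(spec, "power_spectrum"))
  in_band <- which(spec$freq_hz >= cfg$peak_search_low_hz &
                   spec$freq_hz <= cfg$peak_search_high_hz)
  if (!length(in_band)) stopf("peak search band contains no spectral bins")
  i <- in_band[which.max(spec$power[in_band])]  # which.max: first max -> lowest f
  list(peak_frequency_hz = spec$freq_hz[i], peak_height = spec$power[i])
}

#' Tremor dominance (normalized peak power)
#'
#' The fraction of total signal power concentrated in a window of width
#' `cfg$dominance_window_hz` centred on the identified peak frequency:
#' power summed over bins with |f - f_peak| <= window/2 (endpoints
#' inclusive), divided by the total non-DC one-sided power of the filtered
#' signal. Values near 1 indicate a clearly detectable tremor whose peak
#' accounts for most of the signal energy; values near 0 indicate the peak
#' is part of the background noise.
#'
#' @param spec A `power_spectrum`.
#' @param peak_frequency_hz Peak frequency from [find_peak()].
#' @param cfg A [tremor_config()].
#' @return Dominance in \[0, 1\]. A spectrum with zero total power returns 0
#'   with a warning (degenerate recording).
#' @export
tremor_dominance <- function(spec, peak_frequency_hz, cfg = tremor_config()) {
  stopifnot(inherits(spec, "power_spectrum"))
  if (peak_frequency_hz < spec$freq_hz[1] ||
      peak_frequency_hz > spec$freq_hz[length(spec$freq_hz)]) {
    stopf("peak frequency %g Hz lies outside the spectrum range", peak_frequency_hz)
  }
  non_dc <- spec$freq_hz > 0
  total <- sum(spec$power[non_dc])
  if (total == 0) {
    warning("degenerate recording: total spectral power is zero", call. = FALSE)
    return(0)
  }
  half_w <- cfg$dominance_window_hz / 2
  # tolerance keeps grid endpoints (e.g. +/-0.3 Hz on a 0.1 Hz grid) inclusive
  tol <- 1e-9 * spec$freq_hz[length(spec$freq_hz)]
  in_win <- non_dc & abs(spec$freq_hz - peak_frequency_hz) <= half_w + tol
  min(sum(spec$power[in_win]) / total, 1)
}

#' Full spectral tremor characterization of one recording
#'
#' Composes the pipeline: vector magnitude, zero-phase band-pass, one-sided
#' FFT power spectrum, in-band peak search, and the dominance ratio. The
#' recording is called tremor-positive when dominance >= the configured
#' cutoff.
#'
#' @param rec An [accel_recording()].
#' @param cfg A [tremor_config()].
#' @return An object of class `tremor_peak` with fields
#'   `peak_frequency_hz`, `peak_height`, `dominance`, `tremor_present`,
#'   `label`, and the `config` used.
#' @examples
#' prof <- subject_profile("s1", tremor_frequency_hz = 14.31)
#' rec <- simulate_recording(prof, recording_label("s1", "standing"), seed = 1)
#' analyze_recording(rec)
#' @export
analyze_recording <- function(rec, cfg = tremor_config()) {
  spec <- compute_spectrum(bandpass(vector_magnitude(rec), cfg))
  pk <- find_peak(spec, cfg)
  dom <- tremor_dominance(spec, pk$peak_frequency_hz, cfg)
  structure(list(peak_frequency_hz = pk$peak_frequency_hz,
                 peak_height = pk$peak_height,
                 dominance = dom,
                 tremor_present = dom >= cfg$dominance_cutoff,
                 label = rec$label,
                 config = cfg),
            class = "tremor_peak")
}

#' @export
print.tremor_peak <- function(x, ...) {
  cat("Tremor characterization\n")
  if (!is.null(x$label)) cat("  recording:", format(x$label), "\n")
  cat(sprintf("  peak: %.2f Hz (height %.4g)\n", x$peak_frequency_hz, x$peak_height))
  cat(sprintf("  dominance: %.3f -> tremor %s\n", x$dominance,
              if (x$tremor_present) "PRESENT" else "absent"))
  invisible(x)
}

#' @export
plot.power_spectrum <- function(x, ..., xlim = c(0, 30)) {
  graphics::plot(x$freq_hz, x$power, type = "h", xlim = xlim,
                 xlab = "Frequency (Hz)", ylab = "Power", ...)
  invisible(x)
}
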
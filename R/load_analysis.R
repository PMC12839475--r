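#' Detect the load threshold of a tremor response
#'
#' The load threshold is the smallest load at which tremor is consistently
#' elicited: the smallest scheduled load whose dominance reaches the
#' configured cutoff at that step AND at every subsequent (heavier) step.
#' A single isolated exceedance that is not sustained at higher loads does
#' not set the threshold. Returns `NA` when no such load exists (a
#' non-responder across the tested range).
#'
#' @param steps A data.frame of per-load results, ascending in `load_kg`,
#'   with columns `load_kg` and `dominance` (as produced by
#'   [analyze_load_series()]).
#' @param cfg A [tremor_config()] supplying `dominance_cutoff`.
#' @return The threshold load in kg, or `NA_real_` if tremor is never
#'   consistently elicited.
#' @export
detect_load_threshold <- function(steps, cfg = tremor_config()) {
  if (!is.data.frame(steps) || !nrow(steps)) stopf("steps must be a non-empty data.frame")
  if (is.unsorted(steps$load_kg, strictly = TRUE)) {
    stopf("steps must be strictly ascending in load_kg")
  }
  ok <- steps$dominance >= cfg$dominance_cutoff
  sustained <- rev(cumprod(rev(ok))) == 1  # TRUE where ok holds here and at all heavier loads
  j <- which(sustained)[1]
  if (is.na(j)) NA_real_ else steps$load_kg[j]
}

#' Frequency stability of supra-threshold tremor
#'
#' Once tremor is elicited by sufficient load, its frequency is expected to
#' stay close to the subject's standing tremor frequency. This check returns
#' `TRUE` iff every step at or above the threshold has a peak frequency
#' within `cfg$stability_tolerance_hz` of the standing frequency.
#'
#' @param steps Per-load results data.frame (see [detect_load_threshold()]),
#'   with columns `load_kg` and `peak_frequency_hz`.
#' @param standing_frequency_hz The subject's standing tremor peak frequency.
#' @param threshold_kg The detected load threshold (must be present).
#' @param cfg A [tremor_config()].
#' @return Logical.
#' @export
frequency_stability <- function(steps, standing_frequency_hz, threshold_kg,
                                cfg = tremor_config()) {
  if (is.na(threshold_kg)) stopf("frequency_stability requires a detected threshold")
  supra <- steps$load_kg >= threshold_kg
  if (!any(supra)) stopf("no steps at or above the threshold load")
  all(abs(steps$peak_frequency_hz[supra] - standing_frequency_hz) <=
        cfg$stability_tolerance_hz)
}

#' Amplitude modulation of tremor by load
#'
#' Spearman rank correlation (average ranks for ties) between load and
#' spectral peak height over the steps at or above the threshold. A positive
#' value indicates that tremor amplitude grows with muscle load. With fewer
#' than three supra-threshold steps the trend is not identifiable and
#' `NA_real_` is returned (an insufficient-data marker, not an error).
#'
#' @param steps Per-load results data.frame with columns `load_kg` and
#'   `peak_height`.
#' @param threshold_kg The detected load threshold.
#' @return Spearman rho in \[-1, 1\], or `NA_real_`.
#' @export
amplitude_trend <- function(steps, threshold_kg) {
  if (is.na(threshold_kg)) return(NA_real_)
  supra <- steps[steps$load_kg >= threshold_kg, , drop = FALSE]
  if (nrow(supra) < 3) return(NA_real_)
  spearman_correlation(supra$load_kg, supra$peak_height)$rho
}

# all permutations of 1..n as an (n! x n) matrix; n <= 8 keeps this small
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1), n, after = pos - 1), drop = FALSE]
    out[row + seq_len(nrow(sub)), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Spearman rank correlation with exact small-sample permutation p-value
#'
#' rho is the product-moment correlation of average ranks. The two-sided
#' p-value is computed from the exact permutation distribution of rho
#' (all n! orderings of one vector) when `exact` -- by default for n <= 8 --
#' and from the large-sample t approximation otherwise.
#'
#' @param a,b Equal-length numeric vectors, n >= 3.
#' @param exact Force or forbid exact enumeration; default `NULL` chooses
#'   exact for n <= 8.
#' @return A list with `rho`, `p_two_sided`, `n`, and `method`. A constant
#'   input vector yields `rho = NA` (undefined) with a warning.
#' @examples
#' spearman_correlation(c(1, 2, 3, 4), c(10, 20, 30, 40))  # rho 1, p 2/24
#' @export
spearman_correlation <- function(a, b, exact = NULL) {
  n <- length(a)
  if (length(b) != n) stopf("a and b must have equal length")
  if (n < 3) stopf("need at least 3 observations")
  if (anyNA(a) || anyNA(b)) stopf("missing values are not supported")
  ra <- rank(a); rb <- rank(b)
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) {
    warning("constant input: Spearman rho is undefined", call. = FALSE)
    return(list(rho = NA_real_, p_two_sided = NA_real_, n = n, method = "undefined"))
  }
  rho <- stats::cor(ra, rb)
  if (is.null(exact)) exact <- n <= 8
  if (exact) {
    perms <- all_permutations(n)
    rho_perm <- apply(perms, 1, function(p) stats::cor(ra, rb[p]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_two_sided = p, n = n, method = method)
}

#' Characterize a subject's tremor response across a load ladder
#'
#' Runs [analyze_recording()] on every leg-press recording, orders the
#' results by ascending load, and summarizes the load response: the load
#' threshold beyond which tremor is consistently elicited, whether the
#' supra-threshold tremor frequency stays close to the standing frequency,
#' and the rank correlation of peak height with load (amplitude
#' modulation).
#'
#' @param recordings List of leg-press [accel_recording()]s, one per load
#'   (labels must carry `load_kg`).
#' @param standing Optional standing [accel_recording()] for the same
#'   subject; its peak frequency becomes the stability reference.
#' @param cfg A [tremor_config()].
#' @return An object of class `tremor_load_series` with `subject_id`, the
#'   per-step results data.frame `steps`, `threshold_kg`,
#'   `standing_frequency_hz`, `stable_frequency`, and
#'   `amplitude_trend_rho` (each `NA` when not determinable).
#' @export
analyze_load_series <- function(recordings, standing = NULL, cfg = tremor_config()) {
  if (!length(recordings)) stopf("recordings must be non-empty")
  loads <- vapply(recordings, function(r) {
    if (is.null(r$label) || r$label$condition != "leg_press") {
      stopf("every recording in a load series must be labeled leg_press with a load")
    }
    r$label$load_kg
  }, numeric(1))
  ord <- order(loads)
  if (anyDuplicated(loads)) stopf("duplicate loads in series")
  recordings <- recordings[ord]
  results <- lapply(recordings, analyze_recording, cfg = cfg)
  steps <- data.frame(
    load_kg = loads[ord],
    peak_frequency_hz = vapply(results, `[[`, numeric(1), "peak_frequency_hz"),
    peak_height = vapply(results, `[[`, numeric(1), "peak_height"),
    dominance = vapply(results, `[[`, numeric(1), "dominance"),
    tremor_present = vapply(results, `[[`, logical(1), "tremor_present")
  )
  subject_id <- recordings[[1]]$label$subject_id

  threshold <- detect_load_threshold(steps, cfg)
  standing_f <- NA_real_
  stable <- NA
  if (!is.null(standing)) {
    standing_f <- analyze_recording(standing, cfg)$peak_frequency_hz
  }
  if (!is.na(threshold) && !is.na(standing_f)) {
    stable <- frequency_stability(steps, standing_f, threshold, cfg)
  }
  rho <- amplitude_trend(steps, threshold)
  structure(list(subject_id = subject_id, steps = steps,
                 threshold_kg = threshold,
                 standing_frequency_hz = standing_f,
                 stable_frequency = stable,
                 amplitude_trend_rho = rho,
                 config = cfg),
            class = "tremor_load_series")
}

#' @export
print.tremor_load_series <- function(x, ...) {
  cat(sprintf("Load-series tremor analysis: subject %s, %d load steps\n",
              x$subject_id, nrow(x$steps)))
  cat(sprintf("  load threshold: %s\n",
              if (is.na(x$threshold_kg)) "none detected (non-responder over tested range)"
              else sprintf("%g kg", x$threshold_kg)))
  if (!is.na(x$standing_frequency_hz)) {
    cat(sprintf("  standing frequency: %.2f Hz; supra-threshold frequency stable: %s\n",
                x$standing_frequency_hz,
                if (is.na(x$stable_frequency)) "n/a" else x$stable_frequency))
  }
  cat(sprintf("  amplitude trend (Spearman rho, height vs load): %s\n",
              if (is.na(x$amplitude_trend_rho)) "n/a" else sprintf("%.2f", x$amplitude_trend_rho)))
  invisible(x)
}

#' @export
summary.tremor_load_series <- function(object, ...) {
  print(object)
  cat("\nPer-load results:\n")
  print(object$steps, row.names = FALSE)
  invisible(object)
}

#' @export
plot.tremor_load_series <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  shade <- gray(1 - pmin(x$steps$dominance, 1))
  graphics::plot(x$steps$load_kg, x$steps$peak_frequency_hz, pch = 19, col = shade,
                 xlab = "Load (kg)", ylab = "Peak frequency (Hz)", ...)
  if (!is.na(x$standing_frequency_hz)) {
    graphics::abline(h = x$standing_frequency_hz, col = "red", lty = 2)
  }
  if (!is.na(x$threshold_kg)) graphics::abline(v = x$threshold_kg, col = "blue", lty = 3)
  graphics::plot(x$steps$load_kg, x$steps$peak_height, type = "b", pch = 19,
                 xlab = "Load (kg)", ylab = "Peak height")
  if (!is.na(x$threshold_kg)) graphics::abline(v = x$threshold_kg, col = "blue", lty = 3)
  invisible(x)
}
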
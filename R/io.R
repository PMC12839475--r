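#' Recording labels
#'
#' A label ties a recording to a subject, a measurement condition from the
#' study protocol (supine rest, supine with one leg lifted, seated with an
#' extended knee, standing, or seated in the leg press), the leg measured,
#' and -- for leg-press recordings only -- the applied load in kg.
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param condition One of `"supine_rest"`, `"supine_leg_lifted"`,
#'   `"seated_extended"`, `"standing"`, `"leg_press"`.
#' @param load_kg Applied load in kg; required if and only if
#'   `condition == "leg_press"`.
#' @param side `"left"` or `"right"` (default `"left"`; the load protocol
#'   measures the left leg).
#' @return An object of class `recording_label`.
#' @export
recording_label <- function(subject_id, condition, load_kg = NULL, side = "left") {
  conditions <- c("supine_rest", "supine_leg_lifted", "seated_extended",
                  "standing", "leg_press")
  condition <- match.arg(condition, conditions)
  side <- match.arg(side, c("left", "right"))
  if (condition == "leg_press") {
    if (is.null(load_kg) || is.na(load_kg)) {
      stopf("leg_press recordings require load_kg")
    }
    if (load_kg < 0) stopf("load_kg must be non-negative")
  } else if (!is.null(load_kg) && !is.na(load_kg)) {
    stopf("load_kg is only meaningful for condition 'leg_press'")
  }
  structure(list(subject_id = as.character(subject_id),
                 condition = condition,
                 load_kg = if (condition == "leg_press") as.numeric(load_kg) else NA_real_,
                 side = side),
            class = "recording_label")
}

#' @export
format.recording_label <- function(x, ...) {
  lab <- sprintf("%s/%s/%s", x$subject_id, x$condition, x$side)
  if (!is.na(x$load_kg)) lab <- sprintf("%s @ %g kg", lab, x$load_kg)
  lab
}

#' @export
print.recording_label <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Construct a triaxial accelerometer recording
#'
#' The raw unit of measurement: four equal-length series (time in seconds
#' and x/y/z acceleration in m/s^2) with strictly increasing, approximately
#' uniform time stamps, plus the sampling rate and an optional label.
#'
#' @param t Time stamps in seconds (strictly increasing, length >= 2).
#' @param x,y,z Acceleration components in m/s^2, same length as `t`.
#' @param sampling_rate_hz Sampling rate in Hz; if `NULL`, inferred as the
#'   reciprocal of the median time step.
#' @param label Optional [recording_label()].
#' @return An object of class `accel_recording`.
#' @export
accel_recording <- function(t, x, y, z, sampling_rate_hz = NULL, label = NULL) {
  n <- length(t)
  if (n < 2) stopf("a recording needs at least 2 samples")
  if (length(x) != n || length(y) != n || length(z) != n) {
    stopf("t, x, y, z must have equal length")
  }
  dt <- diff(t)
  if (any(dt <= 0)) stopf("time stamps must be strictly increasing")
  if (is.null(sampling_rate_hz)) sampling_rate_hz <- 1 / stats::median(dt)
  if (!is.null(label) && !inherits(label, "recording_label")) {
    stopf("label must be a recording_label")
  }
  structure(list(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                 z = as.numeric(z),
                 sampling_rate_hz = as.numeric(sampling_rate_hz),
                 label = label),
            class = "accel_recording")
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("Triaxial accelerometer recording: %d samples, %.6g Hz, %.3g s\n",
              length(x$t), x$sampling_rate_hz, x$t[length(x$t)] - x$t[1]))
  if (!is.null(x$label)) cat("  label:", format(x$label), "\n")
  invisible(x)
}

meta_path <- function(path) sub("\\.csv$", ".meta.json", path, ignore.case = TRUE)

#' Read a triaxial recording from CSV
#'
#' Expects a comma-separated file with header `t,x,y,z`: time in seconds and
#' acceleration in m/s^2. The sampling rate is inferred from the reciprocal
#' median time step; if `cfg` is supplied and the inferred rate differs from
#' the configured one by more than 1%, a warning is emitted and the
#' configured rate is used. Label fields are read from a JSON sidecar
#' (`<basename>.meta.json`) when present.
#'
#' @param path Path to the CSV file.
#' @param cfg Optional [tremor_config()] supplying the nominal sampling rate.
#' @return An [accel_recording()].
#' @export
read_recording <- function(path, cfg = NULL) {
  if (!file.exists(path)) stopf("recording file not found: %s", path)
  df <- utils::read.csv(path, comment.char = "#")
  names(df) <- tolower(names(df))
  if ("time" %in% names(df) && !("t" %in% names(df))) names(df)[names(df) == "time"] <- "t"
  missing <- setdiff(c("t", "x", "y", "z"), names(df))
  if (length(missing)) {
    stopf("recording %s is missing column(s): %s", path, paste(missing, collapse = ", "))
  }
  if (nrow(df) < 2) stopf("recording %s has fewer than 2 samples", path)
  if (!all(vapply(df[c("t", "x", "y", "z")], is.numeric, logical(1)))) {
    stopf("recording %s has non-numeric data", path)
  }
  if (any(diff(df$t) <= 0)) stopf("recording %s has non-monotone time stamps", path)

  label <- NULL
  mp <- meta_path(path)
  if (file.exists(mp)) {
    meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
    load_kg <- meta$load_kg
    if (!is.numeric(load_kg)) load_kg <- NULL
    label <- recording_label(meta$subject_id %||% "unknown",
                             meta$condition %||% "standing",
                             load_kg = load_kg,
                             side = meta$side %||% "left")
  }

  rate <- 1 / stats::median(diff(df$t))
  if (!is.null(cfg)) {
    if (abs(rate - cfg$sampling_rate_hz) / cfg$sampling_rate_hz > 0.01) {
      warning(sprintf(
        "inferred sampling rate %.4g Hz differs from configured %.4g Hz by >1%%; using configured value",
        rate, cfg$sampling_rate_hz), call. = FALSE)
      rate <- cfg$sampling_rate_hz
    }
  }
  accel_recording(df$t, df$x, df$y, df$z, sampling_rate_hz = rate, label = label)
}

#' Write a triaxial recording to CSV (with a JSON label sidecar)
#'
#' Samples are written at full double precision so that
#' `read_recording(write_recording(rec))` round-trips exactly. When the
#' recording carries a label, it is stored in `<basename>.meta.json`.
#'
#' @param rec An [accel_recording()].
#' @param path Destination CSV path.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "accel_recording"))
  df <- data.frame(t = rec$t, x = rec$x, y = rec$y, z = rec$z)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  if (!is.null(rec$label)) {
    lab <- rec$label
    meta <- list(subject_id = lab$subject_id, condition = lab$condition,
                 load_kg = if (is.na(lab$load_kg)) NULL else lab$load_kg,
                 side = lab$side)
    jsonlite::write_json(Filter(Negate(is.null), meta),
                         meta_path(path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

label_to_list <- function(label) {
  if (is.null(label)) return(NULL)
  list(subject_id = label$subject_id, condition = label$condition,
       load_kg = if (is.na(label$load_kg)) NULL else label$load_kg,
       side = label$side)
}

#' Write an analysis report as JSON
#'
#' Serializes one or more per-recording results ([analyze_recording()]
#' output) and/or load-series results ([analyze_load_series()] output) to a
#' JSON document, always embedding the full analysis configuration for
#' auditability. A load series with no detected threshold writes an explicit
#' `null` for `threshold_kg` rather than omitting the field.
#'
#' @param results A single result or a list of `tremor_peak` /
#'   `tremor_load_series` objects.
#' @param path Destination path for the JSON report.
#' @param cfg The [tremor_config()] used to produce the results.
#' @return Invisibly, `path`.
#' @export
write_report <- function(results, path, cfg = tremor_config()) {
  if (inherits(results, c("tremor_peak", "tremor_load_series"))) {
    results <- list(results)
  }
  if (!length(results)) stopf("results must be non-empty")

  ser_peak <- function(r) {
    list(type = "recording",
         label = label_to_list(r$label),
         peak_frequency_hz = r$peak_frequency_hz,
         peak_height = r$peak_height,
         dominance = r$dominance,
         tremor_present = r$tremor_present)
  }
  ser_series <- function(r) {
    list(type = "load_series",
         subject_id = r$subject_id,
         steps = lapply(seq_len(nrow(r$steps)), function(i) {
           s <- r$steps[i, ]
           list(load_kg = s$load_kg, peak_frequency_hz = s$peak_frequency_hz,
                peak_height = s$peak_height, dominance = s$dominance,
                tremor_present = s$tremor_present)
         }),
         threshold_kg = if (is.na(r$threshold_kg)) NA else r$threshold_kg,
         standing_frequency_hz = if (is.na(r$standing_frequency_hz)) NA else r$standing_frequency_hz,
         stable_frequency = if (is.na(r$stable_frequency)) NA else r$stable_frequency,
         amplitude_trend_rho = if (is.na(r$amplitude_trend_rho)) NA else r$amplitude_trend_rho)
  }
  entries <- lapply(results, function(r) {
    if (inherits(r, "tremor_peak")) ser_peak(r)
    else if (inherits(r, "tremor_load_series")) ser_series(r)
    else stopf("unsupported result class: %s", paste(class(r), collapse = "/"))
  })
  doc <- list(config = unclass(cfg), results = entries)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

#' Read a cohort table
#'
#' Tab-separated, one row per patient, with columns `patient`, `age_years`,
#' `sex`, `weight_kg`, `duration_years`, `tremor_frequency_hz`,
#' `medication`. A present tremor frequency must lie in the 13--18 Hz band
#' that defines high-frequency orthostatic tremor.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with one row per patient.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stopf("cohort table not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("patient", "age_years", "sex", "weight_kg", "duration_years",
                "tremor_frequency_hz", "medication")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stopf("cohort table is missing column(s): %s", paste(missing, collapse = ", "))
  }
  f <- df$tremor_frequency_hz
  bad <- !is.na(f) & (f < 13 | f > 18)
  if (any(bad)) {
    stopf("tremor_frequency_hz outside the 13-18 Hz band for patient(s): %s",
          paste(df$patient[bad], collapse = ", "))
  }
  if (!all(df$sex %in% c("M", "F"))) stopf("sex must be 'M' or 'F'")
  df
}
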
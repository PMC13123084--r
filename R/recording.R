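#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

#' Names of the 13 raw sensor channels
#'
#' The collar device records tri-axial acceleration, tri-axial gravity,
#' tri-axial rotation rate (gyroscope) and a 4-component attitude
#' quaternion, giving 13 numeric channels per sample.
#'
#' @return Character vector of length 13.
#' @export
imu_channels <- function() {
  c(
    "acc_x", "acc_y", "acc_z",
    "grav_x", "grav_y", "grav_z",
    "rot_x", "rot_y", "rot_z",
    "att_x", "att_y", "att_z", "att_w"
  )
}

#' The token used for samples without a behaviour label
#'
#' Unlabelled samples are carried through I/O unchanged, terminate bouts,
#' and are dropped from feature sets when a window ends on one.
#'
#' @return A length-1 character string.
#' @export
unlabelled_label <- function() "unlabelled"

#' Construct a labelled IMU recording
#'
#' A recording is a tibble with one row per sample holding the 13 sensor
#' channels, a behaviour `label`, and a `subject_id`; the sampling rate is
#' stored in the `sample_rate_hz` attribute. Sample index is implicit,
#' contiguous and 0-based.
#'
#' @param samples Data frame with the 13 channel columns (see
#'   [imu_channels()]) and optionally `label` and `subject_id` columns.
#' @param subject_id Subject identifier; overrides any `subject_id` column.
#' @param sample_rate_hz Sampling rate in Hz (default 50).
#' @param check_quaternion If `TRUE`, warn when attitude quaternions deviate
#'   from unit norm by more than `1e-3` (simulator output always satisfies
#'   this; imported data may not).
#'
#' @return A tibble of class `imu_recording`.
#' @export
imu_recording <- function(samples, subject_id = NULL, sample_rate_hz = 50,
                          check_quaternion = FALSE) {
  samples <- tibble::as_tibble(samples)
  missing_ch <- setdiff(imu_channels(), names(samples))
  if (length(missing_ch) > 0) {
    stop("recording is missing required channel column(s): ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  for (ch in imu_channels()) {
    if (!is.numeric(samples[[ch]])) {
      stop("channel '", ch, "' is not numeric", call. = FALSE)
    }
  }
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      sample_rate_hz <= 0) {
    stop("sample_rate_hz must be a single positive number", call. = FALSE)
  }
  if (is.null(subject_id)) {
    subject_id <- if ("subject_id" %in% names(samples)) {
      as.character(samples$subject_id[1])
    } else {
      "subject1"
    }
  }
  if (!"label" %in% names(samples)) {
    samples$label <- rep(unlabelled_label(), nrow(samples))
  }
  samples$label <- as.character(samples$label)
  samples$label[is.na(samples$label) | samples$label == ""] <- unlabelled_label()
  samples$subject_id <- as.character(subject_id)
  samples <- samples[, c(imu_channels(), "label", "subject_id")]

  if (check_quaternion && nrow(samples) > 0) {
    qn <- samples$att_x^2 + samples$att_y^2 + samples$att_z^2 + samples$att_w^2
    bad <- sum(abs(qn - 1) >= 1e-3)
    if (bad > 0) {
      warning(bad, " sample(s) have attitude quaternions off unit norm by >= 1e-3",
              call. = FALSE)
    }
  }

  structure(samples,
            sample_rate_hz = sample_rate_hz,
            class = c("imu_recording", class(tibble::tibble())))
}

#' Sampling rate of a recording
#'
#' @param rec An `imu_recording` (or any tibble carrying a
#'   `sample_rate_hz` attribute).
#' @return Sampling rate in Hz; defaults to 50 when no attribute is present.
#' @export
sample_rate <- function(rec) {
  sr <- attr(rec, "sample_rate_hz")
  if (is.null(sr)) 50 else sr
}

#' Convert a duration in samples to seconds
#'
#' Bout statistics and window sizes are reported in sample units; at the
#' default 50 Hz rate one sample unit is 20 ms, so e.g. a 300-sample window
#' is 6 s.
#'
#' @param samples Numeric vector of durations in sample units.
#' @param sample_rate_hz Sampling rate in Hz (default 50).
#' @return Durations in seconds.
#' @examples
#' samples_to_seconds(300) # 6
#' @export
samples_to_seconds <- function(samples, sample_rate_hz = 50) {
  samples / sample_rate_hz
}

#' Read a labelled recording from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row containing the 13
#' channel columns plus `label` and `subject_id` (and optionally a repeated
#' `sample_rate_hz` column, collapsed to the recording attribute on read).
#' Missing or empty label cells become the unlabelled token. Row order is
#' preserved.
#'
#' @param path Path to the CSV file.
#' @param sample_rate_hz Fallback sampling rate when the file carries none.
#' @return An [imu_recording()].
#' @export
read_recording <- function(path, sample_rate_hz = 50) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = character())
  missing_ch <- setdiff(imu_channels(), names(raw))
  if (length(missing_ch) > 0) {
    stop("CSV is missing required column(s): ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  for (ch in imu_channels()) {
    v <- suppressWarnings(as.numeric(raw[[ch]]))
    bad <- which(is.na(v) & !(raw[[ch]] %in% c("NA", "")))
    if (length(bad) > 0) {
      stop("non-numeric value in channel '", ch, "' at data row ", bad[1],
           ": '", raw[[ch]][bad[1]], "'", call. = FALSE)
    }
    raw[[ch]] <- v
  }
  sr <- sample_rate_hz
  if ("sample_rate_hz" %in% names(raw) && nrow(raw) > 0) {
    sr <- as.numeric(raw$sample_rate_hz[1])
  }
  subject <- if ("subject_id" %in% names(raw) && nrow(raw) > 0) {
    raw$subject_id[1]
  } else {
    NULL
  }
  imu_recording(raw[, intersect(c(imu_channels(), "label", "subject_id"),
                                names(raw))],
                subject_id = subject, sample_rate_hz = sr)
}

#' Write a labelled recording to CSV
#'
#' Columns are written in a fixed, documented order: the 13 channels of
#' [imu_channels()], then `label`, `subject_id` and `sample_rate_hz`
#' (repeated per row so one file is self-describing). The file round-trips
#' through [read_recording()]: channels to 12 significant digits, labels
#' exactly.
#'
#' @param rec An [imu_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  out <- tibble::as_tibble(rec)[, c(imu_channels(), "label", "subject_id")]
  out$sample_rate_hz <- rep(sample_rate(rec), nrow(out))
  for (ch in imu_channels()) {
    out[[ch]] <- formatC(out[[ch]], digits = 12, format = "g")
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write recording to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}
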
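#' Run-length-encode a label track into behavioural bouts
#'
#' A bout is a maximal run of identical behaviour labels: a homogeneous,
#' uninterrupted stretch of one behaviour from its start to its finish.
#' Runs of the unlabelled token are excluded from the result but still
#' terminate adjacent bouts (an uncoded gap breaks a bout; it is never
#' bridged).
#'
#' @param x A character vector of per-sample labels, or a data frame with a
#'   `label` column (e.g. an [imu_recording()]). For multi-subject data,
#'   call per recording so bouts never span subjects, e.g.
#'   `purrr::map_dfr(recordings, extract_bouts, .id = "subject_id")`.
#'
#' @return A tibble with columns `behaviour`, `start` (0-based sample
#'   index), `end` (exclusive) and `length_samples`, in temporal order.
#' @examples
#' extract_bouts(c("walk", "walk", "sit", "walk"))
#' @export
extract_bouts <- function(x) {
  labels <- if (is.data.frame(x)) x$label else as.character(x)
  if (length(labels) == 0) {
    return(tibble::tibble(behaviour = character(), start = integer(),
                          end = integer(), length_samples = integer()))
  }
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != unlabelled_label()
  tibble::tibble(
    behaviour = r$values[keep],
    start = as.integer(starts[keep]),
    end = as.integer(ends[keep]),
    length_samples = as.integer(r$lengths[keep])
  )
}

#' Per-behaviour bout summary statistics
#'
#' Computes, for every behaviour with at least one bout, the median bout
#' length (midpoint of the two central values for even counts), the
#' arithmetic mean, the sample standard deviation (n-1 denominator, 0 for a
#' single bout) and the number of occurrences — all in sample units.
#' Behaviours without any bout are omitted.
#'
#' @param bouts A bout tibble from [extract_bouts()] (rows from several
#'   recordings may be bound together).
#' @param behaviour_set Optional character vector fixing the row order;
#'   behaviours absent from `bouts` are dropped, others follow in the order
#'   given.
#' @param sample_rate_hz If non-`NULL`, adds `median_s`/`mean_s` columns
#'   converted to seconds at this rate.
#'
#' @return A tibble with columns `behaviour`, `median_samples`,
#'   `mean_samples`, `std_samples`, `n_occurrences`.
#' @export
bout_stats <- function(bouts, behaviour_set = NULL, sample_rate_hz = NULL) {
  out <- bouts %>%
    dplyr::group_by(.data$behaviour) %>%
    dplyr::summarise(
      median_samples = stats::median(.data$length_samples),
      mean_samples = mean(.data$length_samples),
      std_samples = ifelse(dplyr::n() > 1, stats::sd(.data$length_samples), 0),
      n_occurrences = dplyr::n(),
      .groups = "drop"
    )
  if (!is.null(behaviour_set)) {
    out <- out[match(intersect(behaviour_set, out$behaviour), out$behaviour), ]
  }
  if (!is.null(sample_rate_hz)) {
    out <- dplyr::mutate(out,
      median_s = samples_to_seconds(.data$median_samples, sample_rate_hz),
      mean_s = samples_to_seconds(.data$mean_samples, sample_rate_hz))
  }
  out
}

#' Bout statistics for a whole study
#'
#' Convenience wrapper: extracts bouts per recording (so bouts never span
#' subjects) and pools them into one summary table.
#'
#' @param recordings A list of [imu_recording()] objects, or a single one.
#' @inheritParams bout_stats
#' @return A tibble as from [bout_stats()].
#' @export
study_bout_stats <- function(recordings, behaviour_set = NULL,
                             sample_rate_hz = NULL) {
  if (is.data.frame(recordings)) recordings <- list(recordings)
  bouts <- purrr::map_dfr(recordings, extract_bouts)
  bout_stats(bouts, behaviour_set = behaviour_set,
             sample_rate_hz = sample_rate_hz)
}
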
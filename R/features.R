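#' The default sliding-window size grid
#'
#' Window sizes of 15, 32, 60, 81, 100, 149, 200 and 300 samples (0.3 to
#' 6 s at 50 Hz), spanning the range of typical bout lengths.
#'
#' @return Integer vector of window sizes in samples.
#' @export
default_window_grid <- function() {
  c(15L, 32L, 60L, 81L, 100L, 149L, 200L, 300L)
}

#' Default stride for a window size
#'
#' Windows scroll 10 samples forward, but only 5 samples for the very
#' small windows (sizes up to 32) so that short windows still produce a
#' dense sampling of the stream.
#'
#' @param size Window size in samples.
#' @return Stride in samples.
#' @export
default_stride <- function(size) {
  ifelse(size <= 32, 5L, 10L)
}

#' The default per-window statistic set
#'
#' Five descriptive statistics per channel: mean, standard deviation,
#' minimum, maximum and median. With the 32 derived channels this yields
#' the standard 160-feature vector.
#'
#' @return Character vector of statistic names.
#' @export
default_stats <- function() {
  c("mean", "sd", "min", "max", "median")
}

#' Derive the 16-channel signal set from a 13-channel recording
#'
#' Appends three channels to the 13 raw ones: the acceleration x/z ratio
#' (`acc_xz_ratio`), the acceleration magnitude (`acc_mag`) and the
#' rotation-rate magnitude (`rot_mag`). The x/z ratio is guarded with a
#' sign-preserving clamp of the denominator at `eps`, since raw division is
#' unbounded whenever the z axis passes through zero.
#'
#' @param rec An [imu_recording()] (or data frame with the 13 channels).
#' @param eps Lower bound on `|acc_z|` in the ratio denominator.
#' @return A tibble with 16 numeric channel columns, same length as `rec`.
#' @export
derive_channels <- function(rec, eps = 1e-6) {
  d <- tibble::as_tibble(rec)[, imu_channels()]
  sgn <- ifelse(d$acc_z >= 0, 1, -1)
  denom <- sgn * pmax(abs(d$acc_z), eps)
  d$acc_xz_ratio <- d$acc_x / denom
  d$acc_mag <- sqrt(d$acc_x^2 + d$acc_y^2 + d$acc_z^2)
  d$rot_mag <- sqrt(d$rot_x^2 + d$rot_y^2 + d$rot_z^2)
  d
}

#' Append per-channel gradients, doubling the channel count
#'
#' The gradient of each channel is the central difference over the sample
#' index (unit spacing), with one-sided differences at both ends, so the
#' output has the same length as the input and windows slice signal and
#' gradient identically. Gradient columns are named `d_<channel>`.
#'
#' @param channels A tibble of numeric channel columns (e.g. from
#'   [derive_channels()]); needs at least 2 rows.
#' @return A tibble with twice as many columns.
#' @export
add_gradients <- function(channels) {
  channels <- tibble::as_tibble(channels)
  n <- nrow(channels)
  if (n < 2) stop("input too short: gradients need at least 2 samples",
                  call. = FALSE)
  grads <- purrr::map(channels, function(x) {
    g <- numeric(n)
    g[1] <- x[2] - x[1]
    g[n] <- x[n] - x[n - 1]
    if (n > 2) g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
    g
  })
  names(grads) <- paste0("d_", names(channels))
  dplyr::bind_cols(channels, tibble::as_tibble(grads))
}

#' Window start positions for a recording length
#'
#' Half-open windows `[start, start + size)` in 0-based coordinates,
#' advanced by `stride`; every window lies fully inside the recording, so
#' the count is `floor((n - size) / stride) + 1` when `n >= size` and 0
#' otherwise.
#'
#' @param n Recording length in samples.
#' @param size Window size in samples (>= 2).
#' @param stride Stride in samples; `NULL` uses [default_stride()].
#' @return Integer vector of 0-based window starts (possibly empty).
#' @examples
#' segment_windows(100, 60, 10) # 0 10 20 30 40
#' @export
segment_windows <- function(n, size, stride = NULL) {
  if (size < 2) stop("window size must be at least 2 samples", call. = FALSE)
  if (is.null(stride)) stride <- default_stride(size)
  if (stride < 1 || stride > size) {
    stop("stride must be in [1, size]", call. = FALSE)
  }
  if (n < size) return(integer(0))
  as.integer(seq.int(0L, n - size, by = stride))
}

#' Label of a window under the last-sample rule
#'
#' A window is assigned the behaviour of its final sample, even when it
#' spans a transition between behaviours. Windows whose final sample is
#' unlabelled receive the unlabelled token (and are dropped from feature
#' sets downstream).
#'
#' @param labels Per-sample label vector.
#' @param start 0-based window start.
#' @param size Window size.
#' @return A single label string.
#' @export
label_window <- function(labels, start, size) {
  stopifnot(start + size <= length(labels))
  labels[start + size] # 0-based start + size - 1, in 1-based indexing
}

#' Descriptive statistics of one window
#'
#' @param values Numeric vector (one channel sliced to one window).
#' @param stats Statistic names from `c("mean","sd","min","max","median")`,
#'   in the order the features should appear.
#' @return Named numeric vector, one element per statistic. `sd` of a
#'   single value is 0.
#' @export
window_statistics <- function(values, stats = default_stats()) {
  fns <- list(
    mean = mean,
    sd = function(x) if (length(x) > 1) stats::sd(x) else 0,
    min = min, max = max,
    median = stats::median
  )
  bad <- setdiff(stats, names(fns))
  if (length(bad) > 0) stop("unknown statistic(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  vapply(stats, function(s) fns[[s]](values), numeric(1))
}

# Vectorised per-window statistics for one channel: rows = windows.
# idx is an n_windows x size matrix of 1-based sample indices.
channel_window_stats <- function(x, idx, stats) {
  m <- matrix(x[idx], nrow = nrow(idx), ncol = ncol(idx))
  w <- ncol(m)
  out <- matrix(0, nrow(m), length(stats))
  for (j in seq_along(stats)) {
    out[, j] <- switch(stats[j],
      mean = rowMeans(m),
      sd = if (w > 1) {
        mu <- rowMeans(m)
        sqrt(pmax(0, (rowSums(m^2) - w * mu^2) / (w - 1)))
      } else rep(0, nrow(m)),
      min = do.call(pmin, as.data.frame(m)),
      max = do.call(pmax, as.data.frame(m)),
      median = apply(m, 1, stats::median)
    )
  }
  out
}

#' Extract windowed features from a labelled recording
#'
#' Composes the full feature pipeline: derive the 16 channels, append
#' their gradients (32 channels), slide windows of `size` samples over the
#' recording, and compute each statistic of each channel per window —
#' 32 x 5 = 160 features at the defaults. Each window is labelled by its
#' last sample; windows ending on an unlabelled sample are dropped.
#'
#' @param rec An [imu_recording()], or a list of them (features are
#'   extracted per recording and row-bound, so windows never span
#'   subjects).
#' @param size Window size in samples.
#' @param stride Stride; `NULL` uses [default_stride()].
#' @param stats Statistic set, see [window_statistics()].
#' @param eps Clamp for the acceleration x/z ratio, see [derive_channels()].
#'
#' @return A tibble with one row per retained window: the feature columns
#'   (named `<channel>_<stat>`), then `label`, `subject_id` and
#'   `window_start` (0-based). Attributes `window_size` and `stride` record
#'   the windowing. Zero rows when the recording is shorter than `size`.
#' @export
extract_features <- function(rec, size, stride = NULL,
                             stats = default_stats(), eps = 1e-6) {
  if (is.null(stride)) stride <- default_stride(size)
  if (is.list(rec) && !is.data.frame(rec)) {
    out <- purrr::map_dfr(rec, extract_features, size = size,
                          stride = stride, stats = stats, eps = eps)
    attr(out, "window_size") <- as.integer(size)
    attr(out, "stride") <- as.integer(stride)
    return(out)
  }
  n <- nrow(rec)
  starts <- if (n >= size) segment_windows(n, size, stride) else integer(0)
  channels <- if (n >= max(2, size)) {
    add_gradients(derive_channels(rec, eps = eps))
  } else {
    NULL
  }
  ch_names <- if (is.null(channels)) {
    ch16 <- c(imu_channels(), "acc_xz_ratio", "acc_mag", "rot_mag")
    c(ch16, paste0("d_", ch16))
  } else {
    names(channels)
  }
  feat_names <- as.vector(t(outer(ch_names, stats, paste, sep = "_")))

  if (length(starts) == 0) {
    empty <- matrix(numeric(0), 0, length(feat_names),
                    dimnames = list(NULL, feat_names))
    out <- tibble::as_tibble(empty)
    out$label <- character(0)
    out$subject_id <- character(0)
    out$window_start <- integer(0)
  } else {
    labs <- vapply(starts, function(s) label_window(rec$label, s, size), "")
    keep <- labs != unlabelled_label()
    starts <- starts[keep]
    labs <- labs[keep]
    idx <- outer(starts, seq_len(size), `+`) # 1-based: start + 1..size
    mats <- purrr::map(channels, channel_window_stats, idx = idx,
                       stats = stats)
    feat <- do.call(cbind, mats)
    colnames(feat) <- feat_names
    out <- tibble::as_tibble(feat)
    out$label <- labs
    out$subject_id <- rep(rec$subject_id[1], length(starts))
    out$window_start <- starts
  }
  attr(out, "window_size") <- as.integer(size)
  attr(out, "stride") <- as.integer(stride)
  out
}

#' Names of the feature columns in a feature set
#'
#' @param features A tibble from [extract_features()].
#' @return Character vector of the feature column names (everything except
#'   `label`, `subject_id`, `window_start`).
#' @export
feature_names <- function(features) {
  setdiff(names(features), c("label", "subject_id", "window_start"))
}
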
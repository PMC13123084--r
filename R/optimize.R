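#' Fit the quadratic window-size response of AUC
#'
#' Ordinary least squares of `auc = b0 + b1 * w + b2 * w^2` on individual
#' runs (each run is one point; per-size means are not pre-averaged).
#' Window size is in sample units throughout.
#'
#' @param points Data frame with columns `window_size` and `auc` (rows with
#'   missing AUC are dropped); at least 3 distinct window sizes required.
#' @return An object of class `auc_quadratic`: coefficients `beta0`,
#'   `beta1`, `beta2`, `r_squared`, the overall F-test `p_value`, `n`, the
#'   window-size range, and the underlying `lm` fit.
#' @export
fit_quadratic <- function(points) {
  points <- points[!is.na(points$auc), , drop = FALSE]
  if (length(unique(points$window_size)) < 3) {
    stop("quadratic fit needs at least 3 distinct window sizes",
         call. = FALSE)
  }
  fit <- stats::lm(auc ~ window_size + I(window_size^2), data = points)
  # a noiseless quadratic is a legitimate input: muffle the perfect-fit note
  sm <- suppressWarnings(summary(fit))
  p <- if (is.null(sm$fstatistic)) {
    NA_real_
  } else {
    stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE)
  }
  cf <- unname(stats::coef(fit))
  structure(list(beta0 = cf[1], beta1 = cf[2], beta2 = cf[3],
                 r_squared = sm$r.squared,
                 p_value = unname(p), n = nrow(points),
                 range = range(points$window_size), lm = fit),
            class = "auc_quadratic")
}

#' @export
print.auc_quadratic <- function(x, ...) {
  cat("Quadratic AUC response: auc =", signif(x$beta0, 4), "+",
      signif(x$beta1, 4), "* w +", signif(x$beta2, 4), "* w^2\n")
  cat("  n =", x$n, " R^2 =", signif(x$r_squared, 3),
      " p =", format.pval(x$p_value, digits = 3), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the coefficients of a quadratic AUC response
#'
#' @param x An `auc_quadratic` from [fit_quadratic()].
#' @param ... Unused.
#' @return A tibble with one row per regression term.
#' @method tidy auc_quadratic
#' @export
tidy.auc_quadratic <- function(x, ...) {
  sm <- suppressWarnings(summary(x$lm))$coefficients
  tibble::tibble(
    term = c("(Intercept)", "window_size", "window_size^2"),
    estimate = sm[, 1], std.error = sm[, 2],
    statistic = sm[, 3], p.value = sm[, 4]
  )
}

#' One-row summary of a quadratic AUC response
#'
#' @param x An `auc_quadratic` from [fit_quadratic()].
#' @param ... Unused.
#' @return A tibble with `r.squared`, `p.value`, `nobs` and the analytic
#'   `vertex` (`-b1 / (2 * b2)`, `NA` when the fit is not concave).
#' @method glance auc_quadratic
#' @export
glance.auc_quadratic <- function(x, ...) {
  vertex <- if (!is.na(x$beta2) && x$beta2 < 0) {
    -x$beta1 / (2 * x$beta2)
  } else {
    NA_real_
  }
  tibble::tibble(r.squared = x$r_squared, p.value = x$p_value,
                 nobs = x$n, vertex = vertex)
}

#' Locate the AUC optimum of a fitted quadratic on a window grid
#'
#' If the fit is concave (`b2 < 0`) and its vertex `-b1 / (2 * b2)` lies
#' inside the grid range, the vertex is the local maximum. A concave fit
#' whose vertex falls outside the range is clamped to the nearest grid
#' boundary and flagged out-of-range; a non-concave fit returns the
#' boundary with the larger fitted value, flagged.
#'
#' @param fit An `auc_quadratic` from [fit_quadratic()].
#' @param grid Window grid (only its range is used).
#' @return A tibble with `vertex_samples`, `concave` and `in_range`.
#' @export
locate_optimum <- function(fit, grid = default_window_grid()) {
  lo <- min(grid); hi <- max(grid)
  predict_at <- function(w) fit$beta0 + fit$beta1 * w + fit$beta2 * w^2
  if (!is.na(fit$beta2) && fit$beta2 < 0) {
    v <- -fit$beta1 / (2 * fit$beta2)
    if (v >= lo && v <= hi) {
      tibble::tibble(vertex_samples = v, concave = TRUE, in_range = TRUE)
    } else {
      tibble::tibble(vertex_samples = if (v < lo) lo else hi,
                     concave = TRUE, in_range = FALSE)
    }
  } else {
    best <- if (isTRUE(predict_at(hi) >= predict_at(lo))) hi else lo
    tibble::tibble(vertex_samples = as.numeric(best), concave = FALSE,
                   in_range = FALSE)
  }
}

#' Grid window closest to a bout median
#'
#' The deployment window for a behaviour: the grid value minimising the
#' absolute distance to the behaviour's median bout length (ties go to the
#' smaller window; medians beyond the grid maximum clamp to it).
#'
#' @param bout_median Median bout length in samples.
#' @param grid Window grid.
#' @return A single grid value.
#' @examples
#' select_window(77)  # 81
#' select_window(366) # 300
#' @export
select_window <- function(bout_median, grid = default_window_grid()) {
  grid <- sort(grid)
  grid[which.min(abs(grid - bout_median))]
}

#' Grid window farthest from a bout median
#'
#' The "no bout length window" reference: the grid value maximising the
#' distance to the bout median (e.g. 300 for medians in the 62-85 range,
#' 15 for medians in the 293-366 range).
#'
#' @inheritParams select_window
#' @return A single grid value.
#' @export
farthest_window <- function(bout_median, grid = default_window_grid()) {
  grid <- sort(grid)
  grid[which.max(abs(grid - bout_median))]
}

#' Fit per-behaviour window optima and compare them to bout medians
#'
#' For every behaviour present in both the experiment and the bout
#' statistics: fit the quadratic AUC response over all its runs, locate
#' the local maximum on the grid, and report the difference between that
#' optimum and the behaviour's median bout length, together with the
#' deployment window selected by bout median.
#'
#' @param experiment An `experiment_table` from [run_experiment()].
#' @param bout_stats A tibble from [bout_stats()] covering every modelled
#'   behaviour.
#' @param grid Window grid; defaults to the experiment's own grid.
#'   Behaviours whose valid runs cover fewer than 3 distinct window sizes
#'   are skipped with a warning.
#' @return A tibble of class `window_optima`: per behaviour, `beta0..2`,
#'   `r_squared`, `p_value`, `vertex_samples`, `concave`, `in_range`,
#'   `bout_median_samples`, `difference_samples` (vertex minus median) and
#'   `selected_window`.
#' @export
optimise_windows <- function(experiment, bout_stats, grid = NULL) {
  if (is.null(grid)) grid <- attr(experiment, "window_grid")
  if (is.null(grid)) grid <- default_window_grid()
  behaviours <- unique(experiment$behaviour)
  fits <- purrr::map_dfr(behaviours, function(b) {
    pts <- experiment[experiment$behaviour == b & !is.na(experiment$auc), ]
    fit <- tryCatch(fit_quadratic(pts), error = function(e) {
      warning("skipping behaviour '", b, "': ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(fit)) return(NULL)
    opt <- locate_optimum(fit, grid)
    tibble::tibble(behaviour = b, beta0 = fit$beta0, beta1 = fit$beta1,
                   beta2 = fit$beta2, r_squared = fit$r_squared,
                   p_value = fit$p_value) %>%
      dplyr::bind_cols(opt)
  })
  if (nrow(fits) == 0) {
    stop("no behaviour had enough valid runs for a quadratic fit",
         call. = FALSE)
  }
  out <- compare_to_bout_median(fits, bout_stats, grid = grid)
  structure(out, window_grid = as.integer(grid),
            class = c("window_optima", class(tibble::tibble())))
}

#' Attach bout medians and their distance to the fitted optima
#'
#' @param optima A tibble with `behaviour` and `vertex_samples` columns
#'   (e.g. the fit block built by [optimise_windows()]).
#' @param bout_stats A tibble from [bout_stats()]; every behaviour in
#'   `optima` must appear in it.
#' @param grid Window grid used for [select_window()].
#' @return `optima` with `bout_median_samples`, `difference_samples`
#'   (= vertex - median) and `selected_window` columns appended.
#' @export
compare_to_bout_median <- function(optima, bout_stats,
                                   grid = default_window_grid()) {
  missing_b <- setdiff(optima$behaviour, bout_stats$behaviour)
  if (length(missing_b) > 0) {
    stop("no bout statistics for behaviour(s): ",
         paste(missing_b, collapse = ", "), call. = FALSE)
  }
  med <- bout_stats$median_samples[match(optima$behaviour,
                                         bout_stats$behaviour)]
  optima %>%
    dplyr::mutate(
      bout_median_samples = med,
      difference_samples = .data$vertex_samples - med,
      selected_window = vapply(med, select_window, numeric(1), grid = grid)
    )
}

#' Bout-length window versus farthest-window performance
#'
#' Per behaviour, compares the mean AUC at the bout-matched window (the
#' grid value nearest the bout median) against the mean AUC at the grid
#' window farthest from the bout median — the package's counterpart of the
#' "bout length window" vs "no bout length window" comparison.
#'
#' @param experiment An `experiment_table` covering the full grid.
#' @param optima A `window_optima` tibble from [optimise_windows()].
#' @return A tibble with `behaviour`, `bout_window`, `far_window`,
#'   `auc_bout_window`, `auc_far_window` and `auc_gain` (bout minus far).
#' @export
bout_vs_nonbout_report <- function(experiment, optima) {
  grid <- attr(optima, "window_grid")
  if (is.null(grid)) grid <- default_window_grid()
  purrr::map_dfr(seq_len(nrow(optima)), function(i) {
    b <- optima$behaviour[i]
    med <- optima$bout_median_samples[i]
    wb <- select_window(med, grid)
    wf <- farthest_window(med, grid)
    mean_at <- function(w) {
      mean(experiment$auc[experiment$behaviour == b &
                            experiment$window_size == w], na.rm = TRUE)
    }
    tibble::tibble(behaviour = b, bout_window = wb, far_window = wf,
                   auc_bout_window = mean_at(wb),
                   auc_far_window = mean_at(wf),
                   auc_gain = mean_at(wb) - mean_at(wf))
  })
}
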
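grid8 <- function() default_window_grid()

test_that("noiseless quadratics and lines are recovered exactly", {
  w <- grid8()
  pts <- tibble::tibble(window_size = w,
                        auc = 0.9 - 1e-5 * (w - 100)^2)
  fit <- fit_quadratic(pts)
  expect_lt(fit$beta2, 0)
  expect_equal(-fit$beta1 / (2 * fit$beta2), 100, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  line <- tibble::tibble(window_size = w, auc = 0.5 + 0.001 * w)
  lf <- fit_quadratic(line)
  expect_equal(lf$beta2, 0, tolerance = 1e-12)
  expect_equal(lf$r_squared, 1, tolerance = 1e-9)

  expect_error(fit_quadratic(tibble::tibble(window_size = c(15, 15, 32),
                                            auc = c(0.6, 0.7, 0.8))),
               "3 distinct")
})

test_that("the quadratic fit equals the closed-form normal equations", {
  withr::with_seed(41, {
    for (i in 1:10) {
      w <- rep(grid8(), 3)
      y <- runif(length(w), 0.5, 1)
      fit <- fit_quadratic(tibble::tibble(window_size = w, auc = y))
      want <- oracle_quadratic_fit(w, y)
      expect_equal(c(fit$beta0, fit$beta1, fit$beta2), want$beta,
                   tolerance = 1e-9)
      expect_equal(fit$r_squared, want$r_squared, tolerance = 1e-9)
    }
  })
})

test_that("tidy and glance expose coefficients and the vertex", {
  w <- grid8()
  fit <- fit_quadratic(tibble::tibble(window_size = w,
                                      auc = 0.9 - 2e-5 * (w - 81)^2))
  td <- tidy(fit)
  expect_equal(td$term,
               c("(Intercept)", "window_size", "window_size^2"))
  gl <- glance(fit)
  expect_equal(gl$vertex, 81, tolerance = 1e-6)
  expect_equal(gl$nobs, 8)
})

test_that("optimum location clamps and flags per the concavity rules", {
  mk <- function(b0, b1, b2) {
    structure(list(beta0 = b0, beta1 = b1, beta2 = b2), class = "auc_quadratic")
  }
  # concave, interior vertex at 65
  o1 <- locate_optimum(mk(0.5, 2 * 65 * 1e-5, -1e-5), grid8())
  expect_equal(o1$vertex_samples, 65, tolerance = 1e-9)
  expect_true(o1$concave && o1$in_range)
  # concave, vertex 400 -> clamped to 300
  o2 <- locate_optimum(mk(0.5, 2 * 400 * 1e-5, -1e-5), grid8())
  expect_equal(o2$vertex_samples, 300)
  expect_false(o2$in_range)
  # convex increasing -> upper boundary, flagged non-concave
  o3 <- locate_optimum(mk(0.5, 1e-4, 1e-6), grid8())
  expect_equal(o3$vertex_samples, 300)
  expect_false(o3$concave)
  # convex decreasing -> lower boundary
  o4 <- locate_optimum(mk(0.9, -1e-3, 1e-7), grid8())
  expect_equal(o4$vertex_samples, 15)
})

test_that("noisy concave curves recover the vertex within one grid step", {
  w <- rep(grid8(), each = 30)
  true_vertex <- 100
  withr::with_seed(43, {
    y <- 0.9 - 6e-6 * (w - true_vertex)^2 + rnorm(length(w), 0, 0.02)
  })
  fit <- fit_quadratic(tibble::tibble(window_size = w, auc = y))
  v <- locate_optimum(fit, grid8())$vertex_samples
  # within +/- 1 grid step of 100 (neighbours 81 and 149)
  expect_gte(v, 81)
  expect_lte(v, 149)
})

test_that("window selection picks the nearest grid value, ties to smaller", {
  expect_equal(select_window(77, grid8()), 81)
  expect_equal(select_window(366, grid8()), 300)
  expect_equal(select_window(149, grid8()), 149)
  expect_equal(select_window(46, c(32, 60)), 32) # tie -> smaller
  expect_equal(select_window(5, grid8()), 15)
})

test_that("the farthest window mirrors the bout-median geometry", {
  for (med in c(62, 66, 77, 85)) {
    expect_equal(farthest_window(med, grid8()), 300)
  }
  for (med in c(293, 300, 366)) {
    expect_equal(farthest_window(med, grid8()), 15)
  }
})

test_that("optima tables join bout medians and report differences", {
  # construct a synthetic experiment with exact concave AUC responses
  mk_runs <- function(b, vertex) {
    tidyr::expand_grid(window_size = grid8(), fold = 1:3) %>%
      dplyr::mutate(behaviour = b, iteration = 1L,
                    auc = 0.9 - 1e-5 * (window_size - vertex)^2,
                    status = "ok")
  }
  et <- dplyr::bind_rows(mk_runs("stand", 65), mk_runs("eat", 290))
  bs <- tibble::tibble(behaviour = c("stand", "eat"),
                       median_samples = c(77, 366),
                       mean_samples = c(197, 785), std_samples = c(596, 810),
                       n_occurrences = c(2952L, 72L))
  opt <- optimise_windows(et, bs, grid = grid8())
  stand <- opt[opt$behaviour == "stand", ]
  expect_equal(stand$vertex_samples, 65, tolerance = 1e-6)
  expect_equal(stand$difference_samples, -12, tolerance = 1e-6)
  expect_equal(stand$selected_window, 81)
  eat <- opt[opt$behaviour == "eat", ]
  expect_equal(eat$difference_samples, 290 - 366, tolerance = 1e-6)
  expect_equal(eat$selected_window, 300)

  expect_error(compare_to_bout_median(opt, bs[1, ]), "eat")
})

test_that("the bout-window report beats the farthest window on concave fixtures", {
  mk_runs <- function(b, vertex) {
    tidyr::expand_grid(window_size = grid8(), fold = 1:3,
                       iteration = 1:2) %>%
      dplyr::mutate(behaviour = b,
                    auc = 0.92 - 8e-6 * (window_size - vertex)^2,
                    status = "ok")
  }
  et <- dplyr::bind_rows(mk_runs("walk", 62), mk_runs("lie", 293))
  bs <- tibble::tibble(behaviour = c("walk", "lie"),
                       median_samples = c(62, 293),
                       mean_samples = c(170, 664), std_samples = c(547, 2657),
                       n_occurrences = c(3957L, 394L))
  opt <- optimise_windows(et, bs, grid = grid8())
  rep <- bout_vs_nonbout_report(et, opt)
  expect_equal(rep$far_window[rep$behaviour == "walk"], 300)
  expect_equal(rep$far_window[rep$behaviour == "lie"], 15)
  expect_true(all(rep$auc_bout_window >= rep$auc_far_window))
  expect_true(all(rep$auc_gain >= 0))
})
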
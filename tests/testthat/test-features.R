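test_that("the derived channel set has 16 channels with correct magnitudes", {
  rec <- make_test_recording(10)
  d <- derive_channels(rec)
  expect_equal(ncol(d), 16)

  df <- tibble::as_tibble(matrix(0, 2, 13), .name_repair = "minimal")
  names(df) <- imu_channels()
  df$acc_x <- c(3, 0); df$acc_z <- c(4, 0)
  d0 <- derive_channels(imu_recording(df))
  expect_equal(d0$acc_mag, c(5, 0))
  expect_equal(d0$rot_mag, c(0, 0))
})

test_that("the acceleration x/z ratio is clamped, sign-preservingly", {
  df <- tibble::as_tibble(matrix(0, 3, 13), .name_repair = "minimal")
  names(df) <- imu_channels()
  df$acc_x <- c(1, 1, -2)
  df$acc_z <- c(0, -1e-9, 0.5)
  d <- derive_channels(imu_recording(df), eps = 1e-6)
  expect_equal(d$acc_xz_ratio, c(1e6, -1e6, -4))
  expect_true(all(is.finite(d$acc_xz_ratio)))
})

test_that("gradients double the channel count and match the finite-difference oracle", {
  ramp <- tibble::tibble(a = 2 * (0:9))
  g <- add_gradients(ramp)
  expect_equal(ncol(g), 2)
  expect_true(all(g$d_a == 2))

  const <- tibble::tibble(a = rep(5, 8))
  expect_true(all(add_gradients(const)$d_a == 0))

  withr::with_seed(10, {
    x <- rnorm(50)
    g2 <- add_gradients(tibble::tibble(a = x))
    expect_equal(g2$d_a, oracle_gradient(x), tolerance = 1e-12)
  })

  expect_error(add_gradients(tibble::tibble(a = 1)), "too short")
})

test_that("window segmentation follows the stride arithmetic", {
  expect_equal(segment_windows(100, 60, 10), c(0L, 10L, 20L, 30L, 40L))
  expect_equal(length(segment_windows(100, 60, 10)),
               floor((100 - 60) / 10) + 1)
  expect_equal(segment_windows(59, 60, 10), integer(0))
  expect_equal(segment_windows(60, 60, 10), 0L)
  # default stride: 5 for the small windows, 10 above
  expect_equal(default_stride(15), 5L)
  expect_equal(default_stride(32), 5L)
  expect_equal(default_stride(60), 10L)
  expect_equal(diff(segment_windows(100, 15))[1], 5L)
})

test_that("windows are labelled by their last sample", {
  labels <- c("A", "A", "A", "B")
  expect_identical(label_window(labels, 0, 4), "B")
  expect_identical(label_window(labels, 0, 3), "A")
  expect_identical(label_window(c("A", "A"), 0, 2), "A")
  labs <- c("A", "A", unlabelled_label())
  expect_identical(label_window(labs, 0, 3), unlabelled_label())
})

test_that("window statistics match direct computation and the naive oracle", {
  expect_equal(unname(window_statistics(rep(3, 7))), c(3, 0, 3, 3, 3))
  expect_equal(unname(window_statistics(c(1, 2, 3, 4))),
               c(2.5, sd(1:4), 1, 4, 2.5))
  withr::with_seed(11, {
    for (i in 1:20) {
      x <- rnorm(sample(2:50, 1))
      expect_equal(window_statistics(x), oracle_window_stats(x),
                   tolerance = 1e-12)
    }
  })
  expect_error(window_statistics(1:3, stats = "kurtosis"), "unknown")
})

test_that("feature extraction yields 160 features and the window-count formula", {
  rec <- make_test_recording(100)
  f <- extract_features(rec, size = 60, stride = 10)
  expect_equal(length(feature_names(f)), 160)
  expect_equal(nrow(f), 5)
  expect_equal(f$window_start, c(0L, 10L, 20L, 30L, 40L))
  expect_true(all(f$label == "walk"))

  # empty recording -> empty feature set with full schema
  f0 <- extract_features(make_test_recording(0, labels = character(0)),
                         size = 60)
  expect_equal(nrow(f0), 0)
  expect_equal(length(feature_names(f0)), 160)
})

test_that("per-window features equal brute-force recomputation on raw slices", {
  rec <- make_test_recording(400, labels = rep(c("a", "b"), 200))
  f <- extract_features(rec, size = 32, stride = 5)
  ch <- add_gradients(derive_channels(rec))
  withr::with_seed(12, picks <- sample(nrow(f), 25))
  for (i in picks) {
    s <- f$window_start[i]
    slice <- ch[(s + 1):(s + 32), ]
    for (col in c("acc_x", "d_acc_mag", "rot_mag", "d_att_w")) {
      want <- oracle_window_stats(slice[[col]])
      got <- unlist(f[i, paste0(col, "_", names(want))])
      expect_equal(unname(got), unname(want), tolerance = 1e-12)
    }
  }
})

test_that("windows ending on unlabelled samples are dropped", {
  labels <- rep("walk", 100)
  labels[95:100] <- unlabelled_label()
  rec <- make_test_recording(100, labels = labels)
  f <- extract_features(rec, size = 60, stride = 10)
  # windows ending at samples 59..99 by stride 10: ends 60,70,80,90,100 ->
  # the last window (end sample index 99, unlabelled) is dropped
  expect_equal(nrow(f), 4)
  expect_true(all(f$label == "walk"))
})

test_that("feature extraction is deterministic and multi-subject aware", {
  recs <- list(make_test_recording(80, subject = "s1", seed = 1),
               make_test_recording(90, subject = "s2", seed = 2))
  f1 <- extract_features(recs, size = 60)
  f2 <- extract_features(recs, size = 60)
  expect_identical(f1, f2)
  expect_setequal(unique(f1$subject_id), c("s1", "s2"))
  # windows never span subjects: counts add up per recording
  expect_equal(nrow(f1),
               length(segment_windows(80, 60)) +
                 length(segment_windows(90, 60)))
})
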
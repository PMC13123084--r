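test_that("fold assignment partitions subjects evenly and reproducibly", {
  p3 <- assign_folds(c("a", "b", "c"), 3, seed = 1)
  expect_equal(sort(table(p3$fold)), sort(table(1:3)))

  p56 <- assign_folds(sprintf("d%02d", 1:56), 3, seed = 2)
  expect_equal(sort(as.integer(table(p56$fold))), c(18L, 19L, 19L))

  expect_identical(assign_folds(letters[1:9], 3, seed = 5),
                   assign_folds(letters[1:9], 3, seed = 5))
  expect_error(assign_folds(c("a", "b"), 3), "folds")
})

test_that("one-vs-all binarisation counts label frequency", {
  labels <- c("walk", "sit", "walk", "run")
  expect_equal(binarise_labels(labels, "walk"), c(1L, 0L, 1L, 0L))
  expect_equal(sum(binarise_labels(labels, "walk")),
               sum(labels == "walk"))
  expect_equal(binarise_labels(rep("x", 3), "x"), rep(1L, 3))
  expect_equal(binarise_labels(rep("x", 3), "y"), rep(0L, 3))
})

test_that("SMOTE balances classes with on-segment synthetic points", {
  withr::with_seed(20, {
    x_min <- matrix(rnorm(10 * 4), 10, 4)
    x_maj <- matrix(rnorm(50 * 4, mean = 5), 50, 4)
    x <- rbind(x_min, x_maj)
    y <- c(rep(1L, 10), rep(0L, 50))
  })
  out <- smote_balance(x, y, k = 5, seed = 99)
  expect_equal(out$n_synthetic, 40L)
  expect_equal(sum(out$y == 1), sum(out$y == 0))

  syn <- as.matrix(out$x)[(nrow(x) + 1):nrow(out$x), ]
  # every synthetic point lies on a segment between two minority originals:
  # check it is within the minority bounding box and collinear with a pair
  on_segment <- apply(syn, 1, function(p) {
    for (i in 1:9) for (j in (i + 1):10) {
      a <- x_min[i, ]; b <- x_min[j, ]
      d <- b - a
      t <- sum((p - a) * d) / sum(d * d)
      if (t >= -1e-9 && t <= 1 + 1e-9 &&
          sqrt(sum((a + t * d - p)^2)) < 1e-8) return(TRUE)
    }
    FALSE
  })
  expect_true(all(on_segment))
})

test_that("SMOTE leaves balanced input unchanged and skips tiny minorities", {
  x <- matrix(rnorm(20), 10, 2)
  y <- rep(c(0L, 1L), 5)
  out <- smote_balance(x, y, seed = 1)
  expect_equal(out$n_synthetic, 0L)
  expect_equal(nrow(out$x), 10)

  y1 <- c(1L, rep(0L, 9))
  expect_warning(out1 <- smote_balance(x, y1, seed = 1), "fewer than 2")
  expect_equal(out1$n_synthetic, 0L)
})

test_that("ROC AUC equals pairwise counting and is monotone-invariant", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), "single class")

  withr::with_seed(21, {
    for (i in 1:20) {
      n <- sample(10:40, 1)
      scores <- sample(seq(0, 1, 0.05), n, replace = TRUE) # induces ties
      labels <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) < 2) next
      expect_equal(roc_auc(scores, labels),
                   oracle_pairwise_auc(scores, labels), tolerance = 1e-12)
      # strictly monotone transform leaves AUC unchanged
      expect_equal(roc_auc(exp(3 * scores), labels),
                   roc_auc(scores, labels), tolerance = 1e-12)
    }
  })
})

make_learn_fixture <- function(seed = 31, n_subjects = 4, duration = 1200) {
  cfg <- two_gait_demo_config(seed = seed, n_subjects = n_subjects,
                              duration_samples = duration)
  simulate_study(cfg)
}

test_that("the experiment grid yields one row per run with disjoint subjects", {
  recs <- make_learn_fixture()
  et <- run_experiment(recs, behaviours = c("fastgait", "slowgait"),
                       window_grid = c(32, 60), n_folds = 2,
                       n_iterations = 2,
                       classifier = classifier_gbt(nrounds = 5), seed = 4)
  # behaviours x sizes x folds x iterations
  expect_equal(nrow(et), 2 * 2 * 2 * 2)
  expect_equal(nrow(dplyr::distinct(et, behaviour, window_size, fold,
                                    iteration)), nrow(et))
  expect_equal(audit_subject_independence(et), 0)
  ok <- et[et$status == "ok", ]
  expect_true(all(ok$auc >= 0 & ok$auc <= 1))
})

test_that("experiments are reproducible row for row under a fixed seed", {
  recs <- make_learn_fixture(seed = 32)
  run <- function() {
    run_experiment(recs, behaviours = "fastgait", window_grid = 60,
                   n_folds = 2, n_iterations = 2,
                   classifier = classifier_gbt(nrounds = 5), seed = 77)
  }
  expect_equal(as.data.frame(run()), as.data.frame(run()))
})

test_that("degenerate test folds are recorded, not dropped", {
  # one subject never shows behaviour "rare"
  rec1 <- make_test_recording(300, labels = rep(c("a", "rare"), 150),
                              subject = "s1", seed = 1)
  rec2 <- make_test_recording(300, labels = rep("a", 300),
                              subject = "s2", seed = 2)
  et <- run_experiment(list(rec1, rec2), behaviours = "rare",
                       window_grid = 60, n_folds = 2, n_iterations = 1,
                       classifier = classifier_gbt(nrounds = 3), seed = 9)
  statuses <- et$status[vapply(et$test_subjects,
                               function(s) "s2" %in% s, logical(1))]
  expect_true(all(statuses == "degenerate_test"))
  expect_true(all(is.na(et$auc[et$status == "degenerate_test"])))
  expect_equal(nrow(et), 2) # grid rows all present
})

test_that("combined one-vs-all prediction follows max probability with fixed-order ties", {
  consty <- function(val) {
    structure(list(
      label = "const",
      fit = function(x, y, seed) val,
      predict = function(model, x) rep(model, nrow(x))
    ), class = "boutwin_classifier")
  }
  recs <- make_learn_fixture(seed = 33, n_subjects = 2, duration = 900)
  rec <- recs[[1]]
  train <- function(vals) {
    ms <- purrr::imap(vals, function(v, b) {
      list(behaviour = b, model = v, size = 60L, stride = 10L,
           stats = default_stats(),
           predict_fun = function(model, x) rep(model, nrow(x)))
    })
    structure(ms, class = "ova_models")
  }
  # one certain model dominates everywhere
  pred <- predict_ova(train(list(a = 1, b = 0)), rec)
  expect_true(all(pred$predicted[!is.na(pred$predicted)] == "a"))
  # exact tie -> first behaviour in list order wins
  pred_tie <- predict_ova(train(list(z = 0.5, q = 0.5)), rec)
  expect_true(all(pred_tie$predicted[!is.na(pred_tie$predicted)] == "z"))

  short <- make_test_recording(10)
  expect_warning(p <- predict_ova(train(list(a = 1)), short), "shorter")
  expect_true(all(is.na(p$predicted)))
})

test_that("trained one-vs-all models beat the majority baseline on held-out data", {
  # three clearly distinct signal families with comparable bout lengths
  cfg <- simulation_config(
    list(behaviour_model("stand", "static", 120, bout_sigma_log = 0.3,
                         noise_sd = 0.1),
         behaviour_model("walk", "gait", 120, bout_sigma_log = 0.3,
                         gait_freq_hz = 2, acc_amplitude = 1,
                         noise_sd = 0.2),
         behaviour_model("eat", "burst", 120, bout_sigma_log = 0.3,
                         acc_amplitude = 0.8, noise_sd = 0.1)),
    n_subjects = 3, duration_samples = 2400, seed = 35)
  recs <- simulate_study(cfg)
  models <- train_ova(recs[1:2],
                      windows = c(stand = 100L, walk = 100L, eat = 100L),
                      classifier = classifier_gbt(nrounds = 20), seed = 6)
  held <- recs[[3]]
  pred <- predict_ova(models, held)
  ok <- !is.na(pred$predicted)
  acc <- mean(pred$predicted[ok] == held$label[ok])
  baseline <- max(table(held$label)) / nrow(held)
  expect_gt(acc, baseline)
})
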
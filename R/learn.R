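#' Assign subjects to cross-validation folds
#'
#' Subject-independent cross-validation: folds partition the subjects (not
#' the windows), so no individual ever contributes to both the training
#' and the test side of a run. The partition is random but as
#' size-balanced as the subject count allows, and deterministic for a
#' fixed seed.
#'
#' @param subject_ids Character vector of unique subject identifiers.
#' @param n_folds Number of folds (default 3).
#' @param seed Seed for the shuffle.
#' @return A tibble of class `cv_plan` with columns `subject_id` and
#'   `fold` (1-based), carrying `n_folds` and `seed` attributes.
#' @export
assign_folds <- function(subject_ids, n_folds = 3, seed = 1L) {
  subject_ids <- unique(as.character(subject_ids))
  if (length(subject_ids) < n_folds) {
    stop("need at least as many subjects (", length(subject_ids),
         ") as folds (", n_folds, ")", call. = FALSE)
  }
  shuffled <- withr::with_seed(seed, sample(subject_ids))
  plan <- tibble::tibble(
    subject_id = shuffled,
    fold = rep_len(seq_len(n_folds), length(shuffled))
  ) %>% dplyr::arrange(.data$subject_id)
  structure(plan, n_folds = as.integer(n_folds), seed = as.integer(seed),
            class = c("cv_plan", class(tibble::tibble())))
}

#' One-vs-all label binarisation
#'
#' @param labels Character vector of window labels.
#' @param target The positive-class behaviour.
#' @return Integer vector: 1 where `labels == target`, else 0.
#' @export
binarise_labels <- function(labels, target) {
  as.integer(labels == target)
}

#' Balance a binary training set with SMOTE
#'
#' Synthetic Minority Over-sampling Technique: each synthetic minority row
#' is `x_i + u * (x_nn - x_i)` with `u ~ Uniform(0, 1)` and `x_nn` one of
#' the `k` nearest minority neighbours of `x_i` (Euclidean distance in
#' feature space). Synthetic rows are added until the classes are exactly
#' 1:1. Apply to the training partition only — synthetic points live in
#' feature space and must never touch test data.
#'
#' @param x Feature matrix or data frame (numeric columns only).
#' @param y Binary integer labels (0/1), one per row of `x`.
#' @param k Number of minority nearest neighbours to interpolate towards;
#'   truncated to (minority size - 1) when the minority class is small.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return A list with `x` (augmented tibble), `y` (augmented labels) and
#'   `n_synthetic`. When the minority class has fewer than 2 rows the
#'   input is returned unchanged with a warning and `n_synthetic = 0`.
#' @export
smote_balance <- function(x, y, k = 5, seed = NULL) {
  xm <- as.matrix(x)
  if (is.null(colnames(xm))) {
    colnames(xm) <- paste0("V", seq_len(ncol(xm)))
  }
  y <- as.integer(y)
  run <- function() {
    counts <- table(factor(y, levels = c(0, 1)))
    n0 <- counts[["0"]]; n1 <- counts[["1"]]
    if (n0 == n1) {
      return(list(x = tibble::as_tibble(xm), y = y, n_synthetic = 0L))
    }
    minority <- if (n1 < n0) 1L else 0L
    min_idx <- which(y == minority)
    n_syn <- abs(n0 - n1)
    if (length(min_idx) < 2) {
      warning("minority class has fewer than 2 rows; SMOTE skipped",
              call. = FALSE)
      return(list(x = tibble::as_tibble(xm), y = y, n_synthetic = 0L))
    }
    mm <- xm[min_idx, , drop = FALSE]
    kk <- min(k, nrow(mm) - 1)
    d <- as.matrix(stats::dist(mm))
    diag(d) <- Inf
    nn_raw <- apply(d, 1, function(row) order(row)[seq_len(kk)])
    nn <- if (kk == 1) matrix(nn_raw, ncol = 1) else t(nn_raw)
    base <- sample.int(nrow(mm), n_syn, replace = TRUE)
    pick <- nn[cbind(base, sample.int(kk, n_syn, replace = TRUE))]
    u <- stats::runif(n_syn)
    syn <- mm[base, , drop = FALSE] +
      u * (mm[pick, , drop = FALSE] - mm[base, , drop = FALSE])
    list(x = tibble::as_tibble(rbind(xm, syn)),
         y = c(y, rep(minority, n_syn)),
         n_synthetic = as.integer(n_syn))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Binary ROC AUC with tie correction
#'
#' Area under the receiver operating characteristic curve, computed as the
#' Mann-Whitney U statistic normalised by `n_pos * n_neg` (ties counted as
#' one half). Equals the probability that a random positive outscores a
#' random negative, and is invariant under any strictly monotone transform
#' of the scores.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary labels (0/1); both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC AUC is undefined with a single class", call. = FALSE)
  }
  r <- rank(scores) # midranks handle ties as 1/2
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Gradient-boosted-tree classifier specification
#'
#' The default classifier behind the one-vs-all runs: binary logistic
#' gradient-boosted decision trees with library defaults. Any classifier
#' can be substituted by supplying an object with the same `fit(x, y,
#' seed)` / `predict(model, x)` contract, where `predict` returns
#' positive-class probabilities.
#'
#' @param nrounds Number of boosting rounds.
#' @param params Named list of additional booster parameters.
#' @return A list of class `boutwin_classifier` with elements `fit`,
#'   `predict` and `label`.
#' @export
classifier_gbt <- function(nrounds = 50, params = list()) {
  structure(list(
    label = paste0("gbt(nrounds=", nrounds, ")"),
    fit = function(x, y, seed = 1L) {
      p <- utils::modifyList(
        list(objective = "binary:logistic", nthread = 1,
             seed = as.integer(seed)),
        params)
      dm <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
      xgboost::xgb.train(params = p, data = dm, nrounds = nrounds,
                         verbose = 0)
    },
    predict = function(model, x) {
      stats::predict(model, xgboost::xgb.DMatrix(as.matrix(x)))
    }
  ), class = "boutwin_classifier")
}

# Deterministic sub-seed for a run, kept well below 2^31.
derive_seed <- function(seed, ...) {
  parts <- c(...)
  s <- as.double(seed %% 1000003L)
  for (p in parts) s <- (s * 131 + as.double(p)) %% 2147480009
  as.integer(s)
}

#' Run the full one-vs-all window-size experiment
#'
#' For every combination of behaviour, window size, fold and iteration:
#' extract features at that window size, balance the training folds with
#' SMOTE, train a binary classifier (target behaviour vs all the rest),
#' score the held-out fold and record the ROC AUC. Folds are fixed across
#' iterations; the iteration index only reseeds the SMOTE and classifier
#' random streams. At the defaults (8 window sizes x 3 folds x 10
#' iterations) this yields 240 runs per behaviour.
#'
#' Runs whose test fold contains a single class for the target behaviour
#' are recorded with `status = "degenerate_test"` and a missing AUC rather
#' than silently dropped, so the run grid stays auditable.
#'
#' @param recordings List of [imu_recording()] objects.
#' @param behaviours Behaviours to model; default all labelled behaviours
#'   present (in order of first appearance).
#' @param window_grid Integer vector of window sizes.
#' @param cv_plan A [assign_folds()] plan; `NULL` builds one from
#'   `n_folds` and `seed`.
#' @param n_folds,n_iterations Cross-validation shape (defaults 3 and 10).
#' @param classifier A [classifier_gbt()]-style specification.
#' @param smote Apply SMOTE to the training partition (default `TRUE`).
#' @param smote_k SMOTE neighbour count.
#' @param stats Per-window statistic set.
#' @param seed Master seed; all sub-streams derive from it.
#' @param verbose Print progress per window size.
#'
#' @return A tibble of class `experiment_table`: one row per run with
#'   columns `behaviour`, `window_size`, `fold`, `iteration`, `auc`,
#'   `n_train` (post-SMOTE), `n_test`, `status`, and list columns
#'   `train_subjects` / `test_subjects` for subject-independence audits.
#'   The `cv_plan` attribute stores the fold assignment.
#' @export
run_experiment <- function(recordings, behaviours = NULL,
                           window_grid = default_window_grid(),
                           cv_plan = NULL, n_folds = 3, n_iterations = 10,
                           classifier = classifier_gbt(), smote = TRUE,
                           smote_k = 5, stats = default_stats(),
                           seed = 1L, verbose = FALSE) {
  if (is.data.frame(recordings)) recordings <- list(recordings)
  subjects <- vapply(recordings, function(r) as.character(r$subject_id[1]), "")
  if (anyDuplicated(subjects)) {
    stop("recordings must have unique subject ids", call. = FALSE)
  }
  if (is.null(cv_plan)) {
    cv_plan <- assign_folds(subjects, n_folds = n_folds, seed = seed)
  }
  n_folds <- attr(cv_plan, "n_folds")
  all_labels <- unique(unlist(lapply(recordings, function(r) r$label)))
  all_labels <- setdiff(all_labels, unlabelled_label())
  if (is.null(behaviours)) behaviours <- all_labels
  if (length(all_labels) < 2) {
    stop("need at least 2 behaviours present in the data", call. = FALSE)
  }

  rows <- list()
  for (size in window_grid) {
    if (verbose) message("window size ", size)
    feats <- extract_features(recordings, size = size, stats = stats)
    fcols <- feature_names(feats)
    fold_of <- cv_plan$fold[match(feats$subject_id, cv_plan$subject_id)]
    for (fold in seq_len(n_folds)) {
      is_test <- fold_of == fold
      x_tr <- feats[!is_test, fcols]
      x_te <- feats[is_test, fcols]
      lab_tr <- feats$label[!is_test]
      lab_te <- feats$label[is_test]
      tr_subj <- sort(unique(feats$subject_id[!is_test]))
      te_subj <- sort(unique(feats$subject_id[is_test]))
      for (bi in seq_along(behaviours)) {
        b <- behaviours[bi]
        y_tr <- binarise_labels(lab_tr, b)
        y_te <- binarise_labels(lab_te, b)
        for (it in seq_len(n_iterations)) {
          sub_seed <- derive_seed(seed, size, fold, bi, it)
          status <- "ok"
          auc <- NA_real_
          n_train <- length(y_tr)
          if (length(unique(y_te)) < 2) {
            status <- "degenerate_test"
          } else if (length(unique(y_tr)) < 2) {
            status <- "degenerate_train"
          } else {
            xt <- x_tr; yt <- y_tr
            if (smote) {
              if (min(table(y_tr)) < 2) {
                status <- "smote_skipped"
              } else {
                bal <- smote_balance(x_tr, y_tr, k = smote_k,
                                     seed = sub_seed)
                xt <- bal$x; yt <- bal$y
              }
            }
            n_train <- length(yt)
            model <- withr::with_seed(sub_seed,
                                      classifier$fit(xt, yt, seed = sub_seed))
            p <- classifier$predict(model, x_te)
            auc <- roc_auc(p, y_te)
          }
          rows[[length(rows) + 1]] <- tibble::tibble(
            behaviour = b, window_size = as.integer(size),
            fold = as.integer(fold), iteration = as.integer(it),
            auc = auc, n_train = as.integer(n_train),
            n_test = length(y_te), status = status,
            train_subjects = list(tr_subj), test_subjects = list(te_subj)
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, cv_plan = cv_plan, window_grid = as.integer(window_grid),
            behaviours = behaviours, seed = as.integer(seed),
            class = c("experiment_table", class(tibble::tibble())))
}

#' Audit subject independence of an experiment
#'
#' @param experiment An `experiment_table` from [run_experiment()].
#' @return Number of runs whose train and test subject sets overlap
#'   (0 for a valid subject-independent experiment).
#' @export
audit_subject_independence <- function(experiment) {
  overlaps <- purrr::map2_int(experiment$train_subjects,
                              experiment$test_subjects,
                              ~ length(intersect(.x, .y)))
  sum(overlaps > 0)
}

#' Train final one-vs-all models at behaviour-specific window sizes
#'
#' @param recordings List of [imu_recording()] objects (the training data).
#' @param windows Named integer vector: window size per behaviour.
#' @param classifier A [classifier_gbt()]-style specification.
#' @param smote,smote_k,stats,seed As in [run_experiment()].
#' @return A named list of class `ova_models`: per behaviour, the fitted
#'   model with its window size, stride and feature statistics.
#' @export
train_ova <- function(recordings, windows, classifier = classifier_gbt(),
                      smote = TRUE, smote_k = 5, stats = default_stats(),
                      seed = 1L) {
  if (is.data.frame(recordings)) recordings <- list(recordings)
  stopifnot(!is.null(names(windows)), all(names(windows) != ""))
  models <- purrr::imap(windows, function(size, b) {
    feats <- extract_features(recordings, size = size, stats = stats)
    fcols <- feature_names(feats)
    y <- binarise_labels(feats$label, b)
    if (length(unique(y)) < 2) {
      stop("behaviour '", b, "' is absent (or universal) in training data",
           call. = FALSE)
    }
    x <- feats[, fcols]
    sub_seed <- derive_seed(seed, size, match(b, names(windows)))
    if (smote && min(table(y)) >= 2) {
      bal <- smote_balance(x, y, k = smote_k, seed = sub_seed)
      x <- bal$x; y <- bal$y
    }
    model <- withr::with_seed(sub_seed, classifier$fit(x, y, seed = sub_seed))
    list(behaviour = b, model = model, size = as.integer(size),
         stride = default_stride(size), stats = stats,
         predict_fun = classifier$predict)
  })
  structure(models, classifier = classifier$label, class = "ova_models")
}

#' Predict a behaviour label per sample by combining one-vs-all models
#'
#' Each behaviour's model scores its own windowing of the recording; at
#' every sample index the predicted behaviour is the one whose model
#' assigns the highest probability among the windows covering that
#' sample (per model, the maximum over its covering windows). Ties are
#' broken by the fixed behaviour order of the model list. Samples covered
#' by no window (recording edges, or a recording shorter than the
#' smallest window) get `NA`.
#'
#' @param models An `ova_models` list from [train_ova()].
#' @param rec An [imu_recording()] to predict on (labels are ignored).
#' @return A tibble with columns `sample` (0-based) and `predicted`.
#' @export
predict_ova <- function(models, rec) {
  n <- nrow(rec)
  if (n < min(vapply(models, `[[`, integer(1), "size"))) {
    warning("recording shorter than the smallest model window; no predictions",
            call. = FALSE)
    return(tibble::tibble(sample = seq_len(n) - 1L,
                          predicted = NA_character_))
  }
  prob <- matrix(-Inf, n, length(models))
  colnames(prob) <- names(models)
  for (j in seq_along(models)) {
    m <- models[[j]]
    if (n < m$size) next
    rec_all <- rec
    rec_all$label <- rep("any", n) # keep every window for scoring
    feats <- extract_features(rec_all, size = m$size, stride = m$stride,
                              stats = m$stats)
    x <- feats[, feature_names(feats)]
    p_hat <- m$predict_fun(m$model, x)
    for (w in seq_along(p_hat)) {
      s <- feats$window_start[w]
      span <- (s + 1):(s + m$size)
      prob[span, j] <- pmax(prob[span, j], p_hat[w])
    }
  }
  covered <- rowSums(is.finite(prob)) > 0
  best <- apply(prob, 1, which.max) # ties: first (fixed behaviour order)
  tibble::tibble(
    sample = seq_len(n) - 1L,
    predicted = ifelse(covered, names(models)[best], NA_character_)
  )
}
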
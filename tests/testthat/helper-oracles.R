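# Independent oracles used across the suite. Each is a deliberately naive
# implementation kept separate from the package's code paths.

# Brute-force run-length encoding: scan sample by sample.
oracle_rle_bouts <- function(labels) {
  out <- list()
  i <- 1
  n <- length(labels)
  while (i <= n) {
    j <- i
    while (j < n && labels[j + 1] == labels[i]) j <- j + 1
    out[[length(out) + 1]] <- data.frame(
      behaviour = labels[i], start = i - 1L, end = j,
      length_samples = j - i + 1L, stringsAsFactors = FALSE)
    i <- j + 1
  }
  df <- do.call(rbind, out)
  df[df$behaviour != "unlabelled", , drop = FALSE]
}

# O(n^2) pairwise ROC AUC: count positive-over-negative pairs, ties 1/2.
oracle_pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Closed-form least squares for auc ~ 1 + w + w^2 via the normal equations.
oracle_quadratic_fit <- function(w, y) {
  X <- cbind(1, w, w^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  yhat <- X %*% beta
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(beta = as.numeric(beta), r_squared = 1 - ss_res / ss_tot)
}

# Naive descriptive statistics of one window slice.
oracle_window_stats <- function(x) {
  c(mean = mean(x),
    sd = if (length(x) > 1) sd(x) else 0,
    min = min(x), max = max(x), median = median(x))
}

# Naive central-difference gradient with one-sided ends.
oracle_gradient <- function(x) {
  n <- length(x)
  g <- numeric(n)
  for (i in seq_len(n)) {
    g[i] <- if (i == 1) x[2] - x[1]
    else if (i == n) x[n] - x[n - 1]
    else (x[i + 1] - x[i - 1]) / 2
  }
  g
}

# Small fully-labelled recording with deterministic channel values.
make_test_recording <- function(n = 100, labels = NULL, subject = "s1",
                                seed = 42) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * 13), n, 13)
    df <- tibble::as_tibble(m, .name_repair = "minimal")
    names(df) <- imu_channels()
    df$label <- if (is.null(labels)) rep("walk", n) else labels
    imu_recording(df, subject_id = subject)
  })
}
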
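#' Describe one behaviour for the collar-IMU simulator
#'
#' Each behaviour is parameterised by the signal family it produces
#' (`kind`) and by its bout-length distribution. Bout lengths are drawn
#' from a log-normal distribution parameterised directly by its median in
#' sample units, so the quantity the window-selection method targets is a
#' direct simulator input.
#'
#' @param name Behaviour name.
#' @param kind One of `"static"` (posture held still: gravity channels carry
#'   the posture vector, accelerometer channels carry only noise), `"gait"`
#'   (locomotion: sinusoidal acceleration and rotation-rate signals at
#'   `gait_freq_hz`), or `"burst"` (irregular activity: alternating quiet
#'   and high-variance sub-segments).
#' @param bout_median_samples Median bout length in samples (>= 1).
#' @param bout_sigma_log Log-normal shape parameter of the bout-length
#'   distribution; 0 gives every bout exactly the median length.
#' @param gait_freq_hz Fundamental gait (stride) frequency in Hz (gait
#'   kind only).
#' @param duty_cycle Fraction of each stride period during which the gait
#'   oscillation is active (gait kind only). 1 gives a continuous
#'   sinusoid; values below 1 give intermittent stepping — bursts of the
#'   carrier oscillation separated by quiet phases, as in slow ambling
#'   locomotion.
#' @param carrier_freq_hz Frequency of the oscillation inside active
#'   phases; defaults to `gait_freq_hz` (continuous gaits).
#' @param acc_amplitude Peak acceleration amplitude in simulator units.
#' @param amp_sigma_log Log-normal shape of the per-bout amplitude factor
#'   (0 = every bout at exactly `acc_amplitude`); models bout-to-bout
#'   variation in movement vigour.
#' @param noise_sd Standard deviation of additive Gaussian sensor noise.
#' @param posture_gravity Unit 3-vector giving the baseline collar
#'   orientation (the constant component of the gravity channels).
#'
#' @return A list of class `behaviour_model`.
#' @export
behaviour_model <- function(name, kind = c("static", "gait", "burst"),
                            bout_median_samples, bout_sigma_log = 0.6,
                            gait_freq_hz = NA_real_, acc_amplitude = 0,
                            noise_sd = 0.05,
                            posture_gravity = c(0, 0, 1),
                            duty_cycle = 1, carrier_freq_hz = NA_real_,
                            amp_sigma_log = 0) {
  kind <- match.arg(kind)
  stopifnot(bout_median_samples >= 1, bout_sigma_log >= 0,
            acc_amplitude >= 0, noise_sd >= 0,
            length(posture_gravity) == 3,
            duty_cycle > 0, duty_cycle <= 1, amp_sigma_log >= 0)
  if (is.na(carrier_freq_hz)) carrier_freq_hz <- gait_freq_hz
  nrm <- sqrt(sum(posture_gravity^2))
  if (abs(nrm - 1) > 1e-6) {
    stop("posture_gravity must have unit norm (got ", signif(nrm, 6), ")",
         call. = FALSE)
  }
  if (kind == "gait" && (is.na(gait_freq_hz) || gait_freq_hz <= 0)) {
    stop("gait behaviours need a positive gait_freq_hz", call. = FALSE)
  }
  structure(list(name = name, kind = kind,
                 bout_median_samples = bout_median_samples,
                 bout_sigma_log = bout_sigma_log,
                 gait_freq_hz = gait_freq_hz,
                 duty_cycle = duty_cycle,
                 carrier_freq_hz = carrier_freq_hz,
                 amp_sigma_log = amp_sigma_log,
                 acc_amplitude = acc_amplitude,
                 noise_sd = noise_sd,
                 posture_gravity = posture_gravity),
            class = "behaviour_model")
}

#' Configure a simulated collar-IMU study
#'
#' @param behaviours List of [behaviour_model()] objects (at least one; a
#'   single behaviour is allowed for degenerate checks, in which case the
#'   transition rule is vacuous).
#' @param n_subjects Number of simulated subjects.
#' @param duration_samples Recording length per subject in samples; must be
#'   at least the largest configured bout median.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param subject_gain_sd Standard deviation (log scale) of the per-subject
#'   multiplicative gain applied to dynamic signal components; models
#'   device placement and animal size differences.
#' @param seed Master seed; subject `i` uses the derived stream `seed + i`.
#'
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(behaviours, n_subjects = 9,
                              duration_samples = 36000,
                              sample_rate_hz = 50, subject_gain_sd = 0.1,
                              seed = 1L) {
  if (length(behaviours) < 1) stop("need at least one behaviour", call. = FALSE)
  stopifnot(all(vapply(behaviours, inherits, logical(1), "behaviour_model")))
  if (duration_samples < 1) stop("duration_samples must be >= 1", call. = FALSE)
  max_med <- max(vapply(behaviours, `[[`, numeric(1), "bout_median_samples"))
  if (duration_samples < max_med) {
    stop("duration_samples (", duration_samples,
         ") is below the largest bout median (", max_med, ")", call. = FALSE)
  }
  nm <- vapply(behaviours, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("behaviour names must be unique", call. = FALSE)
  names(behaviours) <- nm
  structure(list(behaviours = behaviours, n_subjects = n_subjects,
                 duration_samples = duration_samples,
                 sample_rate_hz = sample_rate_hz,
                 subject_gain_sd = subject_gain_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw bout lengths for a behaviour
#'
#' Lengths are log-normal with log-median `log(bout_median_samples)` and
#' shape `bout_sigma_log`, rounded to the nearest integer with a floor of
#' one sample. Uses the current RNG stream.
#'
#' @param model A [behaviour_model()].
#' @param n Number of draws.
#' @return Integer vector of bout lengths (all >= 1).
#' @export
sample_bout_length <- function(model, n = 1) {
  len <- stats::rlnorm(n, meanlog = log(model$bout_median_samples),
                       sdlog = model$bout_sigma_log)
  pmax(1L, as.integer(round(len)))
}

# Behaviour label track: uniform Markov transitions excluding
# self-transitions, so adjacent bouts never share a label.
simulate_label_track <- function(cfg) {
  models <- cfg$behaviours
  k <- length(models)
  labels <- character(0)
  bout_ids <- integer(0)
  current <- sample.int(k, 1)
  bout <- 0L
  while (length(labels) < cfg$duration_samples) {
    bout <- bout + 1L
    len <- sample_bout_length(models[[current]], 1)
    labels <- c(labels, rep(names(models)[current], len))
    bout_ids <- c(bout_ids, rep(bout, len))
    if (k > 1) {
      nxt <- sample.int(k - 1, 1)
      current <- setdiff(seq_len(k), current)[nxt]
    }
  }
  n <- cfg$duration_samples
  list(labels = labels[seq_len(n)], bout_ids = bout_ids[seq_len(n)])
}

simulate_bout_signal <- function(model, len, sr, gain) {
  t <- (seq_len(len) - 1) / sr
  noise <- function(sd) stats::rnorm(len, 0, sd)
  acc <- matrix(0, len, 3)
  rot <- matrix(0, len, 3)
  grav <- matrix(rep(model$posture_gravity, each = len), len, 3)
  grav <- grav + matrix(stats::rnorm(3 * len, 0, 0.5 * model$noise_sd), len, 3)

  bout_amp <- model$acc_amplitude *
    if (model$amp_sigma_log > 0) stats::rlnorm(1, 0, model$amp_sigma_log) else 1
  if (model$kind == "static") {
    acc[] <- stats::rnorm(3 * len, 0, gain * model$noise_sd)
    rot[] <- stats::rnorm(3 * len, 0, gain * model$noise_sd)
  } else if (model$kind == "gait") {
    phi <- stats::runif(1, 0, 2 * pi)
    # active/quiet gating at the stride frequency (continuous when duty = 1)
    stride_phase <- (model$gait_freq_hz * t + phi / (2 * pi)) %% 1
    a <- gain * bout_amp * as.numeric(stride_phase < model$duty_cycle)
    w <- 2 * pi * model$carrier_freq_hz
    acc[, 1] <- a * sin(w * t + phi) + noise(gain * model$noise_sd)
    acc[, 2] <- 0.6 * a * sin(w * t + phi + pi / 2) + noise(gain * model$noise_sd)
    # vertical axis oscillates at twice the carrier frequency (footfalls)
    acc[, 3] <- 0.8 * a * sin(2 * w * t + phi) + noise(gain * model$noise_sd)
    rot[, 1] <- 0.5 * a * sin(w * t + phi + pi / 3) + noise(gain * model$noise_sd)
    rot[, 2] <- 0.4 * a * sin(w * t + phi + 2 * pi / 3) + noise(gain * model$noise_sd)
    rot[, 3] <- 0.3 * a * sin(w * t + phi + pi) + noise(gain * model$noise_sd)
  } else { # burst: alternating quiet / high-variance sub-segments
    seg <- max(5L, as.integer(round(0.5 * sr)))
    active <- (((seq_len(len) - 1) %/% seg) %% 2) == 0
    sd_vec <- ifelse(active, gain * (bout_amp + model$noise_sd),
                     gain * model$noise_sd)
    for (j in 1:3) acc[, j] <- stats::rnorm(len, 0, sd_vec)
    for (j in 1:3) rot[, j] <- stats::rnorm(len, 0, 0.5 * sd_vec)
  }
  cbind(acc, grav, rot)
}

#' Generate one subject's labelled recording
#'
#' Bouts are concatenated until the configured duration is reached (the
#' final bout is truncated, mirroring a recording that ends mid-behaviour).
#' Labels match the generating behaviour exactly, sample by sample. The
#' attitude quaternion performs a slow random walk renormalised to unit
#' norm at every sample. A per-subject multiplicative gain
#' `exp(N(0, subject_gain_sd))` scales all dynamic signal components.
#' Deterministic given `cfg$seed` and `subject_index` (stream
#' `seed + subject_index`).
#'
#' @param cfg A [simulation_config()].
#' @param subject_index Positive integer; also names the subject
#'   (`"subj<i>"`).
#' @return An [imu_recording()].
#' @export
generate_recording <- function(cfg, subject_index = 1L) {
  stopifnot(inherits(cfg, "sim_config"), subject_index >= 1)
  withr::with_seed(cfg$seed + as.integer(subject_index), {
    gain <- exp(stats::rnorm(1, 0, cfg$subject_gain_sd))
    track <- simulate_label_track(cfg)
    n <- cfg$duration_samples
    sig <- matrix(0, n, 9)
    runs <- rle(track$bout_ids)
    pos <- 1L
    for (r in seq_along(runs$lengths)) {
      len <- runs$lengths[r]
      model <- cfg$behaviours[[track$labels[pos]]]
      sig[pos:(pos + len - 1), ] <-
        simulate_bout_signal(model, len, cfg$sample_rate_hz, gain)
      pos <- pos + len
    }
    # slow attitude random walk, unit-renormalised each sample
    q <- matrix(0, n, 4)
    cur <- c(0, 0, 0, 1)
    steps <- matrix(stats::rnorm(4 * n, 0, 0.005), n, 4)
    for (i in seq_len(n)) {
      cur <- cur + steps[i, ]
      cur <- cur / sqrt(sum(cur^2))
      q[i, ] <- cur
    }
    samples <- tibble::as_tibble(cbind(sig, q), .name_repair = "minimal")
    names(samples) <- imu_channels()
    samples$label <- track$labels
    imu_recording(samples, subject_id = paste0("subj", subject_index),
                  sample_rate_hz = cfg$sample_rate_hz)
  })
}

#' Generate recordings for every subject in a study configuration
#'
#' @param cfg A [simulation_config()].
#' @return A named list of [imu_recording()] objects, one per subject.
#' @export
simulate_study <- function(cfg) {
  recs <- purrr::map(seq_len(cfg$n_subjects),
                     function(i) generate_recording(cfg, i))
  names(recs) <- paste0("subj", seq_len(cfg$n_subjects))
  recs
}

#' Default seven-behaviour study configuration
#'
#' Emulates a multi-subject collar study of freely moving dogs: seven
#' behaviours (stand, sit, lie, eat, walk, trot, run) with bout medians of
#' 77, 174, 293, 366, 62, 85 and 66 samples respectively at 50 Hz. The
#' postural behaviours are static signal families, eat is a burst family
#' (intermittent head movement), and the three gaits carry sinusoidal
#' signatures with increasing fundamental frequency (walk 1.5 Hz, trot
#' 2.5 Hz, run 3.5 Hz) and amplitude.
#'
#' @param seed Master seed.
#' @param n_subjects Number of subjects (default 9, enough for a meaningful
#'   3-fold subject-level split).
#' @param duration_samples Samples per subject (default 36000 = 12 min).
#' @return A [simulation_config()].
#' @export
default_study_config <- function(seed = 1L, n_subjects = 9,
                                 duration_samples = 36000) {
  tilt <- function(deg) c(0, sin(deg * pi / 180), cos(deg * pi / 180))
  behaviours <- list(
    behaviour_model("stand", "static", 77,  noise_sd = 0.05),
    behaviour_model("sit",   "static", 174, noise_sd = 0.05,
                    posture_gravity = tilt(30)),
    behaviour_model("lie",   "static", 293, noise_sd = 0.04,
                    posture_gravity = tilt(75)),
    behaviour_model("eat",   "burst",  366, acc_amplitude = 0.4,
                    noise_sd = 0.08, posture_gravity = tilt(45)),
    behaviour_model("walk",  "gait",   62,  gait_freq_hz = 1.5,
                    acc_amplitude = 0.4, noise_sd = 0.1),
    behaviour_model("trot",  "gait",   85,  gait_freq_hz = 2.5,
                    acc_amplitude = 0.8, noise_sd = 0.1),
    behaviour_model("run",   "gait",   66,  gait_freq_hz = 3.5,
                    acc_amplitude = 1.2, noise_sd = 0.12)
  )
  simulation_config(behaviours, n_subjects = n_subjects,
                    duration_samples = duration_samples, seed = seed)
}

#' Two-gait demonstration configuration with contrasting bout lengths
#'
#' A compact study designed to exhibit the bout-length/window-size
#' phenomenon end to end: a fast continuous gait (3 Hz, strong per-bout
#' amplitude jitter) with short bouts (median 60 samples), a slow
#' intermittent gait (stride rate 0.125 Hz — a 400-sample period —
#' carrying 3 Hz bursts at 50% duty cycle) with long bouts (median 300
#' samples), and a long-bouted static resting background (median 800
#' samples). A short window falls inside either a quiet or an active
#' phase of the slow gait and is then indistinguishable from resting or
#' from a vigour-jittered fast-gait window respectively — only windows
#' long enough to straddle the phase alternation reveal the slow gait —
#' while windows much longer than the fast gait's bouts are contaminated
#' by neighbouring behaviour under last-sample labelling. Together these
#' push each behaviour's AUC optimum towards its own bout median.
#'
#' @param seed Master seed.
#' @param n_subjects Number of subjects (default 6: two per fold in a
#'   3-fold subject split).
#' @param duration_samples Samples per subject (default 9000 = 3 min).
#' @return A [simulation_config()].
#' @export
two_gait_demo_config <- function(seed = 1L, n_subjects = 6,
                                 duration_samples = 9000) {
  behaviours <- list(
    behaviour_model("fastgait", "gait", 60, bout_sigma_log = 0.35,
                    gait_freq_hz = 3, acc_amplitude = 0.6,
                    amp_sigma_log = 0.5, noise_sd = 0.3),
    behaviour_model("slowgait", "gait", 300, bout_sigma_log = 0.25,
                    gait_freq_hz = 0.125, duty_cycle = 0.5,
                    carrier_freq_hz = 3, acc_amplitude = 0.8,
                    amp_sigma_log = 0.25, noise_sd = 0.3),
    behaviour_model("other", "static", 800, bout_sigma_log = 0.35,
                    noise_sd = 0.3)
  )
  simulation_config(behaviours, n_subjects = n_subjects,
                    duration_samples = duration_samples,
                    subject_gain_sd = 0.1, seed = seed)
}
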
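#' Synthetic sEMG generator configuration
#'
#' Emulates the structure of Ninapro DB1: 10 electrode channels sampled at
#' 100 Hz, 52 gestures plus rest (G = 53), 10 repetitions of each per
#' subject. Each gesture owns a fixed per-channel activation amplitude
#' pattern; a smooth rise-hold-fall envelope built from it modulates
#' band-limited Gaussian noise (20-45 Hz, the bulk of surface-EMG power
#' representable at 100 Hz) riding on a baseline noise floor. Repetitions
#' share the gesture's pattern with amplitude and duration jitter; rest
#' sequences are noise floor only. `difficulty` blends every gesture's
#' amplitude pattern towards the across-gesture mean, shrinking class
#' separation: 0 gives well-separated classes, 1 makes all gestures share
#' one pattern.
#'
#' @param n_subjects Number of subjects.
#' @param n_gestures Number of non-rest gestures (labels `1..n_gestures`;
#'   G = `n_gestures + 1`).
#' @param n_repetitions Repetitions per gesture and subject.
#' @param channels Electrode channels.
#' @param rate Sampling rate in Hz.
#' @param duration_s Mean gesture duration in seconds.
#' @param duration_jitter Relative duration jitter (uniform, +/- fraction).
#' @param noise_floor Baseline noise standard deviation (normalized sensor
#'   units).
#' @param difficulty Envelope-overlap parameter in `[0, 1]`.
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 2L, n_gestures = 52L,
                         n_repetitions = 10L, channels = 10L, rate = 100,
                         duration_s = 5, duration_jitter = 0.1,
                         noise_floor = 0.05, difficulty = 0, seed = 1L) {
  if (difficulty < 0 || difficulty > 1) stopf("'difficulty' must lie in [0, 1]")
  for (v in c(n_subjects, n_gestures, n_repetitions, channels))
    if (!is_count(v)) stopf("counts must be positive integers")
  if (rate <= 0) stopf("'rate' must be positive")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_gestures = as.integer(n_gestures),
                 n_repetitions = as.integer(n_repetitions),
                 channels = as.integer(channels), rate = rate,
                 duration_s = duration_s, duration_jitter = duration_jitter,
                 noise_floor = noise_floor, difficulty = difficulty,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Smooth rise-hold-fall window: raised-cosine ramps over 15% of the
# duration at each end.
rise_hold_fall <- function(n, ramp_frac = 0.15) {
  nr <- max(1L, round(n * ramp_frac))
  env <- rep(1, n)
  up <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
  env[seq_len(nr)] <- up
  env[n + 1L - seq_len(nr)] <- up
  env
}

# Band-limited Gaussian noise via a 4th-order Butterworth band-pass.
bandlimited_noise <- function(n, rate, band = c(20, 45)) {
  ny <- rate / 2
  bf <- signal::butter(4, pmin(band / ny, 0.99), type = "pass")
  x <- rnorm(n + 200L)                 # pad to wash out filter transients
  y <- signal::filtfilt(bf, x)[101L:(100L + n)]
  y / sd(y)
}

#' Generate a DB1-structured synthetic dataset
#'
#' See [synth_config()] for the signal model. The layout mirrors DB1:
#' for each subject, every label 0..G-1 (0 = rest) appears with
#' repetitions 1..`n_repetitions`, so the canonical 7/3 repetition split
#' of the default configuration yields 53 x 7 = 371 training sequences
#' per subject.
#'
#' @param cfg A [synth_config()].
#' @return A [gesture_dataset()].
#' @export
generate_dataset <- function(cfg = synth_config()) {
  withr::with_seed(cfg$seed, {
    G <- cfg$n_gestures + 1L
    C <- cfg$channels
    # fixed per-gesture per-channel activation amplitudes (rest = 0)
    amps <- matrix(0, G, C)
    for (g in 2:G) amps[g, ] <- runif(C, 0, 1)^2 * 2
    blended <- (1 - cfg$difficulty) * amps +
      cfg$difficulty * matrix(colMeans(amps[-1L, , drop = FALSE]),
                              G, C, byrow = TRUE)
    blended[1L, ] <- 0                  # rest stays silent
    seqs <- list()
    for (subj in seq_len(cfg$n_subjects)) {
      for (g in 0:(G - 1L)) {
        for (rep_i in seq_len(cfg$n_repetitions)) {
          dur <- cfg$duration_s *
            (1 + runif(1, -cfg$duration_jitter, cfg$duration_jitter))
          N <- max(8L, round(dur * cfg$rate))
          env <- rise_hold_fall(N)
          amp_jit <- rnorm(1, 1, 0.05)
          x <- matrix(0, N, C)
          for (c in seq_len(C)) {
            carrier <- bandlimited_noise(N, cfg$rate)
            x[, c] <- blended[g + 1L, c] * amp_jit * env * carrier +
              rnorm(N, sd = cfg$noise_floor)
          }
          seqs[[length(seqs) + 1L]] <- emg_sequence(
            x, rate = cfg$rate, label = g, repetition = rep_i,
            subject = subj)
        }
      }
    }
    gesture_dataset(seqs, n_labels = G)
  })
}

#' Deterministic label-stream fixture
#'
#' Concatenates runs of labels with given counts, producing a
#' [prediction_stream()] for exact vote-classifier scenarios.
#'
#' @param truth Ground-truth label of the stream.
#' @param schedule List of `c(label, count)` pairs (or a 2-column matrix).
#' @param rate Sampling rate in Hz.
#' @return A [prediction_stream()] (possibly of length 0).
#' @export
generate_label_stream <- function(truth, schedule, rate = 100) {
  if (is.matrix(schedule))
    schedule <- lapply(seq_len(nrow(schedule)), function(i) schedule[i, ])
  preds <- unlist(lapply(schedule, function(p) {
    if (p[2L] < 0) stopf("run counts must be >= 0")
    rep(as.integer(p[1L]), p[2L])
  }))
  prediction_stream(preds %||% integer(), truth = truth, rate = rate)
}
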
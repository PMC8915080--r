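#' Augmentation configuration
#'
#' Bundles the hyperparameters of the three sEMG augmentation operators and
#' the expansion factor. Defaults are the values found effective for small
#' DB1 training sets: wavelet-domain perturbation with sym4 at levels
#' 2/3/4 and perturbation magnitudes b in \{0, 2.5, 5\} applied with
#' probability 0.75; magnitude warping with sigma 0.2 at probability 0.75;
#' additive Gaussian noise at 30 dB SNR with probability 0.25; expansion
#' factor 10.
#'
#' @param wd List with `wavelets` (character), `levels` (integers), `b`
#'   (numeric magnitudes) and `p` (apply probability).
#' @param mw List with `sigma` and `p`.
#' @param gn List with `snr_db` and `p`.
#' @param factor Integer dataset multiplier (>= 1).
#' @param seed Integer seed making [build_augmented_set()] fully
#'   deterministic.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(
    wd = list(wavelets = "sym4", levels = c(2L, 3L, 4L), b = c(0, 2.5, 5), p = 0.75),
    mw = list(sigma = 0.2, p = 0.75),
    gn = list(snr_db = 30, p = 0.25),
    factor = 10L, seed = 1L) {
  for (p in c(wd$p, mw$p, gn$p))
    if (p < 0 || p > 1) stopf("apply probabilities must lie in [0, 1]")
  if (!is_count(factor)) stopf("'factor' must be a positive integer")
  if (!is.finite(gn$snr_db)) stopf("'snr_db' must be finite")
  structure(list(wd = wd, mw = mw, gn = gn, factor = as.integer(factor),
                 seed = as.integer(seed)),
            class = "augmentation_config")
}

#' Additive Gaussian noise at a target SNR
#'
#' Adds zero-mean white Gaussian noise to every channel, scaled per channel
#' (over the whole sequence) so that
#' `10 * log10(signal power / noise power) = snr_db`. Channels with zero
#' power receive no noise; a sequence with zero power on every channel has
#' no defined SNR and is an error.
#'
#' @param seq An [emg_sequence()].
#' @param snr_db Target signal-to-noise ratio in decibels.
#' @param seed Optional integer seed; the caller's RNG stream is untouched
#'   when given, consumed otherwise.
#' @return A new [emg_sequence()] with identical metadata.
#' @export
augment_gn <- function(seq, snr_db = 30, seed = NULL) {
  x <- seq$samples
  pow <- colMeans(x^2)
  if (all(pow == 0)) stopf("all-zero signal: SNR is undefined")
  with_opt_seed(seed, {
    noise_sd <- sqrt(pow / 10^(snr_db / 10))
    noise <- matrix(rnorm(length(x)), nrow(x), ncol(x)) *
      rep(noise_sd, each = nrow(x))
    seq$samples <- x + noise
  })
  seq
}

# Smooth random gain curve: cubic spline through knots ~ Normal(1, sigma^2)
# placed every ~N/4 samples (ends included).
mw_curve <- function(n, sigma) {
  n_knots <- 5L  # both ends included -> knot spacing ~ N/4
  kx <- seq(1L, n, length.out = n_knots)
  ky <- rnorm(n_knots, mean = 1, sd = sigma)
  spline(kx, ky, xout = seq_len(n), method = "natural")$y
}

#' Magnitude warping
#'
#' Multiplies each channel pointwise by an independent smooth random gain
#' curve: a natural cubic spline through knots drawn from
#' `Normal(1, sigma^2)` at evenly spaced positions (spacing about N/4).
#' `sigma = 0` is the identity.
#'
#' @inheritParams augment_gn
#' @param sigma Standard deviation of the knot values (>= 0).
#' @export
augment_mw <- function(seq, sigma = 0.2, seed = NULL) {
  if (sigma < 0) stopf("'sigma' must be non-negative")
  x <- seq$samples
  with_opt_seed(seed, {
    for (c in seq_len(ncol(x))) x[, c] <- x[, c] * mw_curve(nrow(x), sigma)
  })
  seq$samples <- x
  seq
}

#' Wavelet-domain perturbation
#'
#' Per channel: multilevel periodized DWT (depth `max(levels)`), detail
#' coefficients at each selected level multiplied by a random factor
#' `1 + U(-b, b) / 10` (one factor per channel and level), inverse
#' transform, truncation back to N samples. `b = 0` reduces to
#' decompose-reconstruct and is the identity up to reconstruction tolerance.
#'
#' @inheritParams augment_gn
#' @param wavelet Wavelet name (see [wave_decompose()]).
#' @param levels Integer decomposition level(s) whose detail coefficients
#'   are perturbed.
#' @param b Perturbation magnitude (>= 0).
#' @export
augment_wd <- function(seq, wavelet = "sym4", levels = c(2L, 3L, 4L), b = 2.5,
                       seed = NULL) {
  if (b < 0) stopf("'b' must be non-negative")
  levels <- as.integer(levels)
  depth <- max(levels)
  x <- seq$samples
  with_opt_seed(seed, {
    for (c in seq_len(ncol(x))) {
      dec <- wave_decompose(x[, c], wavelet = wavelet, level = depth)
      for (l in levels) dec$d[[l]] <- dec$d[[l]] * (1 + runif(1, -b, b) / 10)
      x[, c] <- wave_reconstruct(dec)
    }
  })
  seq$samples <- x
  seq
}

#' Expand a training set by stochastic augmentation
#'
#' Produces `factor` copies of the input: copy 1 is the originals; each
#' further copy passes every sequence through the operator chain
#' WD -> MW -> GN, each operator applied independently with its configured
#' probability, with wavelet, level and b sampled uniformly from their
#' configured lists per application. Amplitude noise comes last so the SNR
#' is measured against the already-warped signal. The whole expansion is a
#' deterministic function of `cfg$seed`.
#'
#' @param train A [gesture_dataset()].
#' @param cfg An [augmentation_config()].
#' @return A [gesture_dataset()] with `factor * length(train)` sequences.
#' @export
build_augmented_set <- function(train, cfg = augmentation_config()) {
  out <- train$sequences
  withr::with_seed(cfg$seed, {
    for (copy in seq_len(cfg$factor - 1L)) {
      for (s in train$sequences) {
        if (runif(1) < cfg$wd$p) {
          pick <- function(v) v[sample.int(length(v), 1L)]
          s <- augment_wd(s, wavelet = pick(cfg$wd$wavelets),
                          levels = pick(cfg$wd$levels), b = pick(cfg$wd$b))
        }
        if (runif(1) < cfg$mw$p) s <- augment_mw(s, sigma = cfg$mw$sigma)
        if (runif(1) < cfg$gn$p) s <- augment_gn(s, snr_db = cfg$gn$snr_db)
        out[[length(out) + 1L]] <- s
      }
    }
  })
  gesture_dataset(out, n_labels = train$n_labels)
}
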
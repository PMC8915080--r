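# Fixture builders and independent oracles shared across tests.

# Small deterministic dataset: `reps` repetitions of each label 0..G-1,
# white-noise samples (structure-only fixture, classes not separable).
toy_dataset <- function(G = 3L, reps = 2L, N = 30L, C = 2L, rate = 100,
                        seed = 99L, subject = 1L) {
  withr::with_seed(seed, {
    seqs <- list()
    for (g in 0:(G - 1L)) {
      for (r in seq_len(reps)) {
        seqs[[length(seqs) + 1L]] <- emg_sequence(
          matrix(rnorm(N * C), N, C), rate = rate, label = g,
          repetition = r, subject = subject)
      }
    }
    gesture_dataset(seqs, n_labels = G)
  })
}

# Tiny randomly initialized model for structural tests.
toy_model <- function(G = 3L, C = 2L, head = "aot", layers = 2L,
                      filters = c(4L, 5L), seed = 7L, dropout_rate = 0.05,
                      activation = "relu") {
  cfg <- tcn_config(layers = layers, filters = filters, n_labels = G,
                    channels = C, head = head, dropout_rate = dropout_rate,
                    activation = activation)
  tcn_init(cfg, seed = seed)
}

# Brute-force dilated causal convolution straight from the defining sum:
# y[n] = sum_i x[n - d*i] * h[i], zeros before the start. Single channel.
conv_oracle <- function(x, taps, d) {
  N <- length(x)
  y <- numeric(N)
  for (n in seq_len(N)) {
    for (i in seq_along(taps)) {
      src <- n - d * (i - 1L)
      if (src >= 1L) y[n] <- y[n] + x[src] * taps[i]
    }
  }
  y
}

# Independent vote-classifier oracle: explicit per-label counting scan over
# the trailing window, same tie rule (tau-th most recent occurrence latest).
vote_oracle <- function(preds, win, tau) {
  vapply(seq_along(preds), function(n) {
    w <- preds[max(1L, n - win + 1L):n]
    labs <- unique(w)
    cnt <- vapply(labs, function(l) sum(w == l), integer(1))
    mx <- max(cnt)
    if (mx < tau) return(-1L)
    cand <- labs[cnt == mx]
    if (length(cand) > 1L) {
      pos <- vapply(cand, function(l) {
        occ <- which(w == l)
        occ[length(occ) - tau + 1L]
      }, integer(1))
      cand <- cand[which.max(pos)]
    }
    as.integer(cand)
  }, integer(1))
}

# Write a toy DB1-style record directory; `runs` is a data.frame with
# columns label, repetition, n. Returns the directory path.
write_toy_record <- function(runs, C = 2L, rate = 100, dir = tempfile()) {
  dir.create(dir)
  stim <- rep(runs$label, runs$n)
  reps <- rep(runs$repetition, runs$n)
  n_tot <- length(stim)
  set.seed(4)
  emg <- matrix(round(rnorm(n_tot * C), 6), n_tot, C)
  write.table(emg, file.path(dir, "emg.csv"), sep = ",", row.names = FALSE,
              col.names = FALSE)
  write.table(stim, file.path(dir, "stimulus.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  write.table(reps, file.path(dir, "repetition.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(rate = rate), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  dir
}
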
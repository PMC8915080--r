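#' Training configuration
#'
#' Defaults follow the published DB1 protocol: Adam for up to 100 epochs
#' with early stopping, constant learning rate 0.01, batch size 128 and
#' dropout 0.05. The early-stopping criterion (validation loss on a
#' stratified 10% hold-out of the training sequences, patience 10, best
#' weights restored) is this package's choice. `mode = "window"` trains on
#' 200 ms sliding windows (20 samples, step 1 at 100 Hz) instead of full
#' sequences.
#'
#' @param epochs Maximum number of epochs.
#' @param learning_rate Constant Adam learning rate.
#' @param batch_size Sequences per gradient step.
#' @param patience Early-stopping patience in epochs; `Inf` disables early
#'   stopping.
#' @param validation_fraction Fraction of training sequences held out
#'   (stratified by label) to monitor validation loss; 0 disables the
#'   hold-out and early stopping monitors training loss.
#' @param mode `"sequence"` (full repetitions) or `"window"` (sliding
#'   windows).
#' @param window,step Sliding-window length and stride in samples (used in
#'   `"window"` mode).
#' @param seed Integer seed controlling shuffling, dropout and the
#'   validation split; a fixed seed makes training bit-reproducible.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, learning_rate = 0.01,
                         batch_size = 128L, patience = 10L,
                         validation_fraction = 0.1,
                         mode = c("sequence", "window"),
                         window = 20L, step = 1L, seed = 1L) {
  mode <- match.arg(mode)
  if (!is_count(epochs)) stopf("'epochs' must be a positive integer")
  if (!is_count(batch_size)) stopf("'batch_size' must be a positive integer")
  if (!is_count(window) || !is_count(step))
    stopf("'window' and 'step' must be positive integers")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), patience = patience,
                 validation_fraction = validation_fraction, mode = mode,
                 window = as.integer(window), step = as.integer(step),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Cut sequences into fixed-length sliding windows
#'
#' Each sequence of length `N >= window` yields
#' `floor((N - window) / step) + 1` segments inheriting the parent label,
#' repetition and subject. Sequences shorter than `window` are skipped with
#' a message reporting the count.
#'
#' @param dataset A [gesture_dataset()].
#' @param window Window length in samples.
#' @param step Stride in samples.
#' @return A [gesture_dataset()] of window segments.
#' @export
make_sliding_windows <- function(dataset, window = 20L, step = 1L) {
  if (!is_count(window) || !is_count(step))
    stopf("'window' and 'step' must be positive integers")
  out <- list()
  skipped <- 0L
  for (s in dataset$sequences) {
    N <- nrow(s$samples)
    if (N < window) { skipped <- skipped + 1L; next }
    starts <- seq.int(1L, N - window + 1L, by = step)
    for (st in starts) {
      w <- s
      w$samples <- s$samples[st:(st + window - 1L), , drop = FALSE]
      out[[length(out) + 1L]] <- w
    }
  }
  if (skipped > 0L)
    message(sprintf("make_sliding_windows: skipped %d sequence(s) shorter than %d samples",
                    skipped, window))
  if (length(out) == 0L) stopf("no sequence is at least %d samples long", window)
  gesture_dataset(out, n_labels = dataset$n_labels)
}

# Stratified hold-out indices: about `fraction` of each label's sequences,
# at least one per label when the label has >= 2 sequences.
stratified_holdout <- function(labels, fraction) {
  val <- integer()
  for (g in unique(labels)) {
    idx <- which(labels == g)
    n_val <- floor(length(idx) * fraction)
    if (n_val == 0L && length(idx) >= 2L && fraction > 0) n_val <- 1L
    if (n_val > 0L) val <- c(val, sample(idx, n_val))
  }
  sort(val)
}

adam_step <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$delta <- -lr * mhat / (sqrt(vhat) + eps)
  state
}

eval_loss_on <- function(model, mats, labels, class_w, batch_size) {
  tot_loss <- 0; tot_w <- 0; n_ok <- 0L
  for (b0 in seq.int(1L, length(mats), by = batch_size)) {
    sel <- b0:min(b0 + batch_size - 1L, length(mats))
    pb <- pad_batch(mats[sel], ncol(mats[[1L]]))
    r <- tcn_loss_grad(model, pb$X, pb$mask, labels[sel], class_w,
                       training = FALSE, compute_grads = FALSE)
    w <- sum(class_w[labels[sel] + 1L])
    tot_loss <- tot_loss + r$loss * w
    tot_w <- tot_w + w
    n_ok <- n_ok + sum(top1_labels(r$probs) == labels[sel])
  }
  list(loss = tot_loss / tot_w, accuracy = n_ok / length(mats))
}

#' Train a TCN with Adam
#'
#' Minimizes class-weighted cross-entropy (weights inversely proportional
#' to per-label sequence counts, mean 1) with the Adam optimizer. A
#' stratified hold-out monitors validation loss for early stopping; the
#' weights of the best validation epoch are restored. Training is a
#' deterministic function of `cfg$seed`. A non-finite loss aborts with a
#' diagnostic.
#'
#' @param model A `tcn_model` (see [tcn_init()]).
#' @param train_set A [gesture_dataset()].
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch progress?
#' @return List of class `tcn_fit`: `model` (trained), `history`
#'   (data.frame epoch / train_loss / train_acc / val_loss / val_acc),
#'   `best_epoch`, `class_weights`.
#' @export
tcn_train <- function(model, train_set, cfg = train_config(),
                      verbose = FALSE) {
  if (length(train_set$sequences) == 0L) stopf("empty training set")
  if (cfg$mode == "window")
    train_set <- make_sliding_windows(train_set, cfg$window, cfg$step)
  class_w <- class_weights(train_set, n_labels = model$config$n_labels)
  labels_all <- dataset_labels0(train_set)
  mats_all <- lapply(train_set$sequences, function(s) s$samples)

  withr::with_seed(cfg$seed, {
    val_idx <- stratified_holdout(labels_all, cfg$validation_fraction)
    tr_idx <- setdiff(seq_along(mats_all), val_idx)
    mats <- mats_all[tr_idx]; labels <- labels_all[tr_idx]
    vmats <- mats_all[val_idx]; vlabels <- labels_all[val_idx]
    has_val <- length(val_idx) > 0L

    theta <- params_to_vector(model)
    st <- list(m = numeric(length(theta)), v = numeric(length(theta)), t = 0L)
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       train_acc = numeric(), val_loss = numeric(),
                       val_acc = numeric())
    best <- list(loss = Inf, theta = theta, epoch = 0L)
    stale <- 0L

    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(length(mats))
      ep_loss <- 0; ep_w <- 0; ep_ok <- 0L
      for (b0 in seq.int(1L, length(ord), by = cfg$batch_size)) {
        sel <- ord[b0:min(b0 + cfg$batch_size - 1L, length(ord))]
        pb <- pad_batch(mats[sel], model$config$channels)
        r <- tcn_loss_grad(model, pb$X, pb$mask, labels[sel], class_w,
                           training = TRUE)
        g <- grads_to_vector(model, r$grads)
        st <- adam_step(st, g, cfg$learning_rate)
        theta <- theta + st$delta
        model <- vector_to_params(model, theta)
        wb <- sum(class_w[labels[sel] + 1L])
        ep_loss <- ep_loss + r$loss * wb
        ep_w <- ep_w + wb
        ep_ok <- ep_ok + sum(top1_labels(r$probs) == labels[sel])
      }
      tr_loss <- ep_loss / ep_w
      tr_acc <- ep_ok / length(mats)
      if (has_val) {
        vl <- eval_loss_on(model, vmats, vlabels, class_w, cfg$batch_size)
      } else {
        vl <- list(loss = tr_loss, accuracy = tr_acc)
      }
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tr_loss,
                                     train_acc = tr_acc, val_loss = vl$loss,
                                     val_acc = vl$accuracy))
      if (verbose)
        message(sprintf("epoch %3d  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                        epoch, tr_loss, tr_acc, vl$loss, vl$accuracy))
      if (vl$loss < best$loss) {
        best <- list(loss = vl$loss, theta = theta, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= cfg$patience) break
      }
    }
    model <- vector_to_params(model, best$theta)
  })
  structure(list(model = model, history = hist, best_epoch = best$epoch,
                 class_weights = class_w),
            class = "tcn_fit")
}

#' @export
print.tcn_fit <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf("<tcn_fit> %d epoch(s), best epoch %d (val loss %.4f)\n",
              n, x$best_epoch, min(x$history$val_loss)))
  invisible(x)
}

#' Serialize a training history
#'
#' @param fit A `tcn_fit`.
#' @param path JSON file path.
#' @return The path, invisibly.
#' @export
write_history <- function(fit, path) {
  jsonlite::write_json(list(best_epoch = fit$best_epoch,
                            history = fit$history),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
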
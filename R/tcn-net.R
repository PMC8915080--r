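# Forward pass of the TCN. Batches are dense arrays of shape
# (N_max, B, K) with a logical validity mask (N_max, B): sequences shorter
# than N_max are zero-padded at the tail and the padded timesteps are
# masked so they never enter the pooling heads. Causal convolutions only
# look backwards, so tail padding cannot leak into valid timesteps either;
# together this makes a padded-batch forward bit-compatible with solo
# forwards.

flat2 <- function(A) {
  d <- dim(A)
  dim(A) <- c(d[1L] * d[2L], d[3L])
  A
}

unflat2 <- function(M, N, B) {
  dim(M) <- c(N, B, ncol(M))
  M
}

# Causal dilated convolution on a batch array (N, B, Kin) -> (N, B, Kout).
# Tap i (0-based) reads the input delayed by d*i samples; indices before the
# sequence start are zero (left zero-padding), so output n depends only on
# inputs at n, n-d, ..., n-2pd.
conv_causal_batch <- function(X, kernel, bias, d) {
  dms <- dim(X)
  N <- dms[1L]; B <- dms[2L]; kin <- dms[3L]
  ntaps <- dim(kernel)[1L]
  kout <- dim(kernel)[3L]
  Yf <- matrix(rep(bias, each = N * B), N * B, kout)
  for (i in seq_len(ntaps)) {
    s <- d * (i - 1L)
    if (s >= N) break
    Hi <- matrix(kernel[i, , ], kin, kout)
    if (s == 0L) {
      Yf <- Yf + flat2(X) %*% Hi
    } else {
      Xs <- array(0, c(N, B, kin))
      Xs[(s + 1L):N, , ] <- X[1L:(N - s), , , drop = FALSE]
      Yf <- Yf + flat2(Xs) %*% Hi
    }
  }
  unflat2(Yf, N, B)
}

# Residual block: out = shortcut(X) + dropout(activation(conv(X))).
block_forward <- function(X, blk, d, cfg, training) {
  N <- dim(X)[1L]; B <- dim(X)[2L]
  pre <- conv_causal_batch(X, blk$kernel, blk$bias, d)
  act <- if (cfg$activation == "relu") pmax(pre, 0) else pre
  keep <- NULL
  if (training && cfg$dropout_rate > 0) {
    keep <- array(runif(length(act)) >= cfg$dropout_rate, dim(act))
    act <- act * keep / (1 - cfg$dropout_rate)
  }
  short <- if (is.null(blk$shortcut)) X
           else unflat2(flat2(X) %*% blk$shortcut, N, B)
  list(out = short + act, pre = pre, keep = keep, X = X)
}

# Masked sum over time: S[b, k] = sum_n W[n, b] * Y[n, b, k].
masked_time_sum <- function(Y, W) {
  d <- dim(Y)
  Z <- Y * as.vector(W)          # recycles (N, B) over the K slices
  dim(Z) <- c(d[1L], d[2L] * d[3L])
  matrix(colSums(Z), d[2L], d[3L])
}

head_forward <- function(Y, mask, head, type) {
  cnt <- colSums(mask)
  if (any(cnt == 0)) stopf("a batch member has every timestep masked")
  if (type == "aot") {
    s <- masked_time_sum(Y, mask) / cnt
    att <- NULL
    cache <- list()
  } else {
    d <- dim(Y)
    V <- tanh(sweep(flat2(Y) %*% head$W_a, 2L, head$b_a, "+"))
    e <- matrix(V %*% head$u_a, d[1L], d[2L])
    e[!mask] <- -Inf
    emax <- apply(e, 2L, max)
    ex <- exp(sweep(e, 2L, emax, "-"))
    ex[!mask] <- 0
    att <- sweep(ex, 2L, colSums(ex), "/")
    s <- masked_time_sum(Y, att)
    cache <- list(V = V, att = att)
  }
  logits <- sweep(s %*% head$W_o, 2L, head$b_o, "+")
  probs <- softmax_rows(logits)
  c(list(probs = probs, s = s, attention = att), cache)
}

# Stack a list of sample matrices into a padded batch + mask.
pad_batch <- function(mats, channels, max_len = NULL) {
  lens <- vapply(mats, nrow, integer(1))
  N <- max_len %||% max(lens)
  if (N < max(lens)) stopf("'max_len' shorter than the longest sequence")
  B <- length(mats)
  X <- array(0, c(N, B, channels))
  mask <- matrix(FALSE, N, B)
  for (b in seq_len(B)) {
    X[seq_len(lens[b]), b, ] <- mats[[b]]
    mask[seq_len(lens[b]), b] <- TRUE
  }
  list(X = X, mask = mask, lengths = lens)
}

as_sample_mats <- function(x) {
  if (inherits(x, "emg_sequence")) return(list(x$samples))
  if (is.matrix(x)) return(list(x))
  if (inherits(x, "gesture_dataset")) x <- x$sequences
  if (is.list(x))
    return(lapply(x, function(s) if (inherits(s, "emg_sequence")) s$samples
                  else as.matrix(s)))
  stopf("cannot interpret input of class '%s' as sEMG sequences",
        paste(class(x), collapse = "/"))
}

# Full forward pass with caches (internal; used by both prediction and
# backprop).
tcn_forward_cached <- function(model, X, mask, training = FALSE) {
  cfg <- model$config
  caches <- vector("list", cfg$layers)
  H <- X
  for (l in seq_len(cfg$layers)) {
    caches[[l]] <- block_forward(H, model$blocks[[l]], cfg$dilations[l], cfg,
                                 training)
    H <- caches[[l]]$out
  }
  hd <- head_forward(H, mask, model$head, cfg$head)
  list(head = hd, features = H, caches = caches)
}

#' Forward pass of a TCN
#'
#' Runs one or more sequences through the network and returns class
#' probabilities (and, for the attention head, the per-timestep attention
#' weights). Multiple sequences are zero-padded to a common length and
#' masked; the padded forward pass of a sequence is identical to its solo
#' forward pass.
#'
#' @param model A `tcn_model`.
#' @param x An [emg_sequence()], a numeric `N x C` matrix, a list of
#'   either, or a [gesture_dataset()].
#' @param max_len Optional common padded length (defaults to the longest
#'   sequence in the batch).
#' @return List with `probs` (`B x G` matrix), `attention` (`N_max x B`
#'   matrix, zero on padded steps; `NULL` for the AoT head) and `lengths`.
#' @export
tcn_forward <- function(model, x, max_len = NULL) {
  mats <- as_sample_mats(x)
  if (any(vapply(mats, ncol, integer(1)) != model$config$channels))
    stopf("input channel count does not match the model configuration (C = %d)",
          model$config$channels)
  pb <- pad_batch(mats, model$config$channels, max_len)
  fw <- tcn_forward_cached(model, pb$X, pb$mask, training = FALSE)
  list(probs = fw$head$probs, attention = fw$head$attention,
       lengths = pb$lengths)
}

#' @export
#' @rdname tcn_forward
#' @param object,newdata,... S3 method arguments: `predict(model, data)`
#'   returns the `B x G` probability matrix.
predict.tcn_model <- function(object, newdata, ...) {
  tcn_forward(object, newdata)$probs
}

#' Most probable labels
#'
#' Argmax labels (0-based) from a probability matrix; ties are broken
#' towards the lowest label id.
#'
#' @param probs `B x G` probability matrix.
#' @return Integer vector of labels in `0..G-1`.
#' @export
top1_labels <- function(probs) {
  max.col(probs, ties.method = "first") - 1L
}

# --- single-sequence views of the building blocks -------------------------
# Thin wrappers over the batched internals, convenient for composing and
# inspecting the network layer by layer.

#' Causal dilated convolution of a feature map
#'
#' `y[n, k] = sum_j sum_i x[n - d*i, j] * h[i, j, k]` with zero for indices
#' before the start: output `n` depends only on inputs at
#' `n, n-d, ..., n-2pd`.
#'
#' @param x Numeric `N x Kin` matrix (or vector, treated as one channel).
#' @param kernel Array `(2p+1) x Kin x Kout`; for a single-channel filter a
#'   plain numeric vector of taps `h_0..h_2p` is accepted.
#' @param d Dilation factor (>= 1).
#' @param bias Optional length-`Kout` bias (default 0).
#' @return `N x Kout` matrix.
#' @export
causal_dilated_conv <- function(x, kernel, d = 1L, bias = NULL) {
  if (!is_count(d)) stopf("dilation 'd' must be a positive integer")
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
  if (is.null(dim(kernel))) kernel <- array(kernel, c(length(kernel), 1L, 1L))
  kout <- dim(kernel)[3L]
  bias <- bias %||% numeric(kout)
  X <- array(x, c(nrow(x), 1L, ncol(x)))
  Y <- conv_causal_batch(X, kernel, bias, as.integer(d))
  matrix(Y, nrow(x), kout)
}

#' Residual block applied to a feature map
#'
#' `out = shortcut(x) + dropout(activation(conv(x)))`, where the shortcut
#' is the identity when widths match and a 1x1 convolution otherwise.
#' Dropout is inactive here (inference mode).
#'
#' @param x Numeric `N x Kin` matrix.
#' @param block List with `kernel`, `bias` and optional `shortcut` (as in a
#'   `tcn_model`).
#' @param d Dilation factor.
#' @param activation `"relu"` or `"linear"`.
#' @return `N x Kout` matrix.
#' @export
residual_block <- function(x, block, d = 1L, activation = "relu") {
  kin <- dim(block$kernel)[2L]
  kout <- dim(block$kernel)[3L]
  if (ncol(x) != kin) stopf("feature width %d does not match kernel (%d)",
                            ncol(x), kin)
  if (kin != kout && is.null(block$shortcut))
    stopf("width changes from %d to %d but the block has no shortcut projection",
          kin, kout)
  cfg <- list(activation = activation, dropout_rate = 0)
  X <- array(x, c(nrow(x), 1L, kin))
  out <- block_forward(X, block, as.integer(d), cfg, training = FALSE)$out
  matrix(out, nrow(x), kout)
}

#' Average-over-time classification head
#'
#' `s = mean_n y[n, ]` over valid timesteps, then `softmax(s W_o + b_o)`.
#'
#' @param features `N x K` feature matrix.
#' @param W_o,b_o Output layer parameters (`K x G`, length `G`).
#' @param mask Optional logical validity vector of length `N`.
#' @return Probability vector of length `G`.
#' @export
aot_head <- function(features, W_o, b_o, mask = NULL) {
  mask <- mask %||% rep(TRUE, nrow(features))
  if (!any(mask)) stopf("every timestep is masked")
  s <- colMeans(features[mask, , drop = FALSE])
  softmax_vec(as.numeric(s %*% W_o) + b_o)
}

#' Attention classification head
#'
#' `v = tanh(y W_a + b_a)`, `a = softmax(v u_a)` over valid timesteps,
#' `s = sum_n a_n y_n`, then `softmax(s W_o + b_o)`. Masked timesteps get
#' attention weight 0 and the remaining weights sum to 1.
#'
#' @param features `N x K` feature matrix.
#' @param W_a,b_a,u_a Attention parameters (`K x K`, length `K`, `K x 1`).
#' @param W_o,b_o Output layer parameters.
#' @param mask Optional logical validity vector of length `N`.
#' @return List with `probs` (length `G`) and `attention` (length `N`).
#' @export
attention_head <- function(features, W_a, b_a, u_a, W_o, b_o, mask = NULL) {
  mask <- mask %||% rep(TRUE, nrow(features))
  if (!any(mask)) stopf("every timestep is masked")
  Y <- array(features, c(nrow(features), 1L, ncol(features)))
  hd <- head_forward(Y, matrix(mask, ncol = 1L),
                     list(W_a = W_a, b_a = b_a, u_a = matrix(u_a, ncol = 1L),
                          W_o = W_o, b_o = b_o), "att")
  list(probs = as.numeric(hd$probs), attention = as.numeric(hd$attention))
}
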
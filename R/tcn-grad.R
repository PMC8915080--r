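# Reverse-mode gradients of the class-weighted cross-entropy through the
# whole network. Mirrors tcn-net.R structure for structure; validated
# against central finite differences in the test suite.

zero_like_params <- function(model) {
  g <- list(blocks = lapply(model$blocks, function(blk)
    lapply(blk, function(p) array(0, dim(p) %||% length(p)))),
    head = lapply(model$head, function(p) array(0, dim(p) %||% length(p))))
  g
}

conv_backward <- function(X, dpre, kernel, d) {
  dms <- dim(X)
  N <- dms[1L]; B <- dms[2L]; kin <- dms[3L]
  ntaps <- dim(kernel)[1L]
  kout <- dim(kernel)[3L]
  dX <- array(0, dim(X))
  dK <- array(0, dim(kernel))
  dpre_f <- flat2(dpre)
  for (i in seq_len(ntaps)) {
    s <- d * (i - 1L)
    if (s >= N) break
    Hi <- matrix(kernel[i, , ], kin, kout)
    if (s == 0L) {
      dK[i, , ] <- crossprod(flat2(X), dpre_f)
      dX <- dX + unflat2(dpre_f %*% t(Hi), N, B)
    } else {
      Xs <- array(0, c(N, B, kin))
      Xs[(s + 1L):N, , ] <- X[1L:(N - s), , , drop = FALSE]
      dK[i, , ] <- crossprod(flat2(Xs), dpre_f)
      G <- unflat2(dpre_f %*% t(Hi), N, B)
      dX[1L:(N - s), , ] <- dX[1L:(N - s), , , drop = FALSE] +
        G[(s + 1L):N, , , drop = FALSE]
    }
  }
  list(dX = dX, dK = dK, db = colSums(dpre_f))
}

block_backward <- function(cache, blk, d, cfg, dOut) {
  N <- dim(dOut)[1L]; B <- dim(dOut)[2L]
  # branch
  dact <- dOut
  if (!is.null(cache$keep))
    dact <- dact * cache$keep / (1 - cfg$dropout_rate)
  dpre <- if (cfg$activation == "relu") dact * (cache$pre > 0) else dact
  cb <- conv_backward(cache$X, dpre, blk$kernel, d)
  dX <- cb$dX
  grads <- list(kernel = cb$dK, bias = cb$db)
  # shortcut
  if (is.null(blk$shortcut)) {
    dX <- dX + dOut
  } else {
    grads$shortcut <- crossprod(flat2(cache$X), flat2(dOut))
    dX <- dX + unflat2(flat2(dOut) %*% t(blk$shortcut), N, B)
  }
  list(dX = dX, grads = grads)
}

# Loss + gradients for one padded batch. labels are 0-based; class_w has
# length G (index g+1 = weight of label g). The loss is the weighted mean
# cross-entropy: sum_b w_b * nll_b / sum_b w_b.
tcn_loss_grad <- function(model, X, mask, labels, class_w,
                          training = TRUE, compute_grads = TRUE) {
  cfg <- model$config
  fw <- tcn_forward_cached(model, X, mask, training = training)
  probs <- fw$head$probs
  B <- nrow(probs); G <- ncol(probs)
  idx <- cbind(seq_len(B), labels + 1L)
  w <- class_w[labels + 1L]
  wsum <- sum(w)
  nll <- -log(pmax(probs[idx], 1e-300))
  loss <- sum(w * nll) / wsum
  acc <- mean(top1_labels(probs) == labels)
  if (!compute_grads)
    return(list(loss = loss, accuracy = acc, probs = probs))
  if (!is.finite(loss))
    stopf("training diverged: non-finite loss (%g)", loss)

  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits * (w / wsum)

  grads <- zero_like_params(model)
  hd <- fw$head
  Y <- fw$features
  d <- dim(Y); N <- d[1L]
  grads$head$W_o <- crossprod(hd$s, dlogits)
  grads$head$b_o <- colSums(dlogits)
  ds <- dlogits %*% t(model$head$W_o)          # B x K

  ds_rep <- rep(as.vector(ds), each = N)       # (N,B,K) layout
  if (cfg$head == "aot") {
    cnt <- colSums(mask)
    wn <- sweep(1 * mask, 2L, cnt, "/")        # N x B
    dY <- array(ds_rep, d) * as.vector(wn)
  } else {
    att <- hd$att
    V <- hd$V                                  # (N*B) x K
    # da[n,b] = sum_k Y[n,b,k] ds[b,k]
    Z <- Y * ds_rep
    dim(Z) <- c(N * d[2L], d[3L])
    da <- matrix(rowSums(Z), N, d[2L])
    # dY from s = sum_n a Y
    dY <- array(ds_rep, d) * as.vector(att)
    # softmax (per column) backward
    de <- att * sweep(da, 2L, colSums(att * da), "-")
    grads$head$u_a <- crossprod(V, as.vector(de))
    dV <- as.vector(de) %o% as.vector(model$head$u_a)
    dpre_a <- (1 - V^2) * dV
    grads$head$W_a <- crossprod(flat2(Y), dpre_a)
    grads$head$b_a <- colSums(dpre_a)
    dY <- dY + unflat2(dpre_a %*% t(model$head$W_a), N, d[2L])
  }

  dH <- dY
  for (l in rev(seq_len(cfg$layers))) {
    bb <- block_backward(fw$caches[[l]], model$blocks[[l]], cfg$dilations[l],
                         cfg, dH)
    grads$blocks[[l]] <- bb$grads
    dH <- bb$dX
  }
  list(loss = loss, accuracy = acc, probs = probs, grads = grads)
}

grads_to_vector <- function(model, grads) {
  out <- list()
  for (l in seq_along(grads$blocks)) {
    for (nm in names(model$blocks[[l]])) out[[length(out) + 1L]] <- grads$blocks[[l]][[nm]]
  }
  for (nm in names(model$head)) out[[length(out) + 1L]] <- grads$head[[nm]]
  unlist(out, use.names = FALSE)
}
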
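test_that("causal dilated convolution matches the defining sum", {
  # delta kernel is the identity
  x <- c(0.3, -1, 2, 0.5)
  expect_equal(as.numeric(causal_dilated_conv(x, c(1, 0, 0), d = 1)), x)
  # hand case: p = 1, d = 2, taps all one -> left-zero-padded sums
  expect_equal(as.numeric(causal_dilated_conv(c(1, 2, 3, 4), c(1, 1, 1), d = 2)),
               c(1, 2, 4, 6))
  # zero input, bias-free -> zero output
  expect_equal(as.numeric(causal_dilated_conv(rep(0, 6), rnorm(3), d = 2)),
               rep(0, 6))
  expect_error(causal_dilated_conv(x, c(1, 1, 1), d = 0), "dilation")

  # random multichannel cases against the brute-force oracle (sum over
  # input channels of single-channel convolutions)
  withr::with_seed(10, {
    for (rep_i in 1:20) {
      N <- sample(3:40, 1); d <- sample(1:4, 1); p <- sample(0:2, 1)
      kin <- sample(1:3, 1); kout <- sample(1:3, 1)
      x <- matrix(rnorm(N * kin), N, kin)
      kern <- array(rnorm((2 * p + 1) * kin * kout), c(2 * p + 1, kin, kout))
      got <- causal_dilated_conv(x, kern, d = d)
      want <- matrix(0, N, kout)
      for (k in seq_len(kout)) for (j in seq_len(kin))
        want[, k] <- want[, k] + conv_oracle(x[, j], kern[, j, k], d)
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
})

test_that("the residual block is shortcut plus branch and handles width changes", {
  withr::with_seed(2, {
    x <- matrix(rnorm(30), 10, 3)
    # zero branch + identity shortcut = identity
    blk0 <- list(kernel = array(0, c(3, 3, 3)), bias = numeric(3))
    expect_equal(residual_block(x, blk0, d = 1), x)
    # compositional oracle: shortcut + relu(conv)
    blk <- list(kernel = array(rnorm(3 * 3 * 4), c(3, 3, 4)), bias = rnorm(4),
                shortcut = matrix(rnorm(12), 3, 4))
    got <- residual_block(x, blk, d = 2)
    manual <- x %*% blk$shortcut +
      pmax(causal_dilated_conv(x, blk$kernel, d = 2, bias = blk$bias), 0)
    expect_equal(got, manual, tolerance = 1e-12)
    # single-timestep input works (causality degenerate case)
    expect_identical(dim(residual_block(x[1, , drop = FALSE], blk, d = 4)),
                     c(1L, 4L))
    # width change without a shortcut is an error
    expect_error(residual_block(x, list(kernel = blk$kernel, bias = rnorm(4)), 1),
                 "shortcut")
  })
})

test_that("receptive field follows the recursive doubling formula", {
  cfg <- tcn_config(layers = 4, filters = 8, n_labels = 5, channels = 2)
  rf <- receptive_field(cfg, rate = 100)
  expect_identical(rf$samples, 30)
  expect_identical(rf$ms, 300)
  expect_identical(receptive_field(7)$samples, 254)  # 2*(1+2+4+8+16+32+64)
  expect_identical(receptive_field(0)$samples, 0)
  # p = 2 doubles the increments
  expect_identical(receptive_field(3, kernel_half_width = 2)$samples, 28)
})

test_that("AoT head is a masked mean + softmax matching hand arithmetic", {
  # constant features: s equals the constant
  Yc <- matrix(rep(c(1, -2), each = 5), 5, 2)
  W0 <- matrix(0, 2, 3)
  expect_equal(aot_head(Yc, W0, rep(0, 3)), rep(1 / 3, 3))
  # hand-computed 3-timestep case
  Y <- matrix(c(1, 2, 3, 0, -1, 1), 3, 2)
  W <- matrix(c(0.5, -0.2, 0.1, 0.3, -0.4, 0.2), 2, 3)
  b <- c(0.1, -0.1, 0)
  s <- c(mean(Y[, 1]), mean(Y[, 2]))
  logits <- as.numeric(s %*% W) + b
  expect_equal(aot_head(Y, W, b), exp(logits) / sum(exp(logits)),
               tolerance = 1e-12)
  # mask restricts the mean
  m <- c(TRUE, TRUE, FALSE)
  s2 <- colMeans(Y[1:2, ])
  l2 <- as.numeric(s2 %*% W) + b
  expect_equal(aot_head(Y, W, b, mask = m), exp(l2) / sum(exp(l2)),
               tolerance = 1e-12)
  expect_error(aot_head(Y, W, b, mask = rep(FALSE, 3)), "masked")
})

test_that("attention head matches hand arithmetic and collapses to AoT at u_a = 0", {
  withr::with_seed(5, {
    # 2-timestep hand computation
    Y <- matrix(c(1, -1, 0.5, 2), 2, 2)
    W_a <- matrix(c(0.2, -0.1, 0.3, 0.4), 2, 2)
    b_a <- c(0.05, -0.05)
    u_a <- c(1, -0.5)
    W_o <- matrix(c(0.3, 0.1, -0.2, 0.6), 2, 2)
    b_o <- c(0, 0.2)
    V <- tanh(Y %*% W_a + matrix(b_a, 2, 2, byrow = TRUE))
    e <- as.numeric(V %*% u_a)
    a <- exp(e) / sum(exp(e))
    s <- as.numeric(t(a) %*% Y)
    logits <- as.numeric(s %*% W_o) + b_o
    want <- exp(logits) / sum(exp(logits))
    got <- attention_head(Y, W_a, b_a, u_a, W_o, b_o)
    expect_equal(got$probs, want, tolerance = 1e-12)
    expect_equal(got$attention, a, tolerance = 1e-12)

    # normalization and nonnegativity for random parameters
    for (i in 1:10) {
      Yr <- matrix(rnorm(8 * 3), 8, 3)
      hr <- attention_head(Yr, matrix(rnorm(9), 3, 3), rnorm(3), rnorm(3),
                           matrix(rnorm(12), 3, 4), rnorm(4))
      expect_equal(sum(hr$attention), 1, tolerance = 1e-12)
      expect_true(all(hr$attention >= 0))
      expect_equal(sum(hr$probs), 1, tolerance = 1e-12)
    }

    # u_a = 0 -> uniform attention -> exactly the AoT output
    h0 <- attention_head(Y, W_a, b_a, c(0, 0), W_o, b_o)
    expect_equal(h0$attention, c(0.5, 0.5))
    expect_equal(h0$probs, aot_head(Y, W_o, b_o), tolerance = 1e-14)
  })
})

test_that("full-model collapse: attention model with u_a = 0 equals its AoT twin", {
  m <- toy_model(head = "att", layers = 3, filters = c(4, 4, 6), seed = 31)
  m$head$u_a[] <- 0
  twin <- m
  twin$config$head <- "aot"
  twin$head <- m$head[c("W_o", "b_o")]
  x <- withr::with_seed(1, matrix(rnorm(50), 25, 2))
  expect_equal(tcn_forward(m, x)$probs, tcn_forward(twin, x)$probs,
               tolerance = 1e-12)
})

test_that("padding plus masking never changes a sequence's output", {
  withr::with_seed(12, {
    m <- toy_model(G = 4, C = 3, head = "att", layers = 3,
                   filters = c(5, 6, 4), seed = 13)
    mats <- lapply(1:12, function(i) matrix(rnorm(3 * sample(5:40, 1)), ncol = 3))
    solo <- lapply(mats, function(x) tcn_forward(m, x))
    batch <- tcn_forward(m, mats, max_len = 60)
    for (i in seq_along(mats)) {
      expect_lt(max(abs(solo[[i]]$probs - batch$probs[i, ])), 1e-6)
      n <- nrow(mats[[i]])
      expect_equal(batch$attention[seq_len(n), i],
                   as.numeric(solo[[i]]$attention)[seq_len(n)],
                   tolerance = 1e-9)
      # attention vanishes on padded steps and sums to 1 on valid ones
      if (n < 60) expect_true(all(batch$attention[(n + 1):60, i] == 0))
      expect_equal(sum(batch$attention[, i]), 1, tolerance = 1e-9)
    }
  })
})

test_that("every conv layer is causal: future perturbations cannot reach the past", {
  withr::with_seed(42, {
    for (trial in 1:15) {
      L <- sample(1:4, 1)
      cfg <- tcn_config(layers = L, filters = sample(2:6, L, replace = TRUE),
                        n_labels = 3, channels = 2,
                        kernel_half_width = sample(0:2, 1),
                        head = "aot", dropout_rate = 0)
      m <- tcn_init(cfg, seed = trial)
      N <- 30L
      x <- matrix(rnorm(N * 2), N, 2)
      n <- sample(1:(N - 1), 1)
      x2 <- x
      x2[(n + 1):N, ] <- x2[(n + 1):N, ] + rnorm((N - n) * 2, sd = 3)
      f1 <- emgtcn:::tcn_forward_cached(m, array(x, c(N, 1, 2)),
                                        matrix(TRUE, N, 1))
      f2 <- emgtcn:::tcn_forward_cached(m, array(x2, c(N, 1, 2)),
                                        matrix(TRUE, N, 1))
      expect_equal(f1$features[1:n, 1, ], f2$features[1:n, 1, ],
                   tolerance = 1e-12)
    }
  })
})

test_that("receptive-field extent is exact for a bias-free linear stack", {
  withr::with_seed(8, {
    for (trial in 1:15) {
      L <- sample(1:4, 1)
      p <- sample(1:2, 1)
      cfg <- tcn_config(layers = L, filters = sample(2:5, L, replace = TRUE),
                        n_labels = 3, channels = 2, kernel_half_width = p,
                        head = "aot", dropout_rate = 0, activation = "linear")
      m <- tcn_init(cfg, seed = 100 + trial)
      for (l in seq_len(L)) m$blocks[[l]]$bias[] <- 0
      rf <- receptive_field(cfg)$samples
      N <- as.integer(rf + 10)
      x <- matrix(rnorm(N * 2), N, 2)
      last <- function(x) {
        f <- emgtcn:::tcn_forward_cached(m, array(x, c(N, 1, 2)),
                                         matrix(TRUE, N, 1))
        f$features[N, 1, ]
      }
      y0 <- last(x)
      # outside the window: indices < N - 1 - RF (0-based) cannot matter
      x_out <- x; x_out[N - rf - 1, ] <- x_out[N - rf - 1, ] + 5
      expect_equal(last(x_out), y0, tolerance = 1e-10)
      # the oldest in-window index does matter
      x_in <- x; x_in[N - rf, ] <- x_in[N - rf, ] + 5
      expect_gt(max(abs(last(x_in) - y0)), 1e-8)
    }
  })
})

test_that("dropout is active only during training; inference is deterministic", {
  m <- toy_model(dropout_rate = 0.5, seed = 3)
  x <- withr::with_seed(2, matrix(rnorm(40), 20, 2))
  p1 <- tcn_forward(m, x)$probs
  p2 <- tcn_forward(m, x)$probs
  expect_identical(p1, p2)
  # training forwards with dropout differ across draws
  X <- array(x, c(20, 1, 2)); msk <- matrix(TRUE, 20, 1)
  set.seed(1)
  t1 <- emgtcn:::tcn_forward_cached(m, X, msk, training = TRUE)$head$probs
  t2 <- emgtcn:::tcn_forward_cached(m, X, msk, training = TRUE)$head$probs
  expect_gt(max(abs(t1 - t2)), 0)
})

test_that("channel mismatch is rejected", {
  m <- toy_model(C = 2)
  expect_error(tcn_forward(m, matrix(0, 10, 3)), "channel count")
})

test_that("checkpoints round-trip through JSON and validate shapes", {
  m <- toy_model(head = "att", seed = 77)
  f <- tempfile(fileext = ".json")
  save_tcn(m, f)
  back <- load_tcn(f)
  x <- withr::with_seed(9, matrix(rnorm(60), 30, 2))
  expect_equal(tcn_forward(back, x)$probs, tcn_forward(m, x)$probs,
               tolerance = 1e-12)
  expect_identical(tcn_n_params(back), tcn_n_params(m))
  # corrupt a shape
  js <- jsonlite::read_json(f, simplifyVector = TRUE)
  js$params$head.W_o$dim <- c(2, 2)
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(js, f2, auto_unbox = TRUE, digits = NA)
  expect_error(load_tcn(f2), "shape mismatch")
})

test_that("analytic gradients match central finite differences", {
  withr::with_seed(6, {
    for (head in c("aot", "att")) {
      cfg <- tcn_config(layers = 2, filters = c(4, 5), n_labels = 3,
                        channels = 2, head = head, dropout_rate = 0)
      m <- tcn_init(cfg, seed = 19)
      pb <- emgtcn:::pad_batch(list(matrix(rnorm(24), 12, 2),
                                    matrix(rnorm(16), 8, 2)), 2)
      labels <- c(0L, 2L); w <- c(1, 2, 0.5)
      r <- emgtcn:::tcn_loss_grad(m, pb$X, pb$mask, labels, w, training = FALSE)
      g <- emgtcn:::grads_to_vector(m, r$grads)
      theta <- emgtcn:::params_to_vector(m)
      idx <- seq(1, length(theta), by = 7)
      eps <- 1e-5
      loss_at <- function(t) emgtcn:::tcn_loss_grad(
        emgtcn:::vector_to_params(m, t), pb$X, pb$mask, labels, w,
        training = FALSE, compute_grads = FALSE)$loss
      num <- vapply(idx, function(i) {
        tp <- theta; tp[i] <- tp[i] + eps
        tm <- theta; tm[i] <- tm[i] - eps
        (loss_at(tp) - loss_at(tm)) / (2 * eps)
      }, numeric(1))
      expect_lt(max(abs(num - g[idx])), 1e-6)
    }
  })
})
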
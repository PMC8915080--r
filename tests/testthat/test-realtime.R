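test_that("streaming segments grow to 200 ms (20 samples at 100 Hz) then slide", {
  s <- emg_sequence(matrix(seq_len(25 * 2), 25, 2), rate = 100, label = 1)
  segs <- stream_segments(s, segment_ms = 200)
  expect_length(segs, 25L)
  lens <- vapply(segs, nrow, integer(1))
  expect_identical(lens, c(1:20, rep(20L, 5)))
  # iteration 24 (0-based) yields samples 5..24 (0-based) = rows 6..25
  expect_equal(segs[[25]], s$samples[6:25, ])
  # buffer-fill phase on a short sequence
  s5 <- emg_sequence(matrix(1:10, 5, 2), rate = 100, label = 0)
  expect_identical(vapply(stream_segments(s5, 200), nrow, integer(1)), 1:5)
})

test_that("stream simulation emits one label per input sample", {
  s <- emg_sequence(matrix(rnorm(60), 30, 2), rate = 100, label = 4)
  stub <- function(m) 4L
  st <- simulate_stream(stub, s)
  expect_s3_class(st, "prediction_stream")
  expect_identical(st$predictions, rep(4L, 30))
  expect_identical(st$truth, 4L)

  # a real model produces the same labels as solo forwards on each segment
  m <- toy_model(G = 3, C = 2, seed = 14)
  stm <- simulate_stream(m, s, segment_ms = 100)
  segs <- stream_segments(s, segment_ms = 100)
  want <- vapply(segs, function(w) top1_labels(tcn_forward(m, w)$probs),
                 integer(1))
  expect_identical(stm$predictions, want)
})

test_that("vote classifier follows the threshold rule with exact scenarios", {
  # 30 identical labels, w = 300 ms at 100 Hz, tau = 12 -> decisive from
  # iteration 11 (0-based) onward
  st <- generate_label_stream(5, list(c(5, 30)))
  psi <- vote_classify(st, vote_config(300, 12))
  expect_identical(psi, c(rep(-1L, 11), rep(5L, 19)))

  # 11 occurrences in the window stay below tau = 12
  st11 <- generate_label_stream(5, list(c(5, 11), c(0, 6), c(1, 6), c(2, 6)))
  psi11 <- vote_classify(st11, vote_config(300, 12))
  expect_true(all(psi11 == -1L))

  # neither label reaches tau = 7 in a 12-sample window
  st66 <- generate_label_stream(1, list(c(1, 6), c(2, 6)))
  expect_true(all(vote_classify(st66, vote_config(120, 7)) == -1L))

  # tau = 1 gives the modal label at every iteration
  stm <- generate_label_stream(2, list(c(2, 3), c(1, 2)))
  psi1 <- vote_classify(stm, vote_config(50, 1))
  expect_identical(psi1, c(2L, 2L, 2L, 2L, 2L))

  # tau exceeding the window is a configuration error
  expect_error(vote_classify(st, vote_config(100, 12)), "exceeds")
})

test_that("vote classifier equals the brute-force counter on random streams", {
  withr::with_seed(101, {
    for (i in 1:200) {
      n <- sample(10:60, 1)
      preds <- sample(0:3, n, replace = TRUE)
      st <- prediction_stream(preds, truth = 1L, rate = 100)
      win_ms <- sample(c(50, 100, 200), 1)
      win <- round(win_ms * 100 / 1000)
      tau <- sample(seq_len(win), 1)
      expect_identical(vote_classify(st, vote_config(win_ms, tau)),
                       vote_oracle(preds, win, tau))
    }
  })
})

test_that("decisive votes shrink monotonically as tau grows and depend only on the window", {
  withr::with_seed(55, {
    preds <- sample(0:2, 80, replace = TRUE)
    st <- prediction_stream(preds, 0L, 100)
    prev <- NULL
    for (tau in 1:20) {
      psi <- vote_classify(st, vote_config(200, tau))
      dec <- which(psi != -1L)
      if (!is.null(prev)) expect_true(all(dec %in% prev))
      prev <- dec
    }
    # locality: labels older than the window never change the vote
    psi_full <- vote_classify(st, vote_config(200, 5))
    shifted <- prediction_stream(c(sample(0:2, 40, replace = TRUE), preds), 0L, 100)
    psi_shift <- vote_classify(shifted, vote_config(200, 5))
    expect_identical(psi_full[41:80], psi_shift[81:120])
  })
})

test_that("timing analytics map iteration indices to seconds", {
  # correct at iteration 0 -> 0.00 s
  st <- generate_label_stream(3, list(c(3, 30)))
  tr <- timing_analysis(st, cfg = vote_config(300, 12))
  expect_equal(tr$time_to_first_correct, 0)
  # decisive vote at iteration 11 within a still-filling window -> 0.11 s
  expect_equal(tr$response_time, 0.11)
  expect_identical(tr$first_vote_label, 3L)

  # first correct at iteration 42 -> 0.42 s
  st42 <- generate_label_stream(7, list(c(1, 42), c(7, 30)))
  tr42 <- timing_analysis(st42, cfg = vote_config(300, 12))
  expect_equal(tr42$time_to_first_correct, 0.42)

  # never correct / never decisive -> NA sentinels
  stna <- generate_label_stream(9, list(c(1, 5), c(2, 5)))
  trna <- timing_analysis(stna, cfg = vote_config(100, 9))
  expect_true(is.na(trna$time_to_first_correct))
  expect_true(is.na(trna$response_time))
  expect_identical(trna$first_vote_label, -1L)
})

test_that("real-time accuracy weights votes by class", {
  mk <- function(truth, lab) {
    st <- generate_label_stream(truth, list(c(lab, 30)))
    timing_analysis(st, cfg = vote_config(300, 12))
  }
  res <- list(mk(1, 1), mk(2, 3), mk(3, 3))
  # third result: vote 3 for truth 3 correct; second wrong
  expect_equal(realtime_accuracy(res), 2 / 3)
  expect_equal(realtime_accuracy(list(mk(1, 1), mk(2, 2))), 1)
  # no-gesture counts as incorrect
  nog <- timing_analysis(generate_label_stream(4, list(c(1, 5), c(2, 5))),
                         cfg = vote_config(100, 9))
  expect_equal(realtime_accuracy(list(mk(1, 1), mk(2, 4), nog)), 1 / 3)
  # weights covering absent classes trigger the exclusion warning
  expect_warning(realtime_accuracy(res, weights = rep(1, 10)), "excluded")
})

test_that("the (w, tau) grid matches cell-by-cell recomputation", {
  withr::with_seed(77, {
    streams <- lapply(1:6, function(i) {
      truth <- sample(0:2, 1)
      preds <- c(sample(0:2, 10, replace = TRUE), rep(truth, 40))
      prediction_stream(preds, truth, 100)
    })
    ws <- c(100, 200, 300)
    taus <- c(3L, 8L, 25L)
    grid <- grid_search_wt(streams, ws, taus)
    for (i in seq_along(ws)) for (j in seq_along(taus)) {
      cfg <- vote_config(ws[i], taus[j])
      if (taus[j] > round(ws[i] * 100 / 1000)) {
        expect_true(is.na(grid$accuracy[i, j]))
        next
      }
      res <- lapply(streams, function(s)
        timing_analysis(s, vote_classify(s, cfg), cfg))
      expect_equal(grid$accuracy[i, j],
                   suppressWarnings(realtime_accuracy(res)))
      expect_equal(grid$response_time[i, j],
                   mean(vapply(res, function(r) r$response_time, numeric(1)),
                        na.rm = TRUE))
    }
    expect_equal(grid$best$accuracy, max(grid$accuracy, na.rm = TRUE))

    # a perfect constant stream gives accuracy 1 at every feasible cell
    ps <- list(prediction_stream(rep(2L, 50), 2L, 100))
    g1 <- grid_search_wt(ps, c(100, 300), c(5L, 10L))
    expect_true(all(g1$accuracy[!is.na(g1$accuracy)] == 1))
  })
})

test_that("attention-peak correlation reproduces the closed-form Pearson coefficient", {
  x <- c(0.5, 1.2, 2.0, 3.1, 4.0)
  expect_equal(attention_correlation(x, x)$r, 1)
  expect_equal(attention_correlation(x, -2 * x + 3)$r, -1)
  # worked 5-pair case via the textbook formula
  y <- c(1.0, 0.4, 2.2, 1.8, 3.0)
  n <- 5
  r_hand <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(attention_correlation(x, y)$r, r_hand, tolerance = 1e-12)
  expect_error(attention_correlation(c(1, 2), c(1, 2)), "at least 3")
  expect_warning(out <- attention_correlation(rep(1, 5), y), "zero variance")
  expect_true(is.na(out$r))
})
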
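#' Per-iteration prediction stream
#'
#' One predicted label per input sample of a streamed sequence, together
#' with the ground truth and the sampling rate. `-1` never appears here
#' (it is reserved for the vote classifier's 'no gesture' output).
#'
#' @param predictions Integer vector of predicted labels, one per
#'   iteration.
#' @param truth Ground-truth gesture label.
#' @param rate Sampling rate in Hz.
#' @return An object of class `prediction_stream`.
#' @export
prediction_stream <- function(predictions, truth, rate = 100) {
  structure(list(predictions = as.integer(predictions),
                 truth = as.integer(truth), rate = as.numeric(rate)),
            class = "prediction_stream")
}

#' @export
print.prediction_stream <- function(x, ...) {
  cat(sprintf("<prediction_stream> %d iteration(s) @ %g Hz, truth %d\n",
              length(x$predictions), x$rate, x$truth))
  invisible(x)
}

#' Vote post-classifier configuration
#'
#' An analysis window of `window_ms` milliseconds and a count threshold
#' `tau`: at each iteration the classifier assigns the label predicted at
#' least `tau` times within the trailing window, else 'no gesture' (-1).
#' The published operating point is `window_ms = 300`, `tau = 12`.
#'
#' @param window_ms Analysis window duration in ms (> 0).
#' @param tau Count threshold (>= 1; must not exceed the window length in
#'   samples at the stream's rate).
#' @return An object of class `vote_config`.
#' @export
vote_config <- function(window_ms = 300, tau = 12L) {
  if (window_ms <= 0) stopf("'window_ms' must be positive")
  if (!is_count(tau)) stopf("'tau' must be a positive integer")
  structure(list(window_ms = window_ms, tau = as.integer(tau)),
            class = "vote_config")
}

#' Stream a sequence as growing 200 ms segments
#'
#' Reproduces the real-time feeding protocol: iteration 0 presents only
#' the first sample; while the buffer fills, iteration `n` presents all
#' samples so far; once full, the most recent `segment` samples (200 ms =
#' 20 samples at 100 Hz). There are exactly `N` iterations.
#'
#' @param seq An [emg_sequence()].
#' @param segment_ms Segment duration in ms.
#' @return List of `N` sample matrices (the successive model inputs).
#' @export
stream_segments <- function(seq, segment_ms = 200) {
  N <- nrow(seq$samples)
  seg <- max(1L, as.integer(round(segment_ms * seq$rate / 1000)))
  lapply(seq_len(N), function(n)
    seq$samples[max(1L, n - seg + 1L):n, , drop = FALSE])
}

#' Simulate streaming classification of one sequence
#'
#' Feeds the growing/sliding segments of [stream_segments()] through the
#' model and records the argmax label at every iteration.
#'
#' @param model A `tcn_model`, or a function mapping a sample matrix to a
#'   label (useful for stubs and oracles).
#' @param seq An [emg_sequence()].
#' @param segment_ms Segment duration in ms.
#' @return A [prediction_stream()] of length `N`.
#' @export
simulate_stream <- function(model, seq, segment_ms = 200) {
  segs <- stream_segments(seq, segment_ms)
  preds <- if (is.function(model)) {
    vapply(segs, function(m) as.integer(model(m)), integer(1))
  } else {
    # all segment lengths <= seg: pad into batches for speed
    seg_len <- max(vapply(segs, nrow, integer(1)))
    out <- integer(length(segs))
    for (b0 in seq.int(1L, length(segs), by = 256L)) {
      sel <- b0:min(b0 + 255L, length(segs))
      fw <- tcn_forward(model, segs[sel], max_len = seg_len)
      out[sel] <- top1_labels(fw$probs)
    }
    out
  }
  prediction_stream(preds, truth = seq$label, rate = seq$rate)
}

window_samples <- function(cfg, rate) {
  max(1L, as.integer(round(cfg$window_ms * rate / 1000)))
}

# Tie-break of the vote: among labels at the maximal count (>= tau), pick
# the one whose tau-th most recent occurrence in the window is latest
# (most recent evidence).
vote_pick <- function(win, tau) {
  counts <- table(win)
  mx <- max(counts)
  if (mx < tau) return(-1L)
  cand <- as.integer(names(counts)[counts == mx])
  if (length(cand) == 1L) return(cand)
  tau_pos <- vapply(cand, function(l) {
    occ <- which(win == l)
    occ[length(occ) - tau + 1L]        # tau-th counting back from the end
  }, numeric(1))
  cand[which.max(tau_pos)]
}

#' Threshold-vote post-classifier
#'
#' At each iteration `n`, counts how often each label was predicted within
#' the trailing analysis window and emits the label whose count reaches
#' the threshold `tau` (the maximal count wins; ties go to the label whose
#' `tau`-th occurrence is most recent), or `-1` ('no gesture') when no
#' label reaches `tau`.
#'
#' @param stream A [prediction_stream()].
#' @param cfg A [vote_config()].
#' @return Integer vector of per-iteration votes (`-1` = no gesture).
#' @export
vote_classify <- function(stream, cfg = vote_config()) {
  win <- window_samples(cfg, stream$rate)
  if (cfg$tau > win)
    stopf("tau = %d exceeds the analysis window of %d sample(s)", cfg$tau, win)
  preds <- stream$predictions
  vapply(seq_along(preds), function(n)
    vote_pick(preds[max(1L, n - win + 1L):n], cfg$tau), integer(1))
}

#' Timing analytics of one streamed repetition
#'
#' Records, in seconds: the time until the model first outputs the true
#' label (`time_to_first_correct` = first such 0-based iteration divided
#' by the rate), and the vote classifier's response time, i.e. the time
#' from the start of the analysis window current at the first decisive
#' vote until that vote. Events that never happen yield `NA` sentinels.
#'
#' @param stream A [prediction_stream()].
#' @param psi Vote sequence from [vote_classify()] (computed when
#'   missing).
#' @param cfg The [vote_config()] used (needed for the window start).
#' @return An object of class `timing_result`: `time_to_first_correct`,
#'   `response_time`, `first_vote_label`, `modal_vote_label`, `truth`.
#' @export
timing_analysis <- function(stream, psi = NULL, cfg = vote_config()) {
  psi <- psi %||% vote_classify(stream, cfg)
  rate <- stream$rate
  n_corr <- which(stream$predictions == stream$truth)[1L]
  ttfc <- if (is.na(n_corr)) NA_real_ else (n_corr - 1L) / rate
  n_vote <- which(psi != -1L)[1L]
  if (is.na(n_vote)) {
    rt <- NA_real_
    first_lab <- -1L
  } else {
    win <- window_samples(cfg, rate)
    win_start <- max(1L, n_vote - win + 1L)
    rt <- (n_vote - win_start) / rate
    first_lab <- psi[n_vote]
  }
  decided <- psi[psi != -1L]
  modal <- if (length(decided) == 0L) -1L else {
    tab <- table(decided)
    cand <- as.integer(names(tab))
    cand[order(-as.integer(tab), cand)][1L]   # ties -> lowest label id
  }
  structure(list(time_to_first_correct = ttfc, response_time = rt,
                 first_vote_label = first_lab, modal_vote_label = modal,
                 truth = stream$truth),
            class = "timing_result")
}

#' Class-weighted real-time accuracy
#'
#' The fraction of repetitions whose vote label equals the truth, weighted
#' per class (inverse frequency, mean 1, computed over the truths present
#' unless `weights` is supplied). The primary score uses the first
#' decisive vote per repetition; `vote = "modal"` scores the modal vote
#' instead. Classes with no repetitions among the results are excluded
#' with a warning when explicit weights name them.
#'
#' @param results List of [timing_analysis()] results.
#' @param weights Optional length-`G` class weight vector.
#' @param vote `"first"` or `"modal"`.
#' @return Weighted accuracy in `[0, 1]`.
#' @export
realtime_accuracy <- function(results, weights = NULL,
                              vote = c("first", "modal")) {
  vote <- match.arg(vote)
  if (length(results) == 0L) stopf("no timing results")
  truth <- vapply(results, function(r) r$truth, integer(1))
  lab <- vapply(results, function(r)
    if (vote == "first") r$first_vote_label else r$modal_vote_label,
    integer(1))
  if (is.null(weights)) {
    counts <- table(factor(truth, levels = sort(unique(truth))))
    w_class <- (1 / as.numeric(counts))
    w_class <- w_class / mean(w_class)
    w <- w_class[match(truth, sort(unique(truth)))]
  } else {
    present <- sort(unique(truth))
    missing_cls <- setdiff(seq_along(weights) - 1L, present)
    if (length(missing_cls) > 0L)
      warning(sprintf("no repetitions for %d class(es); excluded from the weighted average",
                      length(missing_cls)))
    w <- weights[truth + 1L]
  }
  sum(w * (lab == truth)) / sum(w)
}

#' Grid search over the vote parameters
#'
#' Evaluates [realtime_accuracy()] and the mean response time over a grid
#' of analysis windows and thresholds. Pairs with `tau` exceeding the
#' window length in samples are infeasible and reported as `NA`. The
#' published surface peaks at `w = 1.6 s`, `tau = 60` when streams come
#' from full-sequence-trained DB1 models.
#'
#' @param streams List of [prediction_stream()]s.
#' @param w_values_ms Analysis windows in ms (default 300..2000 by 100).
#' @param tau_values Count thresholds (default 10..80 by 5).
#' @param weights Optional class weights passed to [realtime_accuracy()].
#' @return List of class `vote_grid`: `accuracy` and `response_time`
#'   matrices (rows = windows, cols = thresholds), and `best`
#'   (`window_ms`, `tau`, `accuracy` at the argmax).
#' @export
grid_search_wt <- function(streams, w_values_ms = seq(300, 2000, by = 100),
                           tau_values = seq(10L, 80L, by = 5L),
                           weights = NULL) {
  rate <- streams[[1L]]$rate
  acc <- matrix(NA_real_, length(w_values_ms), length(tau_values),
                dimnames = list(window_ms = w_values_ms, tau = tau_values))
  rt <- acc
  for (i in seq_along(w_values_ms)) {
    for (j in seq_along(tau_values)) {
      cfg <- vote_config(w_values_ms[i], tau_values[j])
      if (cfg$tau > window_samples(cfg, rate)) next
      res <- lapply(streams, function(s)
        timing_analysis(s, vote_classify(s, cfg), cfg))
      acc[i, j] <- suppressWarnings(realtime_accuracy(res, weights))
      rts <- vapply(res, function(r) r$response_time, numeric(1))
      rt[i, j] <- mean(rts, na.rm = TRUE)
    }
  }
  best_idx <- which(acc == max(acc, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  structure(list(accuracy = acc, response_time = rt,
                 best = list(window_ms = w_values_ms[best_idx[1L]],
                             tau = tau_values[best_idx[2L]],
                             accuracy = acc[best_idx[1L], best_idx[2L]])),
            class = "vote_grid")
}

#' @export
print.vote_grid <- function(x, ...) {
  cat(sprintf("<vote_grid> %d x %d cells; best accuracy %.4f at w = %g ms, tau = %d\n",
              nrow(x$accuracy), ncol(x$accuracy), x$best$accuracy,
              x$best$window_ms, x$best$tau))
  invisible(x)
}

#' Export a vote grid as delimited text
#'
#' Writes `<path>.accuracy.tsv` and `<path>.response_time.tsv` with axis
#' headers (rows = window ms, columns = tau).
#'
#' @param grid A `vote_grid`.
#' @param path Base path.
#' @return The path, invisibly.
#' @export
write_vote_grid <- function(grid, path) {
  write.table(grid$accuracy, paste0(path, ".accuracy.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  write.table(grid$response_time, paste0(path, ".response_time.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Export a stream and its votes as delimited text
#'
#' Columns: `iteration` (0-based), `predicted`, `psi`, `truth`.
#'
#' @param stream A [prediction_stream()].
#' @param psi Vote sequence aligned with the stream.
#' @param path File path (TSV).
#' @return The path, invisibly.
#' @export
write_stream <- function(stream, psi, path) {
  write.table(data.frame(iteration = seq_along(stream$predictions) - 1L,
                         predicted = stream$predictions, psi = psi,
                         truth = stream$truth),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Correlation between attention peaks and first-correct timings
#'
#' Pearson product-moment correlation between per-repetition attention
#' peak times and times to the first correct streaming prediction. Pairs
#' with missing values are dropped; fewer than 3 complete pairs is an
#' error, and zero variance in either variable yields `NA` with a
#' warning.
#'
#' @param peaks,firsts Paired numeric vectors (seconds).
#' @return List of class `attention_correlation`: `r`, `n`, `pairs`
#'   (data.frame for scatter export).
#' @export
attention_correlation <- function(peaks, firsts) {
  if (length(peaks) != length(firsts)) stopf("'peaks' and 'firsts' must be paired")
  ok <- is.finite(peaks) & is.finite(firsts)
  peaks <- peaks[ok]; firsts <- firsts[ok]
  if (length(peaks) < 3L) stopf("need at least 3 complete pairs")
  r <- if (sd(peaks) == 0 || sd(firsts) == 0) {
    warning("zero variance: correlation undefined")
    NA_real_
  } else {
    stats::cor(peaks, firsts)
  }
  structure(list(r = r, n = length(peaks),
                 pairs = data.frame(peak_time = peaks,
                                    time_to_first_correct = firsts)),
            class = "attention_correlation")
}

#' @export
print.attention_correlation <- function(x, ...) {
  cat(sprintf("<attention_correlation> r = %.4f over %d pair(s)\n", x$r, x$n))
  invisible(x)
}
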
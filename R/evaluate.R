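#' Offline evaluation: weighted top-1 / top-3 and confusion matrix
#'
#' Runs every sequence through the model (or any predictor function) and
#' computes class-weighted top-1 and top-3 accuracies and the `G x G`
#' confusion matrix from the argmax predictions. The weight of each
#' sequence is its class weight (inverse frequency, mean 1, per
#' [class_weights()]); with `weights = NULL` the weights are derived from
#' the test set itself. Top-k ties are broken towards the lowest label id.
#'
#' @param model A `tcn_model`, or a function mapping a [gesture_dataset()]
#'   to a `B x G` probability matrix.
#' @param test_set A [gesture_dataset()].
#' @param weights Optional length-`G` class weight vector (typically from
#'   the training set).
#' @param batch_size Sequences per forward batch.
#' @return An object of class `eval_report`: `top1`, `top3`, `confusion`
#'   (rows = truth), `predicted` (0-based labels), `probs`.
#' @export
evaluate_offline <- function(model, test_set, weights = NULL,
                             batch_size = 64L) {
  if (length(test_set$sequences) == 0L) stopf("empty test set")
  G <- test_set$n_labels
  labels <- dataset_labels0(test_set)
  if (is.function(model)) {
    probs <- model(test_set)
  } else {
    n <- length(test_set$sequences)
    probs <- do.call(rbind, lapply(seq.int(1L, n, by = batch_size), function(b0)
      predict(model, test_set$sequences[b0:min(b0 + batch_size - 1L, n)])))
  }
  if (ncol(probs) != G) stopf("predictor returned %d columns, expected G = %d",
                              ncol(probs), G)
  weights <- weights %||% class_weights(test_set)
  w <- weights[labels + 1L]

  pred <- top1_labels(probs)
  # top-3: the three largest probabilities, ties towards the lowest label id
  in_top3 <- vapply(seq_len(nrow(probs)), function(i) {
    ord <- order(-probs[i, ], seq_len(G))[1:3] - 1L
    labels[i] %in% ord
  }, logical(1))

  top1 <- sum(w * (pred == labels)) / sum(w)
  top3 <- sum(w * in_top3) / sum(w)
  confusion <- matrix(0L, G, G, dimnames = list(truth = 0:(G - 1L),
                                                predicted = 0:(G - 1L)))
  for (i in seq_along(labels))
    confusion[labels[i] + 1L, pred[i] + 1L] <-
      confusion[labels[i] + 1L, pred[i] + 1L] + 1L
  structure(list(top1 = top1, top3 = top3, confusion = confusion,
                 predicted = pred, labels = labels, probs = probs,
                 weights = weights),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d sequences: weighted top-1 %.4f, top-3 %.4f\n",
              length(x$labels), x$top1, x$top3))
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Metrics and per-sequence predictions go to JSON; the confusion matrix
#' additionally to a tab-delimited file (`<path>.confusion.tsv`).
#'
#' @param report An `eval_report`.
#' @param path JSON file path.
#' @return The path, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(list(top1 = report$top1, top3 = report$top3,
                            predicted = report$predicted,
                            labels = report$labels),
                       path, auto_unbox = TRUE, digits = NA)
  write.table(report$confusion, paste0(path, ".confusion.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  invisible(path)
}

#' Per-gesture average attention profiles
#'
#' For a model with the attention head, extracts each sequence's attention
#' weight vector, linearly resamples it to the gesture's median duration,
#' renormalizes to sum 1 and averages within gesture. The peak time is the
#' argmax of the average curve in seconds.
#'
#' @param model A `tcn_model` with `head = "att"`.
#' @param dataset A [gesture_dataset()].
#' @return A list of class `attention_profiles`; one entry per observed
#'   gesture with `label`, `curve`, `time` (seconds) and `peak_time`.
#' @export
extract_attention_profile <- function(model, dataset) {
  if (model$config$head != "att")
    stopf("attention profiles require a model with the attention head")
  labels <- dataset_labels0(dataset)
  atts <- lapply(dataset$sequences, function(s) {
    fw <- tcn_forward(model, s)
    as.numeric(fw$attention)[seq_len(nrow(s$samples))]
  })
  rate <- dataset$rate
  out <- lapply(sort(unique(labels)), function(g) {
    sel <- which(labels == g)
    lens <- lengths(atts[sel])
    target <- as.integer(round(median(lens)))
    curves <- vapply(atts[sel], function(a) {
      if (length(a) == target) return(a)
      r <- approx(seq(0, 1, length.out = length(a)), a,
                  xout = seq(0, 1, length.out = target))$y
      r / sum(r)
    }, numeric(target))
    curve <- rowMeans(matrix(curves, nrow = target))
    tt <- (seq_len(target) - 1L) / rate
    list(label = g, curve = curve, time = tt,
         peak_time = tt[which.max(curve)])
  })
  names(out) <- vapply(out, function(p) as.character(p$label), character(1))
  structure(out, class = "attention_profiles")
}

#' @export
print.attention_profiles <- function(x, ...) {
  cat(sprintf("<attention_profiles> %d gesture(s); peak times (s): %s\n",
              length(x),
              paste(sprintf("%s=%.2f", names(x),
                            vapply(x, function(p) p$peak_time, numeric(1))),
                    collapse = ", ")))
  invisible(x)
}
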
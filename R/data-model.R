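#' One sEMG gesture repetition
#'
#' An `emg_sequence` holds the multichannel recording of a single gesture
#' repetition: an `N x C` matrix of samples (time-major, 0-based timestep
#' semantics, half-open intervals throughout the package) together with its
#' sampling rate, gesture label, repetition index and subject id.
#'
#' @param samples Numeric matrix, `N` timesteps by `C` channels.
#' @param rate Sampling frequency in Hz (positive scalar).
#' @param label Integer gesture id in `[0, G - 1]`; 0 denotes rest.
#' @param repetition Integer repetition index (DB1 uses 1..10).
#' @param subject Integer subject id.
#' @return An object of class `emg_sequence`.
#' @examples
#' s <- emg_sequence(matrix(rnorm(100), 50, 2), rate = 100, label = 3,
#'                   repetition = 2)
#' nrow(s$samples)
#' @export
emg_sequence <- function(samples, rate, label, repetition = 1L, subject = 1L) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  dimnames(samples) <- NULL
  if (nrow(samples) < 1L || ncol(samples) < 1L)
    stopf("'samples' must have at least one timestep and one channel")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stopf("'rate' must be a positive sampling frequency in Hz")
  if (!is_count(label, min = 0L)) stopf("'label' must be a non-negative integer")
  structure(
    list(samples = samples, rate = as.numeric(rate), label = as.integer(label),
         repetition = as.integer(repetition), subject = as.integer(subject)),
    class = "emg_sequence")
}

#' @export
print.emg_sequence <- function(x, ...) {
  cat(sprintf("<emg_sequence> %d samples x %d channels @ %g Hz, label %d, rep %d, subject %d\n",
              nrow(x$samples), ncol(x$samples), x$rate, x$label, x$repetition,
              x$subject))
  invisible(x)
}

#' A collection of sEMG sequences sharing channel layout and rate
#'
#' @param sequences List of [emg_sequence()] objects.
#' @param n_labels Number of gesture classes `G` (labels run `0..G-1`, rest =
#'   0). Defaults to `max(label) + 1`.
#' @param rate Sampling rate; defaults to (and must equal) the rate shared by
#'   all members.
#' @return An object of class `gesture_dataset` with fields `sequences`,
#'   `n_labels`, `channels`, `rate`.
#' @export
gesture_dataset <- function(sequences, n_labels = NULL, rate = NULL) {
  if (length(sequences) == 0L) stopf("'sequences' must be non-empty")
  if (!all(vapply(sequences, inherits, logical(1), "emg_sequence")))
    stopf("all members of 'sequences' must be emg_sequence objects")
  channels <- ncol(sequences[[1L]]$samples)
  rates <- vapply(sequences, function(s) s$rate, numeric(1))
  chans <- vapply(sequences, function(s) ncol(s$samples), integer(1))
  if (any(chans != channels)) stopf("all sequences must share the channel count")
  if (length(unique(rates)) != 1L) stopf("all sequences must share the sampling rate")
  if (!is.null(rate) && rate != rates[1L]) stopf("'rate' disagrees with sequence rates")
  labels <- dataset_labels0(sequences)
  n_labels <- as.integer(n_labels %||% (max(labels) + 1L))
  if (any(labels >= n_labels))
    stopf("label %d exceeds n_labels - 1 = %d", max(labels), n_labels - 1L)
  structure(list(sequences = sequences, n_labels = n_labels,
                 channels = channels, rate = rates[1L]),
            class = "gesture_dataset")
}

dataset_labels0 <- function(x) {
  seqs <- if (inherits(x, "gesture_dataset")) x$sequences else x
  vapply(seqs, function(s) s$label, integer(1))
}

#' Per-sequence metadata of a dataset
#'
#' @param dataset A [gesture_dataset()].
#' @return A data.frame with one row per sequence: `label`, `repetition`,
#'   `subject`, `n_samples`.
#' @export
dataset_summary <- function(dataset) {
  data.frame(
    label = dataset_labels0(dataset),
    repetition = vapply(dataset$sequences, function(s) s$repetition, integer(1)),
    subject = vapply(dataset$sequences, function(s) s$subject, integer(1)),
    n_samples = vapply(dataset$sequences, function(s) nrow(s$samples), integer(1)))
}

#' @export
print.gesture_dataset <- function(x, ...) {
  cat(sprintf("<gesture_dataset> %d sequences, G = %d labels, C = %d channels @ %g Hz\n",
              length(x$sequences), x$n_labels, x$channels, x$rate))
  invisible(x)
}

#' @export
length.gesture_dataset <- function(x) length(x$sequences)

#' Repetition-based train/test split specification
#'
#' Intra-subject evaluation on DB1 splits by repetition index, never randomly:
#' the canonical protocol trains on repetitions 1, 3, 4, 6, 8, 9, 10 and
#' tests on 2, 5, 7.
#'
#' @param train_repetitions,test_repetitions Disjoint integer sets, union
#'   within 1..10.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_repetitions = c(1L, 3L, 4L, 6L, 8L, 9L, 10L),
                       test_repetitions = c(2L, 5L, 7L)) {
  tr <- sort(unique(as.integer(train_repetitions)))
  te <- sort(unique(as.integer(test_repetitions)))
  if (length(intersect(tr, te)) > 0L)
    stopf("train and test repetition sets must be disjoint")
  if (!all(c(tr, te) %in% 1:10))
    stopf("repetition indices must lie in 1..10")
  structure(list(train_repetitions = tr, test_repetitions = te),
            class = "split_spec")
}

#' Split a dataset by repetition membership
#'
#' Partitions the dataset into train and test subsets according to a
#' [split_spec()]. Sequence order within each subset follows the input order,
#' so the split is deterministic. A sequence whose repetition index belongs to
#' neither set is a configuration error and is reported, not silently dropped.
#'
#' @param dataset A [gesture_dataset()].
#' @param spec A [split_spec()].
#' @return A list with elements `train` and `test`, each a `gesture_dataset`
#'   (or `NULL` when a side is empty).
#' @examples
#' # DB1 structure: 53 labels x 10 repetitions -> 371 train / 159 test
#' @export
split_intra_subject <- function(dataset, spec = split_spec()) {
  reps <- vapply(dataset$sequences, function(s) s$repetition, integer(1))
  unknown <- setdiff(unique(reps), c(spec$train_repetitions, spec$test_repetitions))
  if (length(unknown) > 0L)
    stopf("repetition(s) %s belong to neither the train nor the test set",
          paste(unknown, collapse = ", "))
  mk <- function(idx) {
    if (length(idx) == 0L) return(NULL)
    gesture_dataset(dataset$sequences[idx], n_labels = dataset$n_labels)
  }
  list(train = mk(which(reps %in% spec$train_repetitions)),
       test = mk(which(reps %in% spec$test_repetitions)))
}

#' Inverse-frequency class weights
#'
#' The idle (rest) gesture is heavily overrepresented in DB1-style data, so
#' evaluation metrics weight each gesture inversely proportionally to its
#' number of sequences. Weights are normalized to mean 1 so that a balanced
#' dataset yields unit weights.
#'
#' @param dataset A [gesture_dataset()], or an integer vector of per-class
#'   counts (length `G`).
#' @param n_labels Number of classes; defaults to `dataset$n_labels`.
#' @return Numeric weight vector of length `G` (index `g + 1` holds the
#'   weight of label `g`).
#' @examples
#' class_weights(c(30, 10))  # -> 0.5, 1.5
#' @export
class_weights <- function(dataset, n_labels = NULL) {
  if (inherits(dataset, "gesture_dataset")) {
    n_labels <- n_labels %||% dataset$n_labels
    counts <- tabulate(dataset_labels0(dataset) + 1L, nbins = n_labels)
  } else {
    counts <- as.numeric(dataset)
    n_labels <- n_labels %||% length(counts)
  }
  absent <- which(counts == 0) - 1L
  if (length(absent) > 0L)
    stopf("no sequences for label(s): %s", paste(absent, collapse = ", "))
  w <- 1 / counts
  w / mean(w)
}
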
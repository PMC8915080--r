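# Reading DB1-structured records and the plain-text dataset interchange
# format used for fixtures and CLI round-trips.

read_array_file <- function(dir, stems) {
  for (stem in stems) {
    for (ext in c("csv", "tsv", "txt")) {
      f <- file.path(dir, paste0(stem, ".", ext))
      if (file.exists(f)) {
        sep <- if (ext == "csv") "," else "\t"
        return(as.matrix(read.table(f, sep = sep, header = FALSE)))
      }
    }
  }
  NULL
}

#' Read a DB1-structured record
#'
#' A record is a directory holding the continuous signal of one acquisition
#' session as delimited-text arrays: `emg` (one row per sample, one column
#' per electrode), a per-sample gesture label vector (`stimulus` or
#' `restimulus`), and a per-sample repetition vector (`repetition` or
#' `rerepetition`). An optional `manifest.json` may carry `rate` and
#' `n_labels`; the DB1 default of 100 Hz is assumed otherwise. The signal is
#' segmented into one [emg_sequence()] per maximal run of constant
#' (label, repetition); rest runs carry label 0. No onset/offset trimming is
#' applied.
#'
#' @param path Directory containing the record.
#' @param subject Integer subject id attached to every sequence.
#' @param rate Sampling rate override; default comes from the manifest or
#'   100 Hz.
#' @param include_rest Keep rest (label 0) segments? Default `TRUE`.
#' @return A [gesture_dataset()].
#' @export
read_db1_record <- function(path, subject = 1L, rate = NULL,
                            include_rest = TRUE) {
  if (!dir.exists(path)) stopf("record directory '%s' does not exist", path)
  emg <- read_array_file(path, "emg")
  stim <- read_array_file(path, c("stimulus", "restimulus"))
  reps <- read_array_file(path, c("repetition", "rerepetition"))
  if (is.null(emg)) stopf("format error: record lacks an 'emg' array")
  if (is.null(stim))
    stopf("format error: record lacks a 'stimulus'/'restimulus' array")
  if (is.null(reps))
    stopf("format error: record lacks a 'repetition'/'rerepetition' array")
  stim <- as.integer(stim)
  reps <- as.integer(reps)
  if (length(stim) == 0L || nrow(emg) == 0L)
    stopf("format error: empty label or signal array")
  if (nrow(emg) != length(stim) || length(stim) != length(reps))
    stopf("format error: emg (%d), stimulus (%d) and repetition (%d) lengths differ",
          nrow(emg), length(stim), length(reps))
  manifest <- file.path(path, "manifest.json")
  meta <- if (file.exists(manifest)) jsonlite::read_json(manifest) else list()
  rate <- rate %||% meta$rate %||% 100
  # maximal runs of constant (label, repetition)
  brk <- c(TRUE, stim[-1L] != stim[-length(stim)] | reps[-1L] != reps[-length(reps)])
  run_id <- cumsum(brk)
  starts <- which(brk)
  run_lab <- stim[starts]
  run_rep <- reps[starts]
  # DB1 marks rest with repetition 0; inherit the following gesture's
  # repetition so rest segments partition cleanly by repetition too
  for (i in seq_along(run_rep)) {
    if (run_rep[i] == 0L) {
      nxt <- which(run_rep[seq_along(run_rep) > i] > 0L)
      run_rep[i] <- if (length(nxt) > 0L) run_rep[i + nxt[1L]]
                    else if (i > 1L) run_rep[i - 1L] else 1L
    }
  }
  out <- list()
  for (id in seq_along(starts)) {
    idx <- which(run_id == id)
    if (!include_rest && run_lab[id] == 0L) next
    out[[length(out) + 1L]] <- emg_sequence(
      emg[idx, , drop = FALSE], rate = rate, label = run_lab[id],
      repetition = run_rep[id], subject = subject)
  }
  n_labels <- as.integer(meta$n_labels %||% (max(stim) + 1L))
  gesture_dataset(out, n_labels = n_labels)
}

#' Write / read a dataset as a directory of delimited-text files
#'
#' The interchange layout is a `manifest.json` (rate, `G`, `C`, per-sequence
#' metadata) plus one headerless CSV per sequence under `sequences/`. It is
#' the fixture format for tests and the CLI.
#'
#' @param dataset A [gesture_dataset()].
#' @param dir Target directory (created if needed).
#' @return `write_gesture_dataset()` returns `dir` invisibly;
#'   `read_gesture_dataset()` returns a [gesture_dataset()].
#' @export
write_gesture_dataset <- function(dataset, dir) {
  seqdir <- file.path(dir, "sequences")
  dir.create(seqdir, recursive = TRUE, showWarnings = FALSE)
  meta <- dataset_summary(dataset)
  meta$file <- sprintf("sequences/seq_%05d.csv", seq_len(nrow(meta)))
  for (i in seq_along(dataset$sequences)) {
    write.table(dataset$sequences[[i]]$samples, file.path(dir, meta$file[i]),
                sep = ",", row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(
    list(rate = dataset$rate, n_labels = dataset$n_labels,
         channels = dataset$channels, sequences = meta),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_gesture_dataset
#' @export
read_gesture_dataset <- function(dir) {
  manifest <- file.path(dir, "manifest.json")
  if (!file.exists(manifest)) stopf("no manifest.json under '%s'", dir)
  meta <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  seqs <- lapply(seq_len(nrow(meta$sequences)), function(i) {
    m <- meta$sequences[i, ]
    emg_sequence(as.matrix(read.table(file.path(dir, m$file), sep = ",")),
                 rate = meta$rate, label = m$label, repetition = m$repetition,
                 subject = m$subject)
  })
  gesture_dataset(seqs, n_labels = meta$n_labels)
}
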
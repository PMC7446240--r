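#' Epoched multi-channel trials
#'
#' A `channel_epochs` object holds a trials x channels x samples array of
#' epoched recordings together with the sampling rate, the time of the first
#' sample relative to the alignment event, and a per-trial condition label.
#'
#' @param data numeric array, trials x channels x samples.
#' @param fs sampling rate in Hz (> 0).
#' @param labels character vector of per-trial condition labels.
#' @param t0_ms time of the first sample relative to the event, in ms.
#' @return an object of class `channel_epochs`.
#' @export
channel_epochs <- function(data, fs, labels, t0_ms = 0) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("data must be trials x channels x samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  labels <- as.character(labels)
  if (length(labels) != dim(data)[1L]) {
    stop("labels length must equal the number of trials")
  }
  if (anyNA(data)) stop("epoch data contain NA")
  structure(list(data = data, fs = fs, labels = labels, t0_ms = t0_ms),
            class = "channel_epochs")
}

#' @export
print.channel_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<channel_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
    d[1L], d[2L], d[3L], x$fs))
  cat(sprintf("  time: [%g, %g) ms, %d conditions\n", x$t0_ms,
              x$t0_ms + d[3L] / x$fs * 1000, length(unique(x$labels))))
  invisible(x)
}

# Time axis (ms) of the sample grid.
epoch_times_ms <- function(epochs) {
  d <- dim(epochs$data)
  epochs$t0_ms + (seq_len(d[3L]) - 1L) / epochs$fs * 1000
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean signal over a baseline window
#' (typically the pre-event fixation period).
#'
#' @param epochs a [channel_epochs] object.
#' @param baseline_window numeric length-2, half-open window `[t0, t1)` in ms
#'   relative to the alignment event.
#' @return a [channel_epochs] object.
#' @export
baseline_correct <- function(epochs, baseline_window) {
  stopifnot(inherits(epochs, "channel_epochs"), length(baseline_window) == 2L)
  t <- epoch_times_ms(epochs)
  sel <- t >= baseline_window[1L] & t < baseline_window[2L]
  if (!any(sel)) stop("baseline window lies outside the epoch")
  base <- apply(epochs$data[, , sel, drop = FALSE], c(1L, 2L), mean)
  epochs$data <- epochs$data - as.vector(base)  # recycles over samples
  epochs
}

#' Write / read epochs as delimited text plus a JSON sidecar
#'
#' The interchange format is a directory containing one CSV per trial
#' (channels x samples, no headers) and a `meta.json` sidecar with the
#' sampling rate, epoch start time, and per-trial condition labels.
#'
#' @param epochs a [channel_epochs] object.
#' @param dir directory to create/read.
#' @return `write_epochs` returns `dir` invisibly; `read_epochs` returns a
#'   [channel_epochs] object.
#' @export
write_epochs <- function(epochs, dir) {
  stopifnot(inherits(epochs, "channel_epochs"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs$data)
  files <- sprintf("trial_%04d.csv", seq_len(d[1L]))
  for (i in seq_len(d[1L])) {
    utils::write.table(epochs$data[i, , , drop = TRUE],
                       file.path(dir, files[i]),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  meta <- list(fs = epochs$fs, t0_ms = epochs$t0_ms, labels = epochs$labels,
               n_channels = d[2L], n_samples = d[3L], files = files)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("no meta.json sidecar in ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  n_trials <- length(meta$files)
  data <- array(NA_real_, c(n_trials, meta$n_channels, meta$n_samples))
  for (i in seq_len(n_trials)) {
    m <- as.matrix(utils::read.table(file.path(dir, meta$files[i]), sep = ","))
    data[i, , ] <- m
  }
  channel_epochs(data, fs = meta$fs, labels = meta$labels, t0_ms = meta$t0_ms)
}

#' Read / write event tables
#'
#' Event tables are TSV files with columns `onset_s`, `duration_s`,
#' `condition`, one row per block.
#' @param events data frame with those columns.
#' @param path file path.
#' @return `read_events` returns the validated data frame.
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("onset_s", "duration_s", "condition") %in% names(events)))
  utils::write.table(events, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("onset_s", "duration_s", "condition") %in% names(ev))) {
    stop("event table must have onset_s, duration_s, condition columns: ", path)
  }
  ev
}
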
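#' Construct a continuous EEG-style recording
#'
#' Container for a multichannel recording with a stimulus event table, the
#' sensor-space entry point of the pipeline. Amplitudes are in microvolts.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param sample_rate sampling rate in Hz.
#' @param events data frame with columns `sample` (0-based stimulus latency in
#'   samples), `condition` (`"Go"` or `"NoGo"`) and `correct` (logical).
#' @param channel_labels optional character vector of channel names.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sample_rate, events,
                          channel_labels = NULL) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("recording data must be finite", call. = FALSE)
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be positive", call. = FALSE)
  events <- as.data.frame(events)
  req <- c("sample", "condition", "correct")
  if (!all(req %in% names(events)))
    stop("events needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  if (nrow(events) && (min(events$sample) < 0 || max(events$sample) >= ncol(data)))
    stop("event latencies must lie within [0, n_samples)", call. = FALSE)
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  structure(
    list(data = data, sample_rate = sample_rate, events = events,
         channel_labels = channel_labels),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$sample_rate, nrow(x$events)))
  invisible(x)
}

# internal epoch-set constructor; data is trials x channels x samples
new_epoch_set <- function(data, times_ms, sample_rate, condition, correct,
                          channel_labels = NULL) {
  stopifnot(length(dim(data)) == 3L,
            dim(data)[3L] == length(times_ms),
            dim(data)[1L] == length(condition),
            length(condition) == length(correct))
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(dim(data)[2L]))
  structure(
    list(data = data, times_ms = times_ms, sample_rate = sample_rate,
         condition = as.character(condition), correct = as.logical(correct),
         channel_labels = channel_labels),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d trials x %d channels x %d samples @ %g Hz [%g, %g) ms\n",
    d[1L], d[2L], d[3L], x$sample_rate, min(x$times_ms),
    max(x$times_ms) + 1000 / x$sample_rate))
  tab <- table(x$condition)
  cat("  conditions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      sprintf("| correct: %d/%d\n", sum(x$correct), d[1L]))
  invisible(x)
}

#' @export
`[.epoch_set` <- function(x, i, ...) {
  new_epoch_set(x$data[i, , , drop = FALSE], x$times_ms, x$sample_rate,
                x$condition[i], x$correct[i], x$channel_labels)
}

n_epochs <- function(x) dim(x$data)[1L]

#' Zero-phase band-pass filter
#'
#' Applies a zero-phase band-pass (the squared magnitude response of an
#' order-`order` Butterworth, i.e. the response of forward-backward
#' filtering) to every channel. Works on continuous recordings, epoch sets
#' and plain samples-in-rows matrices; output length equals input length.
#'
#' @param x an `eeg_recording`, `epoch_set`, or samples x channels matrix.
#' @param f_lo,f_hi band edges in Hz; `0 <= f_lo < f_hi < sample_rate/2`.
#'   `f_lo = 0` gives a low-pass.
#' @param order Butterworth order of the underlying single-pass filter
#'   (default 4, so the effective two-pass roll-off is 8th order).
#' @param sample_rate required when `x` is a bare matrix.
#' @param ... passed on to methods.
#'
#' @return An object of the same class as `x`, filtered.
#' @export
bandpass_filter <- function(x, f_lo, f_hi, order = 4L, ...) {
  UseMethod("bandpass_filter")
}

#' @rdname bandpass_filter
#' @export
bandpass_filter.eeg_recording <- function(x, f_lo, f_hi, order = 4L, ...) {
  x$data <- t(.zero_phase_bandpass(t(x$data), x$sample_rate, f_lo, f_hi, order))
  x
}

#' @rdname bandpass_filter
#' @export
bandpass_filter.epoch_set <- function(x, f_lo, f_hi, order = 4L, ...) {
  d <- dim(x$data)
  mat <- .epochs_to_mat(x$data)
  mat <- .zero_phase_bandpass(mat, x$sample_rate, f_lo, f_hi, order)
  x$data <- .mat_to_epochs(mat, d[1L], d[2L])
  x
}

#' @rdname bandpass_filter
#' @export
bandpass_filter.matrix <- function(x, f_lo, f_hi, order = 4L,
                                   sample_rate, ...) {
  .zero_phase_bandpass(x, sample_rate, f_lo, f_hi, order)
}

#' Cut stimulus-locked epochs from a recording
#'
#' Extracts one epoch per event using the half-open window
#' `[tmin_ms, tmax_ms)`, so at 1000 Hz the default window holds exactly 1000
#' samples. Events too close to the recording edge are skipped with a
#' warning.
#'
#' @param recording an [eeg_recording()].
#' @param tmin_ms,tmax_ms epoch window relative to the stimulus, in ms.
#'
#' @return An `epoch_set` with condition and correctness labels preserved in
#'   event order.
#' @export
epoch_recording <- function(recording, tmin_ms = -100, tmax_ms = 900) {
  stopifnot(inherits(recording, "eeg_recording"), tmin_ms < tmax_ms)
  fs <- recording$sample_rate
  off_lo <- as.integer(round(tmin_ms * fs / 1000))
  off_hi <- as.integer(round(tmax_ms * fs / 1000)) - 1L  # half-open
  n_samp <- off_hi - off_lo + 1L
  ev <- recording$events
  total <- ncol(recording$data)
  first <- ev$sample + off_lo
  last <- ev$sample + off_hi
  ok <- first >= 0L & last < total
  if (any(!ok))
    warning(sprintf("%d event(s) too close to the recording edge were skipped",
                    sum(!ok)), call. = FALSE)
  ev <- ev[ok, , drop = FALSE]
  if (nrow(ev) == 0L)
    return(new_epoch_set(
      array(numeric(0), c(0L, nrow(recording$data), n_samp)),
      (off_lo:off_hi) * 1000 / fs, fs, character(0), logical(0),
      recording$channel_labels))
  n_ch <- nrow(recording$data)
  data <- array(NA_real_, c(nrow(ev), n_ch, n_samp))
  for (k in seq_len(nrow(ev))) {
    idx <- (ev$sample[k] + off_lo):(ev$sample[k] + off_hi) + 1L
    data[k, , ] <- recording$data[, idx]
  }
  new_epoch_set(data, (off_lo:off_hi) * 1000 / fs, fs,
                ev$condition, ev$correct, recording$channel_labels)
}

#' Amplitude-threshold artifact rejection
#'
#' Removes every epoch in which any channel sample strictly exceeds
#' `+threshold_uv` or falls strictly below `-threshold_uv` (boundary values
#' are retained). The default mirrors the conventional +/- 75 microvolt
#' criterion.
#'
#' @param epochs an `epoch_set`.
#' @param threshold_uv rejection threshold in microvolts (> 0).
#'
#' @return A list with elements `epochs` (the retained `epoch_set`) and
#'   `log` (list with `n_total`, `n_kept`, `n_removed`, `removed_idx`).
#' @export
reject_artifacts <- function(epochs, threshold_uv = 75) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!is.numeric(threshold_uv) || threshold_uv <= 0)
    stop("threshold_uv must be positive", call. = FALSE)
  n <- n_epochs(epochs)
  bad <- vapply(seq_len(n),
                function(k) any(abs(epochs$data[k, , ]) > threshold_uv),
                logical(1))
  keep <- which(!bad)
  list(
    epochs = epochs[keep],
    log = list(n_total = n, n_kept = length(keep),
               n_removed = n - length(keep), removed_idx = which(bad))
  )
}

#' Select epochs by condition and correctness
#'
#' @param epochs an `epoch_set`.
#' @param condition condition label to retain (default `"NoGo"`).
#' @param correct_only if `TRUE` (default) keep only correct-response trials.
#'
#' @return The matching `epoch_set`; errors if no epoch matches.
#' @export
select_condition <- function(epochs, condition = "NoGo", correct_only = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (n_epochs(epochs) == 0L) stop("epoch set is empty", call. = FALSE)
  keep <- epochs$condition == condition
  if (correct_only) keep <- keep & epochs$correct
  if (!any(keep))
    stop(sprintf("no epochs match condition '%s'%s", condition,
                 if (correct_only) " with correct responses" else ""),
         call. = FALSE)
  epochs[which(keep)]
}

#' EOG regression artifact correction
#'
#' Optional plumbing: subtracts, per channel, the least-squares projection of
#' the data onto one or more ocular reference channels. Not a substitute for
#' a full ocular-artifact model; provided so a sensor-space chain can be
#' exercised end to end.
#'
#' @param recording an [eeg_recording()].
#' @param eog_channels indices or labels of the ocular channels.
#'
#' @return The recording with EOG channels regressed out of the remaining
#'   channels (EOG channels themselves are dropped).
#' @export
regress_eog <- function(recording, eog_channels) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (is.character(eog_channels))
    eog_channels <- match(eog_channels, recording$channel_labels)
  if (anyNA(eog_channels) || !length(eog_channels))
    stop("unknown EOG channel(s)", call. = FALSE)
  eog <- t(recording$data[eog_channels, , drop = FALSE])
  rest <- setdiff(seq_len(nrow(recording$data)), eog_channels)
  y <- t(recording$data[rest, , drop = FALSE])
  beta <- qr.solve(cbind(1, eog), y)
  cleaned <- y - cbind(1, eog) %*% beta
  recording$data <- t(cleaned)
  recording$channel_labels <- recording$channel_labels[rest]
  recording
}
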
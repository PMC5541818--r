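# Preprocessing chain: band-pass filter, downsample, epoch extraction,
# baseline correction. The canonical order is
#   bandpass_filter() -> downsample_recording() -> extract_epochs() ->
#   baseline_correct()
# yielding 1000 ms stimulus-locked epochs at 600 Hz (600 samples/channel).

#' Zero-phase band-pass filter a recording
#'
#' 4th-order Butterworth high-pass and low-pass applied in cascade, each
#' forward and backward (zero phase). The cascade is used instead of a
#' single band-pass polynomial because with band edges as extreme as
#' 0.5 Hz at a 2400 Hz rate the 8-pole transfer function is numerically
#' unstable, while the split sections are well conditioned. Default band
#' 0.5--60 Hz.
#'
#' @param raw A `raw_recording`.
#' @param low_hz,high_hz Band edges; `0 < low_hz < high_hz < fs/2`.
#' @return The filtered `raw_recording` (same shape and sampling rate).
#' @export
bandpass_filter <- function(raw, low_hz = 0.5, high_hz = 60) {
  stopifnot(inherits(raw, "raw_recording"))
  check_scalar_number(low_hz, "low_hz")
  check_scalar_number(high_hz, "high_hz")
  nyq <- raw$fs_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stopf("invalid band edges: need 0 < low_hz < high_hz < fs/2 = %g", nyq)
  }
  hp <- signal::butter(4, low_hz / nyq, type = "high")
  lp <- signal::butter(4, high_hz / nyq, type = "low")
  for (ch in seq_len(nrow(raw$data))) {
    raw$data[ch, ] <- signal::filtfilt(lp, signal::filtfilt(hp, raw$data[ch, ]))
  }
  raw
}

#' Notch-filter the mains component
#'
#' 2nd-order Butterworth band-stop applied zero-phase; part of the simulated
#' acquisition chain (real amplifiers notch at acquisition time).
#'
#' @param raw A `raw_recording`.
#' @param freq_hz Mains frequency (default 50 Hz).
#' @param width_hz Stop-band full width.
#' @return The filtered `raw_recording`.
#' @export
notch_filter <- function(raw, freq_hz = 50, width_hz = 4) {
  stopifnot(inherits(raw, "raw_recording"))
  nyq <- raw$fs_hz / 2
  band <- c(freq_hz - width_hz / 2, freq_hz + width_hz / 2) / nyq
  if (band[1] <= 0 || band[2] >= 1) stopf("notch band outside (0, fs/2)")
  bf <- signal::butter(2, band, type = "stop")
  for (ch in seq_len(nrow(raw$data))) {
    raw$data[ch, ] <- signal::filtfilt(bf, raw$data[ch, ])
  }
  raw
}

#' Downsample a recording with anti-alias filtering
#'
#' Integer-factor decimation. The per-channel mean is removed, a zero-phase
#' 6th-order Butterworth low-pass at 80% of the new Nyquist frequency is
#' applied, the mean is restored, and every `factor`-th sample is kept, so a
#' constant signal is preserved exactly. Annotation sample indices are
#' rescaled.
#'
#' @param raw A `raw_recording`.
#' @param target_fs_hz New sampling rate; must divide `fs_hz` evenly and be
#'   lower than it (upsampling is an error).
#' @return The decimated `raw_recording`.
#' @export
downsample_recording <- function(raw, target_fs_hz = 600) {
  stopifnot(inherits(raw, "raw_recording"))
  check_scalar_number(target_fs_hz, "target_fs_hz", lower = 1e-6)
  if (target_fs_hz >= raw$fs_hz) {
    stopf("target_fs_hz (%g) must be below fs_hz (%g); upsampling is not supported",
          target_fs_hz, raw$fs_hz)
  }
  factor <- raw$fs_hz / target_fs_hz
  if (abs(factor - round(factor)) > 1e-9) {
    stopf("fs_hz (%g) must be an integer multiple of target_fs_hz (%g)",
          raw$fs_hz, target_fs_hz)
  }
  factor <- as.integer(round(factor))
  bf <- signal::butter(6, 0.8 / factor)
  keep <- seq(1L, ncol(raw$data), by = factor)
  out <- matrix(0, nrow = nrow(raw$data), ncol = length(keep))
  for (ch in seq_len(nrow(raw$data))) {
    x <- raw$data[ch, ]
    mu <- mean(x)
    y <- signal::filtfilt(bf, x - mu) + mu
    out[ch, ] <- y[keep]
  }
  ann <- raw$annotations
  if (!is.null(ann)) {
    ann$sample_index <- as.integer(round((ann$sample_index - 1L) / factor)) + 1L
  }
  raw_recording(out, target_fs_hz, raw$channel_labels, ann)
}

#' Extract stimulus-locked epochs
#'
#' One epoch per stimulus event in the schedule, labelled target/nontarget
#' and tagged with image and stream identity. Events whose epoch would run
#' past either end of the recording are dropped with a warning, not an
#' error.
#'
#' @param raw A `raw_recording`.
#' @param schedule An `rsvp_schedule` used to locate events when the
#'   recording carries no annotations. Recordings from
#'   [simulate_recording()] (and annotation-bearing loaders) are epoched
#'   from their own annotations, which correctly track lead-in and
#'   downsampling.
#' @param epoch_length_ms Post-stimulus epoch length (default 1000 ms).
#' @param pre_ms Pre-stimulus context to retain for baseline correction
#'   (default 200 ms).
#' @return An object of class `epoch_set`: `data` (epochs x channels x
#'   samples array, uV), `fs_hz`, `labels` (logical), `image_ids`,
#'   `stream_ids`, `epoch_length_ms`, `pre_ms`, `channel_labels`. The sample
#'   axis spans `[-pre_ms, epoch_length_ms)` relative to stimulus onset.
#' @export
extract_epochs <- function(raw, schedule = NULL, epoch_length_ms = 1000,
                           pre_ms = 200) {
  stopifnot(inherits(raw, "raw_recording"))
  check_scalar_number(epoch_length_ms, "epoch_length_ms", lower = 1e-6)
  check_scalar_number(pre_ms, "pre_ms", lower = 0)
  # annotations carried by the recording track any lead-in and downsampling;
  # fall back to schedule onsets for annotation-free recordings
  ev <- if (!is.null(raw$annotations)) raw$annotations else {
    stopifnot(inherits(schedule, "rsvp_schedule"))
    e <- schedule$events
    data.frame(sample_index = as.integer(round(e$onset_s * raw$fs_hz)) + 1L,
               stream = e$stream, image_id = e$image_id,
               is_target = e$is_target)
  }
  if (is.null(ev) || nrow(ev) == 0L) stopf("no events to epoch")

  fs <- raw$fs_hz
  n_post <- as.integer(round(epoch_length_ms / 1000 * fs))
  n_pre <- as.integer(round(pre_ms / 1000 * fs))
  len <- n_pre + n_post
  starts <- ev$sample_index - n_pre
  ok <- starts >= 1L & (starts + len - 1L) <= ncol(raw$data)
  if (!all(ok)) {
    warnf("dropping %d event(s) whose epochs fall outside the recording",
          sum(!ok))
    ev <- ev[ok, , drop = FALSE]
    starts <- starts[ok]
  }
  if (nrow(ev) == 0L) stopf("all epochs fall outside the recording")

  n_ep <- nrow(ev)
  n_ch <- nrow(raw$data)
  idx <- as.integer(outer(starts, 0:(len - 1L), "+"))
  data <- array(0, dim = c(n_ep, n_ch, len))
  for (ch in seq_len(n_ch)) {
    data[, ch, ] <- raw$data[ch, ][idx]
  }

  structure(list(data = data,
                 fs_hz = fs,
                 labels = as.logical(ev$is_target),
                 image_ids = ev$image_id,
                 stream_ids = ev$stream,
                 epoch_length_ms = epoch_length_ms,
                 pre_ms = pre_ms,
                 channel_labels = raw$channel_labels),
            class = "epoch_set")
}

#' Baseline-correct an epoch set
#'
#' Subtracts, per epoch and channel, the mean over a baseline window given
#' in ms relative to stimulus onset (default: the 200 ms immediately before
#' onset). With `window = "whole_epoch"` the whole-epoch mean is used
#' instead. When pre-stimulus context is present and `crop = TRUE`, the
#' pre-stimulus samples are removed afterwards so the epoch spans exactly
#' `[0, epoch_length_ms)`.
#'
#' @param epochs An `epoch_set`.
#' @param baseline_window_ms Length-2 numeric window (ms relative to onset,
#'   e.g. `c(-200, 0)`) or the string `"whole_epoch"`.
#' @param crop Drop pre-stimulus samples after correction (default `TRUE`).
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, baseline_window_ms = c(-200, 0),
                             crop = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- epochs$fs_hz
  len <- dim(epochs$data)[3]
  t_ms <- (seq_len(len) - 1) / fs * 1000 - epochs$pre_ms

  if (identical(baseline_window_ms, "whole_epoch")) {
    sel <- rep(TRUE, len)
  } else {
    if (!is.numeric(baseline_window_ms) || length(baseline_window_ms) != 2L ||
        baseline_window_ms[1] >= baseline_window_ms[2]) {
      stopf("`baseline_window_ms` must be an increasing length-2 window or \"whole_epoch\"")
    }
    sel <- t_ms >= baseline_window_ms[1] & t_ms < baseline_window_ms[2]
    if (!any(sel)) stopf("baseline window contains no samples")
  }

  # mean over the selected samples, per epoch x channel
  d <- dim(epochs$data)
  base_mean <- rowMeans(matrix(epochs$data[, , sel, drop = FALSE],
                               nrow = d[1] * d[2]))
  if (crop && epochs$pre_ms > 0) {   # crop first: one less full-size copy
    keep <- t_ms >= 0
    epochs$data <- epochs$data[, , keep, drop = FALSE]
    epochs$pre_ms <- 0
  }
  epochs$data <- epochs$data - base_mean  # recycles over the sample axis
  epochs
}

#' Subset an epoch set by epoch index
#'
#' @param x An `epoch_set`.
#' @param i Epoch indices (integer or logical).
#' @param ... Unused.
#' @return An `epoch_set` containing the selected epochs.
#' @export
`[.epoch_set` <- function(x, i, ...) {
  x$data <- x$data[i, , , drop = FALSE]
  x$labels <- x$labels[i]
  x$image_ids <- x$image_ids[i]
  x$stream_ids <- x$stream_ids[i]
  x
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs_hz))
  cat(sprintf("  %d targets / %d nontargets; span [%g, %g) ms\n",
              sum(x$labels), sum(!x$labels), -x$pre_ms, x$epoch_length_ms))
  invisible(x)
}

#' Run the full preprocessing chain
#'
#' Band-pass filter, downsample, epoch and baseline-correct in the canonical
#' order.
#'
#' @param raw A `raw_recording`.
#' @param schedule The `rsvp_schedule` defining events.
#' @param low_hz,high_hz Band-pass edges.
#' @param target_fs_hz Rate after downsampling (skipped when equal to the
#'   recording rate).
#' @param epoch_length_ms,pre_ms Epoching parameters.
#' @param baseline_window_ms Baseline window passed to [baseline_correct()].
#' @return An `epoch_set` spanning `[0, epoch_length_ms)` post-stimulus.
#' @export
preprocess <- function(raw, schedule, low_hz = 0.5, high_hz = 60,
                       target_fs_hz = 600, epoch_length_ms = 1000,
                       pre_ms = 200, baseline_window_ms = c(-200, 0)) {
  raw <- bandpass_filter(raw, low_hz, high_hz)
  if (target_fs_hz < raw$fs_hz) {
    raw <- downsample_recording(raw, target_fs_hz)
  }
  ep <- extract_epochs(raw, schedule, epoch_length_ms, pre_ms)
  baseline_correct(ep, baseline_window_ms, crop = TRUE)
}
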
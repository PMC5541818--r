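# Synthetic multi-channel EEG generation locked to an RSVP schedule.
#
# Background activity is AR(1)-filtered Gaussian noise per channel plus a
# sinusoidal mains component. Every attended target presentation adds a
# Gaussian-envelope P300 deflection whose amplitude shrinks and latency
# grows with the repetition index (second/third viewing of the same image),
# projected onto a fixed scalp topography.

#' P300 template for the synthetic EEG generator
#'
#' Describes the planted evoked response per repetition (first, second,
#' third viewing of a target). Defaults: 300 ms / 6 uV on the first viewing,
#' 300 ms / 5.5 uV on the second, 400 ms / 4 uV on the third, 200 ms FWHM,
#' topography maximal at Pz.
#'
#' @param peak_latency_ms Peak latency after stimulus onset, one value per
#'   repetition index.
#' @param amplitude_uV Peak amplitude in microvolts per repetition index,
#'   measured at the maximal channel of the topography (Pz by default), the
#'   convention in which ERP amplitudes are reported.
#' @param width_ms Full width at half maximum of the Gaussian envelope.
#' @param topography Per-channel weight vector; normalised to unit Euclidean
#'   norm. Default: centro-parietal pattern over the standard 16-channel
#'   montage, maximal at Pz.
#' @param channel_labels Channel labels matching `topography`.
#' @return An object of class `erp_template`.
#' @export
erp_template <- function(peak_latency_ms = c(300, 300, 400),
                         amplitude_uV = c(6, 5.5, 4),
                         width_ms = 200,
                         topography = NULL,
                         channel_labels = default_montage()) {
  if (length(peak_latency_ms) != length(amplitude_uV)) {
    stopf("`peak_latency_ms` and `amplitude_uV` must have equal length")
  }
  check_scalar_number(width_ms, "width_ms", lower = 1e-6)
  if (is.null(topography)) {
    topography <- default_topography(channel_labels)
  }
  if (length(topography) != length(channel_labels)) {
    stopf("`topography` length must match `channel_labels`")
  }
  nrm <- sqrt(sum(topography^2))
  if (nrm <= 0) stopf("`topography` must be non-zero")
  topography <- as.numeric(topography / nrm)
  structure(list(peak_latency_ms = as.numeric(peak_latency_ms),
                 amplitude_uV = as.numeric(amplitude_uV),
                 width_ms = as.numeric(width_ms),
                 topography = topography,
                 # per-channel gains such that the maximal channel reaches
                 # amplitude_uV exactly
                 gain = topography / max(abs(topography)),
                 channel_labels = channel_labels),
            class = "erp_template")
}

# Centro-parietal P300-like pattern, maximal at Pz.
default_topography <- function(labels) {
  w <- rep(0.1, length(labels))
  gains <- c(Pz = 1, P3 = 0.6, P4 = 0.6, Cz = 0.5, O1 = 0.4, O2 = 0.4,
             C3 = 0.3, C4 = 0.3)
  hit <- match(names(gains), labels)
  w[hit[!is.na(hit)]] <- gains[!is.na(hit)]
  w
}

#' @export
print.erp_template <- function(x, ...) {
  cat("<erp_template>\n")
  for (r in seq_along(x$peak_latency_ms)) {
    cat(sprintf("  rep %d: peak %g ms, %g uV\n", r, x$peak_latency_ms[r],
                x$amplitude_uV[r]))
  }
  cat(sprintf("  FWHM %g ms; topography max at %s\n", x$width_ms,
              x$channel_labels[which.max(abs(x$topography))]))
  invisible(x)
}

#' Simulate a continuous multi-channel EEG recording
#'
#' Generates background EEG (AR(1) noise), mains interference, and planted
#' P300 deflections at every target presentation that is attended according
#' to the gaze trace. Unattended presentations contribute no evoked
#' component -- the premise that images missed during gaze travel carry no
#' P300. The repetition index of a presentation is its stream's position in
#' the viewing order (left = 1, right = 2, bottom = 3).
#'
#' @param schedule An `rsvp_schedule`.
#' @param gaze A `gaze_trace`; computed by [derive_gaze()] with defaults if
#'   `NULL`.
#' @param template An [erp_template()].
#' @param fs_hz Sampling rate (>= 600 Hz).
#' @param noise_sd_uV Marginal standard deviation of the AR(1) background.
#' @param line_noise_uV Amplitude of the mains sinusoid.
#' @param line_freq_hz Mains frequency (default 50 Hz).
#' @param ar_coef AR(1) coefficient of the background process, defined per
#'   sample at the acquisition reference rate `ar_ref_fs_hz` and adapted to
#'   the simulation rate as `ar_coef^(ar_ref_fs_hz/fs_hz)`, so the noise
#'   autocorrelation time (about 8 ms at the defaults) does not depend on
#'   the rate the recording is generated at.
#' @param ar_ref_fs_hz Reference rate at which `ar_coef` is defined
#'   (default 2400 Hz, the acquisition rate).
#' @param duration_s Recording length; default covers the last event plus
#'   1.5 s. An explicit shorter duration is an error.
#' @param lead_in_s Quiet lead-in prepended before the first stimulus
#'   (default 2 s) so that pre-stimulus baselines exist for every event;
#'   annotation sample indices include the lead-in.
#' @param seed Integer seed; the recording is deterministic given the seed.
#' @return An object of class `raw_recording`: `data` (channels x samples
#'   matrix, uV), `fs_hz`, `channel_labels`, `annotations` (data frame with
#'   `sample_index`, `onset_s`, `stream`, `image_id`, `is_target`).
#' @examples
#' sched <- generate_schedule(n_streams = 1, n_blocks = 1,
#'                            images_per_block = 20, targets_per_block = 2,
#'                            min_target_gap_frames = 3, seed = 1)
#' rec <- simulate_recording(sched, fs_hz = 600, seed = 1)
#' dim(rec$data)
#' @export
simulate_recording <- function(schedule,
                               gaze = NULL,
                               template = erp_template(),
                               fs_hz = 600,
                               noise_sd_uV = 10,
                               line_noise_uV = 2,
                               line_freq_hz = 50,
                               ar_coef = 0.95,
                               ar_ref_fs_hz = 2400,
                               duration_s = NULL,
                               lead_in_s = 2,
                               seed = 1L) {
  stopifnot(inherits(schedule, "rsvp_schedule"),
            inherits(template, "erp_template"))
  check_scalar_number(fs_hz, "fs_hz", lower = 600)
  check_scalar_number(noise_sd_uV, "noise_sd_uV", lower = 0)
  check_scalar_number(line_noise_uV, "line_noise_uV", lower = 0)
  check_scalar_number(ar_coef, "ar_coef", lower = 0, upper = 0.999)
  if (fs_hz <= 2 * line_freq_hz) {
    stopf("fs_hz must exceed twice the mains frequency")
  }
  if (is.null(gaze)) gaze <- derive_gaze(schedule)
  stopifnot(inherits(gaze, "gaze_trace"))

  check_scalar_number(lead_in_s, "lead_in_s", lower = 0)
  labels <- template$channel_labels
  n_ch <- length(labels)
  ev <- schedule$events
  need_s <- max(ev$onset_s) + lead_in_s + 1.5
  if (is.null(duration_s)) duration_s <- need_s
  if (duration_s < need_s) {
    stopf("recording duration %.2f s too short for events (need >= %.2f s)",
          duration_s, need_s)
  }
  n_samp <- ceiling(duration_s * fs_hz)

  a_eff <- ar_coef^(ar_ref_fs_hz / fs_hz)
  data <- with_seed(seed, {
    innov_sd <- noise_sd_uV * sqrt(1 - a_eff^2)
    m <- matrix(rnorm(n_ch * n_samp, sd = innov_sd), nrow = n_ch)
    for (ch in seq_len(n_ch)) {
      m[ch, ] <- as.numeric(stats::filter(m[ch, ], a_eff,
                                          method = "recursive"))
    }
    if (line_noise_uV > 0) {
      tt <- (seq_len(n_samp) - 1) / fs_hz
      line <- line_noise_uV * sin(2 * pi * line_freq_hz * tt)
      m <- m + matrix(line, nrow = n_ch, ncol = n_samp, byrow = TRUE)
    }
    m
  })

  # planted P300s at attended target presentations
  frame_ms <- 1000 / schedule$flash_rate_hz
  dly_frames <- as.integer(round(schedule$stream_delays_ms / frame_ms))
  sigma_s <- template$width_ms / 1000 / (2 * sqrt(2 * log(2)))
  n_rep <- length(template$amplitude_uV)
  tgt <- ev[ev$is_target, , drop = FALSE]
  if (nrow(tgt) > 0) {
    for (i in seq_len(nrow(tgt))) {
      s_idx <- as.integer(tgt$stream[i])
      rep_idx <- min(s_idx, n_rep)
      pres_frame <- tgt$frame_index[i] + dly_frames[s_idx]
      if (as.character(gaze$attended[pres_frame + 1L]) !=
          as.character(tgt$stream[i])) next
      amp <- template$amplitude_uV[rep_idx]
      if (amp == 0) next
      center <- lead_in_s + tgt$onset_s[i] +
        template$peak_latency_ms[rep_idx] / 1000
      lo <- max(1L, floor((center - 4 * sigma_s) * fs_hz) + 1L)
      hi <- min(n_samp, ceiling((center + 4 * sigma_s) * fs_hz) + 1L)
      if (hi < lo) next
      tt <- ((lo:hi) - 1) / fs_hz
      bump <- amp * exp(-(tt - center)^2 / (2 * sigma_s^2))
      gain <- if (!is.null(template$gain)) template$gain else
        template$topography / max(abs(template$topography))
      data[, lo:hi] <- data[, lo:hi] + outer(gain, bump)
    }
  }

  annotations <- data.frame(sample_index = as.integer(round((ev$onset_s + lead_in_s) * fs_hz)) + 1L,
                            onset_s = ev$onset_s,
                            stream = ev$stream,
                            image_id = ev$image_id,
                            is_target = ev$is_target)

  raw_recording(data, fs_hz, labels, annotations)
}

#' Construct a raw continuous recording object
#'
#' @param data Channels x samples numeric matrix (microvolts).
#' @param fs_hz Sampling rate.
#' @param channel_labels Channel labels (one per row of `data`).
#' @param annotations Optional event data frame with at least `sample_index`.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(data, fs_hz, channel_labels = NULL,
                          annotations = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stopf("`data` must be a numeric channels x samples matrix")
  }
  check_scalar_number(fs_hz, "fs_hz", lower = 1e-6)
  if (is.null(channel_labels)) {
    channel_labels <- paste0("CH", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stopf("`channel_labels` must have one entry per data row")
  }
  structure(list(data = data, fs_hz = as.numeric(fs_hz),
                 channel_labels = channel_labels,
                 annotations = annotations),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs_hz, ncol(x$data) / x$fs_hz))
  if (!is.null(x$annotations)) {
    cat(sprintf("  %d annotated events\n", nrow(x$annotations)))
  }
  invisible(x)
}
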
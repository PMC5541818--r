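# Stimulus scheduling for single-, dual- and triple-stream RSVP.
#
# A schedule is built from one base image sequence (the left stream); the
# right and bottom streams replay the identical sequence after fixed delays,
# so every image is presented once per stream and a target can be viewed up
# to three times.

#' Generate a multi-stream RSVP stimulus schedule
#'
#' Builds a blocked image sequence flashed at a fixed rate, with a prescribed
#' number of targets per block and a minimum frame gap between consecutive
#' targets (so that the images skipped while the observer's gaze travels
#' between streams are nontargets by construction). The right and bottom
#' streams are exact delayed copies of the base (left) sequence.
#'
#' Target positions within each block are drawn uniformly among all
#' placements satisfying the gap constraint, conditioned on the last target
#' of the previous block, via the standard combinatorial bijection between
#' gap-constrained and unconstrained subsets.
#'
#' @param n_streams Number of simultaneous streams (1, 2 or 3).
#' @param n_blocks Number of blocks in the base sequence.
#' @param images_per_block Images per block.
#' @param targets_per_block Targets per block.
#' @param flash_rate_hz Presentation rate in Hz (frames per second).
#' @param stream_delays_ms Per-stream delay in ms (first entry must be 0);
#'   each delay must be an integer multiple of the frame period. Default:
#'   0/750/1500 ms, i.e. 3 frames between streams at 4 Hz.
#' @param min_target_gap_frames Minimum allowed difference between
#'   consecutive target frame indices in the base sequence. Default 1 for
#'   single, 6 for dual, 9 for triple streams (delay span + refixation + 1).
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @param randomize_reappearance If `TRUE`, each target's presentation on the
#'   delayed streams is jittered by up to `reappearance_jitter_frames` frames
#'   so the observer cannot anticipate the exact reappearance time. Off by
#'   default; breaks the exact delayed-copy invariant when enabled.
#' @param reappearance_jitter_frames Maximum jitter (frames) when
#'   `randomize_reappearance = TRUE`.
#'
#' @return An object of class `rsvp_schedule`: a list with `events` (one row
#'   per presentation: `stream`, `frame_index`, `onset_s`, `image_id`,
#'   `is_target`), the base sequence, and all generation parameters.
#' @examples
#' sched <- generate_schedule(n_streams = 2, n_blocks = 2,
#'                            images_per_block = 50, targets_per_block = 5,
#'                            seed = 1)
#' table(sched$events$stream, sched$events$is_target)
#' @export
generate_schedule <- function(n_streams = 3,
                              n_blocks = 10,
                              images_per_block = 200,
                              targets_per_block = 20,
                              flash_rate_hz = 4,
                              stream_delays_ms = NULL,
                              min_target_gap_frames = NULL,
                              seed = 1L,
                              randomize_reappearance = FALSE,
                              reappearance_jitter_frames = 1L) {
  n_streams <- check_count(n_streams, "n_streams", 1L)
  if (n_streams > 3L) stopf("`n_streams` must be 1, 2 or 3")
  n_blocks <- check_count(n_blocks, "n_blocks", 1L)
  images_per_block <- check_count(images_per_block, "images_per_block", 1L)
  targets_per_block <- check_count(targets_per_block, "targets_per_block", 0L)
  check_scalar_number(flash_rate_hz, "flash_rate_hz", lower = 1e-6)
  frame_ms <- 1000 / flash_rate_hz

  if (is.null(stream_delays_ms)) {
    stream_delays_ms <- (seq_len(n_streams) - 1L) * 3 * frame_ms
  }
  if (length(stream_delays_ms) != n_streams) {
    stopf("`stream_delays_ms` must have one entry per stream")
  }
  if (stream_delays_ms[1] != 0) stopf("the first (left) stream delay must be 0")
  delay_frames <- stream_delays_ms / frame_ms
  if (any(abs(delay_frames - round(delay_frames)) > 1e-9)) {
    stopf("stream delays must be integer multiples of the frame period (%g ms)",
          frame_ms)
  }
  delay_frames <- as.integer(round(delay_frames))

  if (is.null(min_target_gap_frames)) {
    min_target_gap_frames <- c(1L, 6L, 9L)[n_streams]
  }
  min_target_gap_frames <- check_count(min_target_gap_frames,
                                       "min_target_gap_frames", 1L)

  if (targets_per_block > images_per_block) {
    stopf("targets_per_block (%d) exceeds images_per_block (%d)",
          targets_per_block, images_per_block)
  }
  if (targets_per_block * min_target_gap_frames > images_per_block) {
    stopf(paste0("infeasible target placement: targets_per_block (%d) x ",
                 "min_target_gap_frames (%d) > images_per_block (%d)"),
          targets_per_block, min_target_gap_frames, images_per_block)
  }

  n_images <- n_blocks * images_per_block
  target_frames <- with_seed(seed, {
    place_targets(n_blocks, images_per_block, targets_per_block,
                  min_target_gap_frames)
  })

  is_target <- logical(n_images)
  is_target[target_frames + 1L] <- TRUE
  base <- data.frame(frame_index = 0:(n_images - 1L),
                     image_id = seq_len(n_images),
                     is_target = is_target)

  streams <- STREAM_LEVELS[seq_len(n_streams)]
  jitter <- NULL
  if (randomize_reappearance && n_streams > 1L && targets_per_block > 0L) {
    jmax <- check_count(reappearance_jitter_frames,
                        "reappearance_jitter_frames", 0L)
    jitter <- with_seed(seed + 1L, {
      matrix(sample(seq(-jmax, jmax), length(target_frames) * (n_streams - 1L),
                    replace = TRUE),
             nrow = length(target_frames))
    })
  }

  ev <- vector("list", n_streams)
  for (s in seq_len(n_streams)) {
    onset <- base$frame_index / flash_rate_hz + stream_delays_ms[s] / 1000
    if (!is.null(jitter) && s > 1L) {
      idx <- target_frames + 1L
      onset[idx] <- onset[idx] + jitter[, s - 1L] / flash_rate_hz
    }
    ev[[s]] <- data.frame(stream = factor(streams[s], levels = STREAM_LEVELS),
                          frame_index = base$frame_index,
                          onset_s = onset,
                          image_id = base$image_id,
                          is_target = base$is_target)
  }
  events <- do.call(rbind, ev)
  events <- events[order(events$onset_s, as.integer(events$stream)), ]
  rownames(events) <- NULL

  structure(list(events = events,
                 base = base,
                 flash_rate_hz = flash_rate_hz,
                 n_streams = n_streams,
                 stream_delays_ms = as.numeric(stream_delays_ms),
                 n_blocks = n_blocks,
                 images_per_block = images_per_block,
                 targets_per_block = targets_per_block,
                 min_target_gap_frames = min_target_gap_frames,
                 seed = as.integer(seed),
                 randomize_reappearance = isTRUE(randomize_reappearance)),
            class = "rsvp_schedule")
}

# Uniform gap-constrained target placement, block by block.
# Positions are 0-based frame indices into the base sequence. Within each
# block the k positions p_1 < ... < p_k (1-based within the sequence) satisfy
# p_{j+1} - p_j >= g and p_1 >= L + g where L is the previous block's last
# target; the map q_j = p_j - a + 1 - (j-1)(g-1) is a bijection onto
# unconstrained k-subsets of 1..m', sampled uniformly.
place_targets <- function(n_blocks, m, k, g) {
  if (k == 0L) return(integer(0))
  out <- integer(0)
  last <- -Inf   # last target position so far (1-based)
  for (b in seq_len(n_blocks)) {
    start <- (b - 1L) * m + 1L
    end <- b * m
    a <- max(start, if (is.finite(last)) last + g else start)
    m_eff <- end - a + 1L - (k - 1L) * (g - 1L)
    if (m_eff < k) {
      # cannot happen when k*g <= m (checked by the caller)
      stopf("internal error: infeasible block %d placement", b)
    }
    q <- sort(sample.int(m_eff, k))
    p <- q + a - 1L + (seq_len(k) - 1L) * (g - 1L)
    last <- p[k]
    out <- c(out, p)
  }
  out - 1L  # 0-based frame indices
}

#' @export
print.rsvp_schedule <- function(x, ...) {
  cat(sprintf("<rsvp_schedule> %d stream(s) @ %g Hz\n", x$n_streams,
              x$flash_rate_hz))
  cat(sprintf("  %d block(s) x %d images (%d targets/block), gap >= %d frames\n",
              x$n_blocks, x$images_per_block, x$targets_per_block,
              x$min_target_gap_frames))
  cat(sprintf("  stream delays: %s ms; %d events; seed %d\n",
              paste(x$stream_delays_ms, collapse = "/"),
              nrow(x$events), x$seed))
  invisible(x)
}

#' Derive the deterministic gaze trace for a multi-stream schedule
#'
#' Simulates the attention-shift protocol: the observer fixates the left
#' stream; on seeing a target there, attention moves to the right stream
#' until the same image reappears (one delay span later), then -- for triple
#' streams -- to the bottom stream, and finally travels back to the left
#' stream over `refixation_frames` frames during which no stream is attended.
#' Base images none of whose presentations occur on an attended stream are
#' recorded as missed. With delay span D frames and refixation r, each
#' attended target causes exactly D + r missed base images (5 for the default
#' dual and 8 for the default triple geometry; r = 3 gives 6 and 9).
#'
#' @param schedule An `rsvp_schedule`.
#' @param refixation_frames Frames needed to re-fixate the left stream
#'   (default 2; plausible values 2-3).
#' @return An object of class `gaze_trace`: `attended` (factor, one entry per
#'   frame of the extended timeline, levels left/right/bottom/none),
#'   `missed_base_frames` (0-based base frame indices never attended) and
#'   `missed_image_ids`.
#' @examples
#' sched <- generate_schedule(n_streams = 2, n_blocks = 1,
#'                            images_per_block = 100, targets_per_block = 5,
#'                            seed = 2)
#' gz <- derive_gaze(sched)
#' length(gz$missed_base_frames)  # 5 per attended target
#' @export
derive_gaze <- function(schedule, refixation_frames = 2L) {
  stopifnot(inherits(schedule, "rsvp_schedule"))
  r <- check_count(refixation_frames, "refixation_frames", 0L)
  frame_ms <- 1000 / schedule$flash_rate_hz
  dly <- as.integer(round(schedule$stream_delays_ms / frame_ms))
  n_frames <- nrow(schedule$base)
  d_max <- max(dly)
  horizon <- n_frames + d_max + r + 1L

  att <- rep("left", horizon)  # frame f stored at att[f + 1]
  if (schedule$n_streams >= 2L) {
    targets <- schedule$base$frame_index[schedule$base$is_target]
    resume <- 0L
    for (t in targets) {
      if (t < resume) next  # target flashed while gaze was away: missed
      # excursion: right stream for dly[2] frames, bottom for the rest,
      # then r frames of refixation travel
      seg <- function(from, to, what) {
        if (to >= from) att[(from:to) + 1L] <<- what
      }
      seg(t + 1L, t + dly[2], "right")
      if (schedule$n_streams >= 3L) seg(t + dly[2] + 1L, t + dly[3], "bottom")
      seg(t + d_max + 1L, t + d_max + r, "none")
      resume <- t + d_max + r + 1L
    }
  }
  att <- factor(att, levels = c(STREAM_LEVELS, "none"))

  # an image is missed iff none of its presentations is on the attended stream
  f <- schedule$base$frame_index
  seen <- att[f + 1L] == "left"
  if (schedule$n_streams >= 2L) seen <- seen | att[f + dly[2] + 1L] == "right"
  if (schedule$n_streams >= 3L) seen <- seen | att[f + dly[3] + 1L] == "bottom"
  missed <- f[!seen]

  structure(list(attended = att,
                 missed_base_frames = missed,
                 missed_image_ids = schedule$base$image_id[!seen],
                 refixation_frames = r,
                 n_streams = schedule$n_streams),
            class = "gaze_trace")
}

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf("<gaze_trace> %d stream(s), refixation %d frames, %d missed base images\n",
              x$n_streams, x$refixation_frames, length(x$missed_base_frames)))
  invisible(x)
}

#' Write a schedule's events to a BIDS-style tab-separated file
#'
#' Columns: `onset` (s, 6 decimals), `duration` (s), `stream`, `image_id`,
#' `is_target` (0/1), with a mandatory header row. Generation parameters are
#' stored in a JSON sidecar (same path with `.json` extension) so that
#' [read_events()] can reconstruct the full schedule object.
#'
#' @param schedule An `rsvp_schedule`.
#' @param path Output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_events <- function(schedule, path) {
  stopifnot(inherits(schedule, "rsvp_schedule"))
  ev <- schedule$events
  df <- data.frame(onset = sprintf("%.6f", ev$onset_s),
                   duration = sprintf("%.6f", 1 / schedule$flash_rate_hz),
                   stream = as.character(ev$stream),
                   image_id = ev$image_id,
                   is_target = as.integer(ev$is_target))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- schedule[setdiff(names(schedule), c("events", "base"))]
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[A-Za-z]+$", ".json", path)

#' Read a schedule back from an events file
#'
#' Inverse of [write_events()]: with the JSON sidecar present the returned
#' object is identical to the one written.
#'
#' @param path Events `.tsv` path.
#' @return An `rsvp_schedule`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stopf("events file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 1L) stopf("events file %s is empty", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("onset", "duration", "stream", "image_id", "is_target")
  if (!identical(header, need)) {
    stopf("events file %s: expected header %s", path,
          paste(need, collapse = "\t"))
  }
  n <- length(lines) - 1L
  if (n < 1L) stopf("events file %s has no data rows", path)
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  for (i in seq_len(n)) {
    p <- parts[[i]]
    if (length(p) != 5L) {
      stopf("events file %s line %d: expected 5 fields, found %d",
            path, i + 1L, length(p))
    }
    onset <- suppressWarnings(as.numeric(p[1]))
    if (is.na(onset)) stopf("events file %s line %d: non-numeric onset '%s'",
                            path, i + 1L, p[1])
    if (onset < 0) stopf("events file %s line %d: negative onset %s",
                         path, i + 1L, p[1])
    if (!p[3] %in% STREAM_LEVELS) {
      stopf("events file %s line %d: unknown stream '%s'", path, i + 1L, p[3])
    }
    if (!p[5] %in% c("0", "1")) {
      stopf("events file %s line %d: is_target must be 0 or 1", path, i + 1L)
    }
  }
  m <- matrix(unlist(parts), ncol = 5L, byrow = TRUE)
  events <- data.frame(stream = factor(m[, 3], levels = STREAM_LEVELS),
                       frame_index = NA_integer_,
                       onset_s = as.numeric(m[, 1]),
                       image_id = as.integer(m[, 4]),
                       is_target = m[, 5] == "1")

  side <- sidecar_path(path)
  if (!file.exists(side)) {
    stopf("sidecar %s not found; cannot reconstruct schedule parameters", side)
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  flash <- meta$flash_rate_hz
  delays <- as.numeric(meta$stream_delays_ms)
  sidx <- as.integer(events$stream)
  events$frame_index <- as.integer(round(
    (events$onset_s - delays[sidx] / 1000) * flash))
  left <- events[events$stream == "left", ]
  left <- left[order(left$frame_index), ]
  base <- data.frame(frame_index = left$frame_index,
                     image_id = left$image_id,
                     is_target = left$is_target)
  events <- events[order(events$onset_s, as.integer(events$stream)), ]
  rownames(events) <- NULL
  rownames(base) <- NULL

  structure(list(events = events,
                 base = base,
                 flash_rate_hz = flash,
                 n_streams = as.integer(meta$n_streams),
                 stream_delays_ms = delays,
                 n_blocks = as.integer(meta$n_blocks),
                 images_per_block = as.integer(meta$images_per_block),
                 targets_per_block = as.integer(meta$targets_per_block),
                 min_target_gap_frames = as.integer(meta$min_target_gap_frames),
                 seed = as.integer(meta$seed),
                 randomize_reappearance = isTRUE(meta$randomize_reappearance)),
            class = "rsvp_schedule")
}
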
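test_that("schedules satisfy block structure, gap and delayed-copy invariants", {
  for (seed in c(1, 7, 23, 99)) {
    s <- generate_schedule(n_streams = 3, n_blocks = 4, images_per_block = 50,
                           targets_per_block = 5, min_target_gap_frames = 6,
                           seed = seed)
    # exact targets per block
    blk <- findInterval(s$base$frame_index, seq(0, 200, by = 50),
                        left.open = FALSE)
    expect_equal(as.numeric(tapply(s$base$is_target, blk, sum)), rep(5, 4))
    # gap constraint over the whole base sequence
    tf <- s$base$frame_index[s$base$is_target]
    expect_true(all(diff(tf) >= 6))
    # each stream carries the same image sequence, shifted by its delay
    ev <- s$events
    left <- ev[ev$stream == "left", ]
    for (st in c("right", "bottom")) {
      sub <- ev[ev$stream == st, ]
      m <- match(left$image_id, sub$image_id)
      expect_false(anyNA(m))
      d_ms <- s$stream_delays_ms[match(st, c("left", "right", "bottom"))]
      expect_equal(sub$onset_s[m] - left$onset_s, rep(d_ms / 1000, nrow(left)))
      expect_identical(sub$is_target[m], left$is_target)
    }
    # image ids unique within a stream
    expect_false(any(duplicated(left$image_id)))
    # onset = frame / rate + delay
    expect_equal(left$onset_s, left$frame_index / s$flash_rate_hz)
  }
})

test_that("target counts are exact for every seed", {
  for (seed in 1:100) {
    s <- generate_schedule(n_streams = 1, n_blocks = 3, images_per_block = 30,
                           targets_per_block = 3, min_target_gap_frames = 4,
                           seed = seed)
    blk <- rep(1:3, each = 30)
    expect_equal(as.numeric(tapply(s$base$is_target, blk, sum)), rep(3, 3))
    tf <- s$base$frame_index[s$base$is_target]
    expect_true(all(diff(tf) >= 4))
  }
})

test_that("zero-target and infeasible placements are handled", {
  s <- generate_schedule(n_streams = 1, n_blocks = 1, images_per_block = 10,
                         targets_per_block = 0, flash_rate_hz = 4,
                         min_target_gap_frames = 1, seed = 0)
  expect_equal(nrow(s$events), 10)
  expect_false(any(s$events$is_target))
  expect_error(
    generate_schedule(n_streams = 1, n_blocks = 1, images_per_block = 20,
                      targets_per_block = 5, min_target_gap_frames = 5,
                      seed = 1),
    "infeasible")
})

test_that("schedules are deterministic in the seed", {
  a <- tiny_schedule(seed = 5)
  b <- tiny_schedule(seed = 5)
  c <- tiny_schedule(seed = 6)
  expect_identical(a$events, b$events)
  expect_false(identical(a$base$is_target, c$base$is_target))
})

test_that("gaze excursions skip the documented number of base images", {
  # isolated targets (large gap) so excursions do not interact; a window is
  # truncated when it runs past the end of the sequence
  expected_missed <- function(s, span) {
    tf <- s$base$frame_index[s$base$is_target]
    n <- nrow(s$base)
    sum(pmin(tf + span, n - 1) - tf)
  }
  dual <- generate_schedule(n_streams = 2, n_blocks = 1, images_per_block = 100,
                            targets_per_block = 5, min_target_gap_frames = 15,
                            seed = 3)
  # delay 3 frames + refixation 2 or 3: 5 or 6 skipped images per target
  expect_equal(length(derive_gaze(dual, 2)$missed_base_frames),
               expected_missed(dual, 5))
  expect_equal(length(derive_gaze(dual, 3)$missed_base_frames),
               expected_missed(dual, 6))
  triple <- generate_schedule(n_streams = 3, n_blocks = 1, images_per_block = 100,
                              targets_per_block = 5, min_target_gap_frames = 15,
                              seed = 3)
  # delays 3 + 6 frames: 8 or 9 skipped images per target
  expect_equal(length(derive_gaze(triple, 2)$missed_base_frames),
               expected_missed(triple, 8))
  expect_equal(length(derive_gaze(triple, 3)$missed_base_frames),
               expected_missed(triple, 9))
  # an interior target misses exactly the nominal count
  s1 <- generate_schedule(n_streams = 2, n_blocks = 1, images_per_block = 60,
                          targets_per_block = 1, min_target_gap_frames = 1,
                          seed = 14)
  tf <- s1$base$frame_index[s1$base$is_target]
  expect_true(tf < 50)  # fixed seed places the single target away from the end
  expect_equal(length(derive_gaze(s1, 2)$missed_base_frames), 5)
  expect_equal(length(derive_gaze(s1, 3)$missed_base_frames), 6)
})

test_that("gaze misses only nontargets under the default gap constraint", {
  for (seed in 1:20) {
    s <- generate_schedule(n_streams = 2, n_blocks = 2, images_per_block = 100,
                           targets_per_block = 10, seed = seed)
    gz <- derive_gaze(s)
    tf <- s$base$frame_index[s$base$is_target]
    expect_length(intersect(tf, gz$missed_base_frames), 0)
  }
  # triple geometry too
  s <- generate_schedule(n_streams = 3, n_blocks = 2, images_per_block = 100,
                         targets_per_block = 10, seed = 4)
  gz <- derive_gaze(s)
  tf <- s$base$frame_index[s$base$is_target]
  expect_length(intersect(tf, gz$missed_base_frames), 0)
})

test_that("gaze trace degenerates gracefully", {
  no_targets <- generate_schedule(n_streams = 2, n_blocks = 1,
                                  images_per_block = 20, targets_per_block = 0,
                                  min_target_gap_frames = 1, seed = 1)
  gz <- derive_gaze(no_targets)
  expect_length(gz$missed_base_frames, 0)
  expect_true(all(gz$attended == "left"))
  single <- generate_schedule(n_streams = 1, n_blocks = 1,
                              images_per_block = 20, targets_per_block = 2,
                              min_target_gap_frames = 3, seed = 1)
  gz1 <- derive_gaze(single)
  expect_length(gz1$missed_base_frames, 0)
  expect_true(all(gz1$attended == "left"))
})

test_that("events files round-trip and validate their input", {
  s <- tiny_schedule(n_streams = 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events(s, path)
  s2 <- read_events(path)
  expect_equal(s2, s)
  # row count: header + n_streams x images
  expect_length(readLines(path), 1 + 2 * 40)

  lines <- readLines(path)
  bad <- withr::local_tempfile(fileext = ".tsv")
  lines[3] <- sub("^[0-9.]+", "-1.0", lines[3])
  writeLines(lines, bad)
  file.copy(sub("\\.tsv$", ".json", path), sub("\\.tsv$", ".json", bad))
  expect_error(read_events(bad), "line 3.*negative onset|negative onset")

  lines2 <- readLines(path)
  lines2[5] <- "not\ta\trow"
  writeLines(lines2, bad)
  expect_error(read_events(bad), "line 5")
})
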
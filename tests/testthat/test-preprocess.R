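# Helper: recording holding pure sinusoids / constants for filter checks.
sine_recording <- function(freq_hz, fs_hz = 600, dur_s = 10, amp = 1) {
  t <- (0:(dur_s * fs_hz - 1)) / fs_hz
  raw_recording(matrix(amp * sin(2 * pi * freq_hz * t), nrow = 1), fs_hz)
}
mid_rms <- function(rec) {
  n <- ncol(rec$data)
  i <- floor(n / 4):ceiling(3 * n / 4)   # avoid filter edge transients
  sqrt(mean(rec$data[1, i]^2))
}

test_that("band-pass filter passes 10 Hz and rejects 100 Hz", {
  r100 <- sine_recording(100, fs_hz = 600)
  out <- bandpass_filter(r100)
  atten_db <- 20 * log10(mid_rms(out) / mid_rms(r100))
  expect_lt(atten_db, -20)

  r10 <- sine_recording(10, fs_hz = 600)
  out10 <- bandpass_filter(r10)
  ripple_db <- abs(20 * log10(mid_rms(out10) / mid_rms(r10)))
  expect_lt(ripple_db, 1)

  zeros <- raw_recording(matrix(0, 2, 1000), 600)
  expect_equal(bandpass_filter(zeros)$data, zeros$data)

  expect_error(bandpass_filter(r10, low_hz = 60, high_hz = 0.5), "band edges")
  expect_error(bandpass_filter(r10, low_hz = 1, high_hz = 400), "band edges")
})

test_that("downsampling decimates, preserves DC and passband RMS, rejects upsampling", {
  r <- raw_recording(matrix(rnorm(2 * 24000), 2, 24000), 2400,
                     annotations = data.frame(sample_index = c(1L, 2401L)))
  d <- downsample_recording(r, 600)
  expect_equal(ncol(d$data), 6000)
  expect_equal(d$fs_hz, 600)
  expect_equal(d$annotations$sample_index, c(1L, 601L))

  const <- raw_recording(matrix(7.5, 1, 24000), 2400)
  expect_equal(downsample_recording(const, 600)$data,
               matrix(7.5, 1, 6000), tolerance = 1e-9)

  s10 <- sine_recording(10, fs_hz = 2400, dur_s = 10)
  s10d <- downsample_recording(s10, 600)
  expect_lt(abs(mid_rms(s10d) / mid_rms(s10) - 1), 0.01)

  expect_error(downsample_recording(s10d, 2400), "upsampling")
  expect_error(downsample_recording(s10, 601), "integer multiple")
})

test_that("epoch extraction produces one labelled epoch per event", {
  s <- generate_schedule(n_streams = 3, n_blocks = 1, images_per_block = 30,
                         targets_per_block = 3, min_target_gap_frames = 6,
                         seed = 2)
  rec <- simulate_recording(s, fs_hz = 600, seed = 2)
  ep <- extract_epochs(rec, s, pre_ms = 0)
  expect_equal(dim(ep$data), c(3 * 30, 16, 600))
  expect_equal(sum(ep$labels), 3 * 3)
  expect_equal(length(ep$image_ids), 90)
  expect_equal(as.vector(table(ep$stream_ids)), c(30, 30, 30))

  # truncated trailing events are dropped with a warning, count reduced exactly
  short <- rec
  short$data <- short$data[, 1:(ncol(rec$data) - 900), drop = FALSE]
  expect_warning(ep2 <- extract_epochs(short, s, pre_ms = 0), "dropping")
  n_lost <- sum(rec$annotations$sample_index + 599 > ncol(short$data))
  expect_equal(dim(ep2$data)[1], 90 - n_lost)
})

test_that("baseline correction subtracts window means and is offset-invariant", {
  X <- array(3.25, dim = c(2, 2, 100))
  ep <- make_epochs(X, fs_hz = 100)
  out <- baseline_correct(ep, "whole_epoch")
  expect_equal(max(abs(out$data)), 0)

  set.seed(1)
  Y <- array(rnorm(4 * 3 * 120), dim = c(4, 3, 120))
  ep1 <- make_epochs(Y, fs_hz = 600)
  ep1$pre_ms <- 100   # first 60 samples are pre-stimulus
  shifted <- ep1
  shifted$data[, 2, ] <- shifted$data[, 2, ] + 42
  a <- baseline_correct(ep1, c(-100, 0))
  b <- baseline_correct(shifted, c(-100, 0))
  expect_equal(a$data, b$data, tolerance = 1e-12)
  expect_equal(dim(a$data)[3], 60)   # cropped to post-stimulus
  expect_equal(a$pre_ms, 0)

  # a template sitting on an exactly-zero baseline is unchanged
  Z <- array(0, dim = c(1, 1, 120))
  Z[1, 1, 61:120] <- sin(seq(0, pi, length.out = 60))
  epz <- make_epochs(Z, fs_hz = 600)
  epz$pre_ms <- 100
  outz <- baseline_correct(epz, c(-100, 0))
  expect_equal(outz$data[1, 1, ], Z[1, 1, 61:120])

  expect_error(baseline_correct(ep, c(5, 5)), "window")
})

test_that("the full chain recovers the planted peak latency at 600 Hz", {
  s <- generate_schedule(n_streams = 1, n_blocks = 1, images_per_block = 20,
                         targets_per_block = 2, min_target_gap_frames = 6,
                         seed = 8)
  rec <- simulate_recording(s, noise_sd_uV = 0, line_noise_uV = 0,
                            fs_hz = 2400, seed = 8)
  ep <- preprocess(rec, s)
  pz <- which(ep$channel_labels == "Pz")
  for (i in which(ep$labels)) {
    expect_lte(abs(which.max(ep$data[i, pz, ]) - 181), 1)  # 300 ms @ 600 Hz
  }
})

test_that("permuting filter and downsample stages changes little on band-limited input", {
  s <- generate_schedule(n_streams = 1, n_blocks = 1, images_per_block = 20,
                         targets_per_block = 2, min_target_gap_frames = 6,
                         seed = 8)
  rec <- simulate_recording(s, fs_hz = 2400, seed = 8)
  a <- downsample_recording(bandpass_filter(rec), 600)
  b <- bandpass_filter(downsample_recording(rec, 600))
  rel <- sqrt(mean((a$data - b$data)^2)) / sqrt(mean(a$data^2))
  expect_lt(rel, 0.01)
})

test_that("the notch filter removes the mains component", {
  r50 <- sine_recording(50, fs_hz = 600)
  out <- notch_filter(r50)
  expect_lt(mid_rms(out) / mid_rms(r50), 0.05)
})
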
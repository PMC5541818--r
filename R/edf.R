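# Minimal EDF (European Data Format, 16-bit) reader/writer for continuous
# recordings, so synthetic and real data share one loader. Covers plain EDF
# with identical sampling rate across signals; events travel in a companion
# tab-separated file (see write_events()).

#' Write a recording to an EDF file
#'
#' Plain EDF, one data record per second, 16-bit samples, physical units uV.
#' The final partial record is zero-padded; the true sample count is
#' recoverable from the recording duration. Quantisation error is bounded by
#' the physical range divided by 2^16.
#'
#' @param rec A `raw_recording`.
#' @param path Output path (conventionally `.edf`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  n_ch <- nrow(rec$data)
  fs <- rec$fs_hz
  if (abs(fs - round(fs)) > 1e-9) stopf("EDF writer requires an integer fs_hz")
  fs <- as.integer(round(fs))
  n_samp <- ncol(rec$data)
  n_rec <- ceiling(n_samp / fs)

  pmin_ <- apply(rec$data, 1, min)
  pmax_ <- apply(rec$data, 1, max)
  span <- pmax_ - pmin_
  pad <- ifelse(span > 0, span * 0.01, 1)
  pmin_ <- pmin_ - pad
  pmax_ <- pmax_ + pad
  dmin <- -32768L
  dmax <- 32767L

  pad_field <- function(x, width) {
    x <- substr(format(x, trim = TRUE, scientific = FALSE), 1, width)
    formatC(x, width = width, flag = "-")
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad_field("0", 8),
                pad_field("X X X X", 80),
                pad_field("synthetic EEG", 80),
                "01.01.00", "00.00.00",
                pad_field(256 + 256 * n_ch, 8),
                pad_field("", 44),
                pad_field(n_rec, 8),
                pad_field(1, 8),
                pad_field(n_ch, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(pad_field(rec$channel_labels, 16),
                 pad_field(rep("EEG", n_ch), 80),
                 pad_field(rep("uV", n_ch), 8),
                 vapply(pmin_, function(x) pad_field(sprintf("%.3f", x), 8), ""),
                 vapply(pmax_, function(x) pad_field(sprintf("%.3f", x), 8), ""),
                 pad_field(rep(dmin, n_ch), 8),
                 pad_field(rep(dmax, n_ch), 8),
                 pad_field(rep("", n_ch), 80),
                 pad_field(rep(fs, n_ch), 8),
                 pad_field(rep("", n_ch), 32))
  for (f in fields) writeChar(paste0(f, collapse = ""), con, eos = NULL)

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    block <- matrix(0, nrow = n_ch, ncol = fs)
    keep <- idx <= n_samp
    block[, keep] <- rec$data[, idx[keep], drop = FALSE]
    dig <- round((block - pmin_) * scale) + dmin
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any plain 16-bit EDF with a
#' uniform sampling rate)
#'
#' @param path EDF path.
#' @param n_samples Optional true sample count (trailing zero-padding of the
#'   final record is dropped when given).
#' @return A `raw_recording` (no annotations; pair with [read_events()]).
#' @export
read_edf <- function(path, n_samples = NULL) {
  if (!file.exists(path)) stopf("EDF file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(n_ch), function(i) rd(16), ""))
  for (i in seq_len(n_ch)) rd(80)
  units <- trimws(vapply(seq_len(n_ch), function(i) rd(8), ""))
  pmin_ <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), ""))
  for (i in seq_len(n_ch)) rd(80)
  spr <- as.integer(vapply(seq_len(n_ch), function(i) rd(8), ""))
  for (i in seq_len(n_ch)) rd(32)
  if (length(unique(spr)) != 1L) {
    stopf("EDF reader supports a single sampling rate across signals")
  }
  fs <- spr[1] / rec_dur
  seek(con, header_bytes)

  data <- matrix(0, nrow = n_ch, ncol = n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    raw_block <- readBin(con, "integer", n = n_ch * spr[1], size = 2,
                         signed = TRUE, endian = "little")
    block <- matrix(raw_block, nrow = spr[1])   # samples x channels
    cols <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    data[, cols] <- t((block - matrix(dmin, spr[1], n_ch, byrow = TRUE)) *
                        matrix(scale, spr[1], n_ch, byrow = TRUE) +
                        matrix(pmin_, spr[1], n_ch, byrow = TRUE))
  }
  if (!is.null(n_samples)) data <- data[, seq_len(n_samples), drop = FALSE]
  raw_recording(data, fs, labels)
}
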
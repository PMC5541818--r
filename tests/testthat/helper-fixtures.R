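# Shared fixture builders and independent oracles for the test suite.

default_channels <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4",
    "O1", "O2", "F7", "F8", "T7", "T8", "Cz", "Pz")
}

# A small schedule: defaults chosen so tests run in well under a second.
tiny_schedule <- function(n_streams = 2, n_blocks = 1, images_per_block = 40,
                          targets_per_block = 4, gap = 5, seed = 1) {
  generate_schedule(n_streams = n_streams, n_blocks = n_blocks,
                    images_per_block = images_per_block,
                    targets_per_block = targets_per_block,
                    min_target_gap_frames = gap, seed = seed)
}

# Construct an epoch_set directly from an array (bypassing the simulator).
make_epochs <- function(data, fs_hz = 600, labels = NULL, image_ids = NULL,
                        stream_ids = NULL, channel_labels = NULL) {
  d <- dim(data)
  if (is.null(labels)) labels <- rep(FALSE, d[1])
  if (is.null(image_ids)) image_ids <- seq_len(d[1])
  if (is.null(stream_ids)) {
    stream_ids <- factor(rep("left", d[1]), levels = c("left", "right", "bottom"))
  }
  if (is.null(channel_labels)) channel_labels <- paste0("CH", seq_len(d[2]))
  structure(list(data = data, fs_hz = fs_hz, labels = labels,
                 image_ids = image_ids, stream_ids = stream_ids,
                 epoch_length_ms = d[3] / fs_hz * 1000, pre_ms = 0,
                 channel_labels = channel_labels),
            class = "epoch_set")
}

# Build an hdca model by hand (for evaluating fixed weights on fixed data).
make_hdca <- function(spatial_weights, temporal_weights, N, fs_hz = 600,
                      intercept = 0, score_mean = NULL, score_sd = NULL) {
  K <- nrow(spatial_weights)
  if (is.null(score_mean)) score_mean <- rep(0, K)
  if (is.null(score_sd)) score_sd <- rep(1, K)
  structure(list(spatial_weights = spatial_weights,
                 temporal_weights = temporal_weights,
                 intercept = intercept, score_mean = score_mean,
                 score_sd = score_sd, N = as.integer(N), K = K,
                 window_s = N / fs_hz, fs_hz = fs_hz, fitted = TRUE),
            class = "hdca")
}

# Naive triple-loop evaluation of the windowed spatial filter:
# y_k = (1/N) sum_n sum_i w_ki x_i[(k-1)N + n]
naive_window_scores <- function(data, Wsp, N) {
  d <- dim(data)
  K <- nrow(Wsp)
  Y <- matrix(0, d[1], K)
  for (e in seq_len(d[1])) {
    for (k in seq_len(K)) {
      acc <- 0
      for (n in seq_len(N)) {
        for (i in seq_len(d[2])) {
          acc <- acc + Wsp[k, i] * data[e, i, (k - 1) * N + n]
        }
      }
      Y[e, k] <- acc / N
    }
  }
  Y
}

# O(n^2) pairwise-comparison oracle for the AUC (ties count 1/2).
pairwise_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Naive stepwise selection oracle built on lm(): same entry/removal rules as
# swlda(), implemented independently with per-candidate refits.
naive_stepwise <- function(X, y, p_enter = 0.10, p_remove = 0.15,
                           max_features = 60) {
  y <- as.numeric(as.logical(y))
  selected <- integer(0)
  path <- list()
  repeat {
    changed <- FALSE
    if (length(selected) < max_features) {
      cand <- setdiff(seq_len(ncol(X)), selected)
      pv <- vapply(cand, function(j) {
        fit <- stats::lm(y ~ ., data = as.data.frame(X[, c(selected, j), drop = FALSE]))
        s <- summary(fit)$coefficients
        s[nrow(s), 4]
      }, 0)
      j <- which.min(pv)
      if (is.finite(pv[j]) && pv[j] < p_enter) {
        selected <- c(selected, cand[j])
        path[[length(path) + 1]] <- c("add", cand[j])
        changed <- TRUE
      }
    }
    repeat {
      if (length(selected) < 1) break
      fit <- stats::lm(y ~ ., data = as.data.frame(X[, selected, drop = FALSE]))
      pv <- summary(fit)$coefficients[-1, 4]
      worst <- which.max(pv)
      if (pv[worst] > p_remove) {
        path[[length(path) + 1]] <- c("drop", selected[worst])
        selected <- selected[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  list(selected = selected, path = path)
}
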
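# Cross-stream score fusion, ROC/AUC evaluation, grouped stratified
# cross-validation and the exact paired Wilcoxon signed-rank test.
#
# The multi-stream step: each image is presented once per stream, so it
# receives up to three single-trial interest scores; the fused score is
# their arithmetic mean and all detection decisions are taken on it.

#' Fuse per-stream interest scores per image
#'
#' Averages the interest scores of the same image across the streams on
#' which it was scored. Single-stream input passes through unchanged.
#'
#' @param scores Data frame with columns `image_id`, `stream`, `score` and
#'   `label` (logical or 0/1, constant within an image).
#' @param all_image_ids Optional vector of image ids that must be covered;
#'   an id with no score raises an error.
#' @return An object of class `score_table`: a data frame with one row per
#'   image (`image_id`, one column per stream present, `fused_score`,
#'   `label`).
#' @examples
#' df <- data.frame(image_id = c(1, 1, 2, 2),
#'                  stream = c("left", "right", "left", "right"),
#'                  score = c(0.4, 0.8, -0.1, 0.1),
#'                  label = c(TRUE, TRUE, FALSE, FALSE))
#' fuse_scores(df)
#' @export
fuse_scores <- function(scores, all_image_ids = NULL) {
  need <- c("image_id", "stream", "score", "label")
  if (!is.data.frame(scores) || !all(need %in% names(scores))) {
    stopf("`scores` must be a data frame with columns %s",
          paste(need, collapse = ", "))
  }
  if (!is.null(all_image_ids)) {
    missing_ids <- setdiff(all_image_ids, scores$image_id)
    if (length(missing_ids) > 0) {
      stopf("no score available for image id(s): %s",
            paste(head(missing_ids, 5), collapse = ", "))
    }
  }
  stream <- as.character(scores$stream)
  bad <- !stream %in% STREAM_LEVELS
  if (any(bad)) stopf("unknown stream(s): %s",
                      paste(unique(stream[bad]), collapse = ", "))
  lab_chk <- tapply(as.logical(scores$label), scores$image_id,
                    function(v) length(unique(v)))
  if (any(lab_chk > 1)) stopf("inconsistent labels within an image id")

  ids <- sort(unique(scores$image_id))
  out <- data.frame(image_id = ids)
  present <- intersect(STREAM_LEVELS, unique(stream))
  for (s in present) {
    sub <- scores[stream == s, ]
    out[[s]] <- sub$score[match(ids, sub$image_id)]
  }
  sc <- as.matrix(out[, present, drop = FALSE])
  out$fused_score <- rowMeans(sc, na.rm = TRUE)
  out$label <- as.logical(scores$label)[match(ids, scores$image_id)]
  class(out) <- c("score_table", "data.frame")
  out
}

#' Threshold fused scores into target/nontarget decisions
#'
#' @param score_table A `score_table` from [fuse_scores()] (or any data
#'   frame with a `fused_score` column).
#' @param threshold Finite decision threshold; images with
#'   `fused_score > threshold` are declared targets.
#' @return Logical vector of decisions, named by image id.
#' @export
classify_by_threshold <- function(score_table, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold)) {
    stopf("`threshold` must be a single number")
  }
  stats::setNames(score_table$fused_score > threshold,
                  score_table$image_id)
}

#' Midpoint decision threshold from training scores
#'
#' The default operating point: halfway between the class medians of the
#' training-set fused scores. All headline evaluation is threshold-free
#' (AUC); this is a convenience for reporting hard decisions.
#'
#' @param scores Numeric scores.
#' @param labels Logical labels.
#' @return A single threshold value.
#' @export
midpoint_threshold <- function(scores, labels) {
  (stats::median(scores[as.logical(labels)]) +
     stats::median(scores[!as.logical(labels)])) / 2
}

#' ROC curve and AUC by the rank (Mann-Whitney) statistic
#'
#' The AUC is the Mann-Whitney U statistic with midranks for ties,
#' identical to the trapezoidal area under the threshold-swept ROC curve.
#'
#' @param scores Numeric scores (larger = more target-like).
#' @param labels Logical (or 0/1) labels; both classes must be present.
#' @return An object of class `rsvp_roc`: `auc`, `curve` (data frame of
#'   `fpr`, `tpr`, from (0,0) to (1,1)), `n_pos`, `n_neg`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE))$auc  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stopf("scores/labels length mismatch")
  if (anyNA(scores) || anyNA(labels)) stopf("scores/labels must not contain NA")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stopf("both classes must be present to evaluate ROC/AUC")
  }
  r <- rank(scores)   # midranks for ties
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(scores, decreasing = TRUE)
  lab_sorted <- labels[ord]
  sc_sorted <- scores[ord]
  # cumulative counts at each distinct threshold
  last_of_tie <- c(diff(sc_sorted) != 0, TRUE)
  tp <- cumsum(lab_sorted)[last_of_tie]
  fp <- cumsum(!lab_sorted)[last_of_tie]
  curve <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))

  structure(list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg),
            class = "rsvp_roc")
}

#' @export
print.rsvp_roc <- function(x, ...) {
  cat(sprintf("<rsvp_roc> AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.rsvp_roc <- function(x, ...) {
  graphics::plot(x$curve$fpr, x$curve$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Grouped, stratified k-fold cross-validation of the detection pipeline
#'
#' Images (not epochs) are assigned to folds -- all stream presentations of
#' one image share a fold, preventing leakage of an image's other-stream
#' epochs into training -- with the target/nontarget ratio balanced across
#' folds. In each fold a classifier is fitted on the training epochs of all
#' streams, the held-out epochs are scored, the scores are fused per image
#' at each fusion level (left only; left+right; left+right+bottom, as
#' available), and the per-image AUC is recorded.
#'
#' @param epochs An `epoch_set` (post-stimulus, baseline-corrected).
#' @param method `"hdca"` or `"swlda"`.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param grouped Assign whole images to folds (default `TRUE`);
#'   `FALSE` reverts to plain epoch-level folds.
#' @param ... Extra arguments to the fitting function ([hdca()] or, for
#'   SWLDA, [build_feature_vectors()]/[swlda()] arguments
#'   `points_per_channel`, `channels_used`, `p_enter`, `p_remove`,
#'   `max_features`).
#' @return An object of class `rsvp_cv`: `fold_aucs` (k x levels matrix,
#'   columns `single`/`dual`/`triple` as available), `mean_auc`,
#'   `fold_of_image`, `method`, `k`, `seed`, and `scores` (per image and
#'   stream, scored while held out).
#' @export
kfold_cv <- function(epochs, method = c("hdca", "swlda"), k = 10, seed = 1L,
                     grouped = TRUE, ...) {
  stopifnot(inherits(epochs, "epoch_set"))
  method <- match.arg(method)
  k <- check_count(k, "k", 2L)

  ids <- epochs$image_ids
  labs <- epochs$labels
  img <- unique(data.frame(image_id = ids, label = labs))
  if (any(duplicated(img$image_id))) stopf("inconsistent labels per image id")
  n_tar <- sum(img$label); n_non <- sum(!img$label)
  if (min(n_tar, n_non) < k) {
    stopf("cannot stratify %d folds with %d targets and %d nontargets",
          k, n_tar, n_non)
  }

  fold_of_image <- with_seed(seed, {
    f <- integer(nrow(img))
    for (cls in c(TRUE, FALSE)) {
      idx <- which(img$label == cls)
      f[idx[sample.int(length(idx))]] <-
        rep_len(seq_len(k), length(idx))
    }
    f
  })
  fold_of_epoch <- if (grouped) {
    fold_of_image[match(ids, img$image_id)]
  } else {
    with_seed(seed, {
      f <- integer(length(ids))
      for (cls in c(TRUE, FALSE)) {
        idx <- which(labs == cls)
        f[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
      }
      f
    })
  }

  streams_present <- intersect(STREAM_LEVELS,
                               unique(as.character(epochs$stream_ids)))
  levels_avail <- seq_along(streams_present)
  level_names <- c("single", "dual", "triple")[levels_avail]

  dots <- list(...)
  feat_args <- dots[intersect(names(dots),
                              c("points_per_channel", "channels_used"))]
  swlda_args <- dots[intersect(names(dots),
                               c("p_enter", "p_remove", "max_features"))]
  hdca_args <- dots[intersect(names(dots), c("window_s", "ridge"))]

  features <- NULL
  U_all <- NULL
  if (method == "swlda") {
    features <- do.call(build_feature_vectors, c(list(epochs), feat_args))
  } else {
    # window means are fold-independent; compute once
    ws <- if (!is.null(hdca_args$window_s)) hdca_args$window_s else 0.025
    hd <- hdca_dims(dim(epochs$data)[3], epochs$fs_hz, ws)
    U_all <- window_means(epochs$data, hd$N, hd$K)
    ridge <- if (!is.null(hdca_args$ridge)) hdca_args$ridge else 0.01
  }

  fold_aucs <- matrix(NA_real_, nrow = k, ncol = length(level_names),
                      dimnames = list(NULL, level_names))
  all_scores <- vector("list", k)
  for (fold in seq_len(k)) {
    test <- fold_of_epoch == fold
    if (method == "hdca") {
      fit <- hdca_fit_core(U_all[!test, , , drop = FALSE], labs[!test], ridge)
      Y <- window_scores_from_means(U_all[test, , , drop = FALSE],
                                    fit$spatial_weights)
      Z <- sweep(sweep(Y, 2, fit$score_mean), 2, fit$score_sd, "/")
      sc <- as.numeric(fit$intercept + Z %*% fit$temporal_weights)
    } else {
      fit <- do.call(swlda, c(list(features[!test, , drop = FALSE],
                                   labs[!test]), swlda_args))
      sc <- swlda_score(fit, features[test, , drop = FALSE])
    }
    df <- data.frame(image_id = ids[test],
                     stream = as.character(epochs$stream_ids[test]),
                     score = sc, label = labs[test], fold = fold)
    all_scores[[fold]] <- df
    for (l in levels_avail) {
      keep <- df$stream %in% streams_present[seq_len(l)]
      st <- fuse_scores(df[keep, ])
      fold_aucs[fold, l] <- roc_auc(st$fused_score, st$label)$auc
    }
  }

  structure(list(fold_aucs = fold_aucs,
                 mean_auc = colMeans(fold_aucs),
                 fold_of_image = stats::setNames(fold_of_image, img$image_id),
                 scores = do.call(rbind, all_scores),
                 method = method, k = k, seed = as.integer(seed),
                 grouped = grouped),
            class = "rsvp_cv")
}

#' @export
print.rsvp_cv <- function(x, ...) {
  cat(sprintf("<rsvp_cv> %s, %d-fold (seed %d, %s)\n", x$method, x$k, x$seed,
              if (x$grouped) "grouped by image" else "epoch-level folds"))
  for (nm in colnames(x$fold_aucs)) {
    cat(sprintf("  %-6s mean AUC %.4f (sd %.4f)\n", nm, mean(x$fold_aucs[, nm]),
                sd(x$fold_aucs[, nm])))
  }
  invisible(x)
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired samples. Zero differences are
#' dropped; |differences| are midranked, and for n <= 25 retained pairs the
#' p-value comes from the exact permutation distribution of the positive
#' rank sum (computed by convolution, so ties are handled exactly); larger n
#' uses the normal approximation with tie correction.
#'
#' @param a,b Equal-length paired numeric vectors (e.g. per-subject AUCs
#'   under two paradigms).
#' @return An object of class `htest` with the positive rank-sum statistic
#'   `V` and the two-sided p-value.
#' @examples
#' a <- c(0.88, 0.79, 0.90, 0.89, 0.88, 0.86, 0.92, 0.91)
#' paired_wilcoxon(a + 0.03, a)$p.value  # 0.0078125 = 2/2^7
#' @export
paired_wilcoxon <- function(a, b) {
  if (length(a) != length(b)) stopf("`a` and `b` must have equal length")
  if (length(a) < 5L) stopf("need at least 5 pairs")
  d <- as.numeric(a) - as.numeric(b)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stopf("degenerate data: all paired differences are zero")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 25L) {
    p <- exact_signed_rank_p(r, V)
    method <- "Exact Wilcoxon signed rank test (midranks)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "Wilcoxon signed rank test (normal approximation)"
  }
  structure(list(statistic = c(V = V), p.value = p, method = method,
                 data.name = "a vs b", n = n),
            class = "htest")
}

# Exact distribution of the positive rank sum with (mid)ranks r: convolve
# the generating polynomial prod_i (1 + z^{2 r_i}) on the doubled-rank
# integer grid, then take the two-sided tail at the observed statistic.
exact_signed_rank_p <- function(r, V) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  counts <- numeric(total + 1L)   # counts[w + 1] = #assignments with sum w
  counts[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), counts[seq_len(total + 1L - ri)])
    counts <- counts + shifted
  }
  probs <- counts / sum(counts)
  v2 <- as.integer(round(2 * V))
  lower <- sum(probs[seq_len(v2 + 1L)])               # P(W2 <= v2)
  upper <- sum(probs[(v2 + 1L):(total + 1L)])         # P(W2 >= v2)
  min(1, 2 * min(lower, upper))
}
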
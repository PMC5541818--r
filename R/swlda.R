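# Stepwise linear discriminant analysis (SWLDA).
#
# Epochs are decimated to a fixed number of points per channel and the
# channels concatenated into one feature vector (14 channels x 60 points =
# 840 features for the canonical 1000 ms / 600 Hz epochs). Class labels are
# regressed on the features by least squares; features enter the
# discriminant one at a time (most significant first, forward entry at
# p < p_enter) and after every entry any retained feature whose partial-F
# p-value has risen above p_remove is dropped (backward removal), until the
# selection stabilises or max_features is reached.

#' Build decimated, concatenated feature vectors from an epoch set
#'
#' Each channel's epoch is reduced to `points_per_channel` values and the
#' channels are concatenated (channel-major order). Default reduction is
#' non-overlapping block means; `method = "subsample"` keeps every j-th
#' sample instead.
#'
#' @param epochs An `epoch_set` (cropped to post-stimulus samples).
#' @param points_per_channel Points kept per channel (default 60); the epoch
#'   sample count must be divisible by it.
#' @param channels_used Channel labels or indices to include. Default: all
#'   channels except `Fp1`/`Fp2` when the standard 16-channel montage is
#'   present (14 channels), otherwise all channels.
#' @param method `"blockmean"` (default) or `"subsample"`.
#' @return Numeric matrix, epochs x (channels x points), with attributes
#'   `channels_used` and `points_per_channel`.
#' @examples
#' \donttest{
#' sched <- generate_schedule(n_streams = 1, n_blocks = 1,
#'                            images_per_block = 60, targets_per_block = 6,
#'                            min_target_gap_frames = 4, seed = 4)
#' ep <- preprocess(simulate_recording(sched, seed = 4), sched)
#' X <- build_feature_vectors(ep)
#' dim(X)  # 60 epochs x 840 features
#' }
#' @export
build_feature_vectors <- function(epochs, points_per_channel = 60,
                                  channels_used = NULL,
                                  method = c("blockmean", "subsample")) {
  stopifnot(inherits(epochs, "epoch_set"))
  method <- match.arg(method)
  points_per_channel <- check_count(points_per_channel, "points_per_channel", 1L)
  labels <- epochs$channel_labels
  if (is.null(channels_used)) {
    channels_used <- if (all(c("Fp1", "Fp2") %in% labels)) {
      setdiff(labels, c("Fp1", "Fp2"))
    } else {
      labels
    }
  }
  ch_idx <- if (is.character(channels_used)) {
    i <- match(channels_used, labels)
    if (anyNA(i)) stopf("unknown channel(s): %s",
                        paste(channels_used[is.na(i)], collapse = ", "))
    i
  } else {
    as.integer(channels_used)
  }

  d <- dim(epochs$data)
  L <- d[3]
  if (L %% points_per_channel != 0L) {
    stopf("epoch sample count (%d) is not divisible by points_per_channel (%d)",
          L, points_per_channel)
  }
  blk <- L %/% points_per_channel
  n_ep <- d[1]
  out <- matrix(0, nrow = n_ep,
                ncol = length(ch_idx) * points_per_channel)
  for (j in seq_along(ch_idx)) {
    X <- matrix(epochs$data[, ch_idx[j], ], nrow = n_ep)   # epochs x samples
    cols <- ((j - 1L) * points_per_channel + 1L):(j * points_per_channel)
    if (method == "blockmean") {
      W <- matrix(0, nrow = L, ncol = points_per_channel)
      for (p in seq_len(points_per_channel)) {
        W[((p - 1L) * blk + 1L):(p * blk), p] <- 1 / blk
      }
      out[, cols] <- X %*% W
    } else {
      out[, cols] <- X[, seq(1L, L, by = blk), drop = FALSE]
    }
  }
  attr(out, "channels_used") <- labels[ch_idx]
  attr(out, "points_per_channel") <- points_per_channel
  out
}

#' Fit a stepwise linear discriminant (SWLDA) model
#'
#' Forward-entry/backward-removal feature selection on a least-squares
#' regression of the 0/1 class labels. Entry: the candidate with the
#' smallest partial-F p-value joins if p < `p_enter`. Removal: after each
#' entry, any retained feature with p > `p_remove` is dropped (largest p
#' first). Ties break to the lowest feature index, so the fit is
#' bit-for-bit reproducible.
#'
#' @param features Numeric matrix (epochs x features), e.g. from
#'   [build_feature_vectors()].
#' @param labels Logical (or 0/1) target labels, both classes present.
#' @param p_enter,p_remove Entry/removal p-value thresholds (defaults 0.10
#'   and 0.15, the established P300-speller convention).
#' @param max_features Cap on the number of retained features (default 60).
#' @return An object of class `swlda`: `selected` (feature indices in entry
#'   order as retained at termination), `weights`, `intercept`, p-values of
#'   the retained features, and the configuration.
#' @export
swlda <- function(features, labels, p_enter = 0.10, p_remove = 0.15,
                  max_features = 60) {
  if (!is.matrix(features) || !is.numeric(features)) {
    stopf("`features` must be a numeric matrix")
  }
  if (any(!is.finite(features))) stopf("`features` must be finite")
  y <- as.numeric(as.logical(labels))
  if (length(y) != nrow(features)) stopf("labels/features length mismatch")
  if (length(unique(y)) < 2L) stopf("both classes must be present")
  check_scalar_number(p_enter, "p_enter", 0, 1)
  check_scalar_number(p_remove, "p_remove", 0, 1)
  max_features <- check_count(max_features, "max_features", 1L)

  n <- nrow(features)
  p_all <- ncol(features)
  variances <- apply(features, 2, var)
  usable <- variances > .Machine$double.eps
  if (!any(usable)) stopf("all feature columns have zero variance")
  if (!all(usable)) {
    warnf("skipping %d zero-variance feature column(s)", sum(!usable))
  }

  selected <- integer(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 10L * max_features + 10L) {
      warnf("stepwise selection did not stabilise; stopping at %d features",
            length(selected))
      break
    }
    changed <- FALSE
    # ---- forward entry
    if (length(selected) < max_features) {
      cand <- setdiff(which(usable), selected)
      if (length(cand) > 0) {
        pv <- forward_pvalues(features, y, selected, cand)
        j <- which.min(pv)                 # which.min takes the lowest index on ties
        if (is.finite(pv[j]) && pv[j] < p_enter) {
          selected <- c(selected, cand[j])
          changed <- TRUE
        }
      }
    }
    # ---- backward removal
    repeat {
      if (length(selected) < 1L) break
      pv <- backward_pvalues(features, y, selected)
      worst <- which.max(pv)
      if (pv[worst] > p_remove) {
        selected <- selected[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }

  if (length(selected) > 0) {
    fit <- stats::lm.fit(cbind(1, features[, selected, drop = FALSE]), y)
    weights <- fit$coefficients[-1]
    intercept <- fit$coefficients[1]
    pvals <- backward_pvalues(features, y, selected)
  } else {
    weights <- numeric(0)
    intercept <- mean(y)
    pvals <- numeric(0)
  }

  structure(list(selected = selected,
                 weights = as.numeric(weights),
                 intercept = as.numeric(intercept),
                 p_values = pvals,
                 p_enter = p_enter, p_remove = p_remove,
                 max_features = max_features,
                 n_features_total = p_all,
                 fitted = TRUE),
            class = "swlda")
}

# Partial-F p-values for adding each candidate to the current model,
# via Frisch-Waugh residualisation against [1 | selected features].
forward_pvalues <- function(X, y, selected, cand) {
  n <- length(y)
  Q <- qr.Q(qr(cbind(1, X[, selected, drop = FALSE])))
  ry <- y - Q %*% crossprod(Q, y)
  Xc <- X[, cand, drop = FALSE]
  Xr <- Xc - Q %*% crossprod(Q, Xc)
  xx <- colSums(Xr^2)
  xy <- as.numeric(crossprod(Xr, ry))
  rss0 <- sum(ry^2)
  df <- n - length(selected) - 2L
  pv <- rep(Inf, length(cand))
  ok <- xx > rss0 * 1e-12 & df > 0
  ss_gain <- ifelse(ok, xy^2 / xx, 0)
  rss1 <- pmax(rss0 - ss_gain, 0)
  Fstat <- ifelse(rss1 > 0, ss_gain * df / rss1, Inf)
  pv[ok] <- pf(Fstat[ok], 1, df, lower.tail = FALSE)
  pv
}

# Partial-F p-values of each retained feature in the current model.
backward_pvalues <- function(X, y, selected) {
  Xd <- cbind(1, X[, selected, drop = FALSE])
  n <- length(y)
  k <- length(selected)
  qr_ <- qr(Xd)
  beta <- qr.coef(qr_, y)
  res <- y - Xd %*% beta
  df <- n - k - 1L
  if (df <= 0) return(rep(0, k))
  sigma2 <- sum(res^2) / df
  XtXi <- chol2inv(qr.R(qr_))
  se <- sqrt(pmax(sigma2 * diag(XtXi)[-1], .Machine$double.eps))
  tt <- beta[-1] / se
  2 * pt(abs(tt), df, lower.tail = FALSE)
}

#' Interest scores from a fitted SWLDA model
#'
#' Linear projection onto the selected features plus intercept. An empty
#' selection yields a constant score.
#'
#' @param model A fitted `swlda` model.
#' @param features Feature matrix with the same total feature count as at
#'   fit time.
#' @return Numeric vector of interest scores, one per epoch (row).
#' @export
swlda_score <- function(model, features) {
  stopifnot(inherits(model, "swlda"))
  if (!is.matrix(features)) features <- matrix(features, nrow = 1)
  if (ncol(features) != model$n_features_total) {
    stopf("feature length mismatch: model expects %d, got %d",
          model$n_features_total, ncol(features))
  }
  if (length(model$selected) == 0L) {
    return(rep(model$intercept, nrow(features)))
  }
  as.numeric(model$intercept +
               features[, model$selected, drop = FALSE] %*% model$weights)
}

#' @export
predict.swlda <- function(object, newdata, ...) swlda_score(object, newdata)

#' @export
coef.swlda <- function(object, ...) {
  c(`(Intercept)` = object$intercept,
    stats::setNames(object$weights, paste0("f", object$selected)))
}

#' @export
print.swlda <- function(x, ...) {
  cat(sprintf("<swlda> %d of %d features selected (p_enter %.2f, p_remove %.2f, max %d)\n",
              length(x$selected), x$n_features_total, x$p_enter, x$p_remove,
              x$max_features))
  if (length(x$selected) > 0) {
    show <- head(x$selected, 10)
    cat(sprintf("  features: %s%s\n", paste(show, collapse = ", "),
                if (length(x$selected) > 10) ", ..." else ""))
  }
  invisible(x)
}
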
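# Hierarchical discriminant component analysis (HDCA).
#
# The epoch is cut into K consecutive windows of T seconds (N = T * fs
# samples). Within window k a spatial filter w_k combines channels:
#
#   y_k = (1/N) * sum_n sum_i  w_ki * x_i[(k-1)N + n]
#
# i.e. the filter applied to the per-window per-channel time-average. The
# w_k are Fisher linear discriminants (target vs nontarget window means,
# shrinkage-regularised pooled covariance). The window scores are then
# combined into one interest score by logistic-regression temporal weights:
#
#   y_IS = sum_k v_k y_k
#
# With 1000 ms epochs at 600 Hz and T = 25 ms: K = 40, N = 15.

#' Fit an HDCA interest-score model
#'
#' @param epochs An `epoch_set` with both classes present and no remaining
#'   pre-stimulus samples (run [baseline_correct()] with `crop = TRUE`
#'   first).
#' @param window_s Temporal window length in seconds (default 0.025). If the
#'   epoch length is not a whole multiple of the window, the final partial
#'   window is dropped with a warning.
#' @param ridge Ridge penalty of the temporal logistic regression (fixed
#'   constant on the standardised window scores; default 0.01).
#' @return An object of class `hdca` with elements `spatial_weights`
#'   (K x channels), `temporal_weights` (length K), `intercept`, `K`, `N`,
#'   `window_s`, `fs_hz`, standardisation statistics `score_mean`/`score_sd`,
#'   and `channel_labels`.
#' @examples
#' \donttest{
#' sched <- generate_schedule(n_streams = 1, n_blocks = 1,
#'                            images_per_block = 100, targets_per_block = 10,
#'                            min_target_gap_frames = 4, seed = 3)
#' rec <- simulate_recording(sched, seed = 3)
#' ep <- preprocess(rec, sched)
#' fit <- hdca(ep)
#' fit
#' }
#' @export
hdca <- function(epochs, window_s = 0.025, ridge = 0.01) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (epochs$pre_ms > 0) {
    stopf("epochs still contain pre-stimulus samples; baseline-correct with crop = TRUE first")
  }
  labels <- epochs$labels
  if (sum(labels) < 2L || sum(!labels) < 2L) {
    stopf("need at least 2 epochs per class to fit HDCA (got %d targets, %d nontargets)",
          sum(labels), sum(!labels))
  }
  check_scalar_number(window_s, "window_s", lower = 1e-6)
  dims <- hdca_dims(dim(epochs$data)[3], epochs$fs_hz, window_s)

  U <- window_means(epochs$data, dims$N, dims$K)     # epochs x channels x K
  fit <- hdca_fit_core(U, labels, ridge)

  structure(c(fit,
              list(window_s = window_s, N = dims$N, K = dims$K,
                   fs_hz = epochs$fs_hz, ridge = ridge,
                   channel_labels = epochs$channel_labels,
                   fitted = TRUE)),
            class = "hdca")
}

hdca_dims <- function(n_samples, fs_hz, window_s) {
  N <- window_s * fs_hz
  if (abs(N - round(N)) > 1e-9) {
    stopf("window_s x fs_hz must be a whole number of samples (got %g)", N)
  }
  N <- as.integer(round(N))
  K <- n_samples %/% N
  if (K < 1L) stopf("epoch shorter than one window")
  if (K * N < n_samples) {
    warnf("epoch length %d is not a multiple of the %d-sample window; dropping the final %d sample(s)",
          n_samples, N, n_samples - K * N)
  }
  list(N = N, K = K)
}

# Per-window per-channel time-averages via one matrix product.
# data: epochs x channels x samples -> epochs x channels x K
window_means <- function(data, N, K) {
  d <- dim(data)
  M <- matrix(data, nrow = d[1] * d[2])          # (epochs*channels) x samples
  W <- matrix(0, nrow = d[3], ncol = K)
  for (k in seq_len(K)) W[((k - 1L) * N + 1L):(k * N), k] <- 1 / N
  array(M %*% W, dim = c(d[1], d[2], K))
}

# Fit spatial FLDs and temporal logistic weights from window means.
hdca_fit_core <- function(U, labels, ridge = 0.01) {
  d <- dim(U)
  n_ch <- d[2]; K <- d[3]
  Wsp <- matrix(0, nrow = K, ncol = n_ch)
  for (k in seq_len(K)) {
    X <- U[, , k, drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, ncol = n_ch)
    Wsp[k, ] <- fld_direction(X, labels)
  }
  Y <- window_scores_from_means(U, Wsp)           # epochs x K
  # orientation convention: targets score higher in every window
  flip <- colMeans(Y[labels, , drop = FALSE]) <
    colMeans(Y[!labels, , drop = FALSE])
  if (any(flip)) {
    Wsp[flip, ] <- -Wsp[flip, ]
    Y[, flip] <- -Y[, flip]
  }
  mu <- colMeans(Y)
  sdv <- apply(Y, 2, sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(Y, 2, mu), 2, sdv, "/")
  co <- logistic_ridge(Z, labels, lambda = ridge)
  list(spatial_weights = Wsp,
       temporal_weights = co$beta,
       intercept = co$intercept,
       score_mean = mu,
       score_sd = sdv)
}

window_scores_from_means <- function(U, Wsp) {
  d <- dim(U)
  Y <- matrix(0, nrow = d[1], ncol = d[3])
  for (k in seq_len(d[3])) {
    X <- matrix(U[, , k], nrow = d[1])
    Y[, k] <- X %*% Wsp[k, ]
  }
  Y
}

# Fisher discriminant direction with Ledoit-Wolf-style shrinkage of the
# pooled within-class covariance toward a scaled identity.
fld_direction <- function(X, labels) {
  m1 <- colMeans(X[labels, , drop = FALSE])
  m0 <- colMeans(X[!labels, , drop = FALSE])
  Xc <- X
  Xc[labels, ] <- sweep(X[labels, , drop = FALSE], 2, m1)
  Xc[!labels, ] <- sweep(X[!labels, , drop = FALSE], 2, m0)
  S <- shrink_covariance(Xc)
  as.numeric(solve(S, m1 - m0))
}

# Ledoit-Wolf (2004) shrinkage toward mu*I, computed from centred rows.
# Uses ||x x' - S||_F^2 = (x'x)^2 - 2 x'Sx + ||S||_F^2 to stay vectorised.
shrink_covariance <- function(Xc) {
  n <- nrow(Xc); p <- ncol(Xc)
  S <- crossprod(Xc) / n
  mu <- sum(diag(S)) / p
  D <- S - diag(mu, p)
  d2 <- sum(D * D) / p
  if (d2 < .Machine$double.eps) return(diag(mu, p))
  cp <- rowSums(Xc^2)
  q <- rowSums((Xc %*% S) * Xc)
  b_bar2 <- sum(cp^2 - 2 * q) / (n^2 * p) + sum(S * S) / (n * p)
  b2 <- min(max(b_bar2, 0), d2)
  rho <- b2 / d2
  rho * diag(mu, p) + (1 - rho) * S
}

#' Window scores for an epoch set under a fitted HDCA model
#'
#' Evaluates `y_k = (1/N) sum_n sum_i w_ki x_i[(k-1)N + n]` for every epoch
#' and window: the spatial filters applied to raw per-window time-averages
#' (no standardisation).
#'
#' @param model A fitted `hdca` model.
#' @param epochs An `epoch_set` with matching channel count.
#' @return Numeric matrix, epochs x K.
#' @export
hdca_window_scores <- function(model, epochs) {
  stopifnot(inherits(model, "hdca"), inherits(epochs, "epoch_set"))
  if (dim(epochs$data)[2] != ncol(model$spatial_weights)) {
    stopf("channel count mismatch: model has %d, epochs have %d",
          ncol(model$spatial_weights), dim(epochs$data)[2])
  }
  n_samples <- dim(epochs$data)[3]
  if (n_samples < model$K * model$N) {
    stopf("epochs provide %d samples but the model needs K x N = %d x %d",
          n_samples, model$K, model$N)
  }
  U <- window_means(epochs$data, model$N, model$K)
  window_scores_from_means(U, model$spatial_weights)
}

#' Per-epoch interest scores under a fitted HDCA model
#'
#' The temporal combination `y_IS = sum_k v_k y_k` (plus the logistic
#' intercept), with the window scores standardised by the training-set
#' statistics stored in the model.
#'
#' @param model A fitted `hdca` model.
#' @param epochs An `epoch_set`.
#' @return Numeric vector of interest scores, one per epoch.
#' @export
hdca_score <- function(model, epochs) {
  Y <- hdca_window_scores(model, epochs)
  Z <- sweep(sweep(Y, 2, model$score_mean), 2, model$score_sd, "/")
  as.numeric(model$intercept + Z %*% model$temporal_weights)
}

#' @export
predict.hdca <- function(object, newdata, type = c("score", "windows"), ...) {
  type <- match.arg(type)
  switch(type,
         score = hdca_score(object, newdata),
         windows = hdca_window_scores(object, newdata))
}

#' @export
coef.hdca <- function(object, ...) {
  list(spatial_weights = object$spatial_weights,
       temporal_weights = object$temporal_weights,
       intercept = object$intercept)
}

#' @export
print.hdca <- function(x, ...) {
  cat(sprintf("<hdca> K = %d windows of %g ms (N = %d samples @ %g Hz), %d channels\n",
              x$K, x$window_s * 1000, x$N, x$fs_hz,
              ncol(x$spatial_weights)))
  top <- order(abs(x$temporal_weights), decreasing = TRUE)[1:min(3, x$K)]
  cat(sprintf("  largest |temporal weights| at windows %s (t = %s ms)\n",
              paste(top, collapse = ", "),
              paste(round((top - 0.5) * x$window_s * 1000), collapse = ", ")))
  invisible(x)
}

# Ridge-penalised logistic regression by iteratively reweighted least
# squares; the intercept is unpenalised. Deterministic.
logistic_ridge <- function(X, y, lambda = 0.01, max_iter = 100, tol = 1e-9) {
  n <- nrow(X); p <- ncol(X)
  Xd <- cbind(1, X)
  pen <- diag(c(0, rep(lambda, p)))
  beta <- numeric(p + 1)
  yy <- as.numeric(y)
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xd, Xd * w) + pen
    g <- crossprod(Xd, yy - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  list(intercept = beta[1], beta = beta[-1])
}
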
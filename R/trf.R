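#' Preprocess a recording for TRF estimation
#'
#' Anti-aliased low-pass at `lowpass_hz` (default 45 Hz), FFT resampling
#' to `target_sfreq` (default 100 Hz), and channelwise z-scoring — the
#' standard memory- and conditioning-friendly preparation for lagged
#' regression models.
#'
#' @param rec a [ts_recording()] with `sfreq >= 100`.
#' @param target_sfreq output sampling rate, Hz.
#' @param lowpass_hz anti-aliasing cutoff, Hz.
#' @return a [ts_recording()] at `target_sfreq`, each channel z-scored.
#' @export
preprocess_for_trf <- function(rec, target_sfreq = 100, lowpass_hz = 45) {
  stopifnot(inherits(rec, "ts_recording"))
  if (rec$sfreq < 100)
    stop_invalid("TRF preprocessing requires sfreq >= 100 Hz")
  n_new <- round(nrow(rec$data) * target_sfreq / rec$sfreq)
  X <- apply(rec$data, 2L, function(x) {
    if (stats::sd(x) == 0)
      stop_invalid("zero-variance channel in TRF preprocessing")
    if (lowpass_hz < rec$sfreq / 2)
      x <- fir_filter(x, lowpass_hz, rec$sfreq, "low")
    zscore(resample_fft(x, n_new))
  })
  ts_recording(X, sfreq = target_sfreq, roles = rec$roles,
               channel_names = rec$channel_names)
}

# Hamming-bump lag basis over [lag_min, lag_max] samples.
# Bumps of `width_s` seconds at 50% overlap; returns lags x n_basis.
hamming_lag_basis <- function(lag_min, lag_max, sfreq, width_s = 0.05,
                              overlap = 0.5) {
  lags <- lag_min:lag_max
  w <- max(3L, round(width_s * sfreq))
  if (w %% 2L == 0L) w <- w + 1L
  step <- max(1L, round(w * (1 - overlap)))
  centers <- seq(lag_min, lag_max, by = step)
  half <- (w - 1L) %/% 2L
  B <- vapply(centers, function(c0) {
    v <- numeric(length(lags))
    idx <- which(lags >= c0 - half & lags <= c0 + half)
    k <- lags[idx] - (c0 - half)
    v[idx] <- 0.54 - 0.46 * cos(2 * pi * k / (w - 1L))
    v
  }, numeric(length(lags)))
  list(basis = B, lags = lags, centers = centers)
}

# lagged design matrix in the bump basis: column j = sum over lags of
# basis[l, j] * x shifted by lags[l]; rows with out-of-range lags dropped
lagged_design <- function(X, lags, basis) {
  X <- as.matrix(X)
  n <- nrow(X)
  lmin <- min(lags); lmax <- max(lags)
  valid <- (1 + max(0, lmax)):(n + min(0, lmin))
  nb <- ncol(basis)
  D <- matrix(0, length(valid), ncol(X) * nb)
  for (p in seq_len(ncol(X))) {
    lag_mat <- vapply(lags, function(l) X[valid - l, p],
                      numeric(length(valid)))
    D[, ((p - 1) * nb + 1):(p * nb)] <- lag_mat %*% basis
  }
  list(D = D, valid = valid)
}

ridge_solve <- function(D, Y, lambda) {
  G <- crossprod(D)
  diag(G) <- diag(G) + lambda
  solve(G, crossprod(D, Y))
}

#' Fit a temporal response function by nested cross-validated ridge
#'
#' Models `y_t = sum_tau h_tau x_(t-tau)` over an integration window
#' (default -250..250 ms) with the kernel expressed in a basis of 50 ms
#' Hamming windows at 50% overlap. The ridge penalty is selected by
#' four-fold nested cross-validation on contiguous time blocks: in each
#' rotation two folds train, one validates (lambda choice), and one
#' tests; every fold serves as test exactly once. Accuracy is the
#' Pearson correlation between prediction and held-out test data,
#' averaged over rotations. `direction = "forward"` encodes (stimulus
#' `x` to multichannel response `y`); `"backward"` decodes (multichannel
#' `x` to source `y`).
#'
#' @param x stimulus signal(s): vector or samples x channels matrix.
#' @param y response signal(s): vector or samples x channels matrix.
#' @param sfreq sampling rate of both, Hz.
#' @param direction `"forward"` or `"backward"` (label only: `x` always
#'   predicts `y`).
#' @param lambdas ridge penalty grid.
#' @param lag_window integration window in seconds, `(min, max)`.
#' @param n_folds folds (contiguous blocks), default 4.
#' @param basis_width_s Hamming bump width, seconds.
#' @return An object of class `trf_model`: `weights` (basis
#'   coefficients), `kernel` (per-lag weights, lags x inputs x outputs
#'   collapsed to a matrix per output), `lags_ms`, `accuracy_r` (per
#'   output), `lambda_selected` (per rotation), `direction`, `folds`.
#' @export
fit_trf <- function(x, y, sfreq, direction = c("forward", "backward"),
                    lambdas = 10^seq(-3, 3, by = 1),
                    lag_window = c(-0.25, 0.25), n_folds = 4,
                    basis_width_s = 0.05) {
  direction <- match.arg(direction)
  X <- as.matrix(x); Y <- as.matrix(y)
  if (nrow(X) != nrow(Y))
    stop_invalid("x and y must have equal length")
  if (any(apply(X, 2, stats::sd) == 0) || any(apply(Y, 2, stats::sd) == 0))
    stop_invalid("zero-variance signal in TRF design")
  lag_min <- round(lag_window[1] * sfreq)
  lag_max <- round(lag_window[2] * sfreq)
  hb <- hamming_lag_basis(lag_min, lag_max, sfreq, basis_width_s)
  ld <- lagged_design(X, hb$lags, hb$basis)
  D <- ld$D
  Yv <- Y[ld$valid, , drop = FALSE]
  n <- nrow(D)
  fold_id <- cut(seq_len(n), n_folds, labels = FALSE)
  acc <- matrix(NA_real_, n_folds, ncol(Yv))
  lambda_sel <- numeric(n_folds)
  W_acc <- 0
  for (test_f in seq_len(n_folds)) {
    val_f <- test_f %% n_folds + 1L
    train <- !(fold_id %in% c(test_f, val_f))
    Dtr <- D[train, , drop = FALSE]; Ytr <- Yv[train, , drop = FALSE]
    Dva <- D[fold_id == val_f, , drop = FALSE]
    Yva <- Yv[fold_id == val_f, , drop = FALSE]
    best <- NULL
    for (lam in lambdas) {
      W <- ridge_solve(Dtr, Ytr, lam)
      pred <- Dva %*% W
      r <- mean(diag(stats::cor(pred, Yva)), na.rm = TRUE)
      if (is.null(best) || (is.finite(r) && r > best$r))
        best <- list(r = r, lam = lam, W = W)
    }
    lambda_sel[test_f] <- best$lam
    Dte <- D[fold_id == test_f, , drop = FALSE]
    Yte <- Yv[fold_id == test_f, , drop = FALSE]
    pred <- Dte %*% best$W
    acc[test_f, ] <- diag(stats::cor(pred, Yte))
    W_acc <- W_acc + best$W / n_folds
  }
  nb <- ncol(hb$basis)
  n_in <- ncol(X)
  # expand basis weights to per-lag kernels, averaged over inputs -> one
  # lags x outputs kernel matrix (plus the full array for completeness)
  kern_arr <- array(0, c(length(hb$lags), n_in, ncol(Yv)))
  for (p in seq_len(n_in))
    kern_arr[, p, ] <- hb$basis %*%
      W_acc[((p - 1) * nb + 1):(p * nb), , drop = FALSE]
  structure(list(
    weights = W_acc, kernel = kern_arr,
    lags_ms = hb$lags / sfreq * 1000,
    accuracy_r = colMeans(acc), accuracy_by_fold = acc,
    lambda_selected = lambda_sel, direction = direction,
    n_inputs = n_in, n_outputs = ncol(Yv), sfreq = sfreq),
    class = "trf_model")
}

#' @export
print.trf_model <- function(x, ...) {
  cat(sprintf(
    "<trf_model %s> %d input(s) -> %d output(s), lags %g..%g ms, mean r = %.3f\n",
    x$direction, x$n_inputs, x$n_outputs, min(x$lags_ms), max(x$lags_ms),
    mean(x$accuracy_r)))
  invisible(x)
}

#' Summarize a TRF kernel across output channels
#'
#' Root-mean-square of the kernel across outputs per lag (sign-invariant
#' summary; its argmax is the peak lag), plus the first principal
#' component across output channels as a representative signed time
#' course. For a single-output model the RMS is `|kernel|` and the PCA
#' is skipped.
#'
#' @param trf a `trf_model` (typically forward).
#' @return list: `peak_lag_ms`, `rms` (per lag), `pc1` (per lag, or
#'   `NULL`), `lags_ms`.
#' @export
kernel_summary <- function(trf) {
  stopifnot(inherits(trf, "trf_model"))
  K <- trf$kernel
  # average over inputs (forward models have one input)
  Km <- apply(K, c(1, 3), mean)              # lags x outputs
  rms <- sqrt(rowMeans(Km^2))
  pc1 <- NULL
  if (ncol(Km) >= 2) {
    pc <- stats::prcomp(t(Km), center = TRUE, scale. = FALSE)
    pc1 <- pc$rotation[, 1] * sqrt(pc$sdev[1])
  }
  list(peak_lag_ms = trf$lags_ms[which.max(rms)], rms = rms, pc1 = pc1,
       lags_ms = trf$lags_ms)
}
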
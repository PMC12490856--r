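#' FastICA decomposition of a multichannel recording
#'
#' Blind source separation by non-Gaussianity maximization: the sensor
#' channels are centered and whitened (PCA), then rotated with the
#' symmetric (parallel) FastICA iteration using the logcosh contrast.
#' Following common practice for drift-sensitive decompositions, the
#' unmixing is FIT on a copy of the data high-pass filtered at
#' `highpass_hz` (default 1 Hz) and APPLIED to the original recording.
#' Component time courses are scaled to unit variance (sign is
#' arbitrary).
#'
#' @param rec a [ts_recording()]; only `"sensor"` channels enter the
#'   decomposition.
#' @param n_components number of components (default
#'   `min(n_channels, 50)`).
#' @param highpass_hz high-pass cutoff for the fitting copy; `NULL`
#'   skips the filter.
#' @param tol convergence tolerance on the unmixing rotation.
#' @param max_iter maximum FastICA iterations.
#' @param seed RNG seed for the random initial rotation.
#' @return An object of class `ica_decomposition`: `unmixing`
#'   (components x channels, applied to centered data), `mixing`
#'   (channels x components), `timecourses` (samples x components, unit
#'   variance), `means`, `n_components`, `n_iter`, `sfreq`.
#' @export
fit_ica <- function(rec, n_components = NULL, highpass_hz = 1,
                    tol = 1e-4, max_iter = 500, seed = 1) {
  stopifnot(inherits(rec, "ts_recording"))
  X <- channels_by_role(rec, "sensor")
  nch <- ncol(X)
  if (is.null(n_components)) n_components <- min(nch, 50L)
  if (n_components > nch)
    stop_invalid("n_components (%d) exceeds sensor channels (%d)",
                 n_components, nch)
  Xfit <- X
  if (!is.null(highpass_hz) && highpass_hz > 0)
    Xfit <- apply(X, 2L, fir_filter, cutoff = highpass_hz,
                  sfreq = rec$sfreq, type = "high")
  mu <- colMeans(Xfit)
  Xc <- sweep(Xfit, 2L, mu)
  # whitening via eigendecomposition of the covariance
  C <- crossprod(Xc) / (nrow(Xc) - 1)
  eg <- eigen(C, symmetric = TRUE)
  keep <- seq_len(n_components)
  d <- eg$values[keep]
  if (any(d <= .Machine$double.eps * max(eg$values)))
    stop_invalid("rank-deficient data: cannot whiten %d components",
                 n_components)
  K <- t(eg$vectors[, keep, drop = FALSE]) / sqrt(d)   # comps x channels
  Z <- Xc %*% t(K)                                     # whitened, n x k
  n <- nrow(Z)
  W <- with_local_seed(seed, {
    W0 <- matrix(stats::rnorm(n_components^2), n_components)
    sym_decorrelate(W0)
  })
  it <- 0L
  repeat {
    it <- it + 1L
    WX <- Z %*% t(W)                 # n x k projections
    G <- tanh(WX)                    # logcosh contrast derivative
    gp <- colMeans(1 - G^2)          # second derivative means
    W1 <- crossprod(G, Z) / n - diag(gp, n_components) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
    if (it >= max_iter)
      stop(sprintf(
        "FastICA did not converge after %d iterations (last delta %.2e)",
        max_iter, delta), call. = FALSE)
  }
  unmix <- W %*% K                   # components x channels (centered data)
  # apply to the ORIGINAL (unfiltered) sensor data
  mu_orig <- colMeans(X)
  S <- sweep(X, 2L, mu_orig) %*% t(unmix)
  sdS <- apply(S, 2L, stats::sd)
  sdS[sdS == 0] <- 1
  S <- sweep(S, 2L, sdS, "/")
  unmix <- unmix / sdS
  mixing <- mpinv(unmix)             # channels x components
  structure(list(unmixing = unmix, mixing = mixing, timecourses = S,
                 means = mu_orig, n_components = n_components,
                 n_iter = it, sfreq = rec$sfreq),
            class = "ica_decomposition")
}

sym_decorrelate <- function(W) {
  sv <- eigen(W %*% t(W), symmetric = TRUE)
  sv$vectors %*% diag(1 / sqrt(pmax(sv$values, 1e-300)),
                      nrow(W)) %*% t(sv$vectors) %*% W
}

mpinv <- function(A, tol = 1e-10) {
  sv <- svd(A)
  pos <- sv$d > tol * max(sv$d)
  sv$v[, pos, drop = FALSE] %*% diag(1 / sv$d[pos], sum(pos)) %*%
    t(sv$u[, pos, drop = FALSE])
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> %d components, %d iterations\n",
              x$n_components, x$n_iter))
  invisible(x)
}

#' Label components by correlation with ECG/EOG references
#'
#' Pearson-correlates every component time course with the ECG reference
#' (and any EOG references) and labels a component `"cardiac"` when
#' `|r_ecg| > threshold_ecg` (default 0.4) and otherwise `"ocular"` when
#' `max |r_eog| > threshold_eog` (default 0.8). All components above the
#' cardiac threshold are labeled cardiac — there is no argmax
#' tie-breaking. Absolute values are used because ICA component sign is
#' arbitrary.
#'
#' @param decomp an `ica_decomposition`.
#' @param ecg_ref numeric vector, the ECG reference channel.
#' @param eog_refs optional matrix/vector of EOG reference channels.
#' @param threshold_ecg,threshold_eog correlation thresholds.
#' @return data.frame: `index`, `r_ecg`, `r_eog`, `label`.
#' @export
classify_components <- function(decomp, ecg_ref, eog_refs = NULL,
                                threshold_ecg = 0.4, threshold_eog = 0.8) {
  stopifnot(inherits(decomp, "ica_decomposition"))
  if (stats::sd(ecg_ref) == 0)
    stop_invalid("zero-variance ECG reference")
  S <- decomp$timecourses
  if (length(ecg_ref) != nrow(S))
    stop_invalid("ECG reference not time-aligned with the decomposition")
  r_ecg <- as.numeric(stats::cor(S, ecg_ref))
  r_eog <- rep(0, ncol(S))
  if (!is.null(eog_refs)) {
    eog_refs <- as.matrix(eog_refs)
    if (any(apply(eog_refs, 2L, stats::sd) == 0))
      stop_invalid("zero-variance EOG reference")
    r_eog <- apply(abs(stats::cor(S, eog_refs)), 1L, max)
  }
  label <- ifelse(abs(r_ecg) > threshold_ecg, "cardiac",
                  ifelse(abs(r_eog) > threshold_eog, "ocular", "other"))
  data.frame(index = seq_len(ncol(S)), r_ecg = r_ecg, r_eog = r_eog,
             label = label, stringsAsFactors = FALSE)
}

#' Reconstruct the three ECG-handling conditions
#'
#' Back-projects component subsets to sensor space to form the three
#' analysis conditions: `ecg_not_rejected` (ocular components removed,
#' cardiac kept), `ecg_rejected` (ocular and cardiac removed), and
#' `ecg_components` (cardiac components only). By linearity,
#' `ecg_rejected + ecg_components` equals `ecg_not_rejected` channelwise
#' (the channel mean, removed before unmixing, is restored to the first
#' two conditions only).
#'
#' @param rec the original [ts_recording()].
#' @param decomp an `ica_decomposition` fit on `rec`.
#' @param labels data.frame from [classify_components()].
#' @return list of class `condition_set` with three [ts_recording()]s.
#' @export
reconstruct_conditions <- function(rec, decomp, labels) {
  stopifnot(inherits(rec, "ts_recording"),
            inherits(decomp, "ica_decomposition"))
  if (nrow(labels) != decomp$n_components)
    stop_invalid("labels must cover all %d components", decomp$n_components)
  X <- channels_by_role(rec, "sensor")
  S <- decomp$timecourses
  A <- decomp$mixing
  back <- function(idx) {
    if (!length(idx)) return(matrix(0, nrow(X), ncol(X)))
    S[, idx, drop = FALSE] %*% t(A[, idx, drop = FALSE])
  }
  cardiac <- labels$index[labels$label == "cardiac"]
  ocular <- labels$index[labels$label == "ocular"]
  keep_all <- setdiff(labels$index, ocular)
  keep_noecg <- setdiff(keep_all, cardiac)
  resid <- sweep(X, 2L, decomp$means) - back(labels$index)
  mk <- function(mat, restore_mean) {
    if (restore_mean) mat <- sweep(mat, 2L, decomp$means, "+")
    ts_recording(mat, sfreq = rec$sfreq,
                 roles = rep("sensor", ncol(mat)),
                 channel_names = colnames(X))
  }
  # residual outside the retained ICA subspace stays with the "brain" data
  structure(list(
    ecg_not_rejected = mk(back(keep_all) + resid, TRUE),
    ecg_rejected     = mk(back(keep_noecg) + resid, TRUE),
    ecg_components   = mk(back(cardiac), FALSE),
    labels = labels),
    class = "condition_set")
}

#' @export
print.condition_set <- function(x, ...) {
  cat(sprintf(
    "<condition_set> %d cardiac, %d ocular, %d other components\n",
    sum(x$labels$label == "cardiac"), sum(x$labels$label == "ocular"),
    sum(x$labels$label == "other")))
  invisible(x)
}

# ---- Riemannian geometry of SPD matrices ------------------------------

spd_sqrt_pair <- function(C) {
  eg <- eigen(C, symmetric = TRUE)
  v <- pmax(eg$values, 1e-12)
  list(half = eg$vectors %*% (sqrt(v) * t(eg$vectors)),
       inv_half = eg$vectors %*% ((1 / sqrt(v)) * t(eg$vectors)))
}

spd_logm <- function(C) {
  eg <- eigen(C, symmetric = TRUE)
  eg$vectors %*% (log(pmax(eg$values, 1e-12)) * t(eg$vectors))
}

spd_expm <- function(C) {
  eg <- eigen(C, symmetric = TRUE)
  eg$vectors %*% (exp(eg$values) * t(eg$vectors))
}

# affine-invariant Riemannian distance between SPD matrices
airm_distance <- function(A, B) {
  iah <- spd_sqrt_pair(A)$inv_half
  M <- iah %*% B %*% iah
  sqrt(sum(log(pmax(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
                    1e-12))^2))
}

# Karcher (Frechet) mean under the affine-invariant metric
riemannian_mean <- function(covs, tol = 1e-6, max_iter = 50) {
  G <- Reduce(`+`, covs) / length(covs)    # arithmetic init
  for (i in seq_len(max_iter)) {
    sp <- spd_sqrt_pair(G)
    T_ <- Reduce(`+`, lapply(covs, function(C)
      spd_logm(sp$inv_half %*% C %*% sp$inv_half))) / length(covs)
    G <- sp$half %*% spd_expm(T_) %*% sp$half
    if (sqrt(sum(T_^2)) < tol) break
  }
  (G + t(G)) / 2
}

#' Riemannian-potato epoch rejection
#'
#' Splits the recording into fixed-length epochs, computes each epoch's
#' channel covariance (ridge-regularized by a small fraction of its trace
#' if near-singular), and rejects epochs whose affine-invariant
#' Riemannian distance to the centroid (Karcher mean) covariance exceeds
#' `z_threshold` standard deviations of the distance distribution. The
#' centroid and rejection set are re-estimated `max_iter` times (default
#' 2: fit, then refit after the first rejection).
#'
#' @param rec a [ts_recording()] (sensor channels are used).
#' @param epoch_len epoch length, seconds.
#' @param z_threshold rejection threshold in SD units.
#' @param max_iter centroid re-estimation passes.
#' @return list: `kept` (epoch indices), `rejected`, `distances`
#'   (final-pass z-scores), `n_epochs`, `epoch_len`.
#' @export
riemannian_potato_reject <- function(rec, epoch_len = 2, z_threshold = 2.5,
                                     max_iter = 2) {
  stopifnot(inherits(rec, "ts_recording"))
  X <- channels_by_role(rec, "sensor")
  nper <- round(epoch_len * rec$sfreq)
  n_ep <- nrow(X) %/% nper
  if (n_ep < 10)
    stop_invalid("need at least 10 epochs (%d available)", n_ep)
  covs <- lapply(seq_len(n_ep), function(e) {
    seg <- X[((e - 1) * nper + 1):(e * nper), , drop = FALSE]
    C <- stats::cov(seg)
    # trace-scaled ridge against singular epochs
    lam <- 1e-10 * sum(diag(C)) / ncol(C)
    ev_min <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < lam * 10) C <- C + diag(max(lam, 1e-12), ncol(C))
    C
  })
  kept <- seq_len(n_ep)
  z <- rep(0, n_ep)
  for (pass in seq_len(max_iter)) {
    centroid <- riemannian_mean(covs[kept])
    d <- vapply(covs, airm_distance, numeric(1), A = centroid)
    sd_d <- stats::sd(d[kept])
    z <- if (is.finite(sd_d) && sd_d > 0) (d - mean(d[kept])) / sd_d
         else rep(0, n_ep)
    new_kept <- which(z <= z_threshold)
    if (identical(new_kept, kept)) break
    kept <- new_kept
  }
  list(kept = kept, rejected = setdiff(seq_len(n_ep), kept),
       distances = z, n_epochs = n_ep, epoch_len = epoch_len)
}
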
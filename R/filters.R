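# Minimal DSP layer: windowed-sinc FIR filters, Butterworth IIR design via
# bilinear transform, zero-phase application, and FFT-based resampling.
# These primitives back the preprocessing steps (high/low-pass copies for
# ICA and TRF, ECG cleaning, IRASA resampling).

# circular-safe FFT convolution of x with kernel h, returning the "same"
# central part (zero-phase when h is symmetric about its center)
fft_convolve_same <- function(x, h) {
  n <- length(x); m <- length(h)
  nfft <- next_pow2(n + m - 1L)
  y <- Re(stats::fft(stats::fft(c(x, rep(0, nfft - n))) *
                       stats::fft(c(h, rep(0, nfft - m))),
                     inverse = TRUE)) / nfft
  start <- (m - 1L) %/% 2L + 1L
  y[start:(start + n - 1L)]
}

# windowed-sinc FIR design (Hamming window), linear phase, odd length.
# type "low" or "high"; cutoff in Hz.
fir_design <- function(cutoff, sfreq, type = c("low", "high"),
                       n_taps = NULL) {
  type <- match.arg(type)
  fc <- cutoff / sfreq                      # normalized (cycles/sample)
  if (fc <= 0 || fc >= 0.5)
    stop_invalid("FIR cutoff must lie strictly inside (0, sfreq/2)")
  if (is.null(n_taps)) {
    # transition width ~ 25% of cutoff, Hamming needs ~3.3/df taps
    df <- max(fc * 0.25, 1e-4)
    n_taps <- ceiling(3.3 / df)
  }
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  m <- n_taps - 1L
  k <- 0:m
  arg <- k - m / 2
  h <- ifelse(arg == 0, 2 * fc, sin(2 * pi * fc * arg) / (pi * arg))
  w <- 0.54 - 0.46 * cos(2 * pi * k / m)
  h <- h * w
  h <- h / sum(h)                           # unit DC gain
  if (type == "high") {
    h <- -h
    h[m / 2 + 1] <- h[m / 2 + 1] + 1        # spectral inversion
  }
  h
}

# zero-phase FIR filter with edge reflection padding
fir_filter <- function(x, cutoff, sfreq, type = c("low", "high"),
                       n_taps = NULL) {
  type <- match.arg(type)
  h <- fir_design(cutoff, sfreq, type, n_taps)
  npad <- min(length(h), length(x) - 1L)
  xp <- c(2 * x[1] - x[(npad + 1):2], x,
          2 * x[length(x)] - x[(length(x) - 1):(length(x) - npad)])
  y <- fft_convolve_same(xp, h)
  y[(npad + 1):(npad + length(x))]
}

# Butterworth IIR design (lowpass/highpass), returns list(b, a)
butter_design <- function(order, cutoff, sfreq, type = c("low", "high")) {
  type <- match.arg(type)
  if (cutoff <= 0 || cutoff >= sfreq / 2)
    stop_invalid("Butterworth cutoff must lie strictly inside (0, sfreq/2)")
  fs2 <- 2 * sfreq
  warped <- fs2 * tan(pi * cutoff / sfreq)  # prewarped analog cutoff
  k <- seq_len(order)
  # analog lowpass prototype poles on the unit circle, left half-plane
  theta <- pi * (2 * k - 1) / (2 * order) + pi / 2
  p <- exp(1i * theta)
  if (type == "low") {
    p <- warped * p
    z <- complex(0)                         # zeros at infinity
  } else {
    p <- warped / p
    z <- rep(0 + 0i, order)                 # zeros at s = 0
  }
  # bilinear transform s -> (2fs)(z-1)/(z+1)
  pz <- (fs2 + p) / (fs2 - p)
  zz <- if (length(z)) (fs2 + z) / (fs2 - z) else complex(0)
  zz <- c(zz, rep(-1 + 0i, order - length(zz)))  # zeros at Nyquist
  a <- Re(poly_from_roots(pz))
  b <- Re(poly_from_roots(zz))
  # normalize gain: unity at DC (low) or Nyquist (high)
  zref <- if (type == "low") 1 + 0i else -1 + 0i
  num <- sum(b * zref^(seq_along(b) - 1))
  den <- sum(a * zref^(seq_along(a) - 1))
  b <- b * Re(den / num)
  list(b = b, a = a)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

iir_apply <- function(x, b, a) {
  # direct-form: convolution with b then recursion with a
  xf <- stats::filter(c(rep(0, length(b) - 1L), x), b, method = "convolution",
                      sides = 1)
  xf <- as.numeric(xf)[length(b):(length(b) + length(x) - 1L)]
  as.numeric(stats::filter(xf, -a[-1], method = "recursive"))
}

# zero-phase (forward-backward) IIR filtering with reflective padding
filtfilt_iir <- function(x, b, a) {
  npad <- min(3L * (max(length(a), length(b)) - 1L) * 10L,
              length(x) - 1L)
  xp <- c(2 * x[1] - x[(npad + 1):2], x,
          2 * x[length(x)] - x[(length(x) - 1):(length(x) - npad)])
  y <- iir_apply(xp, b, a)
  y <- rev(iir_apply(rev(y), b, a))
  y[(npad + 1):(npad + length(x))]
}

# FFT-domain resampling to n_new samples (sinc interpolation; implicit
# anti-aliasing when downsampling because the retained band is truncated)
resample_fft <- function(x, n_new) {
  n <- length(x)
  n_new <- as.integer(round(n_new))
  if (n_new == n) return(x)
  X <- stats::fft(x)
  Y <- complex(length.out = n_new)
  nkeep <- min(n, n_new)
  npos <- nkeep %/% 2L + 1L          # DC .. highest retained positive bin
  nneg <- nkeep - npos               # negative-side bins
  Y[1:npos] <- X[1:npos]
  if (nneg > 0L)
    Y[(n_new - nneg + 1L):n_new] <- X[(n - nneg + 1L):n]
  if (nkeep %% 2L == 0L && nkeep < max(n, n_new)) {
    # retained band has an unpaired Nyquist bin: keep the output Hermitian
    Y[npos] <- Re(Y[npos])
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}
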
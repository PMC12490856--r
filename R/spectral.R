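#' Power spectrum container
#'
#' @param freqs strictly increasing frequencies, Hz.
#' @param power finite positive power values, units^2/Hz.
#' @return An object of class `power_spectrum` with fields `freqs`,
#'   `power`, `resolution` (median frequency step).
#' @export
power_spectrum <- function(freqs, power) {
  if (length(freqs) != length(power))
    stop_invalid("freqs and power must have equal length")
  if (any(diff(freqs) <= 0))
    stop_invalid("freqs must be strictly increasing")
  if (any(!is.finite(power)))
    stop_invalid("power must be finite")
  structure(list(freqs = as.numeric(freqs), power = as.numeric(power),
                 resolution = stats::median(diff(freqs))),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, %.3g-%.3g Hz @ %.3g Hz resolution\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$resolution))
  invisible(x)
}

#' Welch power spectral density
#'
#' Welch's method with Hann window, 50% overlap, per-segment constant
#' detrend and mean averaging. The segment length is `sfreq / resolution`
#' samples, so `resolution` directly sets the frequency bin spacing.
#' Density scaling: the integral of the full spectrum approximates the
#' signal variance (Parseval, up to windowing loss).
#'
#' @param signal numeric vector.
#' @param sfreq sampling rate, Hz.
#' @param fmin,fmax returned frequency band, Hz.
#' @param resolution frequency resolution, Hz.
#' @return a [power_spectrum()].
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 10, by = 1/200))
#' ps <- welch_psd(x, 200, fmin = 1, fmax = 40, resolution = 0.5)
#' ps$freqs[which.max(ps$power)]
welch_psd <- function(signal, sfreq, fmin = 0.1, fmax = sfreq / 2,
                      resolution = 0.5) {
  assert_scalar_num(sfreq, "sfreq", lower = 0, strict_lower = TRUE)
  assert_scalar_num(resolution, "resolution", lower = 0, strict_lower = TRUE)
  nper <- round(sfreq / resolution)
  if (length(signal) < nper)
    stop_invalid("signal shorter than one Welch segment (%d samples)", nper)
  step <- max(1L, floor(nper / 2))
  starts <- seq(1L, length(signal) - nper + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann
  u <- sum(win^2)
  acc <- numeric(nper %/% 2 + 1)
  for (s in starts) {
    seg <- signal[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * win
    X <- stats::fft(seg)[1:(nper %/% 2 + 1)]
    acc <- acc + (Mod(X)^2) / (u * sfreq)
  }
  psd <- acc / length(starts)
  # one-sided density: double everything except DC (and Nyquist if present)
  psd[-1] <- psd[-1] * 2
  if (nper %% 2 == 0) psd[length(psd)] <- psd[length(psd)] / 2
  freqs <- seq(0, nper %/% 2) * (sfreq / nper)
  keep <- freqs >= fmin & freqs <= fmax
  if (!any(keep)) stop_invalid("no frequency bins inside [fmin, fmax]")
  power_spectrum(freqs[keep], psd[keep])
}

#' IRASA fractal/oscillatory separation
#'
#' Irregular-resampling auto-spectral analysis: for each resampling
#' factor `h` the signal is resampled by `h` and by `1/h` (FFT sinc
#' resampling, implicitly anti-aliased) and the geometric mean of the two
#' Welch spectra is taken; the fractal spectrum is the median over the
#' `hset`, and the oscillatory part is the original PSD minus the fractal
#' (it may be negative and is never clipped). Self-similar (power-law)
#' activity is invariant under this procedure while narrowband peaks are
#' displaced to `f*h` and `f/h` and removed by the median.
#'
#' @param signal numeric vector.
#' @param sfreq sampling rate, Hz.
#' @param hset resampling factors, all > 1 (a single `h = 1` is accepted
#'   as the degenerate identity used in tests).
#' @param fmin,fmax analysis band; `fmax` must not exceed
#'   `sfreq / (2 * max(hset))` so the compressed spectra still cover it.
#' @param resolution Welch resolution, Hz.
#' @return list of class `fractal_split`: `fractal` and `original`
#'   ([power_spectrum()]s), `oscillatory` (residual power vector on the
#'   same frequency grid), `hset`.
#' @export
irasa <- function(signal, sfreq, hset = seq(1.1, 1.9, by = 0.05),
                  fmin = 0.1, fmax = NULL, resolution = 0.5) {
  if (any(hset < 1) || (length(hset) > 1 && any(hset == 1)))
    stop_invalid("all resampling factors must be > 1")
  hmax <- max(hset)
  lim <- sfreq / (2 * hmax)
  if (is.null(fmax)) fmax <- lim * 0.95
  if (fmax > lim + 1e-9)
    stop_invalid("fmax must be <= sfreq / (2*max(hset)) = %.3g Hz", lim)
  orig <- welch_psd(signal, sfreq, fmin, fmax, resolution)
  n <- length(signal)
  frac_mat <- vapply(hset, function(h) {
    if (h == 1) return(orig$power)
    up <- resample_fft(signal, round(n * h))
    dn <- resample_fft(signal, round(n / h))
    # resampled series reinterpreted at the nominal sfreq: frequencies are
    # compressed/stretched by h; same segment length keeps the bin grid
    ps_up <- welch_psd(up, sfreq, fmin, fmax, resolution)
    ps_dn <- welch_psd(dn, sfreq, fmin, fmax, resolution)
    p_up <- stats::approx(ps_up$freqs, ps_up$power, orig$freqs, rule = 2)$y
    p_dn <- stats::approx(ps_dn$freqs, ps_dn$power, orig$freqs, rule = 2)$y
    sqrt(p_up * p_dn)
  }, numeric(length(orig$freqs)))
  fractal <- apply(frac_mat, 1L, stats::median)
  structure(list(fractal = power_spectrum(orig$freqs, fractal),
                 original = orig,
                 oscillatory = orig$power - fractal,
                 hset = hset),
            class = "fractal_split")
}

#' @export
print.fractal_split <- function(x, ...) {
  cat(sprintf("<fractal_split> %d bins, hset %.2f-%.2f (n=%d)\n",
              length(x$fractal$freqs), min(x$hset), max(x$hset),
              length(x$hset)))
  invisible(x)
}

#' Fit an aperiodic model to a power spectrum
#'
#' Fixed mode: ordinary least squares of `log10(power)` on
#' `log10(freq)`; the aperiodic exponent is \eqn{\chi = -slope}. Knee
#' mode: nonlinear least squares of
#' \eqn{\log_{10} P(f) = offset - \log_{10}(k + f^{\chi})}; the knee
#' frequency is \eqn{k^{1/\chi}}. The signed log-log slope `b = -chi` is
#' what enters downstream inference ("steepening" = chi increases).
#'
#' @param spectrum a [power_spectrum()] (or `fractal_split`, in which
#'   case its fractal component is fitted).
#' @param fit_range `(lo, hi)` Hz; needs >= 5 bins inside.
#' @param mode `"fixed"` or `"knee"`.
#' @return An object of class `aperiodic_model`: `mode`, `offset`,
#'   `exponent_chi`, `knee_param`, `knee_freq_hz` (knee mode),
#'   `fit_range`, `r_squared`, `mean_abs_error` (log10 units),
#'   `converged`.
#' @export
fit_aperiodic <- function(spectrum, fit_range, mode = c("fixed", "knee")) {
  mode <- match.arg(mode)
  if (inherits(spectrum, "fractal_split")) spectrum <- spectrum$fractal
  stopifnot(inherits(spectrum, "power_spectrum"))
  if (length(fit_range) != 2 || fit_range[1] >= fit_range[2])
    stop_invalid("`fit_range` must be (lo, hi) with lo < hi")
  keep <- spectrum$freqs >= fit_range[1] & spectrum$freqs <= fit_range[2]
  if (sum(keep) < 5)
    stop_invalid("need >= 5 frequency bins inside the fit range")
  f <- spectrum$freqs[keep]
  p <- spectrum$power[keep]
  if (any(p <= 0))
    stop_invalid("non-positive power inside the fit range")
  lf <- log10(f); lp <- log10(p)
  if (mode == "fixed") {
    sxx <- sum((lf - mean(lf))^2)
    slope <- sum((lf - mean(lf)) * (lp - mean(lp))) / sxx
    offset <- mean(lp) - slope * mean(lf)
    pred <- offset + slope * lf
    return(new_aperiodic_model(
      mode, offset, chi = -slope, knee = 0, fit_range = fit_range,
      resid = lp - pred, lp = lp, converged = TRUE))
  }
  # knee mode: chi initialized from a fixed fit above the putative knee
  hi_mask <- f >= max(30, stats::quantile(f, 0.5))
  if (sum(hi_mask) >= 5) {
    init_fit <- fit_aperiodic(power_spectrum(f[hi_mask], p[hi_mask]),
                              range(f[hi_mask]), "fixed")
    chi0 <- max(init_fit$exponent_chi, 0.1)
  } else chi0 <- 1
  obj <- function(par) {
    chi <- exp(par[1]); k <- exp(par[2]); off <- par[3]
    sum((lp - (off - log10(k + f^chi)))^2)
  }
  starts <- list(c(log(chi0), log(10^chi0), mean(lp) + chi0),
                 c(log(max(chi0 * 0.5, 0.05)), log(1), mean(lp)),
                 c(log(chi0 + 0.5), log(15^(chi0 + 0.5)), mean(lp) + 2))
  best <- NULL
  for (st in starts) {
    fit <- try(stats::optim(st, obj, method = "Nelder-Mead",
                            control = list(maxit = 4000, reltol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("knee fit failed in all starts", call. = FALSE)
  chi <- exp(best$par[1]); k <- exp(best$par[2]); off <- best$par[3]
  pred <- off - log10(k + f^chi)
  new_aperiodic_model(mode, off, chi = chi, knee = k,
                      fit_range = fit_range, resid = lp - pred, lp = lp,
                      converged = best$convergence == 0)
}

new_aperiodic_model <- function(mode, offset, chi, knee, fit_range,
                                resid, lp, converged) {
  ss_tot <- sum((lp - mean(lp))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else 1
  structure(list(
    mode = mode, offset = offset, exponent_chi = chi, knee_param = knee,
    knee_freq_hz = if (mode == "knee" && chi > 0) knee^(1 / chi) else NA_real_,
    fit_range = fit_range, r_squared = r2,
    mean_abs_error = mean(abs(resid)), converged = converged),
    class = "aperiodic_model")
}

#' @export
print.aperiodic_model <- function(x, ...) {
  cat(sprintf(
    "<aperiodic_model %s> chi=%.3f offset=%.3f%s r2=%.4f mae=%.4f [%g-%g Hz]%s\n",
    x$mode, x$exponent_chi, x$offset,
    if (x$mode == "knee") sprintf(" knee=%.3g (%.2f Hz)", x$knee_param,
                                  x$knee_freq_hz) else "",
    x$r_squared, x$mean_abs_error, x$fit_range[1], x$fit_range[2],
    if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Model prediction of an aperiodic fit
#'
#' @param object an `aperiodic_model`.
#' @param freqs frequencies at which to evaluate, Hz.
#' @param ... unused.
#' @return predicted `log10(power)` values.
#' @export
predict.aperiodic_model <- function(object, freqs, ...) {
  if (object$mode == "fixed")
    object$offset - object$exponent_chi * log10(freqs)
  else
    object$offset - log10(object$knee_param + freqs^object$exponent_chi)
}

#' Default settings for specparam-style spectral parametrization
#'
#' Matches the reference algorithm's conventions: peak widths bounded to
#' `[1, 6]` Hz, at most 2 peaks, minimum absolute peak height 0, relative
#' peak threshold 2 SD of the flattened spectrum, top 2.5% of residuals
#' dropped in the robust aperiodic fit.
#'
#' @param peak_width_limits `(min, max)` Gaussian full-width bounds, Hz.
#' @param max_n_peaks maximum number of peaks extracted.
#' @param min_peak_height minimum peak height, log10 units.
#' @param peak_threshold relative threshold in SD of the flattened
#'   spectrum.
#' @param robust_percentile percentile of residuals dropped before the
#'   aperiodic refit.
#' @return list of settings.
#' @export
specparam_settings <- function(peak_width_limits = c(1, 6),
                               max_n_peaks = 2,
                               min_peak_height = 0,
                               peak_threshold = 2,
                               robust_percentile = 0.025) {
  list(peak_width_limits = peak_width_limits, max_n_peaks = max_n_peaks,
       min_peak_height = min_peak_height, peak_threshold = peak_threshold,
       robust_percentile = robust_percentile)
}

#' Parametrize a spectrum into aperiodic + Gaussian peaks
#'
#' Specparam-style procedure: (1) initial aperiodic fit; (2) robust refit
#' after dropping the top residual percentile (so narrowband peaks do not
#' bias the aperiodic estimate); (3) iterative extraction of up to
#' `max_n_peaks` Gaussians from the flattened spectrum, each required to
#' exceed both `peak_threshold * SD(flattened)` and `min_peak_height`,
#' with widths clipped to the configured limits; (4) final aperiodic
#' refit on the peak-subtracted spectrum.
#'
#' @param spectrum a [power_spectrum()].
#' @param fit_range `(lo, hi)` Hz.
#' @param settings see [specparam_settings()].
#' @param mode aperiodic mode, `"fixed"` or `"knee"`.
#' @return list with `aperiodic` (an `aperiodic_model`) and `peaks`
#'   (data.frame `center`, `height`, `width` — Gaussian SD in Hz).
#' @export
parametrize_spectrum <- function(spectrum, fit_range,
                                 settings = specparam_settings(),
                                 mode = "fixed") {
  stopifnot(inherits(spectrum, "power_spectrum"))
  keep <- spectrum$freqs >= fit_range[1] & spectrum$freqs <= fit_range[2]
  f <- spectrum$freqs[keep]
  p <- spectrum$power[keep]
  if (any(p <= 0)) stop_invalid("non-positive power inside the fit range")
  sub <- power_spectrum(f, p)
  lp <- log10(p)

  robust_fit <- function(ps) {
    fit0 <- fit_aperiodic(ps, range(ps$freqs), mode)
    resid <- log10(ps$power) - predict(fit0, ps$freqs)
    thr <- stats::quantile(resid, 1 - settings$robust_percentile)
    keep_r <- resid <= thr
    if (sum(keep_r) >= 5)
      fit0 <- fit_aperiodic(power_spectrum(ps$freqs[keep_r],
                                           ps$power[keep_r]),
                            range(ps$freqs), mode)
    fit0
  }

  ap <- robust_fit(sub)
  flat <- lp - predict(ap, f)
  peaks <- data.frame(center = numeric(0), height = numeric(0),
                      width = numeric(0))
  wlim_sd <- settings$peak_width_limits / 2      # limits ~ full widths
  flat_work <- flat
  for (i in seq_len(settings$max_n_peaks)) {
    thr <- settings$peak_threshold * stats::sd(flat_work)
    imax <- which.max(flat_work)
    h <- flat_work[imax]
    if (h < thr || h < settings$min_peak_height || h <= 0) break
    # half-height width estimate around the maximum
    half <- h / 2
    li <- imax; while (li > 1 && flat_work[li] > half) li <- li - 1
    ri <- imax; while (ri < length(f) && flat_work[ri] > half) ri <- ri + 1
    fwhm <- f[ri] - f[li]
    sd_est <- max(wlim_sd[1], min(wlim_sd[2], fwhm / 2.355))
    g <- h * exp(-0.5 * ((f - f[imax]) / sd_est)^2)
    peaks <- rbind(peaks, data.frame(center = f[imax], height = h,
                                     width = sd_est))
    flat_work <- flat_work - g
  }
  if (nrow(peaks)) {
    peak_sum <- rowSums(vapply(seq_len(nrow(peaks)), function(i)
      peaks$height[i] * exp(-0.5 * ((f - peaks$center[i]) /
                                      peaks$width[i])^2),
      numeric(length(f))))
    ap <- fit_aperiodic(power_spectrum(f, 10^(lp - peak_sum)),
                        range(f), mode)
    peaks <- peaks[order(-peaks$height), , drop = FALSE]
    rownames(peaks) <- NULL
  }
  list(aperiodic = ap, peaks = peaks)
}

#' Multiverse grid of aperiodic slope fits
#'
#' Fits one aperiodic model per `(lower, upper)` frequency-range pair.
#' The default sensor grid uses lower limits 0.5 to 10 Hz in 1 Hz steps
#' and upper limits 45 to 145 Hz in 5 Hz steps (210 fits); ECG-style
#' analyses conventionally use a low (0.25-20 Hz) and a high (10-145 Hz)
#' range instead. With `method = "irasa"` one broadband fractal split is
#' computed first and each range is fitted on its fractal component; with
#' `"direct"` the ranges are fitted on the spectrum as given.
#'
#' @param x a [power_spectrum()], `fractal_split`, or raw signal vector
#'   (then `sfreq` is required and a spectrum is computed internally).
#' @param lower_limits,upper_limits numeric vectors of range bounds, Hz.
#' @param method `"direct"` (fit the given spectrum) or `"irasa"`
#'   (fit the fractal component).
#' @param mode aperiodic mode passed to [fit_aperiodic()].
#' @param sfreq sampling rate (signal input only).
#' @param resolution Welch resolution (signal input only).
#' @return data.frame with one row per grid cell: `lo_hz`, `hi_hz`,
#'   `mode`, `method`, `offset`, `exponent`, `knee`, `knee_freq`, `r2`,
#'   `mae`.
#' @export
slope_grid <- function(x,
                       lower_limits = default_meg_grid()$lower,
                       upper_limits = default_meg_grid()$upper,
                       method = c("direct", "irasa"),
                       mode = "fixed", sfreq = NULL, resolution = 0.5) {
  method <- match.arg(method)
  if (!length(lower_limits) || !length(upper_limits))
    stop_invalid("empty slope grid")
  if (max(lower_limits) >= min(upper_limits))
    stop_invalid("every lower limit must be below every upper limit")
  if (is.numeric(x) && is.null(dim(x))) {
    if (is.null(sfreq)) stop_invalid("signal input requires `sfreq`")
    x <- if (method == "irasa")
      irasa(x, sfreq, fmin = min(lower_limits),
            fmax = min(max(upper_limits), sfreq / (2 * 1.9) * 0.999),
            resolution = resolution)
    else welch_psd(x, sfreq, fmin = min(lower_limits),
                   fmax = max(upper_limits), resolution = resolution)
  }
  spec <- if (inherits(x, "fractal_split")) x$fractal else x
  stopifnot(inherits(spec, "power_spectrum"))
  grid <- expand.grid(lo_hz = lower_limits, hi_hz = upper_limits)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    lo <- grid$lo_hz[i]; hi <- min(grid$hi_hz[i], max(spec$freqs))
    fit <- fit_aperiodic(spec, c(lo, hi), mode)
    data.frame(lo_hz = grid$lo_hz[i], hi_hz = grid$hi_hz[i], mode = mode,
               method = method, offset = fit$offset,
               exponent = fit$exponent_chi, knee = fit$knee_param,
               knee_freq = fit$knee_freq_hz, r2 = fit$r_squared,
               mae = fit$mean_abs_error, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Standard multiverse frequency grids
#'
#' `default_meg_grid()`: lower limits 0.5-10 Hz in 1 Hz steps crossed
#' with upper limits 45-145 Hz in 5 Hz steps (10 x 21 = 210 cells).
#' `default_ecg_ranges()`: the low (0.25-20 Hz) and high (10-145 Hz)
#' ranges used for ECG spectra, chosen to keep the ~15 Hz spectral knee
#' out of the middle of a fitting range.
#'
#' @return list with `lower` and `upper` limit vectors
#'   (`default_ecg_ranges()`: data.frame of ranges).
#' @export
default_meg_grid <- function() {
  list(lower = seq(0.5, 10, by = 1), upper = seq(45, 145, by = 5))
}

#' @rdname default_meg_grid
#' @export
default_ecg_ranges <- function() {
  data.frame(lo_hz = c(0.25, 10), hi_hz = c(20, 145),
             band = c("low", "high"), stringsAsFactors = FALSE)
}
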
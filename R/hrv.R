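#' Clean a raw ECG trace
#'
#' High-pass at 0.5 Hz with a zero-phase order-5 Butterworth IIR filter
#' (removes baseline wander without shifting R-peak latencies), then
#' smoothing with a moving-average kernel one period of 50 Hz wide
#' (`round(sfreq / 50)` samples) to suppress powerline noise.
#'
#' @param signal raw ECG vector.
#' @param sfreq sampling rate, >= 250 Hz.
#' @param highpass_hz high-pass cutoff, Hz.
#' @param powerline_hz powerline frequency whose period sets the
#'   smoothing width.
#' @return cleaned ECG vector.
#' @export
clean_ecg <- function(signal, sfreq, highpass_hz = 0.5, powerline_hz = 50) {
  if (sfreq < 250)
    stop_invalid("ECG cleaning requires sfreq >= 250 Hz")
  ba <- butter_design(5, highpass_hz, sfreq, "high")
  y <- filtfilt_iir(signal, ba$b, ba$a)
  w <- max(1L, round(sfreq / powerline_hz))
  kern <- rep(1 / w, w)
  fft_convolve_same(y, kern)
}

#' Detect R peaks from a cleaned ECG
#'
#' QRS complexes are delimited by thresholding a smoothed
#' absolute-gradient envelope (smoothing window `smooth_s`, threshold
#' `thresh_factor` times the rolling median of the envelope); the R peak
#' is the absolute local maximum of the signal inside each
#' supra-threshold region. Regions closer than `refractory_s` to the
#' previous accepted peak are merged/skipped. Detection is invariant to
#' amplitude scaling.
#'
#' @param signal cleaned ECG vector (see [clean_ecg()]).
#' @param sfreq sampling rate, Hz.
#' @param smooth_s gradient-envelope smoothing window, seconds.
#' @param thresh_factor threshold relative to the rolling median.
#' @param median_win_s rolling-median window, seconds.
#' @param refractory_s minimum peak separation, seconds.
#' @return An object of class `rr_series`: `peak_indices` (sample
#'   positions), `rr_ms` (successive R-R intervals, ms), `sfreq`,
#'   `flagged` (intervals outside 250-3000 ms).
#' @export
detect_rpeaks <- function(signal, sfreq, smooth_s = 0.1,
                          thresh_factor = 1.5, median_win_s = 2,
                          refractory_s = 0.25) {
  if (length(signal) < 10 * sfreq)
    stop_invalid("need >= 10 s of ECG for R-peak detection")
  env <- abs(c(0, diff(signal)))
  w <- max(1L, round(smooth_s * sfreq))
  env <- fft_convolve_same(env, rep(1 / w, w))
  mw <- round(median_win_s * sfreq)
  if (mw %% 2L == 0L) mw <- mw + 1L
  roll_med <- stats::runmed(env, k = min(mw, length(env) -
                                           (1 - length(env) %% 2)),
                            endrule = "median")
  above <- env > thresh_factor * roll_med
  if (!any(above)) {
    warning("no QRS regions found")
    return(structure(list(peak_indices = integer(0), rr_ms = numeric(0),
                          sfreq = sfreq, flagged = logical(0)),
                     class = "rr_series"))
  }
  # contiguous supra-threshold runs
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  regions <- cbind(starts[r$values], ends[r$values])
  peaks <- integer(0)
  refr <- round(refractory_s * sfreq)
  for (i in seq_len(nrow(regions))) {
    seg <- regions[i, 1]:regions[i, 2]
    p <- seg[which.max(abs(signal[seg]))]
    if (length(peaks) && (p - peaks[length(peaks)]) < refr) {
      # keep the larger of the two colliding candidates
      if (abs(signal[p]) > abs(signal[peaks[length(peaks)]]))
        peaks[length(peaks)] <- p
    } else {
      peaks <- c(peaks, p)
    }
  }
  rr <- diff(peaks) / sfreq * 1000
  structure(list(peak_indices = peaks, rr_ms = rr, sfreq = sfreq,
                 flagged = rr < 250 | rr > 3000),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d peaks, mean RR %.1f ms (%d flagged)\n",
              length(x$peak_indices),
              if (length(x$rr_ms)) mean(x$rr_ms) else NA, sum(x$flagged)))
  invisible(x)
}

#' Time-domain heart-rate-variability indices
#'
#' Standard definitions on the R-R interval series: `mean_rr` (mean
#' interval, ms), `sdnn` (SD of intervals, ms), `rmssd` (root mean
#' square of successive differences, ms).
#'
#' @param rr an `rr_series` (or numeric vector of R-R intervals, ms).
#' @return named list `(mean_rr, sdnn, rmssd)`.
#' @export
hrv_time_domain <- function(rr) {
  x <- if (inherits(rr, "rr_series")) rr$rr_ms else as.numeric(rr)
  if (length(x) < 10)
    stop_invalid("need >= 10 R-R intervals")
  list(mean_rr = mean(x), sdnn = stats::sd(x),
       rmssd = sqrt(mean(diff(x)^2)))
}

#' Associate HRV indices with aperiodic slopes
#'
#' For every HRV index column and every slope column, computes a
#' standardized effect (index predicting slope) with its 94% HDI and
#' ROPE classification.
#'
#' @param indices_table data.frame: `subject_id` + one column per HRV
#'   index.
#' @param slope_table data.frame: `subject_id` + one column per slope
#'   measure.
#' @param rope ROPE bounds.
#' @param backend,seed passed to [standardized_effect()].
#' @return data.frame: `index`, `slope_measure`, `beta`, `lower`,
#'   `upper`, `category`.
#' @export
correlate_hrv_slope <- function(indices_table, slope_table,
                                rope = c(-0.1, 0.1),
                                backend = "bootstrap", seed = 1) {
  merged <- merge(indices_table, slope_table, by = "subject_id")
  idx_cols <- setdiff(names(indices_table), "subject_id")
  slope_cols <- setdiff(names(slope_table), "subject_id")
  out <- list()
  k <- 0L
  for (ic in idx_cols) for (sc in slope_cols) {
    k <- k + 1L
    est <- standardized_effect(merged[[ic]], merged[[sc]],
                               backend = backend, seed = seed + k)
    out[[k]] <- data.frame(index = ic, slope_measure = sc,
                           beta = est$beta, lower = est$lower,
                           upper = est$upper,
                           category = classify_effect(est, rope),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
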